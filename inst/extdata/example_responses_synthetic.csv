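patient_id,group,tolerance,withdrawal,larger_longer,quit_control,time_spent,phys_psych_problems,neglect_roles,hazardous_use,social_interpersonal,craving,activities_given_up
in__00001,in_clinic,1,0,1,0,0,0,1,0,1,0,0
in__00002,in_clinic,0,0,1,1,0,0,0,1,0,0,0
in__00003,in_clinic,0,0,1,0,0,0,0,0,0,0,0
in__00004,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00005,in_clinic,0,1,1,1,1,0,1,1,1,1,1
in__00006,in_clinic,1,1,1,1,1,1,0,1,1,0,1
in__00007,in_clinic,1,0,0,1,1,1,0,0,0,0,0
in__00008,in_clinic,0,0,0,0,0,0,0,0,0,1,0
in__00009,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00010,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00011,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00012,in_clinic,1,1,1,1,0,1,0,0,1,1,0
in__00013,in_clinic,1,1,1,1,0,0,0,0,1,1,1
in__00014,in_clinic,0,0,0,1,0,0,0,0,0,0,0
in__00015,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00016,in_clinic,1,0,0,0,0,1,0,0,0,0,0
in__00017,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00018,in_clinic,0,0,1,0,0,1,0,0,0,0,0
in__00019,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00020,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00021,in_clinic,1,0,0,0,1,1,1,1,0,1,1
in__00022,in_clinic,1,0,0,0,1,0,0,0,0,1,1
in__00023,in_clinic,1,0,0,0,1,0,0,0,1,1,0
in__00024,in_clinic,0,0,0,0,1,0,0,1,0,0,0
in__00025,in_clinic,0,0,0,0,0,0,0,0,0,1,0
in__00026,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00027,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00028,in_clinic,0,0,1,1,0,1,0,0,1,0,1
in__00029,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00030,in_clinic,0,0,0,0,0,0,0,0,0,0,0
onl_00001,online,0,0,0,0,0,0,0,0,0,0,0
onl_00002,online,0,0,0,0,0,0,0,0,0,0,0
onl_00003,online,0,0,1,0,0,0,0,0,0,0,0
onl_00004,online,1,0,0,0,0,1,0,0,0,1,1
onl_00005,online,0,0,1,0,0,0,0,0,0,0,0
onl_00006,online,0,0,1,0,0,1,0,0,0,0,0
onl_00007,online,0,0,1,0,0,0,0,0,0,0,0
onl_00008,online,1,0,0,0,0,0,0,0,0,0,0
onl_00009,online,0,0,0,0,0,0,0,0,0,0,0
onl_00010,online,1,0,1,0,1,0,0,0,0,0,0
onl_00011,online,0,0,0,0,0,0,0,0,0,0,0
onl_00012,online,1,0,0,0,0,0,0,0,0,0,0
onl_00013,online,1,0,1,0,0,1,0,0,0,1,0
onl_00014,online,0,0,1,1,1,1,1,1,1,1,1
onl_00015,online,0,0,0,0,0,0,0,0,0,0,0
onl_00016,online,0,0,0,0,0,0,0,0,0,1,1
onl_00017,online,1,0,0,0,0,0,0,0,0,0,0
onl_00018,online,1,1,1,0,0,1,0,0,0,0,1
onl_00019,online,1,0,1,1,0,0,0,0,0,1,0
onl_00020,online,1,1,1,1,1,1,1,0,1,1,1
onl_00021,online,1,0,0,0,0,0,0,0,0,0,0
onl_00022,online,0,0,0,0,0,0,0,0,0,0,0
onl_00023,online,0,0,0,0,0,0,0,0,0,0,0
onl_00024,online,0,0,0,0,0,0,0,0,0,0,0
onl_00025,online,0,0,0,0,0,0,0,0,0,0,0
onl_00026,online,0,0,0,0,0,0,0,0,0,0,0
onl_00027,online,0,0,1,1,1,0,1,0,0,0,1
onl_00028,online,0,0,0,0,0,0,0,0,0,0,0
onl_00029,online,1,0,0,1,0,1,0,0,1,1,0
onl_00030,online,0,0,1,0,0,0,0,0,0,0,0
in__00006,in_clinic,1,1,1,1,1,1,0,1,1,0,1
in__00011,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00018,in_clinic,0,0,1,0,0,1,0,0,0,0,0
in__00020,in_clinic,0,0,0,0,0,0,0,0,0,0,0
in__00029,in_clinic,0,0,0,0,0,0,0,0,0,0,0
onl_00004,online,1,0,0,0,0,1,0,0,0,1,1
onl_00016,online,0,0,0,0,0,0,0,0,0,1,1
onl_00028,online,0,0,0,0,0,0,0,0,0,0,0
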