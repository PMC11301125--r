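item_id,group,a,b,anchor
tolerance,in_clinic,1.46,0.99,0
withdrawal,in_clinic,2.19,1.25,0
larger_longer,in_clinic,2.18,0.52,0
quit_control,in_clinic,2.68,0.73,0
time_spent,in_clinic,2.8,0.84,1
phys_psych_problems,in_clinic,2.74,0.44,1
neglect_roles,in_clinic,3.26,1.29,1
hazardous_use,in_clinic,1.54,1.86,0
social_interpersonal,in_clinic,3.08,0.81,0
craving,in_clinic,2.51,0.68,0
activities_given_up,in_clinic,3.51,1,0
tolerance,online,,0.81,0
withdrawal,online,,,0
larger_longer,online,,0.28,0
quit_control,online,,0.87,0
time_spent,online,,,1
phys_psych_problems,online,,,1
neglect_roles,online,,,1
hazardous_use,online,,,0
social_interpersonal,online,2.65,1.07,0
craving,online,,,0
activities_given_up,online,,,0
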