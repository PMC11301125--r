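# checkdif

Measurement equivalence analysis for short dichotomous symptom
checklists compared across two modes of administration (or any two
respondent groups), built around the two-parameter logistic (2PL) item
response model.

## Who this is for

Psychometricians and health-services researchers who field the same
yes/no symptom checklist through two channels — e.g. on paper in clinic
versus remotely through an online patient portal — and need to know
whether the items, and the total scores built from them, behave the same
way in both.  The package covers the full chain: record-level data
hygiene, marginal maximum likelihood 2PL estimation, anchored
multiple-group fitting, iterative differential item functioning (DIF)
detection, expected-test-score impact curves, and DSM-5 style severity
scoring.  A synthetic-data generator reproduces the study design of a
published 11-item alcohol-use-disorder (AUD) checklist comparison, whose
final parameter set ships with the package.

## The model in brief

Each item `j` has discrimination `a_j > 0` and severity `b_j`; a
respondent at latent severity `theta` endorses it with probability

    P_j(theta) = 1 / (1 + exp(-a_j (theta - b_j)))

(logistic metric, no 1.7 constant).  Group `g` has
`theta ~ N(mu_g, sigma2_g)`, with the reference group fixed at `N(0, 1)`
and the focal group's moments freely estimated.  Estimation is
Bock–Aitkin EM over a 61-node quadrature grid; parameters may be shared
across groups or group-specific, and anchor items (shared by assertion)
identify the common metric.  DIF is detected by stepwise
likelihood-ratio testing at a Bonferroni-corrected per-item level
(`0.05 / 11 = .0045` for the 11-item checklist), and its cumulative
effect is summarized as the maximum absolute difference between the two
groups' expected-total-score curves.  The methods vignette
(`vignettes/measurement-equivalence.Rmd`) documents every numerical
choice.

## Worked example

Simulate a dataset at the published study configuration (1603 in-clinic
and 1640 online respondents, published item parameters, focal latent
`N(-0.05, 0.90)`), with some incomplete and duplicate checklists thrown
in, and run the whole pipeline:

```r
library(checkdif)

cfg <- pipeline_config(
  simulation = sim_config(seed = 7, missing_rate = 0.02,
                          duplicate_rate = 0.01),
  anchors = asc_anchors(),   # time_spent, phys_psych_problems, neglect_roles
  seed = 7)
res <- run_pipeline(cfg)
res
```

```
stage simulate: seed 7
stage filter: excluding incomplete checklists
excluded 59 incomplete checklist(s): in_clinic: 25, online: 34
stage select: one checklist per patient (seed 7)
stage dif: iterative detection at familywise alpha 0.05
iteration 1: freeing b for 'larger_longer' (joint p = 1.10e-07)
iteration 2: freeing b for 'social_interpersonal' (joint p = 2.32e-06)
iteration 3: freeing b for 'quit_control' (joint p = 4.23e-05)
stage impact: expected-score curves
stage tabulate: unadjusted severity summary
<pipeline_result>
  analyzed n: in_clinic: 1580, online: 1607 (excluded incomplete: 25/34)
  DIF: 3 flagged item(s) (larger_longer, social_interpersonal, quit_control)
  max |expected score difference| = 0.2136
```

Reading the output: incomplete checklists are excluded (counts per
group), one checklist is kept per patient, and the stepwise DIF search
frees item parameters until nothing clears the `.0045` per-item
threshold.  The three flagged items are all among the four items that
carry DIF in the generating bank; the fourth (`tolerance`, the weakest
effect) does not clear the Bonferroni threshold on this draw — items
near the detection boundary are recovered only in a fraction of
replicates.  The `max |expected score difference|` line is the headline
impact number: the largest shift in expected criteria count (out of 11)
a respondent could see from being assessed under one modality rather
than the other at equal underlying severity, here computed from the
*estimated* (refitted) parameters of this simulated dataset.

The published parameter set itself is available directly:

```r
ic <- impact_curve(asc_item_bank(), latent = asc_latent())
ic
```

```
<impact_curve> groups online vs in_clinic over theta [-4, 4] (801 nodes)
  max |expected score difference| = 0.1287 of 11 items (at theta = 1.11)
  focal-density-weighted mean |difference| = 0.0632
```

i.e. from the published final parameters, DIF shifts the expected
criteria count by at most about 0.13 of a criterion — negligible on a
0–11 scale.  `plot(ic)` draws the two nearly overlapping
expected-score curves.  `replicate_reference_analysis()` additionally
reruns the full simulate-and-detect pipeline over 12 fixed seeds and
tabulates how often each item is flagged.

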