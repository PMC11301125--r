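---
title: "Measurement equivalence of dichotomous symptom checklists: models and methods"
author: "checkdif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement equivalence of dichotomous symptom checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkdif)
```

## The problem

Short yes/no symptom checklists are increasingly administered through more
than one channel: on paper in the clinic, or remotely through an online
patient portal.  If an item behaves differently depending on how it is
administered -- if respondents at the *same* underlying severity endorse it
with different probability online than in clinic -- then total scores, and
the diagnoses built on them, are not comparable across channels.  That
phenomenon is differential item functioning (DIF).  `checkdif` implements
the full analysis chain for testing it on a two-group dichotomous
checklist and for judging whether any DIF that is found actually matters
for the total scores clinicians use.

The package ships, as both a worked replication target and a simulation
default, the published parameter set of an 11-item DSM-5 alcohol use
disorder (AUD) symptom checklist compared across online-portal and
in-clinic administration (`asc_item_bank()`).

## The measurement model

Each item follows a two-parameter logistic (2PL) item response function.
For respondent latent severity $\theta$ and item parameters $a_j > 0$
(discrimination) and $b_j$ (severity),

$$P(Y_j = 1 \mid \theta) = \frac{1}{1 + e^{-a_j(\theta - b_j)}}.$$

The logistic metric is used directly, without the historical 1.7 scaling
constant; all shipped parameter values are on this metric.  Respondents in
group $g$ have $\theta \sim N(\mu_g, \sigma^2_g)$; the reference group is
fixed at $N(0, 1)$, which defines the latent scale, and the focal group's
moments are freely estimated.

Item parameters are estimated by marginal maximum likelihood: the latent
trait is integrated out of each respondent's likelihood,

$$\ell = \sum_p \log \int \prod_j P_j(\theta)^{y_{pj}}
  \bigl(1 - P_j(\theta)\bigr)^{1 - y_{pj}} \, dF_{g(p)}(\theta),$$

with the integral approximated on a fixed grid (below) and the
maximization done by the Bock-Aitkin EM algorithm: the E-step converts
posterior probabilities of each respondent's location into expected
endorsement counts at every grid node, and the M-step refits each item's
logistic curve to those expected counts.  Identical response patterns are
collapsed before estimation, so the per-cycle cost depends on the number
of distinct patterns rather than the number of respondents.

## Numerical choices

These are the package's own choices; each is stated with its rationale
and all of them are exposed through `irt_control()`.

* **Quadrature**: 61 equally spaced nodes on $[-6, 6]$, with weights
  proportional to the group's normal density and renormalized to sum to
  one.  An equally spaced grid makes re-weighting trivial when the focal
  moments move during estimation, and at this density the log-likelihood
  agrees with a 10-times-finer grid to well below $10^{-6}$ (this is
  asserted in the test suite).
* **Convergence**: stop when the log-likelihood improves by less than
  $10^{-5}$ *and* no parameter moves by more than $10^{-4}$, with a cap
  of 500 EM cycles.  Non-convergence is always flagged on the returned
  object, never silent; with very few items the 2PL likelihood can have
  its maximum on the boundary ($a_j \to \infty$), and the flag is the
  honest outcome there.
* **Starting values**: $a_j = 1$, $b_j = 0$ for every item, focal moments
  $0/1$ -- neutral and deterministic, so a given dataset always produces
  the same fit.  Internal refits during DIF testing warm-start from the
  current model, which changes nothing about the fixed point.
* **Focal moments**: updated each cycle from the posterior mean and
  variance of $\theta$ pooled over focal respondents, then refined by a
  short direct maximization of the discretized-normal term so that every
  cycle is a true generalized-EM step (the marginal log-likelihood never
  decreases; the trace is stored on the fit and asserted in tests).
* **Standard errors**: square roots of the diagonal of the inverse
  observed information, with the information computed by central finite
  differences of the marginal log-likelihood at the estimates.  Shared
  parameters have one entry; constrained (non-free) quantities have none.
* **M-step safeguards**: probabilities are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ and the per-item searches run under wide box
  bounds ($a \in [0.05, 50]$), which only matter in degenerate
  quasi-separable configurations.

## DIF detection

DIF testing follows an anchored, iterative likelihood-ratio scheme:

1. Fit a baseline in which every item is constrained equal across groups
   and only the focal latent moments are free.  Anchor items -- items
   asserted DIF-free a priori -- stay constrained throughout and identify
   the common metric.  The shipped default anchors are the three used in
   the published comparison (`asc_anchors()`); for new data an automatic
   mode picks the $k$ items with the smallest joint DIF statistics in a
   preliminary scan.
2. Test every non-anchor item still constrained: free both of its
   parameters and compare by likelihood ratio ($2\Delta\ell$, 2 df).
3. Free the most significant item (smallest $p$; ties broken by item
   order) if it clears the Bonferroni-corrected per-item level
   $\alpha/m$.  Which parameter is freed is decided by 1-df follow-ups
   ($a$ only, $b$ only): the individually significant one(s), or both if
   only the joint test is significant.  Freeing one item per round is the
   standard stepwise purification guard against cascading false
   positives.
4. Re-test the remaining items against the updated model and repeat until
   nothing new is significant; refit once more with standard errors.

The Bonferroni divisor is the *full* item count (here 11, giving the
conventional $.05/11 = .0045$ threshold), not the non-anchor count: the
threshold is then a property of the instrument rather than of the anchor
choice.  The procedure contains no randomness, so a dataset maps to
exactly one report.

## From DIF to impact on total scores

Statistically significant DIF need not matter clinically, because
decisions are made on total scores.  The expected test score at severity
$\theta$ in group $g$ is $T_g(\theta) = \sum_j P_{jg}(\theta)$, and the
cumulative impact of DIF is summarized by
$\max_\theta \lvert T_{\text{focal}}(\theta) - T_{\text{ref}}(\theta)\rvert$
over $\theta \in [-4, 4]$ in steps of 0.01.  The $\pm 4$ range covers
more than 99.99% of both latent distributions, and the reported maximum is
stable to below $10^{-3}$ against further grid refinement.  Because the
maximum can sit in a sparsely populated region of the trait, the package
also reports a focal-density-weighted mean absolute difference as a
secondary, clearly labelled summary of the typical impact.  For the
shipped published bank the two summaries are computed by
`replicate_reference_analysis()` and by the package's acceptance script;
the vignette quotes no number that those computations do not produce.

## Severity scoring

Complete checklists are scored by their criteria count (0-11), mapped to
the DSM-5 severity convention: 0-1 no AUD, 2-3 mild, 4-5 moderate, 6-11
severe, with diagnosis at $\geq 2$ criteria.  `tabulate_severity()`
reports per-group item endorsement and severity distributions with Wilson
95% intervals -- chosen over the Wald interval for its behaviour at
boundary proportions -- plus a chi-square comparison of the severity
distributions.  The tabulation is deliberately *unadjusted*: the
covariate-adjusted prevalence modelling that a full epidemiological
report would add is ordinary logistic regression on variables the
synthetic-data module does not generate, and is out of scope here.

## The synthetic-data generator

No public dataset exists for the replication target (the source data are
protected electronic health records), so the generator stands in for it.
Its defaults *are* the published study configuration: the published
two-group item bank, 1603 in-clinic and 1640 online respondents, focal
latent $N(-0.05, 0.90)$.  Contamination -- blanking one item on a
checklist with probability `missing_rate`, duplicating a patient's
checklist with probability `duplicate_rate` -- is off by default so that
the default sample matches the published analyzed sample sizes, and is
switched on to exercise the record-level filters (`filter_complete()`,
`select_one_per_patient()`).  Missingness is applied completely at random
(MCAR), independent of severity: no missingness mechanism is published,
and MCAR is the neutral default.  Record selection among a patient's
multiple checklists is uniform and unstratified, since nothing is
published about how duplicate checklists interacted with modality.

Passing tests on these simulations show that the estimation and testing
machinery recovers known truths under the stated generative model.  They
do not show robustness to what the generator omits: demographic
covariates, severity-dependent modality self-selection, local item
dependence, or non-random missingness.

One consequence of simulating from published *point estimates* deserves
emphasis.  Items whose published group differences were modest sit near
the detection boundary of the original study; a fresh sample drawn from
those estimates re-detects them only with moderate probability, so
replicates typically flag a subset of the originally flagged items more
often than the full set.  `replicate_reference_analysis()` therefore
reports per-item flag frequencies over its 12 fixed-seed replicates
rather than a single yes/no, and the strongly differing items are the
ones recovered essentially always.

## Problem sizes used by the shipped tests

The test suite exercises full study-scale replicates (11 items,
1603 + 1640 respondents, 12 fixed seeds) for the recovery and detection
checks, and smaller instances -- three to five items, a few hundred
respondents -- where the point is a numerical property (EM versus direct
maximization, finite-difference information versus an independent
Hessian, type-I error calibration over 200 null replicates at 150
respondents per group).  These sizes are the package's chosen balance
between statistical resolution and a test suite that runs in minutes.

## Known limitations

* Two groups only; no polytomous items, no 1PL/3PL variants, no
  multidimensional traits, no Bayesian estimation.
* The DIF scheme is likelihood-ratio based; Wald-based and
  effect-size-based DIF statistics (Mantel-Haenszel, logistic-regression
  DIF) are not provided.
* With very short checklists the 2PL boundary pathology ($\hat a \to
  \infty$) is real; fits flag it via `converged = FALSE` rather than
  regularizing it away.
* The severity tabulation is descriptive; it does not adjust for
  covariates or survey design.
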