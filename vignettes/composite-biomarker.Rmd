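---
title: "A composite biomarker for drug selection in diabetic kidney disease: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A composite biomarker for drug selection in diabetic kidney disease: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkdcompass)
```

## The problem

Patients with type 2 diabetes and kidney disease (DKD) are treated with a
renin-angiotensin-system inhibitor (RASi) as baseline therapy; a GLP1
agonist, a mineralocorticoid-receptor antagonist or an SGLT2 inhibitor may
be added on top. Response is heterogeneous: most patients remain stable on
RASi alone, while a minority progress quickly and may be rescued by an
add-on. The outcome used throughout is the annual percent change in the
estimated glomerular filtration rate,

$$\Delta eGFR = 100\,\frac{eGFR_{t+1}-eGFR_t}{eGFR_t}\ \ (\%/\mathrm{yr}),$$

with controlled disease (CD) defined as a decrease of at most 5%/yr and
uncontrolled disease (UCD) as a drop of more than 10%/yr. Decreases
between 5% and 10% satisfy neither definition; we label them
*indeterminate* and exclude them from binary evaluation rather than forcing
a class. eGFR is taken from the data when present, otherwise computed with
the 4-variable MDRD study equation (IDMS-traceable constant 175 by
default; the constant is an argument). Only visits with eGFR between 30
and 90 ml/min/1.73 m² enter model building; we read that inclusion window
as closed at both ends, and by default apply it to the baseline visit of
each follow-up pair only, so that a follow-up value drifting slightly out
of range does not destroy the pair.

## The model

The prediction pipeline (`fit_plsnn()`) is a hybrid of two stages.

**PLS projection.** Clinical marker panels are strongly collinear, and
repeated visits by the same patient add further redundancy. We therefore
standardize the markers and project them onto $A$ partial-least-squares
components (PLS1, NIPALS with X-deflation). $A$ is chosen by grouped
cross-validation: folds partition *patients*, never single visits, because
pairs from the same patient are correlated and a random split would leak
information. Ties in CV error go to the smaller $A$. At $A=\mathrm{rank}(X)$
the PLS predictions coincide with ordinary least squares, which is the main
internal correctness oracle for this stage.

**Normalized RBF network.** The latent scores (plus, by default, the PLS
linear prediction as one extra coordinate, standardized like the scores)
feed a normalized Gaussian radial-basis-function network:

$$\hat y(z) = \sum_i w_i h_i(z), \qquad
  h_i(z) = \frac{\exp(-\|z-c_i\|^2/2\sigma^2)}
               {\sum_j \exp(-\|z-c_j\|^2/2\sigma^2)}.$$

Because the $h_i$ form a partition of unity, the network reproduces
constants exactly, every prediction lies in $[\min_i w_i, \max_i w_i]$, and
far from the data the prediction tends to the nearest center's weight —
conservative extrapolation behaviour that suits arms with only 50–100
pairs, where a flexible network would otherwise run wild. Centers come
from seeded k-means on the (canonically row-ordered) scores, so a refit on
permuted rows is bit-identical; the shared width is
$\sigma = \gamma \times$ median pairwise center distance; the output
weights solve a ridge least-squares problem via SVD (stable also at
$\lambda = 0$, where centers-at-all-points interpolate the data).

Feeding the linear PLS prediction to the network alongside the scores is a
deliberate resolution of an ambiguity in how the two stages compose: it
gives the network direct access to the linear fit so the radial units only
need to encode the non-linear remainder. `plsnn_control(include_linear =
FALSE)` switches to scores-only.

The prediction of the model fitted on the RASi-only arm is the **composite
biomarker** $\Delta_R$: the expected annual eGFR trend if the patient
stays on RASi alone. Models fitted the same way on the three add-on arms
give $\Delta_G$, $\Delta_M$, $\Delta_S$.

## Variable selection

`rank_variables()` orders candidate markers by VIP,

$$VIP_j = \sqrt{p\,\frac{\sum_a SS_a\,(w_{ja}/\|w_a\|)^2}{\sum_a SS_a}},$$

where $SS_a$ is the outcome sum of squares explained by component $a$.
VIP is scale-free (markers are standardized inside the fit) and normalized
so the mean squared VIP is 1. The statistic itself is a design choice —
the selection procedure we mirror names none — and ties are broken
deterministically (VIP, then $|r|$ with the outcome, then name) so reruns
are reproducible. A constant outcome makes every marker equally
uninformative; we then return equal scores in alphabetical order.

`merge_and_rerank()` implements the consensus heuristic: take the top
$k_{full}$ markers of the full candidate set and the top $k_{expert}$ of
the expert set (defaults 10 and all), pool them, re-fit PLS on the pool,
re-rank by VIP, and keep the top $m = 9$ — the size of the published
consensus panel, which ships as `reduced_panel()` alongside the expert
list `expert_panel()`.

## Counterfactual benefit and recommendation

All four arm models share the same panel. Evaluating them at one
patient's baseline markers gives the benefit of add-on $X$ as the vertical
distance $\Delta_X - \Delta_R$. `recommend_treatment()` operationalizes
the decision rule: if $\Delta_R \ge -5$ (CD predicted) the patient stays
on RASi; otherwise the add-on with the highest predicted $\Delta_X$ is
recommended provided its benefit is positive, with ties resolved in the
fixed order GLP1a, MCRa, SGLT2i. The boundary used for "negative
prognosis" is exposed as an argument (default $-5$; the UCD boundary
$-10$ is reported but deliberately not used for the decision).
`cross_predict()` quantifies the rescue pattern behind this logic: applying
the RASi-only model to add-on patients, residuals (observed minus
$\Delta_R$) are near zero where CD is predicted and grow as $\Delta_R$
falls — the lower the composite biomarker, the larger the add-on effect.

These benefits are differences between expectations of independently
fitted observational models, **not** individual causal effects; there is no
confounding adjustment, by design (see Limitations).

## The synthetic cohort

The real cohort behind this design is access-restricted, so the package
ships a generator (`generate_cohort()`) whose defaults *are* the study
conditions, with known ground truth for validation:

* **Arms and sizes.** 277 RASi-only pairs, 52 GLP1a, 64 MCRa, 104 SGLT2i.
  30% of RASi patients contribute two consecutive annual pairs (latent
  state evolving as an AR(1) with $\phi = 0.8$), exercising the grouped CV
  machinery; add-on patients contribute one pair, the drug starting after
  its baseline visit.
* **Markers.** Two latent factors drive the nine consensus markers through
  a loading matrix with marker-specific noise, then affine maps place them
  on plausible clinical scales (e.g. SBP around 140 mmHg); six pure-noise
  markers are appended. The correlations this induces (several off-diagonal
  $|r| > 0.5$) are the collinearity the PLS stage exists for. Baseline eGFR
  uses a bounded tanh map into (35, 85), so generated baselines always
  satisfy the inclusion window.
* **Outcome.** True prognosis $f(u) = a - b\,\mathrm{softplus}(c\,u_1)$
  (defaults $a=5$, $b=6$, $c=1.5$: smooth, monotone decreasing, spanning
  roughly $+5$ to $-25$ %/yr); add-on rescue
  $g_X(u) = \rho_X \max(0, -(f(u)+5))$, i.e. proportional to how far the
  RASi-only prognosis falls below the CD boundary (defaults
  $\rho = 0.6/0.5/0.7$ for GLP1a/MCRa/SGLT2i); observed
  $\Delta eGFR = f + g_{arm} + \varepsilon$ with $\varepsilon \sim N(0,
  2^2)$ %/yr. Follow-up eGFR is derived from baseline eGFR and the
  observed change. The functional forms are the package's own: the source
  design states only the qualitative pattern (rescue concentrated where
  RASi-only prognosis is poor), and these shapes make it reproducible and
  benefit recovery well-posed.
* **CD/UCD balance.** The RASi arm aims for an equal split of CD and UCD.
  Naturally UCD is rare under $f$, so whole-arm resampling until balance
  would essentially never terminate; instead candidate patients are
  accepted greedily under per-class quotas until the CD and UCD counts
  agree within 10%, with an error after 1000 consecutive rejections.
* **Indication bias.** Half of the add-on patients are drawn from the
  poor-prognosis region $f(u) < -5$ (truncated-normal first latent),
  mirroring the clinical reality that add-ons are started in progressing
  patients and giving the small arms enough sick patients for their models
  to learn the rescue region.

What the generator does **not** emulate: discrete and binary covariates
(the modelling pipeline is restricted to continuous inputs), dropout,
irregular visit spacing, measurement drift, multi-drug add-on
combinations, and real marker-outcome physiology. Passing tests therefore
demonstrate that the pipeline recovers structure *of this kind* from data
*of this size and noise level* — not that the fitted models transfer to
real cohorts.

## Numerical choices and defaults

| Parameter | Default | Why |
|---|---|---|
| PLS components $A$ | grouped CV over $1..\min(5,p,n-1)$, ties to smallest | patient-level correlation; parsimony on ties |
| RBF centers $k$ | $\min(\lceil n/3\rceil, 25)$ | a few points per center at $n \approx 50$; caps complexity at $n = 277$ |
| width scale $\gamma$ | 1.0 | kernels overlap neighbouring centers at the median spacing |
| ridge $\lambda$ | $10^{-3}$ | keeps the weight solve well-posed without visible smoothing |
| shared width | one $\sigma$ for all centers | per-center widths are unstable at the add-on arm sizes |
| annualization | linear division by interval years | intervals are protocol-fixed at 1 year; the geometric correction is second-order |
| balance tolerance | 10%, max 1000 consecutive rejections | reliable termination at the default class frequencies |
| recommendation threshold | $-5$ %/yr | the CD boundary; exposed as an argument |

Degenerate inputs are handled explicitly: zero-variance predictors are
rejected by name, a constant outcome yields the lexicographic equal-score
ranking, identical latent points make the RBF width undefined and error,
and a single center (or a constant target) collapses the network to a
constant — exactly reproducing that constant, by the partition of unity.

All randomness (cohort generation, fold assignment, k-means
initialization) flows from explicit integer seeds through a helper that
restores the caller's RNG state, so two runs of the full pipeline with the
same configuration are byte-identical, including serialized model files.

## Problem sizes used in validation

The packaged checks run the pipeline at the study conditions themselves:
the default 497-pair cohort for prognosis recovery (grouped 70/30 holdout
on the 277 RASi pairs), benefit recovery on all three add-on arms, and a
ten-seed replication of the null-arm experiment; selection recovery uses
50 replicates of a 300 x 20 design at $R^2 \approx 0.5$. These sizes were
chosen to match the scale of the emulated study.

## Known limitations

* **Null-arm bias of the benefit estimate.** With an add-on's rescue
  switched off ($\rho_X = 0$), the mean estimated benefit across the
  cohort should ideally be statistically indistinguishable from zero. The
  packaged null experiment measures a systematic offset of roughly
  +0.5 %/yr instead, and the corresponding check in the test suite
  currently fails, deliberately. Two mechanisms, both properties of the
  study design rather than of any single routine, produce it: the small
  add-on arm's bounded network saturates toward its weight range in the
  sick tail it barely samples, predicting too high exactly where the
  benefit rule looks; and balancing the RASi arm on *observed* CD/UCD
  labels selects partly on outcome noise (UCD is naturally rare), pulling
  the $\Delta_R$ model down. Individual benefit estimates should therefore
  be read against this baseline offset, and cohort-level null calibration
  should be checked before trusting small mean benefits.
* **No confounding adjustment.** Arms are observational; indication bias
  is emulated, not corrected for. Benefit is a model-expectation
  difference.
* **Continuous markers only**, single add-on at a time, one-year horizon;
  iterating predictions over multiple years would require forecasting the
  markers themselves.
* **In-sample Table-style diagnostics are optimistic.** Whether the
  original diagnostics were in-sample is not stated; the package reports
  both in-sample and grouped-CV metrics, clearly labelled, and the CV
  numbers are the ones to quote.

## A worked run

```{r pipeline, eval = FALSE}
cohort <- generate_cohort(generator_config(seed = 7))
pairs  <- build_followup_pairs(cohort$visits)
rasi   <- pairs[pairs$arm == "RASi", ]

cm     <- assemble_matrix(rasi, c(reduced_panel()$marker, paste0("NOISE", 1:6)))
full   <- rank_variables(cm$X, cm$y, groups = cm$groups, seed = 11)
expert <- rank_variables(cm$X[, c("eGFR", "AGE", "TOTCHOL", "SBP")], cm$y,
                         groups = cm$groups, seed = 11)
panel  <- merge_and_rerank(full, expert, cm$X, cm$y, groups = cm$groups, seed = 11)

mset   <- fit_treatment_models(pairs, panel, seed = 42)
est    <- estimate_benefit(mset, pairs)
rec    <- recommend_treatment(est)
plot(cross_predict(mset, pairs[pairs$arm != "RASi", ]))
```
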