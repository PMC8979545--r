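---
title: "Modeling longitudinal brain system segregation with segtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal brain system segregation with segtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segtraj)
```

## The measure

A resting-state functional brain network is a node-by-node matrix of
Fisher-z-transformed Pearson correlations between regional BOLD time
series, with each node assigned to one functional system (default,
visual, frontal–parietal control, and so on). Brain system segregation
summarizes how modular that network is:

$$S \;=\; \frac{\bar Z_w - \bar Z_b}{\bar Z_w},
\qquad
\bar Z_w = \frac{\sum_w Z_w}{W},\quad
\bar Z_b = \frac{\sum_b Z_b}{B},$$

where the within-system mean $\bar Z_w$ pools **all** $W$ within-system
edges of the whole network and $\bar Z_b$ pools all $B$ between-system
edges. We deliberately implement the pooled-edge form rather than a mean
of per-system means: the two differ whenever systems have unequal sizes,
and the pooled form is the exact computation the statistic is defined by.
The diagonal is always excluded. With all edges non-negative the value is
at most 1 (no between-system connectivity) and 0 when within- and
between-system means coincide; it is invariant to rescaling the matrix by
any positive constant, and `system_segregation()` returns the component
means and edge counts for audit. A non-positive within-system mean makes
the ratio meaningless, so it raises an error rather than returning `NaN`
— after negative-edge truncation this can only happen on pathological
input, and it should fail loudly.

## From scans to networks

`censor_frames()` implements motion scrubbing with two rules: frames with
framewise displacement above 0.3 mm are censored, and any maximal run of
retained frames that sits strictly *between* two censored frames and is
shorter than 5 frames is censored too. Runs at the scan edges are kept
regardless of length — the rule targets data sandwiched between motion
events. `select_frames()` then fixes every scan at the same number of
frames (default 100) so that differing scan lengths cannot bias network
estimates, rejecting scans that fall short with an error carrying the
retained count; the pipeline turns those errors into scan exclusions, and
participants left with fewer than two usable scans are excluded
(the motion-QC stage of the exclusion ledger).

Which 100 retained frames to use is genuinely open; we take the first 100
in temporal order, a deterministic choice we document rather than a claim
about any particular study's practice. Multi-run sessions are censored
per run and concatenated afterwards. Interpolation and bandpass filtering
belong to the upstream fMRI preprocessing layer and are out of scope
here; the package correlates retained frames only, which is a documented
fidelity gap relative to a full preprocessing chain.

`build_connectivity()` computes Pearson correlations over the selected
frames, clamps $|r|$ to $1 - 10^{-12}$ before `atanh` (so near-duplicate
node series produce large finite z rather than infinity), and truncates
negative z values to zero by default, since global-signal regression
upstream induces artifactual negative correlations. No edge-density
thresholding is applied — the segregation statistic does not need a
sparse matrix.

## The trajectory model

`fit_segregation_lmm()` fits, by REML via lme4,

$$Y_{ij} = \gamma_{00} + \gamma_{01}\,\mathrm{sex}_j + \gamma_{02}\,\mathrm{age}_j
+ \gamma_{03}\,\mathrm{edu}_j + \gamma_{04}\,\mathrm{age}_j\mathrm{edu}_j
+ \gamma_{10}\,t_{ij} + \gamma_{20}\,\mathrm{motion}_{ij}
+ \gamma_{11}\,t_{ij}\mathrm{sex}_j + \gamma_{12}\,t_{ij}\mathrm{age}_j
+ \gamma_{13}\,t_{ij}\mathrm{edu}_j + \gamma_{14}\,t_{ij}\mathrm{age}_j\mathrm{edu}_j
+ \mu_{0j} + \mu_{1j} t_{ij} + \epsilon_{ij}$$

for participant $j$ at scan $i$: exactly 11 fixed-effect terms, a
per-participant random intercept and time slope, and scan-level mean FD
as a longitudinal covariate. Design choices that were open, and how we
resolved them:

* **Time** is years since each participant's baseline scan
  (`days / 365.25`), so 0 is the baseline. "Normalized time" admits other
  readings; years are interpretable and configurable at the data layer.
* **Age** enters in years, uncentered, as the baseline value — using age
  at scan as the clock would confound the age and time effects, which the
  three-way interaction needs kept apart.
* **Education coding.** The education indicator is 1 = below college
  (college+ is the reference). With this coding the whole sign pattern of
  the planted and recovered effects is coherent: the education main
  effect is negative (below-college participants sit lower), and the
  three-way time × age × education coefficient is negative — each year of
  baseline age steepens the below-college group's annual decline relative
  to their college-educated peers, which is the qualitative phenomenon
  the model targets. Under the opposite coding the same phenomenon flips
  the three-way sign; `edu_reference` makes the choice explicit and
  reversible.
* **Degrees of freedom.** Per-term F tests (all 1 numerator df) and
  t-based intervals use the Satterthwaite approximation via lmerTest; it
  produces the non-integer denominator df this design calls for without
  refitting.
* **Covariate augmentation.** A baseline covariate enters as a main
  effect plus its time interaction (its influence on both level and
  slope); a longitudinally measured covariate enters as a main effect
  only. Missing covariates trigger listwise deletion with per-column
  counts reported, so each augmented model states its own n.
* **Multiple comparisons.** Two longitudinal brain-change outcomes
  (segregation, cortical thickness) are examined, so the pipeline flags
  their three-way terms at 0.05/2 = 0.025.

`simple_slopes()` evaluates the conditional time slope
$\gamma_{10} + \gamma_{11}\bar{\mathrm{sex}} + \gamma_{12}\,\mathrm{age}
+ \gamma_{13}\,\mathrm{grp} + \gamma_{14}\,\mathrm{age}\cdot\mathrm{grp}$
at the rounded mean baseline age and one standard deviation either side;
sex is held at its sample mean because the slope must be evaluated at
*some* value of every time-interacting moderator and the mean is the
neutral choice. `johnson_neyman()` sweeps the same contrast over an age
grid (default 45–86 by 0.5 years, the full baseline range of the
emulated design), marks ages whose confidence interval excludes zero,
and interpolates the boundary crossings between grid points. Probing
ages outside the observed range warns rather than errors — extrapolation
is sometimes wanted, but should be flagged.

## Prognosis: CDR sum of boxes

`fit_cdr_model()` relates longitudinal dementia severity to brain-network
change. The predictor is the **observed** change score — last-scan minus
baseline segregation (`change_score`) — rather than a model-estimated
per-person slope: participants with only two scans would otherwise
receive heavily shrunken estimates, and the observed difference treats
everyone identically. CDR-SB (0–18 in half-point steps) is modeled as a
Gaussian outcome with time × age × Δsegregation and all lower-order
terms, plus the four mandatory covariates (sex, average head motion of
the two anchor scans, scan interval, education group). Options add
pathology and APOE three-way terms, longitudinal structural covariates,
an interim-CDR-change adjustment, substitution of thickness or
hippocampal change for Δsegregation, and quadratic time (a robustness
refit for the zero-inflated, right-skewed outcome). The outcome's
ordinal, floored character is a known misfit for a Gaussian model; the
package keeps the Gaussian LMM as the primary specification and exposes
the quadratic-time refit, whose preservation of the three-way sign is
part of the test suite.

## Block-level permutation testing

For each education group, `permutation_test()` compares each older
participant's first- and last-scan system-block summaries with paired t
tests, then builds a null by pooling all 2N matrices of the group and
randomly reassigning them to N (first, last) pairs each iteration — the
whole matrix is the exchangeable unit, a literal reading of
"shuffled across participants and time points". A variant that only
flips first/last labels within participants (`method = "sign_flip"`) is
provided because the pooled reading is not the only defensible one. The
two-tailed p is the proportion of null $|t|$ at least as extreme as the
observed $|t|$, with **no** +1 smoothing by default — the proportion rule
can return exactly 0 — and a smoothed $(k+1)/(n+1)$ option for users who
need strictly positive p values. The FDR family is all blocks (within-
plus between-system) of one education group, corrected by
Benjamini–Hochberg at 0.05; the family definition is a documented choice.

## What the generator emulates — and what it does not

`cohort_config()` fixes the synthetic study conditions: 265 participants,
baseline age truncated-normal (mean 67.01, s.d. 9.26, range 45–86), 65%
college-educated, per-group prevalences for sex, race, APOE ε4,
continuous CSF pTau and PiB SUVR (lognormal, matched in mean and s.d.;
positivity derived from the >67 pg/ml and >1.42 SUVR cutoffs), four
tri-state cardiovascular flags aggregated as a met-over-available
proportion, GDS (truncated Poisson), TBI, and baseline CDR. Missingness
is completely at random at the observed per-group rates, because only
missing counts — not a mechanism — are available to emulate. One
bookkeeping wrinkle in the emulated counts (a pTau-positive total that
can be read as either 61 or 62) is resolved by parameterizing per-group
positivity rates over non-missing denominators rather than a total.

Scan schedules draw 2–5 visits (probabilities 0.64/0.18/0.11/0.07 — about
36% of participants with three or more scans), a second-scan gap of mean
3.22 and s.d. 1.55 years, later increments matching mean cumulative gaps
of 5.70/6.78/8.05 years, and a hard span cap of 9.24 years. Clinical
visits start within a year of baseline, recur roughly annually, and
extend a truncated-normal 3.77 ± 2.02 (max 10.10) years past the last
scan.

The segregation trajectory is planted through the 11-term equation above
(defaults: a mean level near 0.47, a negative three-way coefficient of
−0.0004 per year per year-of-age, random-effect s.d.s 0.04/0.004,
residual s.d. 0.015 — values chosen once to give mid-life levels,
within-person stability and an effect detectable at the full design
size, and kept fixed thereafter). Each scan's node time series are drawn
from a compound-symmetric block covariance — one within- and one
between-system correlation — because that minimal two-parameter family
pins the population segregation *exactly*: the planted value acts on
Fisher-z correlations and is pushed through `tanh` before covariance
assembly, so `covariance_segregation()` recovers the target to 1e-9.
The within-system z level is held at 0.55 and the between-system level
absorbs the trajectory; a non-positive-definite request errors. FD traces
are Gaussian jitter around a scan-level motion latent plus i.i.d.
Bernoulli spikes (rate 0.05) above the 0.3 mm threshold; inter-spike
correlation is out of scope. CDR-SB series follow a latent linear slope
in (age − 67), Δsegregation and their product (planted three-way
−0.05 — calibrated by pilot simulation to be recoverable in sign at the
design size) plus a rounded, floored Gaussian random walk, since no
clinical noise model is given to emulate.

What passing tests on this generator do **not** show: the generator has
no spatial structure, no heavy-tailed or autocorrelated BOLD noise, no
non-random missingness or attrition, no scanner or session effects, and
compound-symmetric blocks are far simpler than empirical connectomes.
Recovery results demonstrate the estimators are correct under the stated
model, not that real cohorts satisfy that model.

With `timeseries = list(enabled = FALSE)` the generator emits segregation
values analytically (planted value plus residual) instead of realizing
them through time series; model-recovery and calibration studies use
this mode, and the replicate studies in the test suite run at the full
design size (200 trajectory replicates, 200 + 400 prognosis replicates,
500 permutation datasets at 1,000 permutations with the full 10,000
reserved for one-off runs) — sizes chosen to make Monte-Carlo error small
relative to the planted effects.

## Numerical and degenerate-input choices

* $|r|$ clamped to $1 - 10^{-12}$ before `atanh`; constant node series
  raise an error naming the node.
* Planted segregation targets are clamped to [0.05, 0.95] so extreme
  random-effect draws cannot request a degenerate covariance.
* lme4 silently drops collinear fixed-effect columns; the package treats
  that as a specification error naming the dropped terms, because a
  model with missing planned terms is not the model that was asked for.
* Singular variance estimates (e.g. when fitting noiseless data) are
  reported via a flag, not an error — exact-recovery checks depend on
  this.
* Day-level rounding of visit schedules is nudged to keep visit days
  strictly increasing and within the span cap.
* Johnson–Neyman boundaries are linear interpolations of the
  significance margin between grid points; halving the grid step bounds
  the boundary error accordingly.

## Limitations

The package does not preprocess fMRI data, derive parcellations, process
PET/CSF assays, or link geographic/SES indices; its inputs begin at node
time series plus FD traces and tabular clinical data. Gaussian LMMs for
an ordinal bounded outcome, the pooled permutation reading, and the
first-k frame policy are all documented choices with alternatives exposed
where feasible. Reported F statistics from any real private cohort are
not reproducible here by construction; the package's claims are about
correctness and calibration of the machinery, demonstrated on its own
generator.
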