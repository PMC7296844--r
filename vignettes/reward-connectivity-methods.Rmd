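---
title: "Modelling reward learning and reward-network effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward learning and reward-network effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rewardConn models a 66-trial probabilistic reward learning task — 33 trials
with a free choice between a high-reward (80%) and a low-reward (20%)
stimulus, 33 forced ("no choice") trials, 100 points per win, event-related
fMRI at TR 1.56 s — and the analysis chain built on it: reinforcement
learning models of behaviour, model-based GLM regressors, a bilinear dynamic
causal model of a visual–striatal–prefrontal network, and hierarchical group
inference over its connectivity. Because the patient data this kind of study
uses are access controlled, the package ships a first-class synthetic-data
generator that emulates the task and plants known effects, so every stage of
the pipeline can be validated by recovery rather than asserted.

## Behavioural models

Five Rescorla–Wagner learners share the delta rule
$q_a \leftarrow q_a + \alpha\,(\rho\,r - q_a)$ on the chosen (or imposed)
stimulus $a$, with binary outcome $r$. They differ in how free-choice and
forced trials are treated: model 1 ignores forced outcomes; model 2 learns
equally from both; model 3 has condition-specific learning rates
$\alpha_c, \alpha_{nc}$; model 4 condition-specific sensitivities
$\rho_c, \rho_{nc}$; model 5 both. Choices follow a unit-temperature softmax
on the $\rho$-scaled values, so $\rho$ is simultaneously the outcome scaling
and the effective inverse temperature — with binary rewards this is the
identifiable parameterisation, and it is our reading of the model family
(the original specification of the policy link is not public; a lapse or
bias term is deliberately not added). Values start at $q = (0, 0)$;
symmetric, and any other constant start is absorbed by the first few
updates. Model 1 still *reports* prediction errors on forced trials (they
are needed as fMRI regressors) without updating values; `rpeSeries()` can
zero them instead.

Fitting is hierarchical empirical Bayes in unconstrained space
(logit $\alpha$, log $\rho$): per-subject MAP by BFGS with analytic
gradients and jittered restarts, a Gaussian group prior re-estimated by EM
from the MAP estimates and their Laplace covariances, and group-level model
comparison by the integrated BIC — a Monte-Carlo marginal likelihood under
the fitted prior (K = 2000 by default, log-sum-exp guarded) penalised by the
number of prior parameters ($2d$) times the log of the *choice-trial* count,
the likelihood-bearing events. The EM initialiser is a pooled fit with a
light ridge (SD 5) so it stays finite even when the pooled MLE diverges
(saturated choice probabilities); the EM convergence criterion is the group
mean (tolerance $10^{-3}$), with variances floored at $10^{-4}$.

## What the generator emulates — and what it cannot show

`generateCohort()` draws QIDS depression scores from a truncated negative
binomial with mean ≈ 4.5 (matching the study population's mean of ~4.5),
HADS anxiety correlated with QIDS (latent $r \approx 0.5$), age ~ N(58, 9),
sex and site balanced. Unconstrained parameters are Gaussian around
$(\mathrm{logit}\,0.4,\ \mathrm{logit}\,0.2,\ \log 3)$ with variance 0.25
each. Two of these choices deserve justification:

* **Reward sensitivity ρ ≈ 3.** Unit sensitivity makes the softmax nearly
  flat (asymptotic accuracy 0.63) — agents that barely learn, unlike real
  participants who master this easy discrimination. ρ ≈ 3 yields ~86%
  asymptotic choice accuracy, a realistic regime.
* **Logit-spread 0.5 for learning rates.** With means 0.4 / 0.2 this makes
  about 92% of simulated subjects learn faster from free choices, matching
  the ~93% reported behaviourally. A wider spread would inflate recoverable
  individual differences beyond what that statistic allows.

The generator does **not** emulate: reversals or drifting reward
probabilities (so learning rates are only weakly identified — see
limitations), reaction times, lapses and attention drift (a `missRate`
option exists but defaults to 0), scanner artefacts, physiological noise, or
spatial structure (ROI series are generated directly from the DCM forward
model with white observation noise). Passing recovery tests on these
cohorts therefore demonstrates the *estimators* are correct and calibrated,
not that real data would be as informative.

Trial pacing: cue, response and outcome onsets follow each other at gaps
drawn uniformly from 2–6 s (display durations 2 / 0 / 1.5 s within those
gaps). At 66 trials this implies a mean session of ~800 s, so the default
acquisition is 560 volumes (873.6 s) — about five standard deviations of
session-length headroom; schedules that still overrun raise an error rather
than truncate.

## GLM utilities

Event regressors are truncated delta trains at 16 bins per TR convolved
with the canonical double-gamma HRF (peak 6, undershoot 16, ratio 6, 32 s
support) and sampled on the TR grid. The two design variants (four outcome
columns, or one outcome column plus a mean-centred parametric modulator —
binary win or model-derived prediction error) span the same outcome
subspace when the modulator is the win indicator, which the tests verify.
The Monte-Carlo cluster-extent threshold simulates white fields, smooths
them separably (σ = FWHM/2.355, truncated at 4σ, exact per-voxel variance
renormalisation at the edges), thresholds two-sided, and takes the ceiling
of the (1−FWE) quantile of maximal 26-connected cluster sizes. 26-neighbour
connectivity and the two-sided voxel threshold follow common practice; the
acquisition matrix (64 × 64 × 32 at ~3.4 mm, 8 mm smoothing) reproduces an
extent threshold of the same order as the study's 131 voxels, and no closer
agreement should be expected without the real analysis mask.

## The DCM and its inversion

The three-region bilinear model (visual cortex, ventral striatum, mPFC) is
fully connected: six directed between-region influences plus three
self-connections parameterised $-\tfrac12 e^{a}$ so they remain inhibitory.
Four outcome-type inputs (reward, no-reward, choice-trial, no-choice-trial —
each outcome event lies in two of them) drive visual cortex and may modulate
all nine connections; the two cue types also drive visual cortex; button
presses drive all regions. Inputs are mean-centred so A is *average*
connectivity. Haemodynamics are the standard balloon–Windkessel equations
(κ = 0.64, γ = 0.32, α = 0.32, E₀ = 0.4, V₀ = 4, k₁ = 7E₀, k₂ = 2,
k₃ = 2E₀ − 0.2) with only a per-region log transit-time deviation estimated.
Priors are shrinkage-style: A off-diagonal N(0, 1/16) Hz, self N(0, 1/64),
B N(0, 1/16), C N(0, 1), transit N(0, 1/256), noise log-precision N(4, 1).

Integration is fixed-step midpoint (second order) at TR/16, with the
haemodynamic states advanced in log space so their positivity is exact;
step-halving against a shared fine input grid changes the prediction by
well under 1% RMS. Inversion is variational Laplace: Gauss–Newton ascent on
a Laplace free-energy bound with Levenberg damping — candidate steps that
do not increase the bound are rejected and the damping raised, so the
accepted free-energy series is non-decreasing by construction — with the
noise log-precision updated by Newton steps inside each iteration and the
Jacobian obtained by finite differences of the compiled integrator
(forward step $10^{-4}$). Convergence is declared below a free-energy gain
of 0.01.

The synthetic ground truth plants the connectivity structure of interest:
no VIS→VS and no VS→mPFC influence, positive influences elsewhere
(~0.3 Hz), and an mPFC→VS strength declining with centred QIDS (default
−0.03 Hz per point). Planted networks are kept dynamically stable by
rescaling the couplings whenever the spectral abscissa of A would exceed
−0.1 Hz — low-QIDS subjects otherwise land near criticality, which no
physiological network (nor the Euler-family integrator) tolerates.

## Group inference

The PEB layer models each subject's nine A-parameters (their posterior
means, carrying their posterior covariances) as
$(x_i^\top \otimes I_9)\beta$ plus Gaussian between-subject effects with a
common log precision γ ~ N(0, 1); β is marginalised analytically and γ
optimised on the evidence. The design is a ones column plus mean-centred
QIDS, HADS-A, age, sex (±0.5), site (±0.5) and current-MDE status;
commonality effects inherit the subject-level prior variances, covariate
effects the same scaled by 1/16. Bayesian model reduction computes reduced
posteriors and evidence changes analytically (verified against closed-form
refits); the greedy search scans effects in ascending |mean|/SD, prunes any
whose removal does not lower the evidence, repeats to a fixed point, and
the final iteration's model set is combined by evidence-weighted Bayesian
model averaging. Split-sample replication refits the full PEB model (no
reduction) on repeated disjoint halvings — 100 splits, 200 fits — and
reports the sign-stability of a chosen effect; when the cohort is odd the
first half is larger by one.

Two honesty notes on the group level. First, the proportion of negative
halves for a *null* cohort is dominated by that cohort's overall sample
effect, so it is approximately uniform per cohort and only ≈ 0.5 when
averaged over cohorts; the tests do exactly that. Second, group-level PEB
validation uses subject posteriors generated directly from the hierarchical
model (with covariances matched to what DCM inversions produce) where full
inversions would add nothing but runtime; the planted-effect replication
path is still exercised end-to-end (schedules → agents → BOLD → inversion →
PEB) at a reduced cohort size.

## Problem sizes and numerical choices

Validation runs use: 50-subject cohorts × 20 seeds for model recovery
(models 1–3), a 100-subject cohort for parameter recovery, 40 subjects at
SNR 1 for DCM sign recovery, 10 cohorts of 40 for the PEB planted-effect
checks, and 100 splits for replication. Monte-Carlo marginal likelihoods
use K = 2000 (the K → ∞ limit is checked against quadrature on a toy
subject to 1%). Ties in rank correlations use average ranks; the default
correlation Bayes factor integrates Jeffreys' likelihood ratio under a
uniform(−1, 1) prior on ρ.

## Known limitations

* The 66-trial, no-reversal task is weakly informative about learning
  rates: even at the true generative prior, true-vs-recovered Spearman
  correlations for the two learning rates plateau around 0.3–0.5 at 66
  trials (rising to ~0.75 at 330 trials). Conclusions about individual
  learning-rate differences at this session length rest mostly on the group
  level.
* For the same reason, distinguishing model 3 from model 2 at 50 subjects
  is marginal — the evidence gain from splitting the learning rate is of
  the same order as its iBIC penalty; at the study's actual cohort size
  (475) the comparison is decisive, which the package reproduces.
* The PEB commonality estimate of the absent VS→mPFC connection shows a
  small positive bias under strong indirect pathways; the planted-zero
  structure is recovered as "no evidence" rather than as an exact zero.
* Voxel-level analyses operate on small synthetic grids; real-mask cluster
  geometry, spatial autocorrelation and anatomical constraints are out of
  scope.
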