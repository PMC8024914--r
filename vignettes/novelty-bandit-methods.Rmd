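---
title: "Methods: the novelty bandit task, its learning model, and the clinical statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the novelty bandit task, its learning model, and the clinical statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`noveltybandit` implements, end to end, the computational machinery of an
adolescent substance-use study built around a three-armed bandit with
periodic novel-stimulus introductions: the task simulator, the
reinforcement-learning model and its estimation, novelty-propensity and
explore-trial definitions, reward-prediction-error (RPE) modulated fMRI
design and GLM machinery with motion censoring, and the group-level
clinical statistics (Rankit transform, partial correlations, Steiger's z,
VIF, mixed-design ANCOVA, moderation with Johnson–Neyman regions). A
synthetic-cohort generator with planted effects provides recoverable
ground truth for power and calibration studies.

## The task

Three stimuli are offered on every trial. Each stimulus carries a fixed
win probability; choosing it pays `$0.30` with that probability and `$0`
otherwise, and subjects keep 10% of accumulated winnings. Every stimulus
is offered for a lifetime of 5–9 consecutive trials (drawn uniformly)
before being replaced, in place, by a novel stimulus; a default session
introduces 40 novels split evenly over two runs, each run starting with
three fresh stimuli. Win probabilities are uniform on (0, 1), so expected
payoffs are uniform on ($0, $0.30).

Design choices the task description leaves open, resolved here:

* **Payoff semantics.** "A probability of winning between $0.00–$0.30"
  is implemented as Bernoulli `$0.30` feedback with stimulus-specific
  probability, so the *expected* payoff spans $0.00–$0.30 — the same
  dollar scale on which initial values and novelty propensity are
  expressed. The feedback scheme sits behind `sample_feedback()` and can
  be replaced.
* **Session termination.** Sessions are defined by the count of novel
  introductions, not a trial count; a run ends at the first trial an
  expired slot cannot be refilled. Stimuli still alive then have
  truncated *realized* lifetimes (the drawn lifetimes always lie in
  5–9). In the rare draw where several stimuli expire simultaneously
  with too few novels left to refill every slot, the schedule is
  regenerated from a derived seed, keeping "exactly 40 introductions"
  exact; this conditions the lifetime distribution only through final
  transition configurations and leaves it uniform to well within
  sampling error (checked by a goodness-of-fit test in the suite).
* **Positions.** Left/mid/right placement is randomized metadata; the
  learner is position-blind.

## The learning model

Learning follows the delta rule on expected values, for the chosen
stimulus only:

$$\mathrm{RPE}(t) = F(t) - \mathrm{EV}(t), \qquad
  \mathrm{EV}(t+1) = \mathrm{EV}(t) + \alpha\,\mathrm{RPE}(t),$$

with feedback $F$, learning rate $\alpha \in (0, 1]$. Choices follow a
softmax over the three offered EVs with inverse temperature $\beta \ge
0$:

$$P(i) = \frac{e^{\beta\,\mathrm{EV}_i}}{\sum_j e^{\beta\,\mathrm{EV}_j}}.$$

The task description names $\beta$ but not the choice rule; the softmax
is the standard companion of this delta rule in the lineage of bandit
models the study builds on, and is the design choice here. Newly
introduced stimuli enter at $\mathrm{EV}_0 = 0.216$ — the group-average
novelty propensity established on 290 adolescents — which acts as an
optimistic prior (above the $0.15 long-run average payoff) that pulls
early choices toward novel stimuli. Run-initial stimuli also start at
0.216; this is configurable.

### Estimation

The fit criterion is maximum likelihood (the source work does not name
one): minimize $-\sum_t \log P(\text{chosen}_t)$ over responded trials,
with log-sum-exp stabilization so large $\beta$ cannot overflow.
Because trajectories depend only on $\alpha$ and the feedback history —
never on $\beta$ — fitting profiles the likelihood: a coarse grid over
$\alpha$ (21 points by default, each requiring one forward pass per
subject) refined by golden-section search, with $\beta$ optimized on
cached EVs at each candidate $\alpha$. This is deterministic and avoids
random multi-start. `fit_pooled()` shares $\alpha$ across subjects
(mirroring the group-learning-rate workflow: estimate $\alpha$ once,
then hold it fixed for all trajectory/RPE derivations), with $\beta$
either shared or per subject; the package default is shared-$\alpha$ /
free-$\beta$.

Two identifiability facts matter and are surfaced rather than hidden:

* With $\beta$ fixed at 0 every policy is uniform, so $\alpha$ drops out
  of the likelihood; the fit reports `identifiable = FALSE` instead of
  an arbitrary optimum.
* With both parameters free, single-subject likelihoods have a
  pronounced $\alpha$–$\beta$ ridge at this task's scale (three options,
  EVs confined to [$0, $0.30]): free-parameter $\alpha$ from one
  ~100-trial session has standard deviation near 0.15 even though the
  optimizer is verified against a brute-force lattice. Pooling is the
  cure; 200 agents recover the group $\alpha$ to within ±0.02–0.03 in
  practice (tested at ±0.05), and subject-level $\alpha$ recovers well
  when $\beta$ is known.

## Explore trials and novelty propensity

The *lag* of a stimulus is the number of trials since its introduction,
counting its first offer as lag 1. Behaviourally, novel stimuli are most
attractive at lag 2; a responded trial whose chosen stimulus is at lag 2
is an **explore** trial, all other responded trials are non-explore.

**Novelty propensity (NP)** is estimated per subject by logistic
regression, on trials offering a lag-2 stimulus, of the indicator "chose
the novel (minimum-lag) stimulus" on the EV of the best non-novel
offered stimulus ($\mathrm{EV}_{best}$, the maximum EV among stimuli at
lag > 2); NP is the $\mathrm{EV}_{best}$ giving a fitted probability of
0.5, i.e. $-\hat a/\hat b$. The exact construction used on the human
cohort lives in unavailable supplementary material; the logistic
50%-point reading of the main text is implemented, with these guards:
the estimate is declared non-identifiable (missing, never extrapolated
silently) when the outcome or predictor is constant, the fit separates,
or the slope is non-negative. NP so defined is a ratio estimate with
heavy tails — in the three-option softmax, 50% novel choice requires the
novel EV to dominate *two* competitors, so per-subject NP values often
extrapolate below the observable EV range. Cohort summaries therefore
use medians, and the pipeline standardizes NP before group analyses.
Monotonicity (higher generating novelty prior, higher estimated NP) is a
tested property; equality of the cohort mean with the prior is not, and
the human in-sample values (43.2% lag-2 choice, mean NP 0.216) are
documentation, not targets.

## Behavioral metrics

`prop_best_nonnovel()` is the fraction of responded trials (with at
least one non-novel stimulus on offer) whose choice is the non-novel
stimulus with the highest current model EV — computed from trajectories
at the fixed group $\alpha$, not from latent payoff rates. The
novel/non-novel boundary for this metric is lag ≤ 2 (the explore
window); the boundary is configurable since the source is silent.
Partial correlations of transformed clinical scores with these metrics
control for sex, with $df = n - 3$.

## fMRI design machinery

Each trial contributes a cue event (1.5 s) and a feedback event (1.5 s)
separated by uniform 1–2 s jitters. Six event classes (cue/feedback ×
non-explore/explore/no-response) produce one unmodulated regressor each;
the four responded classes add a parametric companion whose event
amplitudes are the *run-mean-centered* decision-time EV (cue) or RPE
(feedback). Events are convolved with a double-gamma HRF (gamma shapes
6 and 16, undershoot ratio 1/6, peak ≈ 5 s — the unspecified upstream
defaults are approximated and configurable) on a TR/16 grid and sampled
at volume onsets. Per-run mean-centering (rather than per-session) is
the convention adopted for amplitude modulation; it makes a constant
modulator vanish exactly and keeps modulated columns separable from
their unmodulated companions. Motion (6 columns) and per-run intercept +
linear drift complete the design.

Censoring: the Euclidean norm of the backward difference of the six
motion parameters is computed per volume; any volume exceeding 0.5 mm
*and its predecessor* are censored. Subjects with strictly more than 15%
of volumes censored are excluded (a subject at exactly 15% is retained —
the rule is stated as "> 15%"). Voxel time series are rescaled to
percent signal change (mean over uncensored volumes) before an OLS GLM
on the censored-row-deleted data; the RPE-modulated feedback
coefficients are the downstream quantities.

## Group-level statistics

* **Rankit transform**: $\Phi^{-1}((r - 0.5)/n)$ on tie-averaged ranks —
  the classical Rankit; Blom/Tukey denominators are options. Applied to
  AUDIT (whose sum scores are strongly right-skewed) and followed by
  z-scoring; CUDIT is z-scored raw. Sex is coded 1 = male, 0 = female.
* **Steiger's z** compares two dependent correlations sharing a
  variable, via Fisher z with the 1980 covariance correction.
* **Mixed-design ANCOVA** on explore/non-explore ROI coefficients uses
  the exact two-level decomposition: between-subject effects on the
  condition mean, Decision effects and covariate-by-Decision
  interactions on the condition difference. All terms are continuous or
  binary single-df terms, so each type-III F is the squared OLS t — no
  general ANOVA engine is needed, and an independent nested-model route
  cross-checks the algebra in the suite. Partial $\eta^2 = F/(F +
  df_{res})$. Tests are two-sided at $\alpha = .05$ with no
  multiple-testing correction at ROI level (the upstream correction is
  spatial/cluster-based and out of scope).
* **Johnson–Neyman regions**: for the moderation model
  $y = b_0 + b_1 x + b_2 m + b_3 xm + \dots$, boundaries solve
  $(b_1 + b_3 m)^2 = t_{crit}^2\,\widehat{\mathrm{Var}}(b_1 + b_3 m)$, a
  quadratic with 0, 1, or 2 real roots; with none, the simple slope is
  significant everywhere or nowhere and the result says which. Verified
  against a dense grid of re-centered regressions.

## The synthetic cohort

`generate_cohort()` emulates the study population: 128 adolescents, 78
male; AUDIT (0–34, mean ≈ 3.4, SD ≈ 5.5, strongly right-skewed) and
CUDIT (0–32, mean ≈ 9.1, SD ≈ 9.4) drawn from a Gaussian copula with
gamma-quantile marginals, rounded and clipped. The latent copula
correlation (0.60) was calibrated once, by Monte Carlo, so the realized
Pearson correlation of the rounded scores averages the target 0.49;
females receive a latent AUDIT shift (+0.35 SD) so they score higher, as
in the study sample. Planted effects: standardized AUDIT lowers choice
precision ($\beta_i = 8 - 1.5\,\mathrm{AUDIT}_z + \varepsilon$, floored
at 0.5 — the behavioral performance deficit is planted through choice
precision rather than learning rate), lowers neural RPE scaling (standardized slopes
−0.3 on explore, −0.1 on non-explore feedback), and a CUDIT×NP
interaction (−0.3) on explore scaling; learning rates are ~N(0.692,
0.06) truncated, novelty priors ~N(0.216, 0.04) truncated to (0, 0.30).
Subject noise on the RPE scalings has SD 0.9 on the standardized scale,
so each planted slope's marginal standardized magnitude is its nominal
value to within a few percent. ROI BOLD is simulated at 4 voxels as
design × amplitudes (baseline 100, white noise SD 1); motion is a
random walk (0.03 mm/volume) plus Bernoulli displacement spikes whose
per-subject rate is Beta(0.6, 20) — median near 2%, with a tail of high
movers so the >15% exclusion rule has bite. The generator returns the
truth table separately; the analysis path never reads it (tested by
scrambling it and comparing outputs).

What the generator does *not* emulate: temporally autocorrelated scanner
noise, physiological confounds, spatial structure, non-response trials
(supported by the data model, not emitted by default), or the diagnosis
and medication structure of the real sample beyond simple correlated
covariates. Passing tests therefore certify the estimators and the
pipeline plumbing under a well-specified generative model — not
robustness to the full messiness of real imaging data.

## Problem sizes, tolerances, numerical choices

Suite and acceptance-script sizes are chosen to make each check
well-powered at desk scale: 200 agents for pooled-$\alpha$ recovery
(tolerance ±0.05); n = 500 observations for the planted logistic
50%-point (±0.02); JN boundaries vs. a 0.001-step grid scan (±0.01);
400 Monte-Carlo replications for GLM coefficient recovery (MC SE ≈
0.009 against a ±0.05 check); 1,000 null cohorts for ANCOVA type-I
calibration (nominal 0.05 ± 2 MC SE); 50 planted cohorts for the ≥80%
power check, with the planted standardized slope defined on the tested
explore−non-explore contrast (0.3). Optimization tolerances: 1e-4 on
$\alpha$, 1e-5 on $\beta$; likelihoods use log-sum-exp; design matrices
are built on a TR/16 grid; ties in lag (which stimulus counts as
"novel") resolve to the first offered position; simultaneous lifetime
expiries resolve by lowest stimulus id. Degenerate inputs error loudly:
constant Rankit input warns and returns zeros, separation in the NP
logistic yields a flagged missing value, rank-deficient GLM designs
name the collinear columns.

## Known limitations

* Single-subject $(\alpha, \beta)$ estimates are ridge-correlated; only
  pooled $\alpha$ (or $\alpha$ at known $\beta$) is sharply identified
  at this task length.
* Per-subject NP is noisy and often extrapolated; analyses should use
  its standardized version and expect missingness.
* The voxelwise whole-brain stage of the original study (3dMVM,
  cluster-extent correction) is intentionally out of scope; the ANCOVA
  operates on ROI-level coefficients.
* Real-data results of the source study (its ROI F values, the
  behavioral r = −0.18) derive from an unavailable human sample and are
  not reproduction targets for this package.
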