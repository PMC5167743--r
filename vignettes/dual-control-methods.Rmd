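---
title: "Models and methods for cross-validating goal-directed and habitual control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for cross-validating goal-directed and habitual control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dualcontrol` implements, as reusable and tested components, the complete
computational apparatus needed to study how two standard laboratory assays of
instrumental control relate to each other:

* the **two-step sequential decision task**, analyzed with a hybrid
  model-based/model-free reinforcement-learning model fitted by hierarchical
  empirical Bayes, and
* the **three-phase instrumental learning task** (discrimination training,
  outcome devaluation, slips-of-action and baseline tests), scored with the
  devaluation sensitivity index (DSI),

together with the cross-task statistics (one-tailed Spearman correlations
with Bonferroni correction, outlier screening, and simple mediation with a
bias-corrected bootstrap, the Sobel test and the κ² effect size) and a
synthetic-cohort generator with a latent goal-directedness trait, so the
entire pipeline — simulate, fit, score, correlate, mediate — runs end to end
against known ground truth. No real subject data ship with the package;
every empirical quantity in the documentation is computed by the code at
run time.

# The two-step task environment

Each trial has two stages. A first-stage choice between two options leads to
one of two second-stage states: option $j$ leads to its *common* state with
probability $p_{\text{common}} = 0.7$ and to the other, *rare*, state
otherwise. A second-stage choice is then rewarded (1) or not (0) with a
probability that drifts across trials as a Gaussian random walk. Defaults
follow the original task design: 201 main trials preceded by 55 practice
trials, walk increments with sd 0.025, and reflecting boundaries at
$[0.25, 0.75]$ with uniform initialization inside the bounds. Reflection
(rather than truncation) is used at the boundaries because it preserves the
drift variance near the bounds, which keeps the exploration incentive
roughly constant across the probability range. All of these are
configurable through `twostep_config()`.

Two deliberate simplifications: simulated sessions contain no invalid
trials (the `valid` flag exists so imported human data with response
omissions share the same schema and are skipped consistently by the
likelihood and the stay-probability counts), and practice trials use
independent reward walks — the task description does not tie the practice
walks to the main-task walks, and keeping them independent makes the
practice block a pure warm-up with no information about the main task.

# The hybrid learner

Model-free values follow a SARSA(λ) scheme. With stage index $i$ and trial
$t$, the chosen values update as

$$Q_{MF}(S_i, a_i) \leftarrow Q_{MF}(S_i, a_i) + \alpha_i \delta_i,$$

with prediction errors

$$\delta_1 = Q_{MF}(S_2, a_2) - Q_{MF}(S_1, a_1), \qquad
  \delta_2 = r - Q_{MF}(S_2, a_2),$$

(no reward follows the first stage), and the second-stage error is carried
back to the first stage through an eligibility weight λ:

$$Q_{MF}(S_1, a_1) \leftarrow Q_{MF}(S_1, a_1) + \alpha_1 \lambda \delta_2.$$

The equations do not by themselves fix an order of operations; we compute
$\delta_1$ with the *pre-update* second-stage value, then $\delta_2$, and
then apply all three increments. This matches the SARSA(λ) convention of
the source task and is verified in the tests with an independently coded
step-by-step trace.

Model-based values plan one step ahead through the (instructed, fixed)
transition matrix:

$$Q_{MB}(S_1, a_j) = P(S_B \mid a_j)\max_a Q_{MF}(S_B, a) +
                     P(S_C \mid a_j)\max_a Q_{MF}(S_C, a).$$

No separate model-based learning of transitions is implemented: subjects
are trained on the transition structure before the task, so the planner
re-evaluates the current cached second-stage values fresh on every trial.
First-stage choice values mix the two systems with weight ω,

$$Q = \omega Q_{MB} + (1 - \omega) Q_{MF},$$

and choices follow a softmax with stage-specific inverse temperatures
$\beta_1, \beta_2$ and a perseveration bonus ρ for repeating the previous
first-stage choice. Perseveration applies at stage 1 only: the ρ term
models choice stickiness of the first-stage options, and the second stage
has no comparable repetition structure. Second-stage choice probabilities
use the raw cached values with $\beta_2$ — once the second state is
reached, planning and caching coincide. The derived quantities
$\beta_{MB} = \omega\beta_1$ and $\beta_{MF} = (1-\omega)\beta_1$ express
how strongly choices follow each system and are the quantities carried
into cross-task correlations; `split_betas()` computes
$\beta_{MF} = \beta_1 - \omega\beta_1$ so the sum identity
$\beta_{MB} + \beta_{MF} = \beta_1$ is exact in floating point.

Value initialization is all-zeros with no forgetting of unchosen options —
the simplest scheme consistent with the update equations. With rewards in
$\{0, 1\}$ this keeps cached second-stage values inside $[0, 1]$, which is
asserted as a property test. The softmax is computed with max-subtraction
so that large $\beta \times Q$ cannot overflow.

The session likelihood (`session_nll()`) is implemented in C++ for speed —
hierarchical fitting evaluates it hundreds of thousands of times — and is
pinned to an independent pure-R trace oracle at tolerance 1e-10 in the
test suite, plus the closed form $2T\ln 2$ for a $\beta = 0$ (uniform)
observer.

# Hierarchical empirical-Bayes fitting

Bounded parameters are mapped to an unconstrained scale (log-odds for
$\alpha_1, \alpha_2, \lambda, \omega$; log for $\beta_1, \beta_2$; identity
for ρ, which the model treats as unbounded), where the group prior is a
diagonal Gaussian. Fitting alternates:

* **E-step** — per-subject maximum-a-posteriori estimates of the
  transformed parameters (`subject_map()`), by quasi-Newton optimization
  with multiple starts (prior mean plus jittered draws; five by default,
  because the likelihood is mildly multimodal), with a diagonal Laplace
  approximation of the posterior from finite-difference curvature;
* **M-step** — moment matching: the prior mean becomes the mean of the MAP
  estimates, and the prior variance the mean of squared estimates plus
  Laplace variances minus the squared mean, so that per-subject
  uncertainty keeps the prior from collapsing.

The prior is initialized at the pooled maximum-likelihood estimate (all
subjects concatenated into one likelihood, values reset per subject) with
a broad variance of 6.25 per dimension. Whether the variance is
re-estimated by EM or held fixed is configurable (`update_variance`);
re-estimation is the default. Convergence is declared when the largest
absolute change in the prior mean drops below 1e-3 (configurable), with a
100-iteration cap. The per-iteration `trajectory` records the variational
(Laplace/ELBO) objective — data log-likelihood plus log prior density at
the MAPs plus the Gaussian entropy term — which is non-decreasing along
the run up to optimizer tolerance; this is asserted in the tests. After
the first iteration, E-steps are warm-started from the previous MAPs, with
a periodic fresh start from the prior mean to guard against mode capture;
this is purely an efficiency schedule and does not change what is being
optimized. Curvature values that come back non-positive (flat directions)
are treated as uninformative and capped at the current prior variance.

The per-subject −LL reported in `em_params_table()` excludes the prior
term — it is the pure data likelihood at the MAP, the convention used when
such tables are reported alongside group parameter estimates.

Two oracle-style checks pin the machinery down: on a reduced two-parameter
problem (only ω and $\beta_1$ free) the MAP matches a dense 200×200 grid
search over the same penalized objective to within one grid step, and with
an essentially point-mass prior (variance $10^{-12}$) the MAP reproduces
the prior mean.

# The instrumental learning task

`sro_map()` fixes the deterministic stimulus–response–outcome structure:
six stimuli, three per response side, each yielding a unique outcome with
100% contingency. Schedules (`build_schedule()`) reproduce the published
design counts exactly:

* training — 8 blocks × 12 trials, each stimulus twice per block (16
  presentations overall);
* outcome devaluation — 36 trials; each trial pairs one left- and one
  right-associated outcome with one of the two devalued. The printed
  description fixes only the pairing rule and the trial count, so the
  schedule uses all nine left×right pairs four times each with the
  devalued side counterbalanced two-and-two;
* slips-of-action — 9 blocks × 12 trials, each stimulus twice per block,
  never directly repeated (enforced across block boundaries as well), two
  outcomes devalued per block. The design constraint that each outcome is
  devalued in exactly three blocks is satisfied constructively by running
  through all nine (left-outcome, right-outcome) pairs, which also
  balances response sides within every block and prevents a response-side
  confound; the resulting 36 devalued / 72 valued trials are asserted for
  every seed;
* baseline — identical structure with devalued *stimuli* instead of
  outcomes.

The no-immediate-repeat orderings are found by rejection sampling, which
at these multiplicities (six stimuli, twice each per block) succeeds after
a handful of draws; an explicit failure guard exists but is unreachable at
the shipped sizes.

## The synthetic responder

The paper-level analyses of this task are purely descriptive, so the
simulated agent is deliberately minimal rather than a trial-by-trial value
learner: during training, per-stimulus accuracy rises from chance toward a
$1-\varepsilon$ ceiling with an exponential learning curve of rate
`a_learn`; in the go/no-go tests it responds on valued trials with
probability `r_base` and slips on devalued trials with probability
`r_base`·(1−g), where g ∈ [0, 1] is its goal-directedness. The baseline
test uses a separate, near-ceiling suppression parameter `g_baseline`,
reflecting that inhibition keyed directly to stimulus identity is easy —
this reproduces the reported ordering in which the baseline difference
score exceeds the slips DSI. Under this responder the DSI has the
closed-form expectation $100\,r_{\text{base}}\,g$, which the tests verify
by simulation; an ideal agent scores exactly 100 and an indiscriminate
responder exactly 0.

## Scoring and the DSI

`score_phase()` computes per-block and overall accuracies for training,
accuracy for outcome devaluation, and for the go/no-go phases the
percentage of responses on valued trials, on devalued trials, and their
difference — the DSI. The percentages are computed **per trial type**
(responses on valued trials out of 72 valued trials; likewise out of 36
devalued), because that normalization is the one consistent with how the
component response rates are conventionally reported; a literal
"share of total responses emitted" normalization is available behind
`normalization = "total_responses"` for comparability.

# Behavioral statistics

The 2×2 repeated-measures ANOVA on stay probabilities is computed through
within-subject contrasts — each effect is a one-sample t test on the
per-subject contrast and $F = t^2$ with $(1, n-1)$ degrees of freedom —
which for a 2×2 design is algebraically the textbook sums-of-squares
repeated-measures ANOVA; the equivalence is asserted against an `aov()`
Error-stratum oracle at tolerance 1e-10. The Friedman test wraps
`stats::friedman.test` (with the fully-tied corner case mapped to a zero
statistic); the Wilcoxon signed-rank test is implemented directly in its
normal-approximation form with tie correction because the base-R function
does not report the Z convention used in this literature, and is checked
against `stats::wilcox.test` p-values. The above-chance binomial test is
the exact upper tail $P(X \ge k)$; because published descriptions of such
tests are often ambiguous between per-subject-trials and
count-of-subjects readings, the function is generic and the study pipeline
uses the cohort mode (number of subjects above chance in the final
training block).

Stay probabilities classify each trial $t \ge 2$ by the *previous* trial's
reward and transition type; the first trial contributes no observation,
and pairs touching an invalid trial are skipped.

# Cross-task statistics

Outlier screening flags subjects whose DSI z-score reaches 2 (plus an
optional manual exclusion list, mirroring studies that also exclude on
qualitative grounds across phases). Spearman correlations use midranks,
one-tailed p-values from the t approximation in the hypothesized
direction, and Bonferroni adjustment over the family of three focal tests
(β_MB–DSI, β_MF–DSI, ω–DSI). All three focal tests are run with a positive
hypothesized direction.

Simple mediation fits the three OLS regressions (`m ~ x`, `y ~ x + m`,
`y ~ x`), reports the paths a, b, c′, c and the indirect effect ab (the
identity $c = c' + ab$ holds exactly on complete data and is asserted at
1e-10), a bias-corrected (not accelerated) percentile bootstrap over
case resamples — 5000 by default, seeded and reproducible — the Sobel
test $Z = ab / \sqrt{b^2\,SE_a^2 + a^2\,SE_b^2}$, and κ². κ² follows the
Preacher–Kelley definition: the observed indirect effect relative to the
largest indirect effect attainable holding the observed variances and the
x–y correlation fixed while keeping the implied correlation matrix
positive semi-definite. The maximizer is found numerically (a fine grid
over the x–m correlation with the inner maximum over the m–y correlation
taken at an interval endpoint, since ab is linear in it); the published
closed form is notoriously easy to mis-transcribe and the numerical
ceiling is exact to grid resolution. Bootstrap resampling is computed
from resampled moment matrices rather than per-resample `lm()` calls,
which makes the 500-replication coverage study in the acceptance suite
(n = 200, true indirect 0.25, 999 resamples each) affordable; measured
coverage lands near the nominal 95%.

# The synthetic cohort

A single standard-normal latent trait G per subject drives, with
standardized loadings, the transformed model-based weight ω (two-step
task), the logit goal-directedness g (instrumental task), and a visual
short-term-memory-like covariate (VPA), with weaker loadings on two
further covariates (WMT and DSST); a loading $\ell$ puts a fraction
$\ell^2$ of a trait's variance on G, so two traits with loadings
$\ell_1, \ell_2$ correlate $\ell_1\ell_2$. Defaults use loadings
$\sqrt{0.5}$ on ω and g (true cross-task correlation 0.5) and 0.6 / 0.35 /
0.3 on VPA / WMT / DSST, giving the qualitative pattern of interest: a
positive ω–DSI association partially mediated by the VPA-like covariate.

Group anchors for the RL parameters are the published group estimates for
this task family (ω 0.68 ± 0.07, β_MB 5.28, β_MF 2.39 — hence β₁ = 7.67,
with sd 1.80 taken from the dominant β_MB component since the β₁ spread
is not separately published — β₂ 4.18 ± 1.59, α₁ 0.50 ± 0.15, α₂
0.52 ± 0.25, λ 0.52 ± 0.24, ρ 0.13 ± 0.03), moment-matched onto the
transformed scale by the delta method. Covariates are clipped to their
published instrument ranges (VPA 3–18, WMT 11–24, DSST 60–110). The
instrumental agent's goal-directedness is centered at g = 0.81 with
logit-scale sd 0.8 and its response propensity at 0.85 ± 0.07, values
chosen so the simulated valued/devalued response rates land near the
reported group percentages (~82% valued, ~16% devalued, DSI in the
mid-60s).

What the generator does *not* emulate: reaction times and response-window
omissions, any learning or fatigue across the test phases, demographic
structure, measurement error in the covariates beyond independent
Gaussian noise, and any true causal structure behind the mediation (the
latent trait induces the correlational pattern only). Passing tests
therefore demonstrate that the estimation and scoring machinery recovers
known structure of this synthetic form — not that real data satisfy these
generating assumptions. In particular the true population coupling
between model-based control and devaluation sensitivity is unknown; the
loading is a free knob of the generator, never a ground-truth claim.

`run_study()` executes the full pipeline in the order of the analyses it
mirrors — EM fit, phase scoring, stay-probability ANOVA, Friedman,
above-chance binomial, Wilcoxon slips-vs-baseline, DSI outlier screen,
the three Bonferroni-corrected focal correlations, covariate
correlations, and the mediation model (x = fitted β_MB, m = VPA,
y = DSI) — and returns one structured report with the ground truth
attached for recovery checks.

# Numerical choices and problem sizes

* Optimizer: BFGS on the 7-dimensional transformed scale, relative
  tolerance 1e-8, 500-iteration cap; objective guarded against overflow
  (softmax by max-subtraction; transformed coordinates beyond ±50 are
  rejected with a large value so line searches cannot leave the numeric
  range of `exp`).
* Laplace curvature: central second differences with step
  $10^{-3}(1 + |\theta|)$.
* EM: tolerance 1e-3 on the prior mean, cap 100 iterations; prior
  variance floored at 1e-4 to avoid degenerate collapse when subjects are
  identical.
* Bias-corrected bootstrap: median-bias correction
  $z_0 = \Phi^{-1}(\#\{ab^* < \widehat{ab}\}/B)$ with the proportion
  clamped away from 0 and 1 for degenerate bootstrap distributions.
* Schedules: rejection sampling for no-repeat orderings with a
  10,000-attempt guard.
* Test-suite problem sizes are chosen to keep the full suite within a few
  minutes on one core while leaving comfortable Monte-Carlo margins: the
  transition-frequency check uses 1e5 draws against a 3σ binomial band;
  agent-signature checks use 1e4-trial sessions (stay-probability cells
  of ~2500 trials, so 3σ ≈ 0.06 for the interaction contrast); parameter
  recovery uses the published cohort size (28 subjects × 201 trials);
  the bootstrap coverage study uses 500 replications at n = 200 with an
  a-priori acceptance band of [0.90, 0.99] around the nominal 95%; the
  end-to-end check runs three n = 300 cohorts with a shortened EM
  schedule and requires a positive fitted-β_MB–DSI correlation in at
  least two of the three.

# Known limitations

* The group prior is diagonal; parameter correlations at the group level
  (e.g. between ω and β₁) are not modeled, matching the cited fitting
  approach but losing any such structure present in data.
* The Laplace E-step can understate posterior uncertainty at boundary-ish
  parameters (ω near 0 or 1), which mildly shrinks the estimated group
  variance there; the cohort-separation checks (pure MF vs pure MB
  cohorts) bound the practical impact.
* The instrumental-task agent is a two-parameter Bernoulli responder: it
  cannot produce sequential dependencies (post-error slowing, fatigue)
  within test phases, so statistics sensitive to trial order in those
  phases are exercised only under exchangeability.
* Fitted β_MB inherits between-subject variance from β₁ that is
  independent of the latent trait, so the realized fitted-β_MB–DSI
  correlation is substantially attenuated relative to the latent
  coupling — a faithful reflection of how such cross-task designs lose
  power, and the reason the end-to-end check uses n = 300.
* One-tailed inference and the z ≥ 2 outlier rule are reconstructions of
  common practice; both are parameterized so other conventions can be
  substituted.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` runs the default
28-subject coupled cohort through the full pipeline (EM capped at 20
iterations, 2000 bootstrap resamples) and writes the headline quantities
— empirical transition rate, fitted and true group-mean ω, recovery error,
group β_MB/β_MF, stay-probability F statistics, training/outcome-
devaluation accuracies, valued/devalued response percentages, mean DSI,
baseline difference, Wilcoxon Z, the focal Spearman coefficients and the
mediation summary — as a flat JSON file. Every value is computed at run
time from the seed passed on the command line.
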