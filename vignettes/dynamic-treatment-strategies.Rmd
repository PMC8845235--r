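---
title: "Learning dynamic drug-prescription strategies from offline ICU trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning dynamic drug-prescription strategies from offline ICU trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Critically ill cardiac patients receive a changing combination of drugs every
day of their ICU stay. Treating prescription as a *dynamic treatment regime*
means learning a decision rule that maps a patient's evolving observable
state — daily vitals, labs, heart-rhythm subtype, demographics, diagnoses —
to the day's drug combination. Two learning signals are available in
retrospective EHR data and they pull in different directions:

* a **supervised** signal: imitate what clinicians actually prescribed
  (safe, but inherits their mistakes and cannot out-perform them);
* a **reinforcement** signal: prefer actions whose *expected return* —
  the discounted terminal reward encoding in-hospital survival — is high
  (can improve outcomes, but may drift into clinically alien regimens).

`icudtr` implements a blended offline actor–critic learner in which a single
trade-off weight $\varepsilon \in [0,1]$ interpolates between the two, plus
the evaluation machinery needed to judge any such policy from retrospective
data alone, and a synthetic ICU cohort generator whose ground truth is known
so that every component can be validated end-to-end.

## Decision-process formulation

Each admission $i$ is a finite trajectory
$(S_{i,t}, A_{i,t}, S_{i,t+1}, r_{i,t})$, $t = 1,\dots,T_i$, where $S_{i,t}$
is the observable state on day $t$, $A_{i,t} \in \{0,1\}^K$ is the day's
binary drug combination, and the reward is terminal-only:
$r_{i,t} = 0$ for $t < T_i$ and $r_{i,T_i} = +r_s$ on survival,
$-r_d$ on in-hospital death (defaults $\pm 15$). The next state after the
final day is the termination marker (a zero state). The terminal-only
convention is forced by the outcome-weighted comparison model, whose
per-day return $V_{i,t} = \gamma^{T_i - t}\, r_{i,T_i}$ only makes sense
when all reward mass sits on the last day.

The true physiological state is latent; networks therefore consume a
**state window**: the last $W = 5$ days of (daily features, one-hot rhythm,
a real-day mask channel), flattened oldest-first, with standardized
demographics appended, plus the admission's padded diagnosis index sequence
routed through a trainable embedding that is mean-pooled across codes. Days
before admission are filled by replicating day 1 with mask 0. A five-day
window bounds the information set explicitly; any window-limited recurrent
policy is representable by a feed-forward map over this window, and the
fully analytic gradients of that map are verified against finite
differences in the test suite to $10^{-6}$ relative error.

## The learner

A deterministic actor $\mu(S\,|\,\theta^\mu)$ emits per-drug probabilities
$(\hat a^1,\dots,\hat a^K) \in (0,1)^K$; a critic $Q(S, A\,|\,\theta^Q)$
estimates the expected return of a state–action pair. Both have slowly
updated target copies. One gradient step on a minibatch of $N$ transitions
sampled uniformly from the offline dataset:

1. **Critic regression.** Targets
   $y_i = r_{i,t} + \gamma\, Q'(S_{i,t+1}, \mu'(S_{i,t+1}))$, with the
   bootstrap term dropped at termination; the critic minimizes the mean
   squared error $\frac1N \sum_i (y_i - Q(S_{i,t}, A_{i,t}))^2$ (Adam).
2. **Actor update.** The blended objective
   $L(\theta^\mu) = \varepsilon\, L_{RL} + (1-\varepsilon)\, L_{SL}$, where
   $L_{RL} = -\frac1N \sum_i Q(S_{i,t}, \mu(S_{i,t}))$ (the deterministic
   policy gradient, flowing through the critic's action input) and $L_{SL}$
   is the per-drug binary cross-entropy to the clinician's action.
3. **Soft target updates** $\theta' \leftarrow \tau\theta + (1-\tau)\theta'$.

$\varepsilon = 0$ is the pure supervised model, $\varepsilon = 1$ the pure
reinforcement model; comparison learners include the outcome-weighted
direct-policy-optimization actor (each day weighted by its standardized
discounted terminal return) and a dual-branch supervised classifier
(separate diagnosis and time-series encoders concatenated into a K-sigmoid
layer).

### Numerical choices

* **Supervised loss form.** The positive-label-only cross-entropy
  $-\frac1N\sum_i\sum_k a^k \log \hat a^k$ is degenerate in isolation: it is
  minimized by predicting 1 for every drug regardless of the state. The
  default is therefore the full binary cross-entropy; the positive-only form
  remains selectable (`sl_mode = "as_printed"`) for audit.
* **Target clipping.** With terminal-only rewards the true return is
  bounded by the reward magnitude, so critic targets are clamped to
  $[-r_d, r_s]$ (`clip_targets = TRUE`). Without this, the offline
  actor–critic exhibits the familiar bootstrap overestimation spiral: the
  actor exploits critic extrapolation error at actions never seen in the
  data, the target critic inherits the inflated values, and $Q$ drifts above
  the maximum attainable return.
* **Bootstrap target actions.** The target critic is evaluated at the
  *binarized* target-actor recommendation (`target_action = "binary"`).
  The critic only ever sees binary drug sets as data, so feeding it the
  actor's fractional probabilities during bootstrapping asks it to
  extrapolate off the action support on every update; over long training
  this recursion visibly mis-signs the critic's policy contrasts. The raw
  probability form remains available (`"probability"`).
* **Probability clamping.** Actor outputs are clamped away from 0/1 by
  $10^{-12}$ before logs.
* **Terminal bootstrapping.** Default drops $\gamma Q'$ at $t = T_i$; a
  strict zero-state reading (`terminal_bootstrap = "zero_state"`) evaluates
  the target networks on the termination marker instead.
* **Learning rates and steps.** Both networks use Adam at $10^{-3}$ by
  default; the packaged studies run 12–25k gradient steps at minibatch
  size 64. A lower actor rate (classic two-timescale training) is
  available by config and trades speed for a slower-drifting actor.

## Preprocessing

Raw trajectory tables become model-ready tensors through a fixed order of
steps — daily binning (24-hour half-open units anchored at admission; means
for point measurements, sums for cumulative outputs), composite variables
(shock index = heart rate / systolic pressure; GCS = eye + verbal + motor;
a missing component makes the composite missing), quantile outlier capping
(values outside per-feature empirical quantile bounds, default
(0.001, 0.999), are set missing), log transform of right-skewed variables,
z-normalization, and k-nearest-neighbour imputation (default $k = 5$,
Euclidean distance over mutually observed features rescaled by the fraction
observed, neighbour search against a reference pool of development rows).
Diagnosis codes are replaced by frequency-rank indices (most frequent = 1,
rank ties broken by code order), sorted ascending within patient and
zero-padded; 0 is reserved for padding and unseen codes map to a reserved
unknown index.

Every data-dependent statistic is fit on the development split once and
frozen into a metadata object that is re-applied verbatim to any other
split — the leakage-safe reading of a split that the source data description
leaves ambiguous. Re-application is deterministic, so transforming the same
raw cohort twice with the same metadata is bit-identical.

## Off-policy evaluation

The estimated in-hospital mortality of a candidate policy is computed by
outcome binning of critic returns:

1. score every state under the clinicians' *actual* actions with the critic;
2. discretize these returns into 5%-quantile units (duplicate edges merged;
   edge ties fall to the lower bin);
3. estimate each unit's mortality rate by the bootstrap mean of its states'
   mortality flags (2000 resamples; percentile interval reported);
4. score every state under the *recommended* actions, assign each return to
   a unit (out-of-range returns clamp to the extreme units — the only
   assignment under which evaluating the behaviour policy against itself is
   coherent), and accumulate expected deaths = unit rate x unit count;
5. divide by the number of states (state-wise) or repeat the whole
   procedure on initial states only with bins refit on initial-state
   returns (trajectory-wise).

The self-evaluation identity — recommended = actual recovers the observed
mortality up to bootstrap noise — is the central correctness check and is
asserted at study scale in the tests. Policy similarity uses the mean
Jaccard coefficient (per-day $|A \cap \hat A| / |A \cup \hat A|$, averaged
within and then across admissions; a day on which both drug sets are empty
counts as 1, since agreeing on "no drugs" is perfect agreement) and the
per-day Hamming treatment difference with its mortality-by-difference
curve.

## Interpretability

Feature importance of a policy is estimated by random forests on pooled
admission-days: features (excluding diagnoses) predict the policy's action.
R has no multi-output forest, so one `ranger` forest is fit per drug and
the impurity importances are averaged over drugs and normalized to sum 1;
drugs with constant targets are skipped and flagged. The 25 one-hot rhythm
subtypes are one categorical variable, so their importances are summed into
a single heart-rhythm entry (mass-conserving). Impurity importance is the
default meaning of "feature importance" here; it is fast and sufficient for
rank comparisons between the clinician and learned policies, though it is
known to favour high-cardinality continuous features over binary ones.

## The synthetic cohort generator

Because the real cohort behind this design is credential-gated, the
generator supplies cohorts with the statistical structure the analysis
assumes — and, unlike real data, a queryable ground truth
(`true_policy_value()` rolls any policy through the environment and
reports its true mortality).

* **Severity.** A latent daily severity $z_t$ follows a bounded AR(1)
  (persistence 0.9, innovation SD 0.35, clipped to $[-3, 3]$, initialized
  at the stationary spread). Simple, controllable, and sufficient for
  parameter-recovery testing.
* **Observations.** 15 named clinical features (vitals, GCS components,
  labs, urine output) are noisy monotone functions of $z_t$ with
  ICU-plausible locations and spreads; right-skewed labs are generated
  multiplicatively and form the default log-transform list. Rhythm subtype
  probabilities shift toward abnormal subtypes as severity rises.
  Missingness is completely at random per feature-day (default 20%); a
  severity-dependent (MNAR) mode exists but is off by default because the
  imputation step assumes nothing stronger than KNN-recoverable structure.
* **Behaviour policy.** Clinicians respond to what they can see: each drug
  is drawn independently with probability
  `plogis(score / temperature)` where the score is linear in an observed
  bedside severity index (the direction-corrected standardized mean of the
  day's charted values) and demographics. Conditioning the behaviour policy
  on observables makes treatment conditionally randomized given the
  recorded state — the no-unmeasured-confounders assumption that offline
  policy learning needs, here true by construction. A quarter of the
  formulary carries positive benefit and is prescribed on roughly half of
  days; the rest is touched rarely (~12%), keeping daily prescriptions
  sparse the way real formularies are used. Dense prescribing is not just
  unrealistic — it degrades the Jaccard metric into one maximized by
  prescribing everything.
* **Outcome.** Death occurs at trajectory end with probability logistic in
  mean severity (weight 0.5) and mean *treatment adequacy* (the
  benefit-weighted fraction of beneficial drugs given), with the adequacy
  weight scaled by `treatment_effect_size`. The intercept is calibrated by
  quadrature on the exact stay-length-averaged severity distribution so
  that the marginal mortality under neutral treatment equals
  `base_mortality` exactly, despite the Jensen inflation a logistic link
  would otherwise introduce.

What the generator does *not* emulate: pharmacokinetics, drug–drug
interactions, dose levels, mid-stay censoring, informative stay length, or
any real EHR schema. Passing tests on this generator therefore show that
the pipeline is correct and that the learner improves outcomes *when its
assumptions hold*; they say nothing about performance on data where
confounding is unmeasured or treatment effects are weaker than the noise.

## Problem sizes used by the tests

The packaged studies run at deliberately moderate scale: cohorts of 60–150
admissions for unit checks and 2,000 admissions (~19,000 admission-days,
K = 20 drugs, 17 processed features) for the study-scale properties;
12,000–25,000 gradient steps for trained models; 20,000 Monte-Carlo
rollouts (binomial SE ≈ 0.002 at 10% mortality) for ground-truth policy
values; 2,000 bootstrap resamples per return unit. These sizes give every
stochastic assertion at least a 2–3 SE margin while keeping a full run in
the minutes range on one CPU core.

## Known limitations

* The actor and critic are single-hidden-layer window models; they
  represent any 5-day-window policy in principle but may need more width
  or steps than a gated recurrent model would for long-range structure.
* Impurity importances are biased toward continuous features.
* The OPE estimator inherits the critic's biases: it ranks policies
  correctly in the tested conditions, but it is not doubly robust and its
  bins are only as good as the critic's returns.
* With K drugs and dense recommendations the Jaccard coefficient saturates;
  comparisons across policies with very different prescription densities
  should lean on the treatment-difference curve as well.
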