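---
title: "Generating synthetic EHR cohorts: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic EHR cohorts: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Electronic health records mix static demographics with time-stamped
measurements, and real cohorts are awkward for generative models in four
specific ways: features are heterogeneous (numeric and categorical, static
and temporal); 30--95% of temporal entries are missing, and the missingness
pattern itself is clinically meaningful; numeric marginals are skewed or
concentrated on discrete grids (respiratory pressures recorded as multiples
of 5, alarm limits pinned at default values), which invites mode collapse
in adversarial training; and sequence lengths vary by an order of magnitude
across patients. `synthehr` generates synthetic cohorts that preserve these
properties while keeping individual records unlinkable to the training
data, and ships the evaluation suite (fidelity and privacy) needed to check
both claims.

# The two-stage model

**Stage 1 — representation.** Every record is mapped into model space:

* Numeric features and measurement times go through *stochastic
  normalization* (`fit_normalizer()`): each unique observed value receives
  a sub-interval of $[0,1]$ whose width is its empirical frequency, and
  every occurrence is replaced by a uniform draw from its interval. The
  normalized marginal is uniform — the easiest target for a GAN — and the
  map is *exactly* invertible (`renormalize_values()`), so synthetic
  numerics always land back on the training support: grid-valued features
  stay on the grid, skewed tails are reproduced by construction. Intervals
  are assigned in ascending value order (the algorithm itself does not fix
  an order), which makes the transform monotone in distribution and the
  inverse a simple interval search; intervals are half-open with the last
  one closed, so the inverse is total after clipping to $[0,1]$.
* Categorical features are one-hot encoded *with an explicit missing slot*
  and passed through a learned codec: a single-hidden-layer perceptron
  encoder to a compact embedding (output tanh-bounded so embeddings share
  the $[-1,1]$ scale of the other model-space blocks) and one linear-softmax
  decoder head per feature, trained with summed cross entropy. Separate
  codecs serve the static and temporal scopes; the temporal codec is applied
  per step with shared weights.
* Missingness is modeled explicitly: binary masks for every block, plus a
  per-step presence channel `step_present` that represents sequence length
  to the networks (a leading run of ones). Padding to `T_max` carries zeros
  and `step_present = 0` and is excluded from every loss term.

**Stage 2 — compression and adversarial training.** A GRU encoder consumes
the per-step concatenation (values, embeddings, time, masks, presence), its
final state joins a feed-forward static branch, and a linear projection
yields the latent state $e$. A mirrored decoder (static heads plus a GRU
unrolled for `T_max` steps) reconstructs every block. The reconstruction
loss is binary cross entropy on all mask channels plus $\lambda$ times
mean squared error on times, values and embeddings, *gated by the masks*:
an unobserved or padded entry contributes exactly nothing (verified
bit-identically in the tests). A Wasserstein GAN with gradient penalty is
then trained over the latent rows: the critic maximizes
$\mathrm{mean}\,D(e) - \mathrm{mean}\,D(\hat e)$ minus
$\eta\,(\lVert\nabla D(\tilde e)\rVert - 1)^2$ on random interpolates
$\tilde e = \epsilon e + (1-\epsilon)\hat e$ with scalar
$\epsilon \sim U(0,1)$ per sample and $\eta = 10$, with five critic steps
per generator step. Both networks are MLPs with tanh hidden layers; the
penalty's parameter gradient is computed exactly (forward-tangent over
reverse mode) rather than approximately, and is finite-difference-verified
in the test suite. The GAN trains in per-dimension standardized latent
space; the affine map is stored and inverted at sampling time, because
WGAN-GP at a fixed learning rate is sensitive to coordinate scales the
encoder is otherwise free to choose.

**Synthesis.** `synthesize()` draws $z \sim N(0, I)$, maps it through the
generator and decoder, derives each record's length from the leading run of
the presence channel (floored at 1), decodes categorical embeddings with
the frozen codec heads, and renormalizes numerics and times (times are then
sorted non-decreasing within each record, since generation does not
guarantee order). The mask channel is authoritative for categorical
missingness: when it says observed but the codec head argmaxes the missing
slot, the best non-missing category is taken.

# Generative read-outs: a deliberate design choice

The decoder heads are likelihood models: mask heads are Bernoulli models
(trained with cross entropy), value heads are fixed-variance Gaussian
models (trained with squared error). At synthesis the package by default
*samples* those observation models instead of taking their modes:

* masks are drawn as seeded Bernoulli variables from the decoded
  probabilities (`mask_readout = "sample"`); a hard 0.5 threshold is
  available (`"threshold"`);
* values are drawn as decoded mean plus seeded Gaussian noise at the
  per-feature training residual SD stored in the model container
  (`value_readout = "sample"`; `"mean"` gives the deterministic decode).

The rationale: where the autoencoder reconstructs a channel sharply
(probabilities near 0/1 — the presence channel and rarely-missing static
blocks behave this way), sampling and thresholding coincide. Where
per-entry variation is irreducible noise for a finite latent code — e.g.
missing-completely-at-random bits, or within-record measurement jitter —
the conditional mean is systematically shrunk: thresholding then collapses
every mask entry to its majority side (synthetic missing rates of 0 or 1
for features whose true rates are 0.35 or 0.8), and mean decoding collapses
value SDs several-fold. Sampling the observation model restores the
marginal behavior without touching training. Both alternatives are exposed
so the deterministic decode remains reproducible.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` | 1 | balance of MSE terms against mask BCE terms in the reconstruction loss |
| `d_e` | 64 | latent width (the GAN's sample space) |
| `hidden` | 128 | GRU / feed-forward hidden width |
| `eta` | 10 | gradient-penalty weight |
| `critic_steps` | 5 | critic updates per generator update |
| `d_z` | `d_e` | generator noise width |
| `d_c` | `min(16, ceil(sum(V_k)/2))` | codec embedding width |
| `max_unique` | `Inf` | optional equal-frequency binning cap for normalizer size |
| outlier percentiles | 0.001 / 0.999 | observed-value bounds per numeric feature |
| reid `tolerance` | 0.05 | numeric match tolerance, min-max-normalized units |
| reid `known_fraction` | 0.5 | fraction of features the adversary knows |
| attribute `k` | 5 | kNN neighbourhood size |

Optimizer settings (Adam rates, batch sizes, epochs) live in
`training_config()` and are not hard-coded anywhere.

# The toy cohort generator

`toy_config()` / `default_mimic_like()` simulate an inpatient-like cohort
with known ground truth: 3 static numerics (age, gender, and a binary
mortality outcome calibrated to 10% prevalence through the intercept of a
logistic model), 3 nonuniform static categoricals, 10 temporal numerics
covering normal, log-normal (skewed), reversed-gamma, discrete-grid and
spike-plus-uniform laws with missingness between 0.35 and 0.80, 2 temporal
categoricals, sequence lengths $1 + \mathrm{NB}(\mu = 8, k = 2)$ capped at
30, and times as cumulative exponential gaps (hence non-decreasing by
construction). A latent per-patient severity shifts several vitals and
drives the outcome, so the outcome signal is recoverable from the features
(the planted-signal tests rely on this); missingness is MCAR by default
with an optional severity-dependent (MAR) dial.

What the generator does *not* emulate: clinically realistic value ranges or
coding systems, cross-feature correlation structure beyond the single
severity factor, informative observation *times*, and non-stationarity
within a stay. Passing tests on this fixture therefore demonstrate the
machinery end to end, not clinical realism.

# Problem sizes and numerical choices

The documented end-to-end configuration trains on 1,600 records (an 80/20
split of a 2,000-record cohort, `T_max = 30`, 18 features) with `d_e = 64`,
hidden width 96, 90 autoencoder epochs at batch 64, and 300 GAN epochs —
about ten minutes on one CPU core. At this scale the synthetic cohort
reproduces per-feature means, SDs and missing rates closely (all
Kolmogorov–Smirnov statistics below 0.2 in the acceptance run, most below
0.1) and the membership-inference attack sits at chance. Two honest
limitations at this scale: train-on-synthetic/test-on-real utility trails
train-on-real (RF AUC roughly 0.55–0.60 versus 0.68 on the toy mortality
task — the latent GAN preserves marginals better than the outcome–feature
coupling), and low-probability temporal categories are reproduced only
approximately. The bucket-matching post-processor
(`bucket_match_postprocess()`, off by default because it can only degrade
utility metrics, never improve them) closes residual marginal gaps: with
200 real-quantile buckets it drives two-sample KS below 0.01 even for a
deliberately mismatched synthetic sample; its per-bucket target counts come
from cumulative rounding (boundary error below one sample) and
within-bucket values are rank-preservingly drawn from the real bucket's
empirical distribution, making it idempotent and monotone.

Other numerical conventions: percentile bounds use the default empirical
quantile definition and filter *strictly* outside values; outlier filtering
defaults to masking the value rather than dropping the patient (the
alternative is exposed), because masking preserves cohort size and
missingness structure; tied timestamps are allowed and kept in stable
order; categorical argmax ties break to the lower vocabulary index; the
normalizer guards half-open intervals by nudging draws strictly below the
upper bound; features never observed in a training split abort fitting
with a named error rather than silently degrading.

# Privacy metrics and their conventions

Membership inference reports the balanced accuracy of a nearest-synthetic-
distance classifier whose threshold is optimized *on the query pool itself*
— an upper bound on attack power, so reported values are conservative
(slightly above 0.5 even for a perfectly private release).
Re-identification gives the adversary a random half of each training
record's features, matches to the nearest synthetic record on those, and
scores success if all unknown numerics fall within the tolerance and all
unknown categoricals match; the baseline replaces the release with holdout
records, and `synth := holdout` reproduces the baseline exactly (a test
asserts identity). Attribute inference compares kNN classifiers fitted on
synthetic versus real data, with multi-class attributes scored by mean
pairwise one-vs-one AUC (verified against brute-force enumeration). The
distance model is Euclidean on min-max-scaled numerics plus Hamming on
categoricals, combined additively; these conventions are reported alongside
every result because attack numbers are only meaningful relative to their
configuration.
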