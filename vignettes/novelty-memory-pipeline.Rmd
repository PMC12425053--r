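---
title: "Quantifying event novelty and its effect on autobiographical memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying event novelty and its effect on autobiographical memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltydiary)
```

## The measurement problem

Daily-diary studies of autobiographical memory collect, for each participant,
a dense sample of self-reported events (here: three events per day over a
two-week window), each with a short free-text description, the participant's
own *regularity* label — `new` (never done before), `periodic` (done
occasionally), `routine` (done almost every day) — and intensity ratings for
seven feelings (happy, positive, sad, negative, excited, calm, afraid) on a
1–5 scale. A delayed memory test then yields a 1–5 vividness rating for every
event and, for a random one-third of events (one per day), a free-text
recall.

The scientific question is how different *sources of novelty* predict memory.
Novelty is operationalized three ways:

* **Event regularity** — the participant's own categorical judgment.
* **Relative semantic similarity (RSS)** — for event $i$ of a participant
  with events $1..n$, embed each description as a vector $e_j$ and take

  $$\mathrm{RSS}_i = \frac{1}{n-1}\sum_{j \ne i}
      \frac{e_i \cdot e_j}{\lVert e_i\rVert\,\lVert e_j\rVert}.$$

  Low RSS means the event is semantically unlike the rest of that person's
  life — *semantic* novelty. Comparisons never cross participants, the
  self-pair is always excluded, and all of a participant's events are
  compared regardless of day.
* **Relative emotion similarity (RES)** — with $m_i$ the 7-vector of raw
  emotion ratings,

  $$\bar d_i = \frac{1}{n-1} \sum_{j\neq i} \lVert m_i - m_j \rVert_2,
  \qquad \mathrm{RES}_i = 1/\bar d_i.$$

  Low RES means the event's *feelings* were unusual for that person. The
  plain reciprocal is the default; a bounded variant $1/(1+\bar d_i)$ is
  available (`res_transform = "shifted_reciprocal"`) since the inversion is
  a convention, not a law. If every other vector is identical to $m_i$
  (so $\bar d_i = 0$) the reciprocal is undefined; the package emits an
  `Inf` *infinite-similarity sentinel* with a warning and model fits drop
  such rows listwise with a reported count. Ratings are used raw: all seven
  share one 1–5 scale, so standardizing before the distance is not forced
  and is not done.

Memory outcomes are **vividness**, **episodic detail counts** scored from
the recall narratives, and **memory stability** — the cosine similarity
between the embedding of the diary-phase description and the embedding of
its recall, a content-level measure of how reproducible the memory is.

## Embeddings: a contract, not a model

Every metric above is defined on arbitrary real vectors, so the embedder is
a pluggable contract (`embedder_spec()`). The pretrained sentence-transformer
conventionally used for paragraph-level diary text (`all-mpnet-base-v2`,
768 dimensions) is supported as an *injected* backend: it requires an
`encoder` function, and fails with an explicit error rather than silently
falling back. The shipped reference backend is a deterministic token-hashing
bag-of-ngrams projector: lower-cased word unigrams and adjacent bigrams are
hashed (polynomial hash mod $2^{31}{-}1$) into `dimension` signed buckets.
It involves no randomness and no downloads, reproduces bitwise across
processes, and — because cosine handles scale — exercises every downstream
code path identically to a learned embedder. Vectors are deliberately not
L2-normalized at embed time, keeping the contract backend-agnostic.

## Detail scoring: a transparent stand-in for an LLM scorer

The Autobiographical-Interview-style scoring counts detail units per
category: *event*, *place*, *time*, *thought/emotion*, *perceptual*
(episodic) versus *non-episodic*. Production studies increasingly delegate
the chunk-and-categorize step to a large language model; that cannot be a
reproducible reference, so the package defines its own two-stage rule
backend and treats any LLM as an injected adapter behind the same contract
(`backend = "llm_adapter"`, never exercised in tests):

1. **Segmentation** (`segment_text()`): split after sentence terminators,
   and within sentences before a coordinating conjunction or comma that
   introduces a finite clause (i.e. is followed by a subject pronoun).
   Spans are 0-based half-open character offsets that cover all
   non-whitespace text — nothing is dropped.
2. **Categorization** (`categorize_chunks()`): a versioned cue lexicon
   (shipped as plain text, one cue per line, category-sectioned) with fixed
   precedence *place > time > perceptual > thought/emotion > event*; a chunk
   firing no cue is non-episodic. Precedence resolves multi-cue chunks
   deterministically — "we met at the park" is a place detail even though
   "met" is an event verb. Each chunk gets exactly one category.

The scoring-validation statistic is preserved as `detail_agreement()`: the
Pearson correlation between two scorers' total-episodic counts over the same
items (defined only for ≥ 3 items with variance in both series).

"Meaningful chunk" has no published operational definition, and neither does
the set of non-episodic subcategories; clause-level segmentation and the
single non-episodic bucket are this package's own decisions, and the lexicon
version is recorded in every scoring result so future revisions remain
distinguishable. Only recall-phase texts are scored in the default pipeline;
scoring diary-phase descriptions is available by calling `score_details()`
on them directly.

## The models

Outcomes are analyzed with participant-level mixed models
(`fit_mixed()`), REML-estimated via `lme4`/`lmerTest`. The headline
vividness model is

```
vividness ~ regularity * rss + res + (1 + rss | participant_id)
```

with `new` as the reference level (marginal means make the results
coding-invariant). If the requested random-slope structure produces a
singular fit — any random-effect variance below $10^{-6}$ times the residual
variance, or an exact boundary fit, or non-convergence — the model is
refitted once with the random intercept only and `fallback_applied` is
recorded; the refit never cascades. Covariates are uncentered by default
(`center = TRUE` is available); slopes are unaffected by centering.

Downstream inference:

* `emm_contrasts()` — estimated marginal means per regularity level
  (covariates at observed means) and all $k(k-1)/2$ pairwise contrasts,
  Tukey-adjusted via the studentized-range distribution. Adjusted $p$ never
  falls below the unadjusted $p$.
* `simple_slopes()` — per-level covariate slopes as linear combinations of
  fixed effects with delta-method standard errors; the difference between
  two level slopes equals the fitted interaction coefficient exactly.
* `compare_models()` — likelihood-ratio comparison of nested fixed-effect
  specifications, always on ML refits (REML likelihoods are not comparable
  across fixed structures), with df equal to the number of dropped
  parameters and the AIC difference reported.
* `emotion_correlations()` — the 7×7 Pearson matrix of the raw ratings;
  constant columns yield flagged `NA`s, never silent zeros.
* `day_level_model()` — end-of-day positivity regressed on the indicator
  that the day contained at least one `new` event, with a participant
  random intercept.

Denominator degrees of freedom for contrasts and slopes use the
Satterthwaite approximation, the convention of the `lmerTest`/`emmeans`
stack this package builds on. Optimizer defaults of `lme4` are kept;
the singularity threshold ($10^{-6}$ relative) is the one numerical
tolerance the package sets itself.

## The synthetic-data generator

`simulate_diary()` produces complete datasets with known ground truth, at
the reference design of 41 participants × 14 days × 3 events/day with the
regularity mixture proportional to 359:1050:264 and one free recall per
day. Its structure, chosen once and fixed:

* **Semantics.** Each participant has a latent "home" vector (32
  dimensions by default); an event is home plus Gaussian noise whose spread
  grows with novelty (sd 0.9 routine, 1.0 periodic, 1.3 new). This yields
  RSS level means ordered routine > periodic > new with level differences
  of a few hundredths against an overall RSS sd of ≈ 0.09 — the same order
  of magnitude as in real diary data, so that simulated effect sizes and
  standard errors are not unrealistically sharp.
* **Emotions.** Latent ratings = per-emotion base + participant shift +
  regularity offsets (new events: more excited and afraid, less calm) +
  shared valence/negative-affect factors (which induce the strong
  happy–positive and sad–negative correlations) + noise, rounded and
  clamped to 1–5. New events get extra arousal-channel spread, making them
  the most emotionally distinct (lowest RES).
* **Vividness.** A latent response
  $3.8 + \text{offset}(reg) + b_{reg}\,\mathrm{RSS}^{c} + b_{res}\,
  \mathrm{RES}^{c} + u_p + s_p\,\mathrm{RSS}^{c} + \varepsilon$
  (defaults: offsets 0/−0.79/−1.55; RSS slopes +2.18 / +0.35 / −2.67 by
  level; RES slope −1.64; $u_p\sim N(0,0.5^2)$, $s_p\sim N(0,0.3^2)$,
  $\varepsilon\sim N(0,0.8^2)$), thresholded at fixed cutpoints
  (round-and-clamp) to a 1–5 rating that the models treat as continuous,
  as linear mixed analyses of such scales do. RSS is centered within
  regularity level inside the linear predictor — the per-level slopes are
  within-level effects, so this only re-anchors the level intercepts and
  makes the offsets equal level-mean differences — and the intercept
  places the grand mean mid-scale (≈ 3.05), keeping floor/ceiling clamping
  under ~10% per tail so discretization attenuates slopes only mildly.
* **Recalls and stability.** The recall embedding is the encoding embedding
  plus Gaussian noise with regularity-dependent sd (0.5/0.55/0.7), giving
  stability ordered new ≳ periodic > routine with level contrasts of
  0.04–0.07 cosine units.
* **Narratives.** Descriptions are 2–5 sentences sampled from a shipped
  category-tagged template bank whose sentences are constructed to be
  scored into exactly their own category by the rule backend; the planted
  per-category counts are part of the ground truth. Recall texts keep each
  sentence with probability 0.9/0.8/0.6 by regularity (at least one).
* **Days.** Positivity = 3.0 + 0.22 × (any `new` event that day) +
  participant intercept (sd 0.4) + noise (sd 0.5).
* **Missingness.** A per-day dropout probability (default 0) removes whole
  participant-days, mirroring how real missed diary days appear as absent
  rows; nothing is imputed, and all metrics are defined over whatever
  events exist, so variable day counts need no special handling.

The generator emulates the *statistical* structure the analysis assumes —
nesting, regularity-graded similarity, opposing within-level slopes,
emotion factor structure. It does not emulate real language (templates are
a closed bank), real embedding geometry (isotropic Gaussian, not a learned
manifold), ordinal measurement processes beyond thresholding, or
self-report biases. Passing recovery tests therefore demonstrates that the
pipeline measures what it defines and recovers generating parameters under
its own assumptions — not that those assumptions hold in any particular
real dataset.

## Verification strategy and problem sizes

The test suite checks, among others: metric equivalence against naive
double-loop oracles over 50 random synthetic participants (5–40 events,
8–64 dimensions, agreement to ~13 significant digits); analytic edge cases
(cosine identity/orthogonality; the forced $\sqrt{112}$ two-vector RES
case); exact recovery of planted detail counts on 500 template narratives
with scorer agreement exactly 1; parameter recovery at study scale (100
replicates at 41 participants: the per-level RSS slopes and the
day-positivity effect covered by their own 95% CIs in ≥ 90, opposing slope
signs jointly detected in ≥ 80); calibration of the regularity omnibus and
interaction likelihood-ratio tests under a null generator (500 replicates,
rejection rates within [0.03, 0.07] at $\alpha = .05$); deterministic
singular-fit fallback on data constructed with realized zero slope
variance (residuals projected orthogonal to the covariate within
participant — with merely distributional zero variance the boundary
estimate occurs only about half the time, a standard property of variance
components at the boundary); and agreement of `emm_contrasts()` with a
closed-form Tukey HSD computation on balanced one-way data. Replicate
counts and dataset sizes are the package's chosen verification design and
run on a single CPU in minutes.

## Known limitations

* The rule lexicon is small and English-only; it is a reference
  implementation for validating scoring *logic*, not a competitive scorer
  for arbitrary prose. Real studies should inject their scorer of choice
  and validate it with `detail_agreement()`.
* The hashing embedder captures lexical overlap only; semantic similarity
  between paraphrases requires the pretrained backend.
* Treating 1–5 vividness as continuous follows field practice but slightly
  attenuates slopes near the scale ends; the generator documents this and
  keeps censoring moderate rather than pretending it away.
* Likelihood-ratio $p$-values for fixed effects use the asymptotic
  $\chi^2$ reference, adequate at the study's size (≈ 41 groups, ≈ 1700
  rows) as the null-calibration test verifies, but not for very small
  samples.

## A worked run

```{r example, eval = FALSE}
sdat <- simulate_diary(sim_config(seed = 1))
metrics <- compute_metrics(sdat$dataset,
                           embeddings = sdat$truth$embeddings,
                           recall_embeddings = sdat$truth$recall_embeddings)
tab <- as_analysis_table(metrics)
fit <- fit_mixed(vividness ~ regularity * rss + res, tab, slope_terms = "rss")
summary(fit)
emm_contrasts(fit, "regularity")
simple_slopes(fit, "rss", "regularity")
day_level_model(sdat$dataset)
```
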