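# noveltydiary

Event novelty metrics and multilevel analysis for autobiographical diary
studies.

## The problem

Intensive-longitudinal (daily diary) studies ask how the *novelty* of
everyday experiences shapes autobiographical memory. Participants report
several events per day over a diary window — a free-text description, their
own regularity label (`new` / `periodic` / `routine`), and 1–5 ratings for
seven feelings — then, at a delayed test, rate the vividness of every event
and freely recall a random one-third of them (one per day). Answering the
scientific question requires metrics that are not in any standard toolbox:

* **RSS (relative semantic similarity)** — for event *i* of one
  participant, the mean cosine similarity between its text embedding and
  the embeddings of every *other* event that participant reported:

      RSS_i = (1 / (n-1)) * sum_{j != i} cos(e_i, e_j)

  Low RSS = semantic novelty. Strictly within-participant, self-pair
  excluded.
* **RES (relative emotion similarity)** — the inverse of the mean Euclidean
  distance between event *i*'s 7-dimensional emotion-rating vector and
  every other such vector from the same participant
  (`1 / dbar_i`, bounded variant `1 / (1 + dbar_i)` available). Low RES =
  emotional distinctiveness.
* **Memory stability** — the cosine similarity between the embedding of the
  diary-phase description and the embedding of its delayed free recall.
* **Episodic detail counts** — Autobiographical-Interview-style scoring of
  recall narratives: deterministic clause segmentation, then one category
  per chunk (event / place / time / thought-emotion / perceptual /
  non-episodic) from a versioned cue lexicon with fixed precedence; any LLM
  scorer can be injected behind the same contract, and scorer agreement is
  quantified as the Pearson correlation of total-episodic counts.

Outcomes are analyzed with participant-level mixed models (REML via
lme4/lmerTest) of the form
`vividness ~ regularity * rss + res + (1 + rss | participant)`, with an
automatic, recorded fallback to a random-intercept-only fit when the
requested structure is singular; Tukey-adjusted marginal-mean contrasts,
per-level simple slopes with delta-method SEs, ML likelihood-ratio model
comparisons, and a day-level model of end-of-day positivity on "did
anything new happen today". A synthetic-data generator produces complete
study-scale datasets (41 participants × 14 days × 3 events/day, regularity
mixture 359:1050:264) with full ground truth for parameter-recovery and
calibration work.

For the model and design details, see the methods vignette:
`vignettes/novelty-memory-pipeline.Rmd`.

## A worked example

```r
library(noveltydiary)

sdat    <- simulate_diary(sim_config(seed = 1))      # 1,722 events, 41 participants
metrics <- compute_metrics(sdat$dataset,
                           embeddings        = sdat$truth$embeddings,
                           recall_embeddings = sdat$truth$recall_embeddings)
tab <- as_analysis_table(metrics)
fit <- fit_mixed(vividness ~ regularity * rss + res, tab, slope_terms = "rss")
simple_slopes(fit, "rss", "regularity")
```

```
     level      slope        se       df   ci_lower  ci_upper      p_value
1      new  2.0758294 0.5141030 1713.674  1.0674939  3.084165 5.634242e-05
2 periodic  0.4597163 0.4140593 1118.849 -0.3527039  1.272137 2.671226e-01
3  routine -2.1947566 0.7688179 1521.949 -3.7028113 -0.686702 4.365914e-03
```

The generating truths for this dataset were +2.18 (new), +0.35 (periodic)
and −2.67 (routine): RSS *increases* recall vividness for self-labeled new
events and *decreases* it for routine ones, and the fitted slopes recover
both signs with the truths inside the 95% CIs. The pairwise regularity
contrasts on vividness:

```r
emm_contrasts(fit, "regularity")
```

```
  level_a  level_b estimate     se   df ci_lower ci_upper p_unadjusted  p_tukey
      new periodic    0.776 0.0599 1670    0.635    0.916     1.29e-36 5.48e-13
      new  routine    1.430 0.0801 1690    1.250    1.620     9.40e-66 1.33e-12
 periodic  routine    0.659 0.0639 1680    0.509    0.809     3.44e-24 1.12e-12
```

New events are recalled most vividly (generating level-mean differences
0.79 and 1.55). Real data enter through `read_dataset()` (CSV or
JSON-lines; schema documented in `?read_dataset` and `?as_diary_dataset`),
after which the identical calls apply with
`compute_metrics(dataset, embedder_spec(...))` embedding the actual texts.

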