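---
title: "Methods: building a subjective well-being profile from status text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a subjective well-being profile from status text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Subjective well-being (SWB) has two constructs: *affect* (the emotional
component, with an intensity and a frequency facet) and *satisfaction with
life* (SWL), a cognitive self-evaluation usually measured by a five-item
scale on a 1–7 range. Self-reports of SWL are episodic and biased toward
peak and recent experience; the language people post on social media offers
a non-intrusive, longitudinal alternative. `swbprofiler` implements a
complete pipeline that turns per-user status updates into an SWB profile:
lexicon-based sentiment scoring, affect feature extraction, closed-vocabulary
category counts and truncated-topic-table scores, elastic-net feature
reduction, and a random-forest regression of self-reported SWL, followed by
a predictive-validity check against CES-D depression scores and
activity-conditioned sentiment z-scores.

Because the corpora such models are trained on are private, the package
ships a synthetic-corpus generator with planted ground truth. Every stage of
the pipeline is exercised and verified on generated data; nothing in the
package requires access to any real social-media dataset.

## Text preprocessing

Raw statuses pass through a fixed order of operations: hyperlink removal
(tokens starting `http://`, `https://` or `www.`), digit removal, emoticon
conversion, punctuation removal, lowercasing, whitespace tokenization. The
order matters twice: URLs are removed first so that `":/"` inside a
hyperlink cannot be read as an emoticon, and emoticons are converted before
punctuation stripping because they are made of punctuation. Emoticon
variants collapse to concept tokens (`":-)"`, `":)"`, `"=)"` →
`"happyface"`; frowns → `"sadface"`), which also covers users who type the
long form directly. Only those two mappings are treated as normative; the
shipped map (`default_smiley_map()`) carries a small editable inventory of
common variants. Stop words are kept, because all downstream scoring uses
closed word lists that already account for them.

## Affect features

Each status is scored by counting valence words from a ±1 lexicon: +1 per
positive token, −1 per negative token, repeats included. Polarity is the
sign of the sum (zero = neutral). Four user-level features follow:

* **mean sentiment** (intensity): the sum of all valence contributions
  divided by the user's *status count* — not the word count. Status lengths
  are extremely uneven (roughly 11% under four words, 24% over twenty), so
  the number of statuses is the more stable unit of expressive output.
* **positive and negative frequency**: proportions of positive and negative
  statuses, with neutral statuses kept in the denominator.
* **positive/negative ratio**: add-one smoothed, (#pos + 1)/(#neg + 1),
  because many users post no negative status at all and the raw ratio is
  undefined there; the raw ratio is also reported for users where it exists.

## Topic and category features

Each user's statuses are concatenated into one document. Category features
count document tokens falling in each closed-vocabulary category; like
sentiment, they are normalized by status count (the resource does not fix a
normalization, so the package uses the same convention throughout; raw
counts are retained).

Topic features come from a *truncated* word–topic probability table: each
topic lists at most 20 words with p(t|w) values. Two scoring rules are
implemented:

* **probability scoring**: p(t|u) = Σ_w p(t|w)·p(w|u), summed over the
  words listed under the topic, with p(w|u) the word's relative frequency in
  the user's document. Truncation makes this rule pathological: a word kept
  in only one topic carries p(t|w) = 1 and overstates that topic, while
  p(w|u) is inflated for users with few words.
* **word-count scoring** (the rule the model uses): every use of a word
  adds 1 to each topic listing it, ignoring p(t|w). This flattens the
  artificial spread — the max/min ratio over a user's positive topic scores
  is typically far smaller than under the probability rule. The package
  tests this as a property on generated fixtures in the brief-status regime
  (few distinct topic words, used once or twice each) rather than assuming
  it universally.

`build_feature_matrix()` assembles affect, categories and topics into one
matrix with namespaced columns (`affect:*`, `cat:*`, `topic:*`); a sparse
user-by-word matrix drives the computation, and the per-document scoring
functions serve as its oracle in the tests.

## Feature reduction and the SWL model

Users are split once into a training fraction (default 1873/2612 ≈ 0.717,
the split proportion of the study the pipeline reproduces) and a held-out
test set. An elastic net — mixing parameter 0.1, i.e. mostly ridge with a
small lasso component — is fitted on the training rows of the category and
topic columns; features with nonzero coefficients at the cross-validated
penalty survive. The mixing value 0.1 is read as the L1/L2 mixing parameter
(its conventional meaning in the glmnet family); the penalty strength is
chosen by 10-fold cross-validation at the 1-SE rule, since no fixed value is
prescribed. The mostly-ridge mixing keeps groups of correlated informative
topics together instead of arbitrarily keeping one representative. The three
sentiment features bypass selection and always enter the model.

The predictor is a random forest (regression mode: each tree is trained on a
bootstrap resample, predictions are the *mean* of tree outputs — majority
vote is the classification analogue). Defaults are ntree = 1000, mtry = 3;
`grid = "default"` runs the eight-cell manual search ntree ∈ {500, 1000,
1500, 2000} × mtry ∈ {2, 3}, scored by out-of-bag (OOB) correlation with
the response — OOB rather than a validation split, consistent with the
pipeline's use of OOB estimates elsewhere. The small mtry values are kept
verbatim from the study design even though they are low for a hundred-plus
features. About 37% of training instances are out-of-bag in each round
(the (1 − 1/n)^n limit, 36.8% at n = 1873), which the package demonstrates
by direct simulation.

Evaluation reports Pearson r with a two-sided p-value and RMSE on the test
users, for a ladder of feature sets (categories only, topics only, topics +
sentiment, all three) against a *jittered-median baseline*: every test user
predicted the training-median SWL plus U(0, 0.001) noise, which makes the
correlation computable while carrying no signal. Variable importance is
plain permutation importance (mean increase in squared error after
permuting one column, averaged over repeats) on held-out data; no
conditional, correlation-adjusted importance is offered.

For the SWB profile the full-feature forest is refitted on *all* users and
each user's OOB prediction is taken as their machine-predicted SWL — the
OOB estimate is as accurate as an equally sized test set, and it provides a
prediction for every user without leakage.

## Predictive validity and activity sentiment

The SWB profile bundles machine-predicted SWL with the three sentiment
features. `cesd_validity()` quantifies what the profile knows about
depression: users holding a CES-D score are split 70/30 and a random forest
predicts CES-D from (a) sentiment only, (b) self-reported SWL + sentiment,
(c) machine-predicted SWL + sentiment, plus the jittered-median baseline —
all four rows on the identical split and seed. CES-D is treated as an
arbitrary continuous criterion (the generator emits the standard 0–60 range
by default; the range is configurable).

`activity_sentiment()` conditions sentiment on topics of daily life: a
status matches an activity if it contains one of the activity's terms
(token-exact; multi-word terms as bigrams), the mean per-status sentiment of
each activity's matches is computed, and the means are standardized across
activities with the population-SD convention (so the z-scores have mean 0,
SD 1 by construction). The *mean* per matched status, not the raw sum, is
standardized: sums scale with corpus size and would not be comparable across
corpora; the raw sum is reported alongside. The shipped activity lexicon is
synthetic (hand-built word lists for religion, holiday, talking to friends,
chores, family, meals, school, maths, and death/disease) and carries two
synthetic rater-label columns whose agreement structure reproduces the
inter-rater reliability reported for this kind of manual term rating,
Cohen's κ = 0.36. What exactly the raters of the original resource judged
is not published; `cohens_kappa()` is therefore generic over categorical
labels.

## The synthetic corpus generator

`sim_corpus()` draws, per user: a latent SWL from a truncated normal (mean
4.2, SD 1.3 on [1, 7]); a self-reported SWL = latent + N(0, 0.6) clamped to
the scale; a status count from a negative binomial (mean 180, size 1 —
heavy-tailed posting behavior), discarding users under the 30-status
retention threshold (about 15–20% at the defaults); and a CES-D score for a
random ~15% subset. Each status is a bag of tokens mixing:

* valence words, with positive emission increasing and negative emission
  decreasing in latent SWL (the negative link three times the positive one —
  negative affect frequency is the more trait-diagnostic channel, as in the
  correlation structure the generator emulates), plus stable per-user
  heterogeneity that caps attainable trait correlations, as in real text;
* words from 10 informative topics whose usage propensity is log-linear in
  SWL, with a shared per-user "appetite" term that makes the informative
  topic scores mutually correlated — exactly the structure an elastic net's
  grouping behavior is meant to handle;
* background topic words, two style vocabularies (swear-like, decreasing in
  SWL; achievement-like, increasing) that appear in the category lexicon but
  not in the topic table, so categories carry predictive signal of their
  own; neutral filler; and, in raw-text mode, emoticons, occasional
  hyperlinks, digits and punctuation to exercise preprocessing;
* with 8% probability a status is "about" one of nine everyday activities:
  it contains an activity term and its valence emission is shifted by an
  activity-specific loading (positive for religion/holiday/social topics,
  negative for school, maths and death/disease), planting the
  activity-sentiment pattern.

Status lengths follow the three strata of the emulated corpus (~11% of
statuses under 4 words, ~65% between 4 and 20, ~24% over 20). One master
seed fans out to per-stage seeds through a fixed affine scheme
(`stage_seed()`), so identical seeds give byte-identical corpora and any
stage can be rerun in isolation.

### Calibration of the defaults, and what they do not emulate

The emission effects were calibrated once, before the acceptance suite was
written, against the correlation structure the pipeline assumes, and then
frozen: mean sentiment vs SWL ≈ 0.21, negative frequency ≈ −0.23, about
79% of users with more positive than negative statuses, and a status
polarity mix of roughly 41% positive / 19% negative / 40% neutral. Two
deliberate deviations from the emulated study's numbers remain:

* the positive-frequency correlation with SWL comes out near 0.2 rather
  than the observed 0.08 — with a single positive-emission channel the
  positive facets cannot be decoupled further without extra machinery;
* the CES-D coupling is stronger than the observed r ≈ −0.27 (the defaults
  give r(self SWL, CES-D) ≈ −0.4): with only ~310 CES-D users (~95 in the
  test fold), the three-way validity ordering is statistically unresolvable
  across seeds at the weaker coupling. The sign and mechanism (CES-D
  depends on latent SWL only) are unchanged; the stronger coupling makes
  the ordering a decidable property at desk scale.

The generator does not model real posting dynamics: no timestamps or
seasonality, no social-graph structure, no multilingual text, no topic
drift, and word emissions are conditionally independent within a status.
Passing tests therefore demonstrate that the *pipeline* recovers planted
structure of this kind — they do not certify accuracy on real social-media
corpora, where vocabulary mismatch, sarcasm and negation scope (all outside
the lexicon approach implemented here) will lower performance.

## Numerical choices and problem sizes

* Correlations on constant vectors are reported as `NA` and flagged, never
  as 0; the CES-D stage and the evaluator both guard this.
* The grid search breaks ties toward smaller ntree, then smaller mtry.
* Elastic-net folds, forest fits, the split, and the baseline jitter all
  derive deterministic stage seeds from one master seed; refitting with the
  same seed reproduces every number exactly.
* The test suite runs the full pipeline at the generator defaults (≈2,100
  retained users after filtering 2,500, ~380k statuses) for ten seeds, and
  the statistical acceptance checks (selection recovery, latent-SWL
  recovery, validity ordering, feature-set ladder) are computed over those
  runs; unit tests use smaller corpora (60–1,000 users). These sizes were
  chosen so the whole suite completes in minutes on a single core while
  keeping the per-seed sampling error small relative to the planted
  effects.

## Known limitations

Lexicon sentiment ignores negation, sarcasm and graded valence; tokenization
is whitespace-based with no lemmatization or Unicode-emoji handling; the
topic table is consumed, never refitted (fitting a topic model is explicitly
out of scope); permutation importance is marginal, not conditional, and
inherits its known bias toward correlated features; and the forest cannot
extrapolate beyond the training response range — predicted SWL is always
inside [min, max] of the training targets.
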