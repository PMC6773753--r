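---
title: "Detecting reports of a child's birth defect in tweets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reports of a child's birth defect in tweets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdcohort)
```

## The problem and the model

Among tweets that mention a birth defect, only about one in ten refers to
the *user's own child*; the rest are news, fundraising, advocacy or other
reported speech. bdcohort implements tweet-level three-way classification —
`defect` (the user reports their child has the defect), `possible_defect`
(the referent or diagnosis is ambiguous, typically a bare personal name or
pronoun whose resolution would need the user's timeline), and `non_defect`
(mere mention) — as the first, automatable step of cohort selection for
observational studies of pregnancy outcomes.

The core statistical problem is extreme class imbalance (~5%/5%/90%)
stacked on short, noisy text. The package therefore combines three levers:

1. **Representation.** Classic-track normalization replaces the highly
   variable surface material — usernames, URLs, personal names, the many
   ways a user refers to her child (*my son*, *our baby*), third-person
   pronouns, and the specific defect term itself — with stable placeholder
   tokens. Collapsing the defect span to `_malformation_` deliberately
   "hides" which defect is mentioned: specific terms are strongly
   associated with the majority class simply because frequent defects
   dominate the news stream, and a model that learns those associations
   would not generalize to rarer defects. N-grams over the normalized
   stream (e.g. `_fppron_ _child_`) carry the class signal.
2. **Algorithm-level weighting.** The SVM (RBF kernel, cost 100) assigns
   higher weights to the minority classes; the default is inverse
   frequency, `N / (K * N_c)`, exposed as a parameter since the original
   weights behind the benchmark are not published.
3. **Data-level sampling.** Five strategies, detailed below, built on the
   Levenshtein ratio `LR = (lensum − lendist)/lensum` ∈ [0, 1].

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `cost` (SVM) | 100 | benchmark value; RBF kernel, one-vs-one multiclass |
| `gamma` (SVM) | 1/p | libsvm convention, p = number of features |
| class weights | inverse frequency | named-vector override available |
| n-gram orders | 1, 2, 3 | counts, not tf-idf; `binary` toggle available |
| `min_df` | 1 | no vocabulary pruning by default |
| `k` (LR threshold) | — | required in (0,1) for similarity sampling; the sizes it induces are corpus-dependent, so it is a free parameter |
| SMOTE neighbors | 5 | the toolkit default for this method |
| LSTM | 128 units, dropout 0.5, 15 epochs, max 800 tokens, batch 32, Adam 0.01 | architecture fixed; optimizer and rate are unstated upstream, chosen for reliable desk-scale convergence |
| split fractions | 0.2 test, then 0.2 dev | ceiling-rounded per class |

## Normalization: order, protection, stability

The classic track runs in a fixed order: usernames/URLs → lexicon spans →
names → deixis words → lowercase → strip → stem. The relative order of the
span/name/deixis steps is underdetermined by the method description; this
package fixes lexicon spans first (so multi-word terms are replaced before
any of their words could be touched), then names, then deixis, and
documents that choice rather than asserting it is the original one.
Placeholders are protected tokens: they are inserted before character
stripping, the stripper whitelists the underscore, and the stemmer skips
anything shaped `_[a-z]+_`. Name replacement is whole-word and skipped
immediately after `#`, because hashtag-fused references are modeled as
single tokens.

Deixis word sets default to `{my, our, ours}`, `{son(s), daughter(s),
child(ren), baby/babies, kid(s)}`, `{she, he, her, him, his, hers}`. The
plural closures are deliberate: they both capture the same referent words
and make normalization stable under stemming (no non-member stems into a
member). Whether *me* belongs with the possessives is genuinely open; it is
left out by default and the sets are configurable.

The stemmer is the classic Porter algorithm, implemented in full and tested
against its canonical outputs. One subtlety: Porter is *not* idempotent
("raising" → "rais" → "rai"), so normalization is idempotent in the precise
sense that re-normalizing its own output **without re-stemming** is the
identity, and the unstemmed pipeline is idempotent outright. The test suite
checks exactly these two properties.

The embedding track mirrors the preprocessing used for public pretrained
tweet vectors, in the stated order: `<USER>`/`<URL>`, slash spacing,
`<NUMBER>`, `<REPEAT>` for repeated punctuation, three-letter trimming plus
`<ELONG>`, `<HASHTAG>`, then a simplified PTB-style tokenization (punctuation
split into its own tokens; contractions are not split) and lowercasing of
non-marker tokens.

## Sampling strategies

*Similarity under-sampling (all)* scans majority tweets in corpus order and
drops a tweet iff its LR to any **retained earlier** majority tweet exceeds
`k`. Keep-first with corpus order as tie-break makes the operation
deterministic and order-stable. An exact prefilter skips pairs whose length
gap alone bounds LR ≤ `k` (since `lendist ≥ |l1 − l2|`), keeping the O(n²)
pass cheap without approximation. LR is computed on classic-normalized text:
near-duplicate fundraisers and headlines typically differ only in
usernames, URLs and hashtags, which normalization collapses.

*Similarity under-sampling (anchors)* drops majority tweets whose maximum
LR to any anchor exceeds `k`, where anchors are development-set minority
tweets a preliminary model misclassified as majority
(`misclassified_anchors()`) — trimming the majority side of the decision
boundary.

*Random under-sampling* to a target size is the control; the comparison
harness automatically reuses the size produced by the preceding similarity
plan. *Whole-set over-sampling* duplicates each minority class
`m = floor(majority / class count)` times — the floor keeps every copy a
complete set while staying nearest the majority count from below. *SMOTE*
interpolates `x + u(x_nn − x)` with `u ~ U(0,1)` among the 5 nearest
same-class neighbors, bringing each minority class up to the majority
count; it is implemented sparsely so large n-gram spaces stay cheap.

## Classifiers and numerical choices

Multinomial Naive Bayes uses add-one smoothing and frequency log-priors
over raw counts (scaling would destroy the count semantics, so the NB path
skips it). The SVM requires min–max-scaled features and refuses unscaled
input; zero-range columns scale to 0 and out-of-range test values clip to
[0, 1], keeping kernel inputs bounded. SVM **class labels come from the
one-vs-one decision rule**; **probabilities** (needed for PR curves) come
from pairwise-coupled sigmoid calibration, whose internal cross-validation
is randomized inside libsvm — the calibrated argmax may therefore rarely
disagree with the label, and labels are never derived from it.

The LSTM is implemented in base R matrix arithmetic: embedding (fine-tuned,
out-of-vocabulary words start at zero and train; the padding vector stays
zero) → LSTM(128, tanh), last hidden state only → dropout 0.5 → dense
softmax, trained 15 epochs with minibatch Adam on categorical
cross-entropy. Everything is deterministic under the seed, which the test
suite verifies by comparing weights across runs. It is intended for
desk-scale corpora; sequence length defaults to 800 with right-zero-padding
and truncation reporting.

Evaluation rounds for display with round-half-up to two decimals, matching
the convention of the reported tables, while machine output keeps raw
values. Undefined metrics (empty predicted column) are reported as 0 with
an explicit flag rather than NaN. The stratified split sends a
ceiling-rounded 20% of each class to test, then a ceiling-rounded 20% of
the remainder to development — the rule that uniquely reproduces the
published per-class test counts (239/240/4123, totalling 4602) from the
published class counts. PR curves sweep unique scores descending; AUC is
the trapezoid over recall anchored at recall 0.

Class order is fixed everywhere as (`defect`, `possible_defect`,
`non_defect`).

## The synthetic generator

`generate_tweets()` emulates the statistical and linguistic structure the
classifiers exploit: largest-remainder class allocation at the natural
0.052/0.052/0.896 proportions; class-conditional templates (bundled as
data, `inst/extdata/synthetic_templates.tsv`) with slots for possessives,
child words, names, defect terms and hashtag-fused forms; per-phenomenon
knobs mirroring the error-analysis inventory (implicit having-relations,
name deixis, hashtag fusion, modifier-interrupted possessives, reported
speech, fundraisers, near-duplicate headline clusters); and decoration
rates for usernames, URLs, hashtags and retweets. Retweets default to 0
because the labeled corpus emulates data that already passed the retrieval
post-filters. The companion `generate_cluster_table()` and
`generate_names()` produce fixture counterparts of the external cluster
and name resources, with planted misspellings sharing their canonical
word's path.

What it does **not** emulate: real lexical diversity (a few dozen templates
versus open vocabulary), annotation disagreement, code-switching, sarcasm,
or the long tail of defect terms. Consequently the default pipeline
separates the synthetic classes almost perfectly — passing tests
demonstrate that signal flows end to end and that every contract holds, not
that real-corpus F1 would reach any particular level. The `label_noise`
knob exists for robustness experiments.

## Problem sizes used by the tests

The unit and property tests run on corpora of 120–600 tweets; the
end-to-end acceptance check trains the weighted SVM on a 5,000-tweet
corpus and compares defect-class F1 against a label-shuffled control. The
exhaustive similarity check compares the package's Levenshtein ratio
against an independent dynamic-programming oracle on all ~1.19 million
ordered pairs of strings of length ≤ 6 over a three-letter alphabet, with
a recursive brute-force cross-check. These sizes were chosen as the
smallest at which the properties are meaningfully exercised.

## Known limitations

* Tweet-level only: no timeline aggregation, deixis resolution across
  tweets, or prenatal-period detection.
* The retrieval post-filter drops a tweet whenever *any* matched span
  overlaps a username/URL token, the stricter reading of the published
  filter.
* Spelling variants are consumed from a file; the variant *generator* is
  out of scope.
* Whether the original n-gram features were binary or counts is unstated;
  counts are the default and a `binary` toggle is provided.
* The LSTM is a faithful desk-scale implementation, not a performance-tuned
  deep-learning stack; transformer models are out of scope.
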