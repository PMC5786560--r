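---
title: "Comparative phenomenology of substance and dream reports: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phenomenology of substance and dream reports: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamlsa)
```

## The scientific question and the model

People who take psychoactive substances and people who dream both produce
free-text narratives of what the experience felt like. `dreamlsa` asks a
quantitative version of an old hypothesis: among all psychoactive
substances, do hallucinogens produce experiences whose *descriptions* are
most similar to descriptions of dreaming — and does the answer depend on
whether the dreams were lucid?

The unit of analysis is not the individual report but the pooled
*document*: all reports of one substance form one document, and dream
reports at the two lucidity extremes (self-rated 1 and 5 on a 1–5 scale)
form two more documents, `dream_low` and `dream_high`. Similarity between
documents is computed in a latent semantic space:

1. **Preprocessing.** Punctuation is removed, text is lowercased and
   tokenized on whitespace, tokens are lemmatized, and lemmas shorter than
   three characters are dropped. Substance documents are additionally
   *censored*: every lemma on a curated list of drug names, slang variants
   and route-of-administration words is removed, so that similarity
   reflects the described effects rather than the identity of the drug.
2. **Weighting.** The term–document matrix holds
   $w_{td} = \mathrm{tf}_{td} \cdot \ln(N / n_t)$, raw counts times the
   plain-logarithm inverse document frequency ($N$ documents, $n_t$ of
   them containing term $t$). Terms are kept only when their document
   frequency lies strictly inside the 5%–95% band, which removes both
   corpus-wide stop-word-like terms and document-specific residue.
3. **Latent semantic analysis.** The matrix is factorized by SVD,
   $W = U S V^\top$, the $D = 20$ largest singular values are retained,
   and the rank-$D$ reconstruction $W_D = U S^* V^\top$ is formed. By the
   Eckart–Young theorem $W_D$ is the best rank-$D$ approximation of $W$ in
   Frobenius norm; truncation mitigates sparseness so that documents using
   related (not identical) vocabulary become comparable.
4. **Similarity.** The similarity of two documents is the Pearson linear
   correlation between their columns of $W_D$. Ranking all substances by
   similarity to a dream document (rank 1 = most similar) yields the
   pipeline's central output.

The statistical layer operates on those ranks: per-category box-plot
summaries, a two-factor fixed-effects ANOVA (drug category × dream
lucidity, each substance contributing its rank against both dream
documents), pairwise nonparametric tests between categories, the
high-vs-low-lucidity difference ranking (where oneirogen-like substances
should surface), Spearman cross-similarity predictions (how well
similarity-to-LSD-like-probes predicts similarity-to-dreams), term-rank
tables behind word clouds, and a stability analysis across the retained
rank $D$.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_reports` | 10 | substances with fewer pooled reports are excluded |
| lucidity split | 1 vs 5 | dream documents use only the scale extremes |
| `min_token_len` | 3 | lemmas shorter than this are discarded |
| `df_min`, `df_max` | 0.05, 0.95 | open document-frequency retention band |
| idf dialect | plain | $\ln(N/n_t)$, no smoothing |
| `D` | 20 | retained singular values |
| `D_grid` | 20–70 by 5 | stability grid (trimmed to the rank bound) |
| `alpha` | 0.05 | significance level, uncorrected by default |

Two dialect choices deserve emphasis. Common library tf-idf
implementations add "+1" smoothing to the idf; that variant is available
(`idf_dialect = "smoothed"`) but is never the default, because the plain
logarithmic form is the definition this pipeline is built on. Similarly,
similarity is computed on the reconstructed *term-space columns* of
$W_D$, not on the $D$-dimensional document coordinates in $V$ — the two
are not equivalent, and the column convention is the one that matches
"low-rank approximation of the word-by-document matrix".

## The lemmatizer

No dictionary lemmatizer is bundled; `lemmatize()` is a deliberately small
rule set for English nouns (irregular-plural exception table, then ordered
suffix detachment: `-ies`→`-y`, `-es` after sibilants, plain `-s`), with
tokens containing digits passed through untouched. It is idempotent, which
makes whole-pipeline preprocessing idempotent. Its limits are documented
rather than hidden: inflected verbs ("snorted") are not reduced to stems,
so censor lists should carry inflected variants explicitly — which is
exactly what real curated censor lists do, since they enumerate slang
variants anyway. Because lemma dialects change vocabularies, the rule-set
identifier (`lemmatizer_id()`) is recorded in every results manifest.

## The synthetic benchmark and what it does (not) show

The corpora this method was designed for are living websites, not
deposited datasets, so the package carries its own acceptance surface: a
topic-model corpus generator with exact ground truth.
`benchmark_config()` freezes it (seed 20180122): a vocabulary of 2,000
word types partitioned into 10 topics (one 200-word support block each,
within-block Dirichlet(0.5) weights); 30 substance classes and two dream
classes whose topic mixtures are Dirichlet(0.3) draws; 200 reports per
class with negative-binomial lengths (mean 120, dispersion 10); and three
class-specific contaminant "drug-name" tokens per substance injected at
rate 0.02, forming the censor list.

Six classes are planted to be dream-like: their mixture is
$0.6\,\mu_{\text{dream\_high}} + 0.4\,\mu_{\text{own}}$, which guarantees
they share at least half their mixture mass with the high-lucidity dream
class. The 0.6 blend weight was chosen so that, at the frozen seed, those
six classes also occupy six of the top eight *ground-truth* ranks against
`dream_high` — with an even 0.5 blend a chance-aligned background class
can intrude, which would make "did the pipeline recover the planted
structure?" ambiguous.

Reports are bags of words drawn i.i.d. from the class's mixed term
distribution. This is a deliberate simplification of a full
per-report topic model: the pipeline only ever consumes class-pooled
documents, so per-report topic variance would be invisible downstream.
Because of it, the expected term distribution of a class is exactly
$p_c = m_c^\top \Phi$ (mixture times topic–word matrix), and ground-truth
similarity is the Pearson correlation between expected distributions —
the same statistic the pipeline estimates.

What passing tests on this corpus show: the pipeline recovers planted
similarity structure through censoring, df filtering, tf-idf and
truncation (Spearman ρ ≥ 0.8 against ground truth across ten consecutive
seeds, with the planted classes dominating the recovered top ranks), the
censor list removes every contaminant, and rankings are stable in $D$.
What they do not show: anything about natural language — no syntax,
no synonymy beyond co-occurrence, no report-level heterogeneity, no
English vocabulary. Convergence of empirical class frequencies to $p_c$
is at the expected $O(1/\sqrt{n})$ rate; at the benchmark's ~24,000
tokens per class the total-variation distance to $p_c$ sits around 0.05–0.09,
and shrinks as the token budget grows.

## Numerical and design choices

* **SVD** is the deterministic LAPACK full decomposition (`svd()`); at
  ~2,000 × 32 there is no reason for randomized solvers. Singular-vector
  sign indeterminacy is irrelevant because only $W_D$ is consumed.
* **df band** is an open interval (strictly more than 5%, strictly less
  than 95% of documents), reading the retention rule literally.
* **Ties** in similarities, term weights and rankings are broken
  lexicographically and flagged, never silently.
* **Zero-variance columns** make Pearson similarity undefined; the result
  is a flagged `NA`, never a silent 0, and such targets are excluded from
  rankings with a warning.
* **ANOVA** uses Type II sums of squares by default because drug
  categories are unbalanced; Types I/III are available by flag. The two
  lucidity observations per substance are treated as fixed-effects
  observations, not repeated measures.
* **Pairwise category tests** default to the two-sample rank-sum test:
  categories have unequal sizes and no natural pairing, so the paired
  signed-rank variant — which remains available for genuinely paired
  inputs — would require discarding data; requesting it for unpaired
  groups is an error, not a silent fallback. Exact p-values are used for
  group sizes up to 25, the normal approximation beyond. Uncorrected
  p < 0.05 is reported by default, with optional Benjamini–Hochberg
  correction.
* **Joint term weighting** implements "average rank across the probe
  substances" as rank-of-mean-weight (default) with mean-of-ranks behind
  a flag; the two agree for a single probe document.
* **Punctuation** is stripped (deleted) before tokenization, so hyphenated
  compounds fuse; a replace-with-space mode is available.
* **Numerals** of three or more characters are retained by default
  (`drop_numeric = FALSE`).
* **Dream documents** enter the factorization jointly with all substance
  documents — one matrix, one SVD, two reference columns — rather than
  one factorization per reference.
* **Censor matching** operates on single lemmatized lowercase tokens;
  multi-word censor entries are not phrase-matched.

## Problem sizes

The test suite and the analysis scripts run the full pipeline on the
benchmark corpus (32 documents, ~790,000 tokens) in a few seconds per
seed; the planted-recovery check spans ten consecutive seeds. The
stability grid trims to {20, 25, 30} on this corpus because the retained
rank cannot exceed the document count of 32; on a corpus with more
documents the full 20–70 grid applies.

## Known limitations

* The rule-based lemmatizer handles English noun inflection only; heavy
  verb-form vocabularies will fragment across inflections.
* With few documents (here 32), the df band quantizes coarsely: a term
  must appear in at least 2 and at most 30 documents.
* The ANOVA is fixed-effects; if the two per-substance observations are
  strongly dependent the F statistics are anti-conservative.
* Ground-truth similarity uses Pearson correlation of expected
  distributions to parallel the pipeline's statistic; a
  divergence-based alternative (Jensen–Shannon) is exported for
  diagnostics but plays no role in acceptance.
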