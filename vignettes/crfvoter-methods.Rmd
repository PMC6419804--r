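---
title: "Methods: stacked CRF ensembles for biomedical NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked CRF ensembles for biomedical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of every
choice that affects numbers: the linear-chain CRF and its training, the
feature-template engine, the hyperparameter optimizers, the two-stage
ensemble, entity-level evaluation, and the synthetic world the test
suite runs in. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Task and data model

Gene/protein-related mention recognition is cast as IOB2 sequence
labeling: a corpus is a set of documents, each a sequence of sentences,
each a sequence of tokens; every token carries a tag that is `O`,
`B-TYPE` or `I-TYPE`, with `B-` on every mention start so adjacent
same-type mentions stay distinguishable. The entity-type inventory
follows the gene/protein annotation scheme (ABBREVIATION, FAMILY,
FULLNAME, IDENTIFIER, NESTED, MULTIPLE, NOCLASS, SEQUENCE);
`gpro_class_counts()` records the published per-class instance counts
used to default the generator's class mixture.

Conventions chosen where the underlying task description was silent:

* **IOB2, not IOB1.** The task material names both; we standardize on
  IOB2 because that is what its own training-example notation uses.
* **Repair is total.** An `I-TYPE` after `O`, after a different type, or
  at sentence start is rewritten to `B-TYPE` with a warning. Decoding
  and voting must always yield a valid tagging; strings that are not
  tags at all are errors, not repair candidates.
* **TSV dialect.** UTF-8, one token per line, label in the last column,
  optional feature columns (lemma, POS, ...) in between, blank line
  after each sentence, `#doc <id>` comment line per document (the plain
  CoNLL format has no document marker; we need one for document-level
  splitting). Token indices are 0-based half-open throughout; character
  offsets index the document text formed by joining all tokens with
  single spaces.
* **Sub-token mentions.** A gold span that cuts inside a token (the
  `B-RafV600E` case) cannot be expressed in token-level IOB2.
  `filter_subtoken_mentions()` routes such spans to an *untrainable*
  partition: excluded from training labels, retained in the evaluation
  gold standard where they necessarily count as false negatives. The
  generator plants such cases at a default rate of 0.85%, the rate
  reported for the real filtered corpus.
* **Split remainder.** `split_corpus()` floors each part's size and
  gives leftover documents to the training split — deterministic, and
  extra data goes where it helps most.
* **Overlapping annotations** (nested/multiple mentions) are not
  linearized into a single IOB sequence by guesswork: overlapping input
  spans are an error.

## The linear-chain CRF

A model over label set $Y$ scores a labeling $y$ of a length-$n$
sentence as

$$\mathrm{score}(x, y) = \sum_{j=1}^{n}\Big[\sum_{f \in \phi(x, j)}
W_{f, y_j} + T_{y_{j-1}, y_j}\Big]$$

with sparse string features $\phi(x, j)$, emission weights $W$,
transition weights $T$, and a virtual START state supplying the $j = 1$
transition, and defines $P(y \mid x) = \exp(\mathrm{score})/Z_x$. The
partition function $Z_x$ and the marginals come from the log-space
forward–backward recursions; decoding is exact Viterbi with ties broken
toward the lowest label index at each backtracking step. Transitions
are first-order label-pair indicators only; higher-order context can be
emulated through emission features but there is no higher-order
lattice, no beam, no pruning.

**Training** maximizes $\sum_i \log P(y_i|x_i) - \rho(\lambda)$ with
$\rho = \frac{1}{c}\lVert\lambda\rVert_1$ or
$\frac{1}{2c}\lVert\lambda\rVert_2^2$ — larger cost $c$ means weaker
regularization, matching the conventional cost parameterization in
which $c$ multiplies the likelihood. L2 uses L-BFGS with the analytic
gradient (observed minus expected feature counts); L1 uses FISTA with
backtracking and soft-thresholding, which yields exact zeros.
Convergence: relative objective change below `tol` (default `1e-6`) or
`max_iter` (default 300). Unseen test-time features contribute zero
weight; there is no OOV smoothing. Numerical checks in the suite:
inference equals exhaustive enumeration over all $|Y|^n$ labelings for
200 random models ($n \le 4$, $|Y| \le 4$, tolerance $10^{-8}$), and
the analytic gradient matches central finite differences to $10^{-5}$
relative error.

A subtlety found while testing: distinct labelings can tie *exactly*
(identical feature rows at two positions make label swaps
score-equivalent), and the decoder resolves such ties through
floating-point sums whose accumulation order differs from any
independent recomputation. The enumeration oracle therefore asserts
optimality of the decoded score, and sequence identity only when the
argmax is unique; the deterministic tie rule is asserted on constructed
zero-weight cases.

## Feature templates

`feature_config()` exposes ~30 boolean switches plus window knobs
(`max_left`, `max_right`, `max_ngram_leng`, each 1–6) and a word-shape
mode. The switch inventory mirrors the tunable surface of a classic
CRF-based recognizer, but the generators are this package's own fully
specified emulations — the original tool documents switch names, not
semantics. Each switch is a pure generator (word identity, neighbor
words, word pairs, character n-grams with boundary marks, shape
sequences, position buckets, disjunctive word windows of width 4/8,
tag/lemma column reads, gazetteer hits); the emitted feature set is the
union of enabled generators, so enabling a switch only adds features.
Two switches are *modifiers*, not generators — `no_mid_ngrams`
restricts n-grams to prefixes/suffixes and `normalize_terms` lowercases
the word-identity feature — so the monotonicity property is quantified
over the additive switches only. A constant bias feature is always
emitted, keeping the all-off configuration trainable. Word shapes map
uppercase→`X`, lowercase→`x`, digit→`0`, other→itself; the default
`chris2uselc` mode additionally collapses runs of more than four
identical shape characters to four. Tag/lemma generators read the
configured input columns and are silently skipped when the column is
absent — the package never computes linguistic annotations itself.

## Hyperparameter search

A configuration space is a flat product of named dimensions
(categorical, integer, continuous). `grid_search()` enumerates finite
spaces exhaustively in lexicographic dimension order (continuous
dimensions are rejected — they must be discretized);
`random_search()` samples every dimension independently and uniformly;
both are deterministic given a seed. The driver maximizes the
objective (a validation F1); the textbook formulation minimizes a
loss, so a loss objective is negated once by the caller.

The tree-structured Parzen estimator splits the trial history at the
$(1-\gamma)$ metric quantile into a good group ($\lceil\gamma
n\rceil$ trials, ties by trial index so neither group is empty) and a
bad group, fits per-dimension densities $l$ (good) and $g$ (bad),
draws `n_candidates` samples from $l$ and proposes the candidate
maximizing $EI(x) = l(x)/g(x)$. Categorical densities are
additive-smoothed frequencies; continuous/integer densities are Parzen
mixtures over the observed values plus one uniform-over-range prior
component with weight $1/(k+1)$. Defaults: $\gamma = 0.25$, 20 random
startup trials, 24 candidates. With `n_startup >= budget` TPE consumes
the random-search code path exactly and is bit-identical to it under
the same seed. Failed objective evaluations score 0 with a warning
rather than aborting a long run. Truly tree-structured (conditional)
dimensions are not implemented; every space used here is flat.

**Bandwidths.** The first implementation used a single Silverman width
per group ($1.06\,s\,k^{-1/5}$ on the group's values). On the 1-D
quadratic benchmark this stagnates: once suggestions cluster, the good
group's standard deviation collapses, the kernel width with it, and
the argmax of $l/g$ keeps re-proposing the cluster center even when
the cluster sits measurably off the optimum — TPE then *loses* to
random search at equal budget. The default rule is therefore
`"neighbor"`: each kernel's width is the distance to its nearest
observed neighbors, clipped to [range/50, range]. Widths adapt to local
point density, isolated good points keep wide kernels, and the uniform
prior component preserves global exploration; with this rule TPE beats
random search on 19 of 20 benchmark seeds. `"silverman"` remains
selectable for comparison.

## Majority voting and the stacked ensemble

`majority_vote()` selects the modal tag per position; ties go to the
earliest-listed labeler (a `prefer_o` mode is available); the voted
sequence is IOB2-repaired. The vote needs an absolute majority at every
token, which is exactly what complementary-error ensembles do not
provide.

`train_crfvoter()` is the two-stage stack. Stage 1 trains (and, where
a space is attached, hyper-optimizes) each base learner on the
training set. Stage 2 has every base tag the development set and
trains a second-level CRF whose features at position $j$ are the base
output labels there — `"<learner>=<tag>"` strings, optionally extended
to positions $j\pm w$ (`window`, default 0: the architecture is
positionwise). Level-2 features are base outputs *only*; raw token
features are deliberately excluded by default so the combiner learns
reliability patterns, not the task itself. The development set must be
disjoint from the bases' training documents — stacking on the bases'
own training predictions would learn from optimistically accurate
inputs. Level-2 defaults (L2 penalty, $c = 15$, the best grid cell of
the cost/penalty space) are exposed but make no fidelity claim, since
the original description does not say whether the combiner was itself
tuned. At prediction time every base tags the input, the stacked rows
are rebuilt, and the level-2 CRF Viterbi-decodes them.

## Evaluation

Entity-level, strict: a true positive is an exact match on (document,
sentence, start, end, type); partial overlaps are not credited.
$R = TP/(TP+FN)$, $P = TP/(TP+FP)$, $F1 = 2PR/(P+R)$, each defined as 0
when its denominator is 0 so the functions are total. Reports round
half-up to two decimals; all computation is done unrounded.
`pairwise_difference()` is the exact percentage of token positions on
which two taggings differ. `mcnemar_test()` marks a system "positive"
on a gold mention when its tags over the mention's span exactly
reproduce the gold tags, counts discordant mentions $b$ (system 1 only
correct) and $c$ (system 2 only), and compares the
continuity-corrected statistic $(|b-c|-1)^2/(b+c)$ with the
$\chi^2_1$ critical value; an exact binomial variant sits behind
`exact = TRUE`; $b + c = 0$ yields an explicit undefined-test flag,
never significance.

## The synthetic world

`generate_corpus()` emulates the *structure* of an annotated patent
corpus, not its text: pseudo-word background vocabulary, documents of
2–4 sentences of 8–14 tokens, mentions placed at Poisson rate 1.2 per
sentence without overlap, class mixture defaulting to the published
type-1 class proportions (ABBREVIATION : FULLNAME : NESTED : FAMILY :
IDENTIFIER ≈ 7516 : 4815 : 89 : 1 : 1, renormalized), and per-class
surface patterns of our own design (documented inventions: uppercase
acronyms, multiword capitalized full names, suffix-patterned family
names, `GPR`+digits identifiers, base-letter sequences). 0.85% of
mentions are fused with a generated suffix into a single token to
exercise the sub-token path. Everything is deterministic under the
config seed. What a green test does **not** establish: performance on
real patent text — there is no linguistic realism, no real lexical
ambiguity (entity surfaces never collide with background words), no
annotation noise, and boundaries are easy once a mention is seen at
all. The generator supports the *logic* of the pipeline and the
*relative* behavior of combiners, nothing more.

`simulate_learner_output()` corrupts gold mentions with per-type
deletion rates, one-token boundary jitter and type confusion —
deletion/distortion only, never hallucination, so simulated labelers
have high precision by construction.

`make_complementary_benchmark()` states the ensemble world: $l$
labelers over $l$ equally weighted entity types, labeler $m$ missing
its own type at 0.95 and all others at 0.45, jitter 0.02. These rates
were chosen once, before running the acceptance suite, to realize the
regime the ensemble argument is about: the expected number of labelers
that detect a given mention is ≈ 1.15, so most recovered mentions are
seen by exactly one labeler — an absolute majority rarely exists and
the vote cannot beat the best base, while the level-2 CRF can learn
the high-precision rule "trust any firing labeler" from the
development set. Uniform class weights (rather than the heavily skewed
corpus default) give each labeler's blind spot equal mass, so "beats
every base" is a symmetric, non-vacuous claim.

## Reproducibility and limits

One master seed fans out to per-stage seeds by fixed offsets
(`derive_seed`), kept inside 32-bit range; generation, splitting,
simulation, training and prediction are bit-reproducible given
(corpora, specs, seed). Models persist as a JSON header plus a TSV
weight table at 17 significant digits, which round-trips IEEE doubles
exactly. Known limitations: no true higher-order CRF lattice (the
higher-order "order" style knobs of other frameworks are accepted in
space definitions but inert), no beam search, no neural encoders, no
word embeddings, no gazetteer learning, no conditional search spaces,
no recursive multi-level voting, and no claim that the synthetic
benchmark predicts absolute scores on any real corpus.
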