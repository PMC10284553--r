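---
title: "Research weaving of a concept lexicon: models, choices, limitations"
author: "ecoweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Research weaving of a concept lexicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoweave)
```

`ecoweave` quantifies how a literature engages with a set of named
concepts. This vignette documents the methods as the package implements
them: the statistical machinery, the tunable parameters and their
defaults, the numerical choices made where a published description is
silent, and what the synthetic test corpus does and does not demonstrate.

## Feature matching

A lexicon feature is a set of lowercase word-stem patterns. The built-in
lexicon has 23 features of complex ecological systems, e.g. the feature
*nonlinearity* with search string `non-linear + non linear + nonlinear`.

Stems match as **token prefixes**: the stem `adapt` matches *adaptation*,
*adaptive* and *adapted*. Prefix matching is what a word-stem search
string means; it captures plurals and British/American spelling variants
(`self-orga` matches both *self-organisation* and *self-organization*)
at the cost of occasional false positives (`scal` matches a musical
*scale*), which is inherent to the method and documented in the tests.

Three normalisation rules keep the dialect variants of a term from being
counted inconsistently:

* the tokenizer keeps internal hyphens (*non-linear* is one token) and
  strips all other punctuation, retaining numerals;
* before unigram matching, internal hyphens are deleted, so the
  hyphenated and joined spellings collapse onto a single joined-form
  matcher, leaving exactly two matchers per dialect family (joined
  unigram, spaced bigram);
* within one feature a token position is counted at most once. Scanning
  left to right, a bigram match consumes both of its positions and takes
  precedence over a unigram match starting at the same position. The
  published description does not say whether an overlapping unigram and
  bigram both increment the tally; first-match-wins is this package's
  choice, made to avoid double counting a single surface mention, and is
  asserted by the test suite.

Relative frequencies divide counts by the article's **total token count
from the counting tokenizer** (after punctuation stripping), not by the
topic-model vocabulary size; frequency is a property of the raw text.
Articles whose 23 counts are all zero are excluded before any analysis,
with a per-group tally logged.

## Diversity, dispersion, indicators

Richness is the number of features with nonzero count. The effective
number of features is the Hill number of order 1,
$\exp(-\sum_f p_f \ln p_f)$, computed on the article's feature-mention
**proportions** (frequencies renormalised to sum to one). Normalising
first is a choice — entropy on raw relative frequencies does not have the
effective-number interpretation — and an unnormalised variant is exposed
via `diversityProfile(normalize = FALSE)`. Group comparisons use one-way
ANOVA.

Group dispersion follows the PERMDISP construction: Gower-centre the
squared Bray-Curtis dissimilarities, eigendecompose, and keep *all*
axes — positive-eigenvalue axes as real coordinates, negative-eigenvalue
axes as imaginary ones (Bray-Curtis is not Euclidean-embeddable, so
negative eigenvalues are expected). Each group's spatial median is the
geometric median, computed by Weiszfeld iteration (relative tolerance
1e-12, with the standard safeguard when an iterate lands on a data
point) separately in the real and imaginary subspaces. A member's
squared distance to its group median is
$d_r^2 - d_i^2$, floored at zero; significance is a one-way ANOVA on the
distances, with an optional permutation F test. On Euclidean-embeddable
inputs this reproduces plain geometric-median distances to 1e-8
(asserted against a brute-force optimiser), and on Bray-Curtis inputs it
agrees with `vegan::betadisper(type = "median")` to that function's own
optimiser tolerance.

Indicator features use the classic IndVal statistic: specificity
$A_g$ = group-mean abundance divided by the summed group means, fidelity
$B_g$ = occurrence fraction within the group, statistic
$\max_g A_g B_g$. We use the original product form without group-size
equalisation and without a square-root transform, because the analysis
this package reproduces names the method but not the variant;
`mode = "presence"` switches abundances to occurrence indicators. The
permutation p uses the add-one convention, $p = (1 + b)/(B + 1)$, so
p = 0 is impossible. Across the 23 features the pipeline reports raw and
Holm-corrected p values — the reference analysis reports counts of
significant features without naming a correction, so both are available.

## Topic stage

Preprocessing for topics is separate from counting: stopwords (a fixed,
versioned English list; configurable) are removed, hyphenated tokens are
joined, and plurals are singularised by rule (-ies→-y, -es after
sibilants dropped, trailing -s dropped) with a small invariant-form
exception list (*species*, *series*, ...). A rule-based singulariser is
deterministic and dependency-free; it is not a lemmatiser and will leave
irregular plurals alone.

LDA is fitted by collapsed Gibbs sampling (compiled; the estimator is
the posterior mean over post-burnin sweeps). The fitting algorithm is an
implementation choice behind the contract — the contract being
deterministic fits for a fixed seed, rows of beta and gamma summing to
one, the K = 1 analytic limit (beta equals the empirical word
distribution when the word prior is flat), and recovery of planted
disjoint-vocabulary topics. Defaults: K = 100 in the reference-scale
configuration, small K in tests; alpha = 50/K, eta = 0.1.

Because LDA puts near-zero probability on most words, each topic's top
words are the beta values **strictly above the upper limit of the
empirical 0.99 highest-density interval**, computed per topic as the
shortest contiguous window of sorted values covering 99% of the words.
The published description conflates "the 0.5% highest probabilities"
with this HDI rule; the HDI rule is implemented as primary and a plain
top-fraction selector (`method = "topfrac"`, default 0.5%) as the
alternative. Whether the interval should be pooled over topics is
ambiguous in the source ("of our data"); per-topic is the default and
`pooled = TRUE` is available. On an exactly uniform topic nothing is
strictly above the threshold and the selection is empty — the natural
reading of "above".

## Networks

The bipartite article-feature network has one edge per nonzero relative
frequency. Projections link two nodes of one side when they share a
neighbour; edge weights are either the shared-neighbour count or
$\sum_k \min(w_{uk}, w_{vk})$. Realized connectance is
$L / [S(S-1)/2]$; strength is the summed incident edge weight.

The ERGM has terms edges + nodematch(group) + nodefactor(group). All
three are dyadic independent, so the model likelihood factorises over
dyads and the MLE is exactly a Bernoulli regression with covariates
(1, same-group, focal-endpoint count ∈ {0,1,2}); it is fitted by Fisher
scoring (IRLS) with information-based standard errors, and the tests
verify agreement with an exhaustive coarse-to-fine likelihood grid.
Complete, empty or separable networks yield a non-convergence flag
rather than a silent huge coefficient. The article network the ERGM sees
must be binary; articles are tied when they share at least τ features,
with τ = 1 as the documented default because the reference analysis
does not state its binarization. The bipartite network is treated as
undirected after projection (directionality is lost there anyway).

## Co-citation

Reference lists (citation keys) from the complexity group build the
co-citation network: each unordered pair of distinct references in one
list adds one to that pair's weight; duplicate keys within a list count
once. Keys are matched verbatim by default, with an optional normaliser
(case-fold, strip punctuation) for raw strings — key-based matching
keeps the pipeline deterministic where reference disambiguation in the
source is unspecified. "Most co-cited" ranks by total co-citation
strength (weighted degree), with ties at the cut broken
lexicographically so the top-n subgraph is reproducible; a flag switches
to unweighted degree. Louvain greedy modularity maximisation (weighted,
seed-controlled node order) supplies the partition and its modularity
$Q = \sum_c (e_c/m - (d_c/2m)^2)$; on all ≤ 8-node fixtures in the test
suite the returned Q equals the exhaustive-enumeration optimum. The
robustness sweep reruns top-n + Louvain across n values and scores
consecutive partitions with the adjusted Rand index on shared nodes.

## Metric catalogue

The standalone metrics use natural logarithms by default (the source
writes "log" without a base) with a base-2 switch. Block statistics use
overlapping windows and plug-in frequencies without bias correction,
matching the plain textbook forms. Two conventions worth noting: SVD
entropy is defined over the *nonzero singular values* with J = 0 for
rank-one matrices (the printed formula's "number of nonzero entries" is
a typographical slip — it would not be rotation invariant); and the
fluctuation-complexity formula is implemented as
$\sum_{ij} P_{ij} [\log(P_i/P_j)]^2$, the standard squared-log-ratio
definition, because the printed formula is garbled.

## The synthetic corpus

`defaultConfig()` encodes the study conditions: 172 complexity and 180
control articles; per-feature inclusion probabilities with linearly
decaying profiles scaled so expected richness is 9/23 (complexity) and
6/23 (control) — the two groups emphasise opposite ends of the feature
list so group-indicative features exist; mention intensities
1 + Poisson(λ − 1) with λ increasing in the inclusion probability;
log-normal article lengths with median 500 filler tokens (sdlog 0.4), a
condensed stand-in for full texts that keeps a 20-replicate end-to-end
test affordable without changing any rate being tested (richness depends
on inclusion probabilities, not length); a 2000-word Zipf filler
vocabulary disjoint from every feature stem; and a 120-reference pool in
3 planted clusters (10:1 within:between weights, 15 references per
article), echoing the three major clusters in the reference analysis.

Feature mentions are injected as surface strings the matcher must
recognise — 80% joined/base form, 10% hyphenated, 10% spaced where a
feature has dialect variants — so the generator round-trips through
every matcher branch, and the per-article planted counts are recovered
*exactly* by the counting stage (a test asserts identity).

What the generator does **not** emulate: real prose (filler is i.i.d.
Zipf noise, so there is no syntax, no polysemy, and no accidental
prefix collisions unless a test plants them), real citation metadata,
group differences in article length, or topical correlation between
features beyond what shared inclusion profiles induce. Passing
end-to-end tests therefore demonstrate that the pipeline detects the
planted structure under its own assumptions — not that the lexicon or
the stems are semantically valid for real articles.

## Determinism and sizes

Every stochastic stage takes a seed; the pipeline's single seed fans out
to per-stage seeds by fixed offsets so stages rerun standalone give the
same answer, and two identical runs produce byte-identical report JSON.
The test suite sizes its simulations deliberately small: null
calibration of the indicator test uses 200 datasets of 40 articles × 10
features with 999 permutations; ERGM recovery uses 100-node graphs over
20 seeds; the end-to-end pattern check runs 20 full-size replicates of
the default corpus. These sizes give the properties being tested
comfortable statistical room while keeping a complete run of the suite
in the low minutes.

## Known limitations

* Prefix stems over-match by design; counts are upper bounds on
  conceptual engagement (e.g. *dynamic* matches any dynamics).
* The word total in relative frequencies is post-tokenization; a
  different punctuation convention shifts all frequencies by a common
  small factor.
* The Gibbs LDA gives a point summary of a multimodal posterior; only
  seeded determinism, not chain convergence, is guaranteed at small
  iteration counts.
* The ERGM covers dyadic-independent terms only; triangles, gwesp and
  other dependent terms are out of scope and would require MCMC-MLE.
* Louvain is greedy: optimality is verified exhaustively on small
  fixtures but is heuristic at scale; the robustness sweep, not a
  guarantee, is the tool for judging partition stability.
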