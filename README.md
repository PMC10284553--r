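# ecoweave

`ecoweave` is an R package for **research weaving** of a scientific
literature: it combines lexicon-based full-text mining with
community-ecology statistics and bibliometric network analysis to
characterise how a field uses a set of concepts. It was built to analyse
how the ecological literature engages with ideas from complex-systems
science, comparing articles that explicitly invoke "ecological complexity"
against a control sample of ordinary ecology articles, but every component
is reusable for any two-group corpus and any feature lexicon.

The package is aimed at quantitative ecologists and science-of-science
researchers who have (i) a corpus of plain-text article full texts with
group labels and reference lists, and (ii) a lexicon of concepts defined
by word-stem search strings.

## What it computes

Treating each lexicon **feature** as a "species" and each article as a
"site", the pipeline chains five analyses:

1. **Feature quantification.** Each feature *f* is counted in each article
   *i* via prefix stem matching over unigrams and bigrams (hyphenated,
   spaced and joined spelling variants collapse onto the same feature),
   giving counts *n<sub>if</sub>* and relative frequencies
   *x<sub>if</sub> = n<sub>if</sub> / N<sub>i</sub>* with *N<sub>i</sub>*
   the article's word count. Articles using no feature are excluded.
2. **Diversity and uniqueness.** Per-article feature richness and the Hill
   number of order 1, exp(−Σ<sub>f</sub> p<sub>f</sub> ln p<sub>f</sub>)
   (an effective number of features), are compared between groups by
   one-way ANOVA. Group dispersion is tested PERMDISP-style: Bray-Curtis
   dissimilarities are embedded by principal coordinates (keeping
   negative-eigenvalue axes), each article's distance to its group's
   spatial median is computed, and distances are compared by ANOVA.
   Indicator features are found with the classic IndVal statistic
   (specificity × fidelity) and a group-label permutation test.
3. **Topic models.** LDA (collapsed Gibbs, compiled) with per-topic
   top-word selection by the upper limit of the empirical 0.99
   highest-density interval of the word probabilities, and a per-feature
   comparison of topic importance between groups.
4. **Feature networks.** The bipartite article-feature network (edges
   weighted by relative usage) is projected to unipartite networks;
   realized connectance *L* / [*S*(*S*−1)/2], node strength and the degree
   distribution are reported, and article ties are modelled with the
   dyadic-independent ERGM Pr(Y = y) ∝ exp(θ′g(y)) with terms
   `edges + nodematch(group) + nodefactor(group)`, whose MLE is obtained
   exactly by Bernoulli maximum likelihood over dyads.
5. **Co-citation clusters.** References co-cited in the same article are
   linked (weight = number of co-citing articles), the top-100 most
   co-cited references are clustered with Louvain modularity optimization,
   and cluster robustness to the subnetwork size is scored by adjusted
   Rand indices.

A catalogue of standalone complexity metrics (Shannon entropy, mean
information gain, fluctuation complexity, SVD entropy, mutual information,
coefficient of variation) is exported as pure functions.

Because the reference corpus (Web of Science full texts) cannot be
redistributed, the package ships a **synthetic corpus generator**
(`simulateCorpus()`) whose defaults emulate the study conditions — 172
"complexity" vs 180 "control" articles, expected feature richness ≈ 9 vs
≈ 6 of 23, and a citation pool with 3 planted co-citation clusters — and
emits planted ground truth for end-to-end validation.

## Worked example

```r
library(ecoweave)

cfg <- defaultConfig(seed = 42)
cfg$nComplexity <- 40L; cfg$nControl <- 40L
sim <- simulateCorpus(cfg, tempfile())

fm   <- relativeFrequency(dropFeatureless(buildFeatureMatrix(sim$corpus)))
grp  <- as.character(fm$group)
prof <- diversityProfile(fm)
round(tapply(prof$richness, grp, mean), 2)
#> complexity    control
#>       9.12       5.68
anovaCompare(prof$richness, grp)$F
#> [1] 47.22854

disp <- dispersionTest(brayCurtis(fm), grp)
round(disp$groupMeans, 3)
#> complexity    control
#>      0.461      0.566
```

Complexity articles mention more features (9.1 vs 5.7 of 23; the ANOVA F
of 47.2 on 1 and 78 df is decisive at this sample size) and sit closer to
their group's multivariate median (0.461 vs 0.566), i.e. they are more
similar to one another — the two qualitative signatures the pipeline is
designed to detect.

```r
ga  <- projectGraph(buildBipartite(fm), "article", "count")
ergmFit(binarizeProjection(ga))$coefficients
#>         term    estimate        se          z            p
#> 1      edges -0.08624003 0.2059945 -0.4186521 6.754704e-01
#> 2  nodematch  1.46454074 0.2059945  7.1096114 1.163701e-12
#> 3 nodefactor  1.66303409 0.1950127  8.5278255 1.491243e-17

cl <- louvainCluster(topNSubgraph(buildCocitation(sim$corpus), 100), seed = 44)
c(communities = cl$nCommunities, Q = round(cl$Q, 3))
#> communities      Q
#>           3  0.309
```

The positive `nodefactor` coefficient says complexity articles are more
likely to form co-occurrence ties; Louvain recovers the three planted
co-citation clusters. `runAll()` chains all stages and writes every
intermediate table plus a deterministic JSON report.

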