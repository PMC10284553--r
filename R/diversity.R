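## Community-ecology style comparisons of article groups: each feature is a
## "species", each article a "site".

#' Per-article diversity profile
#'
#' Feature richness (number of features mentioned) and the Hill number of
#' order 1 (exponential Shannon entropy of the article's feature-mention
#' proportions), an "effective number of features".
#'
#' @param rf relative-frequency matrix, articles x features (or a
#'   [FeatureMatrix-class] with a relfreq assay). No all-zero rows allowed.
#' @param normalize normalize each article's frequencies to proportions
#'   before the entropy (default TRUE); FALSE uses the raw relative
#'   frequencies in the entropy sum.
#' @return data.frame with columns article_id, richness, hill1.
#' @export
diversityProfile <- function(rf, normalize = TRUE) {
  rf <- asArticleMatrix(rf)
  if (is.null(rownames(rf))) rownames(rf) <- seq_len(nrow(rf))
  if (any(rowSums(rf) == 0))
    stop("all-zero article row(s); run dropFeatureless() first")
  richness <- rowSums(rf > 0)
  p <- if (normalize) rf / rowSums(rf) else rf
  h <- apply(p, 1L, function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  })
  data.frame(article_id = rownames(rf), richness = as.integer(richness),
             hill1 = exp(h), row.names = NULL)
}

#' One-way ANOVA group comparison
#'
#' @param values numeric vector (one value per article).
#' @param groups group labels, same length; every group needs >= 2 members.
#' @return list with F, df1, df2, p.
#' @examples
#' anovaCompare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # F = 13.5
#' @export
anovaCompare <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 members")
  tab <- anova(aov(values ~ groups))
  list(F = tab[["F value"]][1L], df1 = tab[["Df"]][1L],
       df2 = tab[["Df"]][2L], p = tab[["Pr(>F)"]][1L])
}

#' Bray-Curtis dissimilarity between articles
#'
#' d(x, y) = sum(|x - y|) / sum(x + y) over feature relative frequencies.
#'
#' @param rf articles x features matrix (or [FeatureMatrix-class] with
#'   relfreq assay); no all-zero rows.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
brayCurtis <- function(rf) {
  rf <- asArticleMatrix(rf)
  if (any(rowSums(rf) == 0)) stop("all-zero article row(s)")
  as.matrix(vegan::vegdist(rf, method = "bray"))
}

# internal: accept FeatureMatrix (features x articles) or plain matrix
# (articles x features) and return articles x features.
asArticleMatrix <- function(rf) {
  if (is(rf, "FeatureMatrix")) t(relFreq(rf)) else as.matrix(rf)
}

# Weiszfeld iteration for the geometric (spatial) median of rows of X.
geometricMedian <- function(X, tol = 1e-12, maxit = 1000L) {
  X <- as.matrix(X)
  if (nrow(X) == 1L) return(X[1L, ])
  m <- colMeans(X)
  for (it in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(X, 2L, m)^2))
    if (any(d < 1e-14)) {
      # median coincides with a data point: perturb along the descent
      # direction of the remaining points (standard Weiszfeld safeguard)
      at <- which(d < 1e-14)[1L]
      others <- d >= 1e-14
      if (!any(others)) return(X[at, ])
      w <- 1 / d[others]
      R <- colSums(sweep(X[others, , drop = FALSE], 2L, m) * w)
      r <- sqrt(sum(R^2))
      if (r <= 1) return(m)     # the data point itself is the median
      step <- (1 - 1 / r) * R / sum(w)
      mNew <- m + step
    } else {
      w <- 1 / d
      mNew <- colSums(X * w) / sum(w)
    }
    if (sqrt(sum((mNew - m)^2)) < tol * (1 + sqrt(sum(m^2)))) return(mNew)
    m <- mNew
  }
  m
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Embeds a dissimilarity matrix by principal coordinates analysis, keeping
#' axes with positive eigenvalues as "real" and axes with negative
#' eigenvalues as "imaginary"; computes each group's spatial (geometric)
#' median in that space; each member's distance to its group median combines
#' the two parts as d^2 = d_real^2 - d_imag^2 (floored at 0); and compares
#' group mean distances with a one-way ANOVA F test. An optional permutation
#' F test (label permutation of distances) is available.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param groups group labels (length nrow(d)); each group >= 2 members.
#' @param nPerm number of label permutations for an additional permutation
#'   p-value (0 = skip).
#' @param seed RNG seed used when `nPerm > 0`.
#' @return list with `distances` (named per-article), `groupMeans`,
#'   `groupSds`, `F`, `df1`, `df2`, `p`, and `pPerm` when requested.
#' @export
dispersionTest <- function(d, groups, nPerm = 0L, seed = 1L) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  groups <- as.factor(groups)
  stopifnot(length(groups) == n)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 members")

  # Gower-centred PCoA keeping negative-eigenvalue axes
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  eig <- eigen(G, symmetric = TRUE)
  tolEig <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tolEig
  neg <- eig$values < -tolEig
  if (!any(pos)) stop("zero dispersion: all points identical")
  Xr <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  Xi <- if (any(neg))
    eig$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eig$values[neg]), sum(neg))
  else matrix(0, n, 0L)

  dist2 <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    mr <- geometricMedian(Xr[idx, , drop = FALSE])
    dr2 <- rowSums(sweep(Xr[idx, , drop = FALSE], 2L, mr)^2)
    if (ncol(Xi) > 0L) {
      mi <- geometricMedian(Xi[idx, , drop = FALSE])
      di2 <- rowSums(sweep(Xi[idx, , drop = FALSE], 2L, mi)^2)
    } else di2 <- 0
    dist2[idx] <- pmax(dr2 - di2, 0)
  }
  distances <- sqrt(dist2)
  names(distances) <- rownames(d)
  if (all(distances < 1e-14)) stop("zero dispersion: all points identical")

  av <- anovaCompare(distances, groups)
  out <- list(
    distances = distances,
    groupMeans = tapply(distances, groups, mean),
    groupSds = tapply(distances, groups, sd),
    F = av$F, df1 = av$df1, df2 = av$df2, p = av$p)
  if (nPerm > 0L) {
    set.seed(seed)
    fPerm <- replicate(nPerm, anovaCompare(distances, sample(groups))$F)
    out$pPerm <- (1 + sum(fPerm >= av$F)) / (nPerm + 1)
  }
  out
}

#' Indicator feature analysis
#'
#' The classic indicator value: per feature and group, specificity
#' A_g = mean abundance in g / sum over groups of mean abundances, fidelity
#' B_g = fraction of the group's articles containing the feature, statistic
#' = max over groups of A_g * B_g, with a group-label permutation p-value
#' using the add-one convention. `mode = "presence"` replaces abundances by
#' occurrence indicators before computing A.
#'
#' @param x articles x features abundance matrix (or [FeatureMatrix-class]
#'   with relfreq assay).
#' @param groups group labels (length = number of articles).
#' @param mode "abundance" or "presence".
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return data.frame with feature, group (best group), A, B, stat, p;
#'   features absent everywhere get NA stats and a `flag` of "absent".
#' @export
indval <- function(x, groups, mode = c("abundance", "presence"),
                   nPerm = 999L, seed = 1L) {
  mode <- match.arg(mode)
  x <- asArticleMatrix(x)
  if (mode == "presence") x <- (x > 0) * 1
  groups <- as.factor(groups)
  stopifnot(nrow(x) == length(groups), nlevels(groups) >= 2L)
  if (nPerm < 99L) stop("nPerm must be >= 99")
  nG <- nlevels(groups)
  nPer <- as.vector(table(groups))

  statOf <- function(G) {
    # G: n x nG 0/1 indicator matrix; returns list(stat per feature, best)
    sums <- crossprod(G, x)                     # nG x p abundance sums
    means <- sums / as.vector(colSums(G))
    tot <- colSums(means)
    A <- sweep(means, 2L, tot, `/`)             # specificity
    occ <- crossprod(G, (x > 0) * 1) / as.vector(colSums(G))
    AB <- A * occ
    AB[!is.finite(AB)] <- 0   # features absent everywhere
    list(stat = apply(AB, 2L, max), best = apply(AB, 2L, which.max))
  }
  Gobs <- stats::model.matrix(~ groups - 1)
  obs <- statOf(Gobs)

  present <- colSums(x > 0) > 0
  set.seed(seed)
  exceed <- numeric(ncol(x))
  for (b in seq_len(nPerm)) {
    Gp <- Gobs[sample(nrow(x)), , drop = FALSE]
    sp <- statOf(Gp)$stat
    exceed <- exceed + (sp >= obs$stat - 1e-12)
  }
  p <- (1 + exceed) / (nPerm + 1)

  out <- data.frame(
    feature = colnames(x),
    group = levels(groups)[obs$best],
    A = NA_real_, B = NA_real_,
    stat = obs$stat, p = p,
    flag = ifelse(present, "", "absent"),
    row.names = NULL)
  # report A and B of the best group
  sums <- crossprod(Gobs, x)
  means <- sums / nPer
  A <- sweep(means, 2L, colSums(means), `/`)
  occ <- crossprod(Gobs, (x > 0) * 1) / nPer
  for (j in seq_len(ncol(x))) {
    out$A[j] <- A[obs$best[j], j]
    out$B[j] <- occ[obs$best[j], j]
  }
  out$stat[!present] <- NA_real_
  out$p[!present] <- NA_real_
  out$A[!present] <- NA_real_
  out$B[!present] <- NA_real_
  out$group[!present] <- NA_character_
  out
}
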