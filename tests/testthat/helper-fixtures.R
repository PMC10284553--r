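# Fixture builders and brute-force oracles shared across the suite.
# Oracles are deliberately naive and independent of the package internals.

# Write a throwaway corpus from named text strings; refs is an optional
# named list of citation-key vectors.
makeCorpus <- function(texts, groups, years = NULL, refs = NULL) {
  dir <- tempfile("fixcorpus")
  dir.create(file.path(dir, "texts"), recursive = TRUE)
  ids <- names(texts)
  for (id in ids)
    writeLines(texts[[id]], file.path(dir, "texts", paste0(id, ".txt")))
  if (is.null(years)) years <- rep(2010L, length(ids))
  refStr <- if (is.null(refs)) rep("", length(ids))
            else vapply(ids, function(id)
              paste(refs[[id]], collapse = "|"), "")
  meta <- data.frame(article_id = ids, group = groups, year = years,
                     text_file = paste0(ids, ".txt"), references = refStr)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  suppressMessages(readCorpus(file.path(dir, "metadata.tsv"),
                              file.path(dir, "texts")))
}

# Plain-R geometric median by direct minimisation of the summed Euclidean
# distance (oracle for the Weiszfeld implementation inside dispersionTest).
oracleGeometricMedian <- function(X) {
  X <- as.matrix(X)
  obj <- function(m) sum(sqrt(rowSums(sweep(X, 2L, m)^2)))
  grad <- function(m) {
    D <- sweep(X, 2L, m)
    nrm <- sqrt(rowSums(D^2))
    -colSums(D / nrm)
  }
  m0 <- optim(colMeans(X), obj, method = "Nelder-Mead",
              control = list(maxit = 50000, reltol = 1e-14))$par
  # gradient polish (objective is smooth away from the data points)
  optim(m0, obj, grad, method = "BFGS",
        control = list(maxit = 10000, reltol = 1e-16))$par
}

# Distances of each point to its group geometric median, computed straight
# from Euclidean coordinates (bypasses PCoA entirely).
oracleMedianDistances <- function(X, groups) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    m <- oracleGeometricMedian(X[idx, , drop = FALSE])
    out[idx] <- sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2L, m)^2))
  }
  out
}

# All set partitions of n elements (restricted growth strings); n <= 9.
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, maxUsed) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (k in seq_len(maxUsed + 1L))
      rec(c(assign, k), max(maxUsed, k))
  }
  rec(integer(0), 0L)
  out
}

# Weighted modularity of a membership vector on an igraph.
modularityOf <- function(g, membership) {
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

# Exhaustive maximum modularity over every partition (graphs of <= 8 nodes).
oracleMaxModularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8L)
  best <- -Inf
  for (p in allPartitions(n)) best <- max(best, modularityOf(g, p))
  best
}

# Brute-force co-occurrence tally: number of articles containing both
# features (count-mode projection oracle).
oracleCooccurrence <- function(rf) {
  p <- ncol(rf)
  M <- matrix(0L, p, p, dimnames = list(colnames(rf), colnames(rf)))
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p))
    M[i, j] <- M[j, i] <- sum(rf[, i] > 0 & rf[, j] > 0)
  M
}

# Log-likelihood of the three-term dyadic-independent ERGM, direct form.
oracleErgmLogLik <- function(theta, adj, groups, focal) {
  n <- nrow(adj)
  ll <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    eta <- theta[1L] + theta[2L] * (groups[i] == groups[j]) +
      theta[3L] * ((groups[i] == focal) + (groups[j] == focal))
    ll <- ll + adj[i, j] * eta - log(1 + exp(eta))
  }
  ll
}

# Coarse-to-fine grid maximisation of the ERGM likelihood (test oracle).
oracleErgmGrid <- function(adj, groups, focal, center = c(0, 0, 0),
                           width = 4, levels = 8L, pts = 9L) {
  best <- center
  for (l in seq_len(levels)) {
    gr <- lapply(best, function(c0) seq(c0 - width, c0 + width, length.out = pts))
    bestLL <- -Inf
    for (a in gr[[1L]]) for (b in gr[[2L]]) for (d in gr[[3L]]) {
      ll <- oracleErgmLogLik(c(a, b, d), adj, groups, focal)
      if (ll > bestLL) { bestLL <- ll; cand <- c(a, b, d) }
    }
    best <- cand
    width <- width / (pts - 1) * 2   # shrink around the winner
  }
  list(theta = best, logLik = bestLL)
}

# Erdos-Renyi style two-group graph with within/between tie probabilities.
simHomophilyGraph <- function(n, pWithin, pBetween, seed) {
  set.seed(seed)
  groups <- rep(c("complexity", "control"), length.out = n)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    pr <- if (groups[i] == groups[j]) pWithin else pBetween
    adj[i, j] <- adj[j, i] <- as.integer(runif(1) < pr)
  }
  list(adj = adj, groups = groups)
}
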