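mkRf <- function() {
  rf <- rbind(a1 = c(0.1, 0.3, 0.0, 0.2),
              a2 = c(0.2, 0.2, 0.0, 0.0),
              a3 = c(0.0, 0.1, 0.4, 0.0),
              a4 = c(0.3, 0.0, 0.1, 0.0))
  colnames(rf) <- c("fA", "fB", "fC", "fD")
  rf
}

test_that("bipartite graph has one weighted edge per nonzero entry", {
  rf <- mkRf()
  b <- buildBipartite(rf, groups = c("complexity", "complexity",
                                     "control", "control"))
  expect_equal(igraph::ecount(b), sum(rf > 0))
  el <- igraph::as_edgelist(b)
  w <- igraph::E(b)$weight
  for (k in seq_len(nrow(el)))
    expect_equal(w[k], rf[el[k, 1], el[k, 2]])
  expect_true(igraph::is_bipartite(b))
})

test_that("count-mode projection equals the brute-force co-occurrence tally", {
  set.seed(14)
  rf <- matrix(rexp(10 * 6) * rbinom(60, 1, 0.5), 10,
               dimnames = list(paste0("a", 1:10), paste0("f", 1:6)))
  rf[rowSums(rf) == 0, 1] <- 0.1
  b <- buildBipartite(rf, groups = rep(c("complexity", "control"), 5))
  g <- projectGraph(b, "feature", "count")
  adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                               sparse = FALSE))
  oracle <- oracleCooccurrence(rf)
  expect_equal(adj[colnames(oracle), colnames(oracle)], oracle + 0)
})

test_that("min_sum projection weights follow the formula", {
  rf <- rbind(a1 = c(0.1, 0.3), a2 = c(0.2, 0.2))
  colnames(rf) <- c("fA", "fB")
  b <- buildBipartite(rf, groups = c("complexity", "control"))
  g <- projectGraph(b, "feature", "min_sum")
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("fA", "fB"))]
  expect_equal(w, 0.1 + 0.2)  # sum over shared articles of min weights
})

test_that("features used by a single article are isolated in the projection", {
  rf <- rbind(a1 = c(0.1, 0, 0.2), a2 = c(0, 0.5, 0.2))
  colnames(rf) <- c("onlyA", "onlyB", "shared")
  b <- buildBipartite(rf, groups = c("complexity", "control"))
  g <- projectGraph(b, "feature", "count")
  expect_equal(igraph::degree(g)["onlyA"] + igraph::degree(g)["onlyB"],
               c(onlyA = 2))  # each links only to "shared"
  expect_equal(unname(igraph::degree(g)["shared"]), 2)
})

test_that("network summary: connectance, strength, degree distribution", {
  gK5 <- igraph::make_full_graph(5)
  igraph::E(gK5)$weight <- 1
  expect_equal(networkSummary(gK5)$connectance, 1)

  # the reference corpus geometry: 23 nodes, 250 of 253 links
  g23 <- igraph::sample_gnm(23, 250)
  igraph::E(g23)$weight <- 1
  expect_equal(networkSummary(g23)$connectance, 250 / 253, tolerance = 1e-12)
  expect_equal(round(networkSummary(g23)$connectance, 3), 0.988)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::E(star)$weight <- 1
  ns <- networkSummary(star)
  expect_equal(max(ns$strength), 4)
  dd <- ns$degreeDistribution
  expect_equal(dd$pk[dd$k == 1], 4 / 5)
  expect_error(networkSummary(igraph::make_empty_graph(1, directed = FALSE)),
               ">= 2 nodes")
})

test_that("intercept-only ERGM equals the logit of the density exactly", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[1, 3] <- adj[3, 1] <- adj[1, 4] <- adj[4, 1] <- 1
  res <- ergmFit(adj, groups = rep(c("complexity", "control"), 2),
                 termsKeep = "edges")
  expect_equal(res$coefficients$estimate[1], qlogis(0.5), tolerance = 1e-10)
  expect_equal(unname(res$stats["edges"]), 3)
})

test_that("ERGM MLE matches an exhaustive likelihood grid on 6 nodes", {
  set.seed(17)
  adj <- matrix(0L, 6, 6)
  # every (same, nfocal) cell mixes ties and non-ties: finite MLE
  ties <- rbind(c(1, 2), c(1, 3), c(4, 5), c(2, 5), c(3, 6), c(1, 6))
  for (k in seq_len(nrow(ties)))
    adj[ties[k, 1], ties[k, 2]] <- adj[ties[k, 2], ties[k, 1]] <- 1L
  groups <- rep(c("complexity", "control"), each = 3)
  res <- ergmFit(adj, groups = groups)
  grid <- oracleErgmGrid(adj, groups, "complexity",
                         center = res$coefficients$estimate, width = 0.5)
  expect_equal(res$coefficients$estimate, grid$theta, tolerance = 1e-4)
  # optimum dominates every grid point
  expect_gte(res$logLik + 1e-8, grid$logLik)
  expect_equal(res$logLik,
               oracleErgmLogLik(res$coefficients$estimate, adj, groups,
                                "complexity"),
               tolerance = 1e-8)
})

test_that("planted homophily is recovered: nodematch near logit ratio", {
  ests <- ses <- numeric(10)
  for (s in 1:10) {
    sim <- simHomophilyGraph(100, 0.8, 0.2, seed = 1000 + s)
    res <- ergmFit(sim$adj, groups = sim$groups)
    co <- res$coefficients
    ests[s] <- co$estimate[co$term == "nodematch"]
    ses[s] <- co$se[co$term == "nodematch"]
  }
  target <- qlogis(0.8) - qlogis(0.2)    # 2.773
  expect_lt(abs(mean(ests) - target), 3 * mean(ses) / sqrt(10))
  expect_true(all(abs(ests - target) < 3.5 * ses))
})

test_that("degenerate graphs are reported as non-converged", {
  adjFull <- matrix(1, 5, 5); diag(adjFull) <- 0
  expect_warning(res <- ergmFit(adjFull,
                                groups = rep(c("complexity", "control"),
                                             length.out = 5),
                                termsKeep = "edges"),
                 "converge")
  expect_false(res$converged)
  expect_error(ergmFit(matrix(0, 3, 3), groups = rep("complexity", 3)),
               ">= 4 nodes")
})

test_that("binarization threshold controls article ties", {
  rf <- rbind(a1 = c(1, 1, 1, 0) * 0.1, a2 = c(1, 1, 0, 0) * 0.1,
              a3 = c(0, 0, 0, 1) * 0.1)
  colnames(rf) <- paste0("f", 1:4)
  b <- buildBipartite(rf, groups = c("complexity", "control", "control"))
  ga <- projectGraph(b, "article", "count")
  g1 <- binarizeProjection(ga, tau = 1)
  g2 <- binarizeProjection(ga, tau = 2)
  expect_equal(igraph::ecount(g1), 1)    # a1-a2 share 2 features
  expect_equal(igraph::ecount(g2), 1)
  g3 <- binarizeProjection(ga, tau = 3)
  expect_equal(igraph::ecount(g3), 0)
  expect_equal(igraph::vcount(g3), 3)    # vertices kept
})
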