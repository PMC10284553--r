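test_that("diversity profile: richness and Hill number of order 1", {
  rf <- rbind(u = c(0.1, 0.1, 0.1, 0.1, 0),
              s = c(0.3, 0, 0, 0, 0),
              m = c(0.5, 0.25, 0.25, 0, 0) / 10)
  colnames(rf) <- paste0("f", 1:5)
  prof <- diversityProfile(rf)
  expect_equal(prof$richness, c(4L, 1L, 3L))
  expect_equal(prof$hill1[1], 4)         # uniform: effective = observed
  expect_equal(prof$hill1[2], 1)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(prof$hill1[3], exp(-sum(p * log(p))), tolerance = 1e-12)
  expect_equal(prof$hill1[3], 2.828, tolerance = 1e-3)
  expect_error(diversityProfile(rbind(c(0, 0))), "all-zero")
})

test_that("hill1 <= richness with equality only at uniform profiles", {
  set.seed(11)
  for (r in 1:1000) {
    x <- rexp(8) * rbinom(8, 1, 0.7)
    if (all(x == 0)) x[1] <- 1
    prof <- diversityProfile(matrix(x, 1))
    expect_lte(prof$hill1, prof$richness + 1e-10)
    expect_gte(prof$hill1, 1 - 1e-10)
  }
})

test_that("one-way ANOVA matches the hand-computed example", {
  res <- anovaCompare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))
  ident <- anovaCompare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(ident$F, 0)
  expect_error(anovaCompare(c(1, 2, 3), c("a", "a", "b")), ">= 2 members")
})

test_that("Bray-Curtis dissimilarity follows the direct formula", {
  rf <- rbind(a = c(0.2, 0.8), b = c(0.8, 0.2), c = c(0.2, 0.8),
              d = c(0.5, 0))
  d <- brayCurtis(rf)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.6)
  e <- brayCurtis(rbind(x = c(1, 0), y = c(0, 1)))
  expect_equal(e["x", "y"], 1)           # disjoint supports
  expect_true(all(diag(d) == 0))
})

test_that("PERMDISP distances match the Euclidean geometric-median oracle", {
  # two squares of different size, plus jitter to avoid exact symmetry ties
  set.seed(3)
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  X <- rbind(sq + matrix(rnorm(8, 0, 0.05), 4),
             3 * sq + 10 + matrix(rnorm(8, 0, 0.05), 4))
  groups <- rep(c("g1", "g2"), each = 4)
  d <- as.matrix(dist(X))
  res <- dispersionTest(d, groups)
  expect_equal(unname(res$distances), oracleMedianDistances(X, groups),
               tolerance = 1e-8)
  expect_equal(res$F, anovaCompare(res$distances, groups)$F)
})

test_that("PERMDISP agrees with the established reference implementation", {
  set.seed(9)
  rf <- matrix(rexp(20 * 6), 20)
  rf <- rf / rowSums(rf)
  groups <- rep(c("complexity", "control"), each = 10)
  d <- brayCurtis(rf)
  res <- dispersionTest(d, groups)
  ref <- vegan::betadisper(as.dist(d), groups, type = "median")
  # agreement limited by the reference's own median optimiser tolerance
  expect_equal(unname(res$distances), unname(ref$distances),
               tolerance = 1e-4)
  refF <- anova(ref)
  expect_lt(abs(res$F - refF[["F value"]][1]), 1e-3)
})

test_that("mirror-image group configurations give F = 0", {
  X1 <- rbind(c(0, 0), c(2, 0), c(0, 3), c(5, 4))
  X2 <- -X1 + 100                       # congruent configuration
  d <- as.matrix(dist(rbind(X1, X2)))
  res <- dispersionTest(d, rep(c("a", "b"), each = 4))
  expect_equal(unname(res$groupMeans["a"]), unname(res$groupMeans["b"]),
               tolerance = 1e-10)
  expect_lt(res$F, 1e-15)
})

test_that("a group of identical points has zero distances", {
  X <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 0), c(9, 4), c(2, 7))
  d <- as.matrix(dist(X))
  res <- dispersionTest(d, rep(c("same", "diff"), each = 3))
  expect_true(all(res$distances[1:3] < 1e-10))
  dAll0 <- matrix(0, 4, 4)
  expect_error(dispersionTest(dAll0, rep(c("a", "b"), each = 2)),
               "zero dispersion")
})

test_that("indval recovers perfect and uninformative indicators", {
  X <- matrix(0, 20, 3, dimnames = list(NULL, c("perf", "flat", "gone")))
  X[1:10, "perf"] <- 2                  # all of group A, absent in B
  X[, "flat"] <- 1                      # everywhere, equal abundance
  groups <- rep(c("A", "B"), each = 10)
  res <- indval(X, groups, nPerm = 199, seed = 4)
  expect_equal(res$stat[res$feature == "perf"], 1.0)
  expect_equal(res$p[res$feature == "perf"], 1 / 200)
  expect_equal(res$group[res$feature == "perf"], "A")
  expect_equal(res$stat[res$feature == "flat"], 0.5)   # A=0.5, B=1
  expect_equal(res$flag[res$feature == "gone"], "absent")
  expect_true(is.na(res$stat[res$feature == "gone"]))
})

test_that("indval presence mode ignores abundance differences", {
  X <- matrix(1, 12, 1, dimnames = list(NULL, "f"))
  X[1:6] <- 50                           # same occupancy, huge abundance gap
  groups <- rep(c("A", "B"), each = 6)
  ab <- indval(X, groups, mode = "abundance", nPerm = 99, seed = 1)
  pr <- indval(X, groups, mode = "presence", nPerm = 99, seed = 1)
  expect_gt(ab$stat, 0.9)
  expect_equal(pr$stat, 0.5)
})
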