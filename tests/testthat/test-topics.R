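test_that("K = 1 with a flat prior recovers the empirical word distribution", {
  docs <- list(c("alpha", "beta", "alpha"), c("gamma", "alpha"))
  tm <- fitTopics(docs, K = 1, seed = 1, eta = 0, iters = 20, burnin = 10)
  emp <- table(factor(unlist(docs), levels = tm@vocabulary)) / 5
  expect_equal(unname(tm@beta[1, ]), unname(as.vector(emp)))
  expect_equal(rowSums(tm@gamma), rep(1, 2))
})

test_that("the same seed reproduces the fit exactly", {
  set.seed(99)
  docs <- replicate(6, sample(letters[1:12], 40, replace = TRUE),
                    simplify = FALSE)
  t1 <- fitTopics(docs, K = 3, seed = 7)
  t2 <- fitTopics(docs, K = 3, seed = 7)
  expect_identical(t1@beta, t2@beta)
  expect_identical(t1@gamma, t2@gamma)
})

test_that("two planted disjoint vocabularies are recovered at K = 2", {
  vocabA <- paste0("aqua", 1:15); vocabB <- paste0("bryo", 1:15)
  set.seed(5)
  docs <- c(replicate(12, sample(vocabA, 60, replace = TRUE), simplify = FALSE),
            replicate(12, sample(vocabB, 60, replace = TRUE), simplify = FALSE))
  tm <- fitTopics(docs, K = 2, seed = 3, iters = 300, burnin = 150)
  planted <- rbind(A = as.numeric(tm@vocabulary %in% vocabA),
                   B = as.numeric(tm@vocabulary %in% vocabB))
  planted <- planted / rowSums(planted)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  sim <- outer(1:2, 1:2, Vectorize(function(k, p)
    cosine(tm@beta[k, ], planted[p, ])))
  # each recovered topic matches one planted topic
  expect_gt(max(sim[1, ]), 0.9)
  expect_gt(max(sim[2, ]), 0.9)
  expect_false(which.max(sim[1, ]) == which.max(sim[2, ]))
})

test_that("HDI top-word selection keeps outliers and drops uniform rows", {
  mkTm <- function(beta) {
    beta <- beta / rowSums(beta)
    D <- 2
    new("TopicModel", K = nrow(beta), beta = beta,
        gamma = matrix(1 / nrow(beta), D, nrow(beta)),
        vocabulary = paste0("w", seq_len(ncol(beta))), seed = 1L)
  }
  # one dominant word among 1000
  b1 <- matrix(c(0.9, rep(0.1 / 999, 999)), 1)
  s1 <- selectTopWords(mkTm(b1))
  expect_equal(s1$selection$word, "w1")
  # uniform row: nothing strictly above the common threshold
  b2 <- matrix(1 / 400, 1, 400)
  s2 <- selectTopWords(mkTm(b2))
  expect_equal(nrow(s2$selection), 0L)
  # constructed spread: selection size tracks the upper tail (~0.5%)
  set.seed(2)
  v <- 1000
  b3 <- matrix(c(rexp(v - 5) * 1e-4, rep(0.05, 5)), 1)
  s3 <- selectTopWords(mkTm(b3))
  expect_gte(nrow(s3$selection), 5L)
  expect_lte(nrow(s3$selection), ceiling(0.015 * v))
  expect_true(all(s3$selection$beta > s3$thresholds[1]))
  expect_true(all(s3$selection$quartile %in% paste0("Q", 1:4)))
})

test_that("top-word selection is invariant to word relabeling", {
  set.seed(8)
  beta <- matrix(rexp(3 * 200), 3); beta <- beta / rowSums(beta)
  tmA <- new("TopicModel", K = 3L, beta = beta,
             gamma = matrix(1 / 3, 4, 3), vocabulary = paste0("w", 1:200),
             seed = 1L)
  perm <- sample(200)
  tmB <- new("TopicModel", K = 3L, beta = beta[, perm],
             gamma = matrix(1 / 3, 4, 3),
             vocabulary = paste0("w", 1:200)[perm], seed = 1L)
  sA <- selectTopWords(tmA); sB <- selectTopWords(tmB)
  expect_equal(table(sA$selection$topic), table(sB$selection$topic))
  expect_equal(sort(sA$selection$word), sort(sB$selection$word))
})

test_that("feature-topic comparison finds the planted group difference", {
  lex <- defaultLexicon()
  set.seed(21)
  filler <- paste0("moss", 1:40)
  mkDoc <- function(nFeat) c(sample(filler, 60, replace = TRUE),
                             rep(c("chaotic", "feedback"), nFeat))
  docs <- c(replicate(10, mkDoc(6), simplify = FALSE),
            replicate(10, mkDoc(0), simplify = FALSE))
  groups <- rep(c("complexity", "control"), each = 10)
  tm <- fitTopics(docs, K = 3, seed = 2, iters = 150, burnin = 75)
  sel <- selectTopWords(tm)
  cmp <- compareFeatureTopics(tm, sel, lex, groups)
  for (f in c("chaos", "feedback")) {
    sub <- cmp[cmp$feature == f, ]
    expect_gt(sub$meanDocProb[sub$group == "complexity"],
              sub$meanDocProb[sub$group == "control"])
  }
  # features with no matching vocabulary are flagged absent
  expect_true(all(cmp$flag[cmp$feature == "fractality"] == "absent"))
  expect_equal(cmp$meanDocProb[cmp$feature == "fractality"], c(0, 0))
})

test_that("group difference centres on zero under random labels", {
  set.seed(31)
  filler <- paste0("fern", 1:30)
  docs <- replicate(16, c(sample(filler, 50, replace = TRUE),
                          rep("chaotic", 3)), simplify = FALSE)
  lex <- defaultLexicon()
  diffs <- vapply(1:5, function(s) {
    groups <- sample(rep(c("complexity", "control"), each = 8))
    tm <- fitTopics(docs, K = 2, seed = s, iters = 80, burnin = 40)
    cmp <- compareFeatureTopics(tm, selectTopWords(tm), lex, groups)
    sub <- cmp[cmp$feature == "chaos", ]
    sub$meanDocProb[sub$group == "complexity"] -
      sub$meanDocProb[sub$group == "control"]
  }, 0)
  expect_lt(abs(mean(diffs)), 0.02)
})
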