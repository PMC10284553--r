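## Topic modelling: LDA fit (collapsed Gibbs, compiled) and the bespoke
## post-processing: highest-density-interval top-word selection, quartile
## ranking, and per-feature group comparison of topic importance.

#' @useDynLib ecoweave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors. Beta and gamma
#' are posterior means averaged over the post-burnin sweeps. Deterministic
#' given `seed`.
#'
#' @param docs list of >= 2 preprocessed token vectors
#'   (see [preprocessForTopics()]).
#' @param K number of topics (>= 1); the reference analysis uses 100,
#'   synthetic tests use small K.
#' @param seed integer RNG seed.
#' @param alpha document-topic Dirichlet concentration (default 50/K).
#' @param eta topic-word Dirichlet concentration. With `eta = 0` the
#'   estimator is the maximum-likelihood word distribution (useful for the
#'   K = 1 analytic limit).
#' @param iters total Gibbs sweeps; `burnin` of them are discarded.
#' @param burnin number of initial sweeps to discard.
#' @return a [TopicModel-class].
#' @export
fitTopics <- function(docs, K, seed = 1L, alpha = 50 / K, eta = 0.1,
                      iters = 200L, burnin = 100L) {
  stopifnot(length(docs) >= 2L, K >= 1L, iters > burnin)
  vocab <- sort(unique(unlist(docs)))
  if (length(vocab) == 0L) stop("empty vocabulary")
  idx <- lapply(docs, function(d) match(d, vocab) - 1L)
  set.seed(seed)
  fit <- lda_gibbs_cpp(idx, length(vocab), as.integer(K), alpha, eta,
                       as.integer(iters), as.integer(burnin))
  beta <- fit$beta
  gamma <- fit$gamma
  colnames(beta) <- vocab
  if (!is.null(names(docs))) rownames(gamma) <- names(docs)
  new("TopicModel", K = as.integer(K), beta = beta, gamma = gamma,
      vocabulary = vocab, seed = as.integer(seed))
}

# Shortest contiguous window of m sorted values; returns its upper limit.
hdiUpper <- function(values, mass) {
  v <- sort(values)
  V <- length(v)
  m <- min(V, max(1L, ceiling(mass * V)))
  if (m == V) return(v[V])
  widths <- v[seq(m, V)] - v[seq(1L, V - m + 1L)]
  i <- which.min(widths)
  v[i + m - 1L]
}

#' Select each topic's top words
#'
#' Because LDA puts near-zero probability on most words in a topic, the top
#' words are selected as the values strictly above the upper limit of the
#' empirical highest-density interval (the shortest contiguous window of
#' sorted beta values covering `hdiMass` of the words). Selected words get
#' within-topic ranks and quartile labels (Q1 = lowest betas among the
#' selection, Q4 = highest). `method = "topfrac"` instead keeps the
#' `topFrac` highest-probability words per topic.
#'
#' @param tm a [TopicModel-class].
#' @param hdiMass HDI mass (default 0.99).
#' @param topFrac fraction of the vocabulary kept under `method="topfrac"`
#'   (default 0.005).
#' @param method "hdi" (default) or "topfrac".
#' @param pooled compute a single HDI threshold from the betas of all topics
#'   pooled, instead of per topic.
#' @return list with `selection` (data.frame: topic, word, beta, rank,
#'   quartile) and `thresholds` (per topic).
#' @export
selectTopWords <- function(tm, hdiMass = 0.99, topFrac = 0.005,
                           method = c("hdi", "topfrac"), pooled = FALSE) {
  stopifnot(is(tm, "TopicModel"))
  method <- match.arg(method)
  K <- tm@K
  V <- length(tm@vocabulary)
  thresholds <- numeric(K)
  rows <- vector("list", K)
  pooledThr <- if (pooled && method == "hdi")
    hdiUpper(as.vector(tm@beta), hdiMass) else NA_real_
  for (k in seq_len(K)) {
    b <- tm@beta[k, ]
    if (method == "hdi") {
      thr <- if (pooled) pooledThr else hdiUpper(b, hdiMass)
      sel <- which(b > thr)
    } else {
      nKeep <- max(1L, round(topFrac * V))
      ord <- order(b, decreasing = TRUE)
      sel <- ord[seq_len(nKeep)]
      thr <- min(b[sel])
    }
    thresholds[k] <- thr
    if (length(sel)) {
      bb <- b[sel]
      rk <- rank(bb, ties.method = "first")
      q <- paste0("Q", ceiling(4 * rk / length(rk)))
      rows[[k]] <- data.frame(topic = k, word = tm@vocabulary[sel],
                              beta = unname(bb), rank = rk, quartile = q,
                              row.names = NULL)
    }
  }
  selection <- if (any(!vapply(rows, is.null, TRUE)))
    do.call(rbind, rows)
  else data.frame(topic = integer(), word = character(), beta = numeric(),
                  rank = integer(), quartile = character())
  list(selection = selection, thresholds = thresholds)
}

# Map lexicon features onto a (preprocessed, hyphen-free) vocabulary using
# the same prefix rules as the counting matcher; bigram stems match the
# joined form.
featureVocabulary <- function(lexicon, vocab) {
  setNames(lapply(seq_along(lexicon@stems), function(i) {
    hit <- rep(FALSE, length(vocab))
    for (st in lexicon@stems[[i]]) {
      pref <- if (length(st) == 2L) paste0(st[1L], st[2L]) else st
      hit <- hit | startsWith(vocab, pref)
    }
    vocab[hit]
  }), lexicon@name)
}

#' Compare feature importance in topics between groups
#'
#' For every lexicon feature and article group: (a) the number of topics
#' whose top-word selection contains a feature-matching word, with each
#' topic attributed to the group holding the larger gamma-weighted share of
#' it; and (b) the mean per-document feature probability
#' sum_k gamma[d,k] * sum_{w in feature} beta[k,w], averaged within group.
#'
#' @param tm a [TopicModel-class].
#' @param sel result of [selectTopWords()].
#' @param lexicon a [FeatureLexicon-class].
#' @param docGroups group label per document (length nrow(gamma)).
#' @return data.frame with one row per feature x group: feature, group,
#'   nTopics, meanDocProb, flag ("absent" when no vocabulary word matches
#'   the feature).
#' @export
compareFeatureTopics <- function(tm, sel, lexicon, docGroups) {
  stopifnot(is(tm, "TopicModel"), is(lexicon, "FeatureLexicon"))
  docGroups <- as.factor(docGroups)
  stopifnot(length(docGroups) == nrow(tm@gamma))
  fv <- featureVocabulary(lexicon, tm@vocabulary)

  # feature indicator over vocabulary
  M <- vapply(fv, function(wds) tm@vocabulary %in% wds,
              logical(length(tm@vocabulary)))
  featBeta <- tm@beta %*% M                      # K x p
  docProb <- tm@gamma %*% featBeta               # D x p

  # attribute each topic to the group with the larger gamma share
  shares <- rowsum(tm@gamma, docGroups)          # g x K (column sums by group)
  topicGroup <- levels(docGroups)[apply(shares, 2L, which.max)]

  out <- do.call(rbind, lapply(seq_along(fv), function(i) {
    fname <- names(fv)[i]
    absent <- length(fv[[i]]) == 0L
    do.call(rbind, lapply(levels(docGroups), function(g) {
      inTopic <- if (absent) 0L else {
        ks <- unique(sel$selection$topic[sel$selection$word %in% fv[[i]]])
        sum(topicGroup[ks] == g)
      }
      data.frame(feature = fname, group = g, nTopics = inTopic,
                 meanDocProb = mean(docProb[docGroups == g, i]),
                 flag = if (absent) "absent" else "",
                 row.names = NULL)
    }))
  }))
  out
}
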