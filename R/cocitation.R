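## Weighted co-citation networks from article reference lists, Louvain
## community detection, and a robustness sweep over the subnetwork size.

# case-fold + strip punctuation/whitespace so raw reference strings behave
# like citation keys
normalizeCitationKey <- function(keys) {
  gsub("[^a-z0-9]", "", tolower(keys))
}

#' Build the co-citation network
#'
#' References become nodes; every unordered pair of distinct references
#' appearing together in an article's reference list increments that pair's
#' edge weight by 1 (duplicate keys within one list count once). By default
#' only the "complexity" group's reference lists are used, mirroring the
#' reference analysis; use `group = NULL` for all articles.
#'
#' @param corpus a [Corpus-class] (or a plain list of character reference
#'   vectors).
#' @param group restrict to one article group, or NULL for all.
#' @param normalizeKeys apply the citation-key normalizer (lowercase,
#'   strip non-alphanumerics).
#' @return an undirected igraph with integer edge weights and a vertex
#'   `strength` attribute (total co-citation strength).
#' @export
buildCocitation <- function(corpus, group = "complexity",
                            normalizeKeys = FALSE) {
  refs <- if (is(corpus, "Corpus")) {
    keep <- if (is.null(group)) rep(TRUE, length(corpus))
            else corpus@meta$group == group
    corpus@meta$references[keep]
  } else corpus
  refs <- lapply(refs, function(r) {
    r <- as.character(r)
    if (normalizeKeys) r <- normalizeCitationKey(r)
    sort(unique(r[nzchar(r)]))
  })
  if (!any(lengths(refs) > 0L)) stop("no references in any article")
  pairs <- list()
  for (r in refs) {
    if (length(r) < 2L) next
    cmb <- utils::combn(r, 2L)
    pairs[[length(pairs) + 1L]] <- cmb
  }
  if (length(pairs) == 0L)
    stop("no co-citations: every reference list has < 2 entries")
  allPairs <- do.call(cbind, pairs)
  key <- paste(allPairs[1L, ], allPairs[2L, ], sep = "\r")
  tab <- table(key)
  uv <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = uv[, 1L], to = uv[, 2L], weight = as.integer(tab)),
    directed = FALSE,
    vertices = sort(unique(unlist(refs))))
  igraph::set_vertex_attr(g, "strength",
    value = igraph::strength(g, weights = igraph::E(g)$weight))
}

#' Top-n most co-cited subnetwork
#'
#' Keeps the `n` nodes with the highest total co-citation strength
#' (weighted degree), ties broken lexicographically by citation key, and
#' returns the induced subgraph. `rankBy = "count"` ranks by unweighted
#' degree instead.
#'
#' @param g co-citation igraph.
#' @param n number of nodes to keep (default 100).
#' @param rankBy "strength" (default) or "count".
#' @return the induced igraph subgraph.
#' @export
topNSubgraph <- function(g, n = 100L, rankBy = c("strength", "count")) {
  rankBy <- match.arg(rankBy)
  if (n <= 0L) stop("n must be positive")
  sc <- if (rankBy == "strength")
    igraph::strength(g, weights = igraph::E(g)$weight)
  else igraph::degree(g)
  nm <- igraph::V(g)$name
  ord <- order(-sc, nm)
  keep <- nm[ord[seq_len(min(n, length(nm)))]]
  igraph::induced_subgraph(g, keep)
}

#' Louvain community detection
#'
#' Greedy weighted-modularity optimization (Louvain). The seed controls the
#' node-order randomization; connected components are handled independently
#' by the algorithm. Returns the partition and its weighted modularity
#' Q = sum_c (e_c / m - (d_c / 2m)^2).
#'
#' @param g weighted (or unweighted) undirected igraph; must be nonempty.
#' @param seed integer RNG seed.
#' @return list with `membership` (named integer vector), `Q`, `nCommunities`.
#' @export
louvainCluster <- function(g, seed = 1L) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  w <- igraph::E(g)$weight
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = w)
  membership <- igraph::membership(cl)
  list(membership = membership,
       Q = igraph::modularity(g, membership, weights = w),
       nCommunities = length(unique(membership)))
}

#' Robustness of co-citation clusters to subnetwork size
#'
#' Recomputes the top-n subgraph and its Louvain partition for each n and
#' reports the adjusted Rand index between consecutive partitions on their
#' shared nodes.
#'
#' @param g co-citation igraph.
#' @param nValues integer vector of subnetwork sizes.
#' @param seed integer RNG seed (reused per clustering).
#' @return list with `partitions` (list of membership vectors, named by n)
#'   and `ari` (data.frame n1, n2, ari for consecutive pairs).
#' @export
robustnessSweep <- function(g, nValues, seed = 1L) {
  parts <- lapply(nValues, function(n)
    louvainCluster(topNSubgraph(g, n), seed = seed)$membership)
  names(parts) <- as.character(nValues)
  ari <- NULL
  if (length(nValues) >= 2L) {
    ari <- do.call(rbind, lapply(seq_len(length(nValues) - 1L), function(i) {
      shared <- intersect(names(parts[[i]]), names(parts[[i + 1L]]))
      data.frame(n1 = nValues[i], n2 = nValues[i + 1L],
                 ari = mclust::adjustedRandIndex(parts[[i]][shared],
                                                 parts[[i + 1L]][shared]))
    }))
  }
  list(partitions = parts, ari = ari)
}
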