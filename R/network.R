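## Article-feature co-occurrence networks: bipartite construction, unipartite
## projection, summary statistics, and a dyadic-independent exponential
## random graph model whose MLE reduces exactly to Bernoulli maximum
## likelihood over dyads.

#' Build the bipartite article-feature network
#'
#' One edge per nonzero relative-frequency entry, weighted by the article's
#' relative usage of the feature. Article vertices carry a `group`
#' attribute; vertex `type` is TRUE for features (igraph bipartite
#' convention).
#'
#' @param rf a [FeatureMatrix-class] with a relfreq assay, or a plain
#'   articles x features relative-frequency matrix (then `groups` must be
#'   given).
#' @param groups article group labels when `rf` is a plain matrix.
#' @return an igraph bipartite graph.
#' @export
buildBipartite <- function(rf, groups = NULL) {
  if (is(rf, "FeatureMatrix")) {
    groups <- as.character(rf$group)
    rf <- t(relFreq(rf))
  }
  rf <- as.matrix(rf)
  if (any(rowSums(rf) == 0)) stop("all-zero article row(s)")
  stopifnot(!is.null(groups), length(groups) == nrow(rf))
  arts <- rownames(rf); feats <- colnames(rf)
  nz <- which(rf > 0, arr.ind = TRUE)
  edges <- rbind(arts[nz[, 1L]], feats[nz[, 2L]])
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(arts), name = arts, type = FALSE,
                            group = groups)
  g <- igraph::add_vertices(g, length(feats), name = feats, type = TRUE,
                            group = NA_character_)
  g <- igraph::add_edges(g, as.vector(edges), weight = rf[nz])
  g
}

#' Project a bipartite network to one mode
#'
#' Nodes of the chosen side are linked when they share at least one
#' neighbor on the other side. `weightMode = "count"` weights an edge by
#' the number of shared neighbors; `"min_sum"` by the sum over shared
#' neighbors k of min(w_uk, w_vk).
#'
#' @param b bipartite igraph from [buildBipartite()].
#' @param side "feature" or "article".
#' @param weightMode "count" or "min_sum".
#' @return an undirected weighted igraph with per-vertex `strength`
#'   attribute (sum of incident edge weights); article-side projections
#'   keep the `group` vertex attribute.
#' @export
projectGraph <- function(b, side = c("feature", "article"),
                         weightMode = c("count", "min_sum")) {
  side <- match.arg(side)
  weightMode <- match.arg(weightMode)
  inc <- bipartiteIncidence(b)                  # articles x features weights
  W <- if (side == "feature") t(inc) else inc
  n <- nrow(W)
  if (weightMode == "count") {
    adj <- tcrossprod((W > 0) * 1)
  } else {
    adj <- matrix(0, n, n, dimnames = list(rownames(W), rownames(W)))
    for (k in seq_len(ncol(W))) {
      wk <- W[, k]
      on <- which(wk > 0)
      if (length(on) >= 2L)
        adj[on, on] <- adj[on, on] + outer(wk[on], wk[on], pmin)
    }
  }
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  if (side == "article") {
    grp <- igraph::V(b)$group[match(igraph::V(g)$name, igraph::V(b)$name)]
    g <- igraph::set_vertex_attr(g, "group", value = grp)
  }
  igraph::set_vertex_attr(g, "strength",
                          value = igraph::strength(g, weights = igraph::E(g)$weight))
}

# articles x features weight matrix of a bipartite graph
bipartiteIncidence <- function(b) {
  stopifnot(igraph::is_bipartite(b))
  arts <- igraph::V(b)$name[!igraph::V(b)$type]
  feats <- igraph::V(b)$name[igraph::V(b)$type]
  inc <- matrix(0, length(arts), length(feats),
                dimnames = list(arts, feats))
  el <- igraph::as_edgelist(b)
  w <- igraph::E(b)$weight
  # orient edges article -> feature
  swap <- el[, 1L] %in% feats
  el[swap, ] <- el[swap, 2:1]
  inc[cbind(match(el[, 1L], arts), match(el[, 2L], feats))] <- w
  inc
}

#' Summary statistics of a projected network
#'
#' Realized connectance RC = L / [S(S-1)/2], per-node strength, and the
#' degree distribution P(k) = N(k)/S.
#'
#' @param g undirected simple igraph.
#' @return list with `connectance`, `S`, `L`, `strength` (named vector) and
#'   `degreeDistribution` (data.frame k, pk).
#' @export
networkSummary <- function(g) {
  S <- igraph::vcount(g)
  if (S < 2L) stop("network must have >= 2 nodes")
  L <- igraph::ecount(g)
  deg <- igraph::degree(g)
  tab <- table(deg)
  list(connectance = L / (S * (S - 1) / 2), S = S, L = L,
       strength = igraph::strength(g, weights = igraph::E(g)$weight),
       degreeDistribution = data.frame(k = as.integer(names(tab)),
                                       pk = as.vector(tab) / S))
}

# dyad covariate table for the three-term model
dyadTable <- function(adj, groups, focalGroup) {
  n <- nrow(adj)
  ij <- which(upper.tri(adj), arr.ind = TRUE)
  data.frame(
    y = adj[ij],
    same = as.integer(groups[ij[, 1L]] == groups[ij[, 2L]]),
    nfocal = (groups[ij[, 1L]] == focalGroup) +
             (groups[ij[, 2L]] == focalGroup))
}

ergmLogLik <- function(theta, dt) {
  eta <- theta[1L] + theta[2L] * dt$same + theta[3L] * dt$nfocal
  sum(dt$y * eta - log1p(exp(eta)))
}

#' Fit the dyadic-independent ERGM
#'
#' Model: Pr(Y = y) proportional to exp(theta' g(y)) with statistics
#' g(y) = (edge count, same-group edge count, number of edge endpoints in
#' the focal group). All three terms are dyadic-independent, so the maximum
#' likelihood estimate coincides with Bernoulli logistic regression over
#' the n(n-1)/2 dyads with covariates (1, same-group indicator, focal
#' endpoint count), fitted by Fisher scoring with information-based
#' standard errors.
#'
#' @param g undirected igraph over article nodes, or a binary adjacency
#'   matrix. Use [binarizeProjection()] to derive it from a weighted
#'   article projection.
#' @param groups node group labels (taken from the `group` vertex attribute
#'   when missing).
#' @param focalGroup the non-reference level of the node-factor term
#'   (default "complexity").
#' @param termsKeep which terms to fit: any subset of
#'   c("edges", "nodematch", "nodefactor"); "edges" is always included.
#' @return list with `coefficients` (data.frame term, estimate, se, z, p),
#'   `stats` (observed g(y)), `logLik`, `converged`.
#' @export
ergmFit <- function(g, groups = NULL, focalGroup = "complexity",
                    termsKeep = c("edges", "nodematch", "nodefactor")) {
  if (inherits(g, "igraph")) {
    if (is.null(groups)) groups <- igraph::V(g)$group
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    adj <- (adj > 0) * 1
  } else {
    adj <- (as.matrix(g) > 0) * 1
  }
  n <- nrow(adj)
  if (n < 4L) stop("need >= 4 nodes")
  stopifnot(!is.null(groups), length(groups) == n)
  dt <- dyadTable(adj, as.character(groups), focalGroup)

  termsKeep <- union("edges", termsKeep)
  form <- stats::as.formula(paste(
    "y ~", paste(c("1", if ("nodematch" %in% termsKeep) "same",
                   if ("nodefactor" %in% termsKeep) "nfocal"),
                 collapse = " + ")))
  allTies <- length(unique(dt$y)) == 1L
  fit <- suppressWarnings(glm(form, family = binomial(), data = dt))
  sm <- summary(fit)$coefficients
  termNames <- c("(Intercept)" = "edges", same = "nodematch",
                 nfocal = "nodefactor")
  co <- data.frame(term = unname(termNames[rownames(sm)]),
                   estimate = sm[, 1L], se = sm[, 2L],
                   z = sm[, 3L], p = sm[, 4L], row.names = NULL)
  gy <- c(edges = sum(dt$y),
          nodematch = sum(dt$y * dt$same),
          nodefactor = sum(dt$y * dt$nfocal))
  converged <- fit$converged && !allTies &&
    all(abs(co$estimate) < 15) && all(is.finite(co$se))
  if (!converged)
    warning("ERGM fit did not converge cleanly ",
            "(complete/empty graph or separation); interpret with care")
  list(coefficients = co, stats = gy, logLik = as.numeric(stats::logLik(fit)),
       converged = converged)
}

#' Binarize a weighted article projection
#'
#' Articles are tied when they share at least `tau` features (count-mode
#' projection weight >= tau).
#'
#' @param g weighted article-side projection from [projectGraph()].
#' @param tau minimum shared-feature count for a tie (default 1).
#' @return an undirected unweighted igraph with the `group` attribute kept.
#' @export
binarizeProjection <- function(g, tau = 1) {
  keep <- igraph::E(g)$weight >= tau
  g2 <- igraph::subgraph_from_edges(g, igraph::E(g)[keep],
                                    delete.vertices = FALSE)
  igraph::delete_edge_attr(g2, "weight")
}
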