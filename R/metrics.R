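## A catalogue of reusable complexity metrics: information-theoretic
## summaries of distributions, sequences and matrices. Natural logarithms
## by default; pass base = 2 for bits.

checkProb <- function(p) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p
}

logB <- function(x, base) if (base == 2) log2(x) else log(x)

#' Shannon entropy of a probability vector
#'
#' -sum p_i log p_i with the 0 log 0 = 0 convention.
#'
#' @param p nonnegative probabilities summing to 1 (tolerance 1e-9).
#' @param base log base: exp(1) (default, nats) or 2 (bits).
#' @return entropy >= 0.
#' @examples shannonEntropy(c(0.5, 0.5))  # log(2)
#' @export
shannonEntropy <- function(p, base = exp(1)) {
  p <- checkProb(p)
  p <- p[p > 0]
  -sum(p * logB(p, base))
}

# entropy of overlapping length-L blocks of a symbol sequence
blockEntropy <- function(s, L, base) {
  n <- length(s)
  stopifnot(n >= L)
  idx <- seq_len(n - L + 1L)
  blocks <- s[idx]
  if (L > 1L) for (j in seq_len(L - 1L))
    blocks <- paste(blocks, s[idx + j], sep = "\r")
  shannonEntropy(as.vector(table(blocks)) / length(blocks), base)
}

#' Mean information gain of a symbol sequence
#'
#' H(L+1) - H(L), where H(L) is the Shannon entropy of the empirical
#' distribution of overlapping length-L blocks: the information gained by
#' knowing one additional step.
#'
#' @param s vector of categorical symbols, length >= L + 1.
#' @param L block length (>= 1).
#' @param base log base.
#' @return gain >= 0 (up to floating point).
#' @export
meanInformationGain <- function(s, L = 1L, base = exp(1)) {
  if (L < 1L) stop("L must be >= 1")
  if (length(s) < L + 1L) stop("sequence must have length >= L + 1")
  blockEntropy(s, L + 1L, base) - blockEntropy(s, L, base)
}

#' Fluctuation complexity of a symbol sequence
#'
#' sum_ij P_ij [log(P_i / P_j)]^2 over empirical successive-pair
#' probabilities P_ij and symbol probabilities P_i: the mean squared
#' log-probability fluctuation between consecutive symbols, a measure of
#' structure (0 for constant sequences and whenever all states are
#' equiprobable).
#'
#' @param s vector of categorical symbols with >= 2 transitions, or a
#'   two-way successive-pair count/probability table (then symbol
#'   probabilities are its margins).
#' @param base log base.
#' @return value >= 0.
#' @export
fluctuationComplexity <- function(s, base = exp(1)) {
  if (is.matrix(s) || is.table(s)) {
    pij <- as.matrix(s) / sum(s)
    if (is.null(rownames(pij)))
      dimnames(pij) <- list(seq_len(nrow(pij)), seq_len(ncol(pij)))
    li <- logB(rowSums(pij), base)
    lj <- logB(colSums(pij), base)
    M <- outer(li, lj, `-`)^2
    M[pij == 0] <- 0
    return(sum(pij * M))
  }
  if (length(unique(s)) < 2L) return(0)
  if (length(s) < 3L) stop("need >= 2 transitions")
  p <- as.vector(table(s)) / length(s)
  names(p) <- names(table(s))
  a <- as.character(s[-length(s)]); b <- as.character(s[-1L])
  pij <- table(a, b) / (length(s) - 1L)
  li <- logB(p[rownames(pij)], base)
  lj <- logB(p[colnames(pij)], base)
  sum(pij * outer(li, lj, `-`)^2)
}

#' Singular value decomposition entropy of a matrix
#'
#' With s_i = sigma_i / sum(sigma) over the k nonzero singular values,
#' J = -(1 / log k) sum s_i log s_i; J = 0 when k = 1 (rank one). Values
#' near 1 mean the matrix cannot be efficiently compressed.
#'
#' @param m numeric matrix with at least one nonzero entry.
#' @return value in [0, 1].
#' @examples svdEntropy(diag(4))  # 1
#' @export
svdEntropy <- function(m) {
  m <- as.matrix(m)
  if (all(m == 0)) stop("zero matrix")
  sv <- svd(m, nu = 0L, nv = 0L)$d
  sv <- sv[sv > max(sv) * max(dim(m)) * .Machine$double.eps]
  k <- length(sv)
  if (k == 1L) return(0)
  s <- sv / sum(sv)
  -sum(s * log(s)) / log(k)
}

#' Mutual information of a two-way count table
#'
#' Plug-in estimate I = H(X) + H(Y) - H(X, Y) from the empirical joint and
#' marginal distributions; zero exactly when the table is a product of its
#' margins.
#'
#' @param joint nonnegative two-way count (or probability) table with
#'   positive total.
#' @param base log base.
#' @return value >= 0 (up to floating point).
#' @export
mutualInformation <- function(joint, base = exp(1)) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("counts must be nonnegative")
  tot <- sum(joint)
  if (tot <= 0) stop("empty table")
  pxy <- joint / tot
  hx <- shannonEntropy(rowSums(pxy), base)
  hy <- shannonEntropy(colSums(pxy), base)
  hxy <- shannonEntropy(as.vector(pxy), base)
  hx + hy - hxy
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean of a series.
#'
#' @param x numeric vector of length >= 2 with nonzero mean.
#' @return value (>= 0 for positive-mean series).
#' @examples coefficientOfVariation(c(2, 4, 6))  # 0.5
#' @export
coefficientOfVariation <- function(x) {
  if (length(x) < 2L) stop("need >= 2 values")
  m <- mean(x)
  if (abs(m) < .Machine$double.eps) stop("zero mean")
  sd(x) / m
}
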