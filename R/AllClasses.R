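#' @import methods
#' @importFrom stats aov anova sd var quantile setNames rpois rlnorm runif
#'   glm binomial coef vcov pnorm p.adjust complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Feature lexicon
#'
#' An ordered collection of named features of complex systems, each carrying
#' one or more lowercase match stems. A stem is either a single word prefix
#' (matched against hyphen-stripped tokens) or a pair of word prefixes
#' (matched against adjacent token pairs). The built-in lexicon holds the 23
#' canonical complexity features with their published search strings.
#'
#' @slot name character vector of unique, nonempty feature labels.
#' @slot stems list (one element per feature) of lists of character vectors;
#'   each inner vector has length 1 (unigram prefix) or 2 (bigram prefix pair).
#' @slot related character vector of free-text concept tags.
#'
#' @seealso [defaultLexicon()], [loadLexicon()], [countFeatures()]
#' @export
setClass("FeatureLexicon",
  representation(name = "character", stems = "list", related = "character"))

setValidity("FeatureLexicon", function(object) {
  msg <- character()
  n <- length(object@name)
  if (any(!nzchar(object@name))) msg <- c(msg, "feature names must be nonempty")
  if (anyDuplicated(object@name))
    msg <- c(msg, sprintf("duplicate feature name: '%s'",
                          object@name[duplicated(object@name)][1L]))
  if (length(object@stems) != n || length(object@related) != n)
    msg <- c(msg, "name, stems and related must have equal length")
  for (i in seq_len(min(n, length(object@stems)))) {
    for (st in object@stems[[i]]) {
      if (!is.character(st) || length(st) < 1L || length(st) > 2L)
        msg <- c(msg, sprintf("feature '%s': each stem must have 1 or 2 parts",
                              object@name[i]))
      else if (any(!nzchar(st)))
        msg <- c(msg, sprintf("feature '%s': empty stem part", object@name[i]))
      else if (any(st != tolower(st)))
        msg <- c(msg, sprintf("feature '%s': stems must be lowercase",
                              object@name[i]))
    }
    if (length(object@stems[[i]]) == 0L)
      msg <- c(msg, sprintf("feature '%s': no stems", object@name[i]))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FeatureLexicon number of features.
#' @param x a FeatureLexicon.
#' @export
setMethod("length", "FeatureLexicon", function(x) length(x@name))

#' @describeIn FeatureLexicon feature labels, in lexicon order.
#' @export
setMethod("names", "FeatureLexicon", function(x) x@name)

setMethod("show", "FeatureLexicon", function(object) {
  cat(sprintf("FeatureLexicon with %d features\n", length(object)))
  cat("  ", paste(head(object@name, 8L), collapse = ", "),
      if (length(object) > 8L) ", ..." else "", "\n", sep = "")
})

#' Feature stems
#'
#' Accessor for the match stems of a [FeatureLexicon-class].
#' @param object a FeatureLexicon.
#' @return list of lists of character vectors (1 or 2 parts each).
#' @export
setGeneric("featureStems", function(object) standardGeneric("featureStems"))

#' @rdname featureStems
#' @export
setMethod("featureStems", "FeatureLexicon", function(object) {
  setNames(object@stems, object@name)
})

#' Article corpus
#'
#' Metadata for a set of articles split into two groups ("complexity" vs
#' "control"), with pointers to plain-text full texts and per-article
#' reference lists (citation keys).
#'
#' @slot meta data.frame with columns article_id, group, year, text_file and
#'   a list-column references.
#' @slot textDir directory holding the plain-text files.
#'
#' @seealso [readCorpus()], [simulateCorpus()]
#' @export
setClass("Corpus", representation(meta = "data.frame", textDir = "character"))

setValidity("Corpus", function(object) {
  msg <- character()
  need <- c("article_id", "group", "year", "text_file", "references")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste("meta must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@meta$article_id))
      msg <- c(msg, sprintf("duplicate article_id: '%s'",
                            object@meta$article_id[duplicated(object@meta$article_id)][1L]))
    bad <- setdiff(unique(object@meta$group), c("complexity", "control"))
    if (length(bad))
      msg <- c(msg, sprintf("unknown group label: '%s'", bad[1L]))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Corpus number of articles.
#' @param x a Corpus.
#' @export
setMethod("length", "Corpus", function(x) nrow(x@meta))

setMethod("show", "Corpus", function(object) {
  tab <- table(object@meta$group)
  cat(sprintf("Corpus of %d articles (%s)\n", length(object),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  cat("  texts in:", object@textDir, "\n")
})

#' @describeIn Corpus article identifiers.
#' @export
setGeneric("articleIds", function(x) standardGeneric("articleIds"))

#' @rdname Corpus-class
#' @export
setMethod("articleIds", "Corpus", function(x) x@meta$article_id)

#' @describeIn Corpus per-article group labels.
#' @export
setGeneric("articleGroups", function(x) standardGeneric("articleGroups"))

#' @rdname Corpus-class
#' @export
setMethod("articleGroups", "Corpus", function(x)
  setNames(x@meta$group, x@meta$article_id))

#' @describeIn Corpus per-article reference lists (citation keys).
#' @export
setGeneric("articleReferences", function(x) standardGeneric("articleReferences"))

#' @rdname Corpus-class
#' @export
setMethod("articleReferences", "Corpus", function(x)
  setNames(x@meta$references, x@meta$article_id))

#' Read one article's full text
#'
#' @param x a [Corpus-class].
#' @param id an article id present in the corpus.
#' @return single character string (the raw text).
#' @export
articleText <- function(x, id) {
  stopifnot(is(x, "Corpus"))
  i <- match(id, x@meta$article_id)
  if (is.na(i)) stop("unknown article id: ", id)
  path <- file.path(x@textDir, x@meta$text_file[i])
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Article-by-feature count matrix
#'
#' A \linkS4class{SummarizedExperiment} with features as rows and articles as
#' columns. The "counts" assay holds nonnegative integer mention counts; an
#' optional "relfreq" assay holds per-article relative frequencies
#' (count / total words in the article). Column metadata carries the article
#' group, year and total word count.
#'
#' @seealso [buildFeatureMatrix()], [relativeFrequency()], [dropFeatureless()]
#' @export
#' @import SummarizedExperiment
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("FeatureMatrix requires a 'counts' assay")
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "counts must be nonnegative")
  if (!all(c("group", "total_words") %in% colnames(colData(object))))
    msg <- c(msg, "colData must have 'group' and 'total_words'")
  else {
    tot <- object$total_words
    if (any(sweep(cnt, 2L, tot, `>`)))
      msg <- c(msg, "a feature count exceeds the article's total word count")
  }
  if (length(msg)) msg else TRUE
})

#' Feature counts assay
#' @param object a [FeatureMatrix-class].
#' @return integer matrix, features x articles.
#' @export
setGeneric("featureCounts", function(object) standardGeneric("featureCounts"))

#' @rdname featureCounts
#' @export
setMethod("featureCounts", "FeatureMatrix", function(object)
  assay(object, "counts"))

#' Relative-frequency assay
#'
#' Per-article relative feature frequencies (count over total words). Compute
#' it with [relativeFrequency()] first.
#' @param object a [FeatureMatrix-class].
#' @return numeric matrix in [0, 1], features x articles.
#' @export
setGeneric("relFreq", function(object) standardGeneric("relFreq"))

#' @rdname relFreq
#' @export
setMethod("relFreq", "FeatureMatrix", function(object) {
  if (!"relfreq" %in% assayNames(object))
    stop("no 'relfreq' assay; run relativeFrequency() first")
  assay(object, "relfreq")
})

#' @rdname Corpus-class
#' @export
setMethod("articleGroups", "FeatureMatrix", function(x)
  setNames(as.character(x$group), colnames(x)))

#' Fitted topic model
#'
#' Latent Dirichlet allocation fit: per-topic word distributions (beta) and
#' per-document topic proportions (gamma).
#'
#' @slot K topic count.
#' @slot beta K x V matrix; rows sum to 1.
#' @slot gamma D x K matrix; rows sum to 1.
#' @slot vocabulary character vector of length V.
#' @slot seed integer seed the fit was run with.
#' @seealso [fitTopics()], [selectTopWords()]
#' @export
setClass("TopicModel",
  representation(K = "integer", beta = "matrix", gamma = "matrix",
                 vocabulary = "character", seed = "integer"))

setValidity("TopicModel", function(object) {
  msg <- character()
  if (nrow(object@beta) != object@K) msg <- c(msg, "beta must have K rows")
  if (ncol(object@beta) != length(object@vocabulary))
    msg <- c(msg, "beta columns must match vocabulary")
  if (ncol(object@gamma) != object@K) msg <- c(msg, "gamma must have K columns")
  if (any(abs(rowSums(object@beta) - 1) > 1e-8))
    msg <- c(msg, "beta rows must sum to 1")
  if (nrow(object@gamma) && any(abs(rowSums(object@gamma) - 1) > 1e-8))
    msg <- c(msg, "gamma rows must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TopicModel", function(object) {
  cat(sprintf("TopicModel: K = %d topics, %d documents, %d-word vocabulary\n",
              object@K, nrow(object@gamma), length(object@vocabulary)))
})
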