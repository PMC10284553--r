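## Article x feature count matrix construction and the exclusion rule for
## articles that mention no feature at all.

#' Build the feature count matrix
#'
#' Tokenizes every article in the corpus and counts lexicon feature mentions,
#' producing a [FeatureMatrix-class] (features as rows, articles as columns)
#' with the article group, year and total word count in `colData`.
#'
#' @param corpus a [Corpus-class].
#' @param lexicon a [FeatureLexicon-class]; defaults to the built-in set.
#' @return a [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(corpus, lexicon = defaultLexicon()) {
  stopifnot(is(corpus, "Corpus"), length(corpus) > 0L)
  ids <- articleIds(corpus)
  toks <- corpusTokens(corpus)
  counts <- matrix(0L, nrow = length(lexicon), ncol = length(ids),
                   dimnames = list(names(lexicon), ids))
  totals <- integer(length(ids))
  for (j in seq_along(ids)) {
    cv <- countFeatures(toks[[j]], lexicon)
    counts[, j] <- cv
    totals[j] <- attr(cv, "total_words")
  }
  cd <- S4Vectors::DataFrame(group = corpus@meta$group,
                             year = corpus@meta$year,
                             total_words = totals,
                             row.names = ids)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  new("FeatureMatrix", se)
}

#' Per-article relative feature frequencies
#'
#' Divides each article's feature counts by its total word count and stores
#' the result as a `relfreq` assay.
#'
#' @param fm a [FeatureMatrix-class]; all articles must have total_words > 0.
#' @return the [FeatureMatrix-class] with a `relfreq` assay added.
#' @export
relativeFrequency <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  tot <- fm$total_words
  if (any(tot == 0L))
    stop("article(s) with zero total words: ",
         paste(colnames(fm)[tot == 0L], collapse = ", "),
         "; drop them with dropFeatureless()")
  assay(fm, "relfreq") <- sweep(featureCounts(fm), 2L, tot, `/`)
  fm
}

#' Drop articles mentioning no feature
#'
#' Removes articles whose feature counts are all zero (including empty
#' texts), reporting how many were removed from each group.
#'
#' @param fm a [FeatureMatrix-class].
#' @return the filtered [FeatureMatrix-class].
#' @export
dropFeatureless <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  zero <- colSums(featureCounts(fm)) == 0L
  if (all(zero)) stop("all articles are featureless")
  if (any(zero)) {
    grp <- as.character(fm$group)[zero]
    message(sprintf(
      "excluded %d featureless article(s) (control = %d, complexity = %d): %s",
      sum(zero), sum(grp == "control"), sum(grp == "complexity"),
      paste(colnames(fm)[zero], collapse = ", ")))
    fm <- fm[, !zero]
  }
  fm
}

#' Write feature count and relative-frequency tables
#'
#' Writes `feature_counts.tsv` and (when present) `feature_relfreq.tsv` in
#' articles x features orientation with a header row of feature names.
#'
#' @param fm a [FeatureMatrix-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFeatureTables <- function(fm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  writeOne <- function(mat, file) {
    df <- data.frame(article_id = colnames(mat), t(mat),
                     check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    file
  }
  paths <- c(paths, writeOne(featureCounts(fm),
                             file.path(dir, "feature_counts.tsv")))
  if ("relfreq" %in% assayNames(fm))
    paths <- c(paths, writeOne(relFreq(fm),
                               file.path(dir, "feature_relfreq.tsv")))
  invisible(paths)
}
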