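## Lexicon loading and token-stream feature counting.
##
## Stems are word prefixes ("adapt" matches "adaptation", "adaptive", ...),
## which is how the published search strings capture plurals and spelling
## variants. A stem with two parts matches a pair of adjacent tokens; internal
## hyphens are deleted before matching, so the three dialect variants of a
## term ("non-linear", "non linear", "nonlinear") collapse into two matchers:
## a joined unigram and a spaced bigram.

# Parse one plus-separated search string into a list of stems:
#  "self-orga + self orga + selforga" -> list("selforga", c("self","orga"))
# (the hyphenated variant joins to the same unigram as the joined variant).
parseStems <- function(spec) {
  alts <- trimws(strsplit(spec, "+", fixed = TRUE)[[1L]])
  if (any(!nzchar(alts))) stop("empty stem in search string: '", spec, "'")
  stems <- lapply(alts, function(a) {
    a <- tolower(a)
    if (grepl(" ", a, fixed = TRUE)) {
      parts <- strsplit(a, " +")[[1L]]
      if (length(parts) != 2L)
        stop("stems may have at most 2 parts: '", a, "'")
      parts
    } else {
      gsub("-", "", a, fixed = TRUE)
    }
  })
  unique(stems)
}

#' Load a feature lexicon
#'
#' Reads a tab-separated lexicon file with columns `name`, `stems`
#' (plus-separated search strings as printed, e.g. `"chaos + chaotic"`) and
#' `related`, or returns the built-in 23-feature complexity lexicon when
#' called with `"default"`.
#'
#' @param path path to a lexicon TSV, or the sentinel `"default"`.
#' @return a [FeatureLexicon-class].
#' @examples
#' lex <- loadLexicon("default")
#' length(lex)  # 23
#' @export
loadLexicon <- function(path = "default") {
  if (identical(path, "default"))
    path <- system.file("extdata", "complexity_features.tsv",
                        package = "ecoweave", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("name", "stems")
  if (!all(need %in% colnames(tab)))
    stop("lexicon file must have columns 'name' and 'stems'")
  if (!"related" %in% colnames(tab)) tab$related <- ""
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(trimws(tab$name[i])))
      stop("lexicon row ", i, ": empty feature name")
    if (!nzchar(trimws(tab$stems[i])))
      stop("lexicon row ", i, " ('", tab$name[i], "'): empty search string")
  }
  if (anyDuplicated(tab$name))
    stop("duplicate feature name: '", tab$name[duplicated(tab$name)][1L], "'")
  stems <- lapply(tab$stems, parseStems)
  new("FeatureLexicon", name = tab$name, stems = stems, related = tab$related)
}

#' The built-in complexity-feature lexicon
#'
#' The 23 canonical features of complex ecological systems with their
#' published word-stem search strings.
#'
#' @return a [FeatureLexicon-class] of 23 features.
#' @export
defaultLexicon <- function() loadLexicon("default")

# Split a lexicon into flat unigram / bigram stem tables for fast matching.
compileLexicon <- function(lexicon) {
  uni <- list(); bi1 <- list(); bi2 <- list()
  for (i in seq_along(lexicon@stems)) {
    for (st in lexicon@stems[[i]]) {
      if (length(st) == 1L) {
        uni[[length(uni) + 1L]] <- c(feature = i, stem = st)
      } else {
        bi1[[length(bi1) + 1L]] <- i
        bi2[[length(bi2) + 1L]] <- st
      }
    }
  }
  list(
    uniFeature = vapply(uni, function(x) as.integer(x[["feature"]]), 1L),
    uniStem    = vapply(uni, function(x) x[["stem"]], ""),
    biFeature  = as.integer(unlist(bi1)),
    biStems    = bi2
  )
}

#' Count feature mentions in a token stream
#'
#' Matches lexicon stems against lowercase tokens. Unigram stems are matched
#' as prefixes of hyphen-stripped tokens; two-part stems as prefixes of
#' adjacent token pairs. Within one feature a token position is counted at
#' most once: scanning left to right, a bigram match consumes both its
#' positions and takes precedence over a unigram match at the same position.
#'
#' @param tokens character vector of lowercase tokens (from [tokenize()]).
#' @param lexicon a [FeatureLexicon-class].
#' @return named integer vector of per-feature counts with attribute
#'   `total_words` (the token count).
#' @examples
#' lex <- defaultLexicon()
#' countFeatures(tokenize("Chaotic attractors and emergent feedbacks"), lex)
#' @export
countFeatures <- function(tokens, lexicon) {
  stopifnot(is(lexicon, "FeatureLexicon"))
  p <- length(lexicon)
  counts <- integer(p)
  names(counts) <- lexicon@name
  n <- length(tokens)
  if (n == 0L) {
    attr(counts, "total_words") <- 0L
    return(counts)
  }
  comp <- compileLexicon(lexicon)
  stripped <- gsub("-", "", tokens, fixed = TRUE)

  # per-feature logical match vectors
  uniHits <- vector("list", p)
  biHits <- vector("list", p)
  for (k in seq_along(comp$uniStem)) {
    f <- comp$uniFeature[k]
    h <- startsWith(stripped, comp$uniStem[k])
    uniHits[[f]] <- if (is.null(uniHits[[f]])) h else uniHits[[f]] | h
  }
  if (n >= 2L) {
    first <- stripped[-n]; second <- stripped[-1L]
    for (k in seq_along(comp$biFeature)) {
      f <- comp$biFeature[k]
      st <- comp$biStems[[k]]
      h <- startsWith(first, st[1L]) & startsWith(second, st[2L])
      biHits[[f]] <- if (is.null(biHits[[f]])) h else biHits[[f]] | h
    }
  }

  for (f in seq_len(p)) {
    U <- uniHits[[f]]; B <- biHits[[f]]
    if (is.null(B) || !any(B)) {
      counts[f] <- if (is.null(U)) 0L else sum(U)
      next
    }
    # left-to-right scan over matched positions; bigram consumes two slots
    pos <- sort(unique(c(which(U), which(B))))
    lastConsumed <- 0L
    cnt <- 0L
    for (i in pos) {
      if (i <= lastConsumed) next
      if (i <= length(B) && B[i]) {
        cnt <- cnt + 1L
        lastConsumed <- i + 1L
      } else if (!is.null(U) && U[i]) {
        cnt <- cnt + 1L
        lastConsumed <- i
      }
    }
    counts[f] <- cnt
  }
  attr(counts, "total_words") <- n
  counts
}
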