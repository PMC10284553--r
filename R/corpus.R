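## Corpus reading, tokenisation and topic-model preprocessing.

#' Tokenize raw text for feature counting
#'
#' Lowercases and extracts word tokens, stripping punctuation but keeping
#' internal hyphens ("non-linear" stays one token) and numerals.
#'
#' @param text character string (may contain newlines).
#' @return character vector of tokens; empty vector for empty text.
#' @examples
#' tokenize("Non-linear dynamics; non linear!")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character())
  text <- tolower(paste(text, collapse = "\n"))
  m <- gregexpr("[[:alnum:]]+(-[[:alnum:]]+)*", text)
  toks <- regmatches(text, m)[[1L]]
  if (length(toks) == 0L) character() else toks
}

# A fixed English stopword list (a standard minimal set, versioned with the
# package so topic-stage results are reproducible).
#' Built-in English stopword list
#' @return character vector of lowercase stopwords.
#' @export
defaultStopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "et",
    "al", "few", "for", "from", "further", "had", "has", "have", "having",
    "he", "her", "here", "hers", "herself", "him", "himself", "his", "how",
    "i", "if", "in", "into", "is", "it", "its", "itself", "may", "me",
    "might", "more", "most", "must", "my", "myself", "no", "nor", "not",
    "of", "off", "on", "once", "only", "or", "other", "our", "ours",
    "ourselves", "out", "over", "own", "same", "she", "should", "so",
    "some", "such", "than", "that", "the", "their", "theirs", "them",
    "themselves", "then", "there", "these", "they", "this", "those",
    "through", "to", "too", "under", "until", "up", "very", "was", "we",
    "were", "what", "when", "where", "which", "while", "who", "whom",
    "why", "will", "with", "would", "you", "your", "yours", "yourself",
    "yourselves")
}

# Invariant plurals and other words the rule-based singularizer must not touch.
singularExceptions <- function() {
  c("species", "series", "analyses", "hypotheses", "data", "taxa", "genera",
    "this", "thus", "less", "process", "always", "perhaps", "across", "is",
    "was", "its", "whereas")
}

#' Preprocess tokens for topic modelling
#'
#' Removes stopwords, joins hyphenated tokens ("non-linear" to "nonlinear")
#' and singularizes plurals by rule (-ies to -y; -xes/-ses/-zes/-ches/-shes
#' drop -es; trailing -s dropped otherwise), with a small exception list of
#' invariant forms.
#'
#' @param tokens character vector from [tokenize()].
#' @param stopwords character vector; defaults to [defaultStopwords()].
#' @return character vector of processed tokens (possibly empty).
#' @examples
#' preprocessForTopics(tokenize("The self-organizing networks"))
#' @export
preprocessForTopics <- function(tokens, stopwords = defaultStopwords()) {
  if (length(tokens) == 0L) return(character())
  tokens <- tokens[!(tokens %in% stopwords)]
  tokens <- gsub("-", "", tokens, fixed = TRUE)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(character())
  exc <- tokens %in% singularExceptions()
  out <- tokens
  w <- !exc
  ies <- w & grepl("ies$", out) & nchar(out) > 4L
  out[ies] <- sub("ies$", "y", out[ies])
  w <- w & !ies
  es <- w & grepl("(x|s|z|ch|sh)es$", out)
  out[es] <- sub("es$", "", out[es])
  w <- w & !es
  s <- w & grepl("[^su]s$", out) & nchar(out) > 3L
  out[s] <- sub("s$", "", out[s])
  out
}

#' Read an article corpus
#'
#' Reads a metadata table (TSV with columns `article_id`, `group`, `year`,
#' `text_file`, `references`; references pipe-separated citation keys) and
#' validates that every referenced text file exists under `textDir`. Group
#' labels are case-folded to lowercase with a warning when that changes them.
#'
#' @param metadataPath path to the metadata TSV.
#' @param textDir directory containing the plain-text full texts.
#' @return a [Corpus-class].
#' @export
readCorpus <- function(metadataPath, textDir) {
  meta <- read.delim(metadataPath, stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("article_id", "group", "year", "text_file", "references")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$article_id))
    stop("duplicate article_id: '",
         meta$article_id[duplicated(meta$article_id)][1L], "'")
  folded <- tolower(meta$group)
  if (any(folded != meta$group)) {
    warning("group labels case-folded to lowercase for ",
            sum(folded != meta$group), " article(s)")
    meta$group <- folded
  }
  bad <- setdiff(unique(meta$group), c("complexity", "control"))
  if (length(bad))
    stop("unknown group label '", bad[1L], "' (article '",
         meta$article_id[match(bad[1L], meta$group)], "')")
  meta$year <- as.integer(meta$year)
  missing <- !file.exists(file.path(textDir, meta$text_file))
  if (any(missing))
    stop("missing text file for article '",
         meta$article_id[which(missing)[1L]], "'")
  refs <- strsplit(meta$references, "|", fixed = TRUE)
  refs <- lapply(refs, function(r) r[nzchar(r)])
  meta$references <- refs
  corp <- new("Corpus", meta = meta, textDir = textDir)
  message(sprintf("read %d articles (complexity = %d, control = %d)",
                  nrow(meta), sum(meta$group == "complexity"),
                  sum(meta$group == "control")))
  corp
}

#' Tokenized full texts of a corpus
#'
#' @param corpus a [Corpus-class].
#' @return named list of token vectors, one per article.
#' @export
corpusTokens <- function(corpus) {
  stopifnot(is(corpus, "Corpus"))
  ids <- articleIds(corpus)
  setNames(lapply(ids, function(id) tokenize(articleText(corpus, id))), ids)
}
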