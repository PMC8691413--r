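# Normalization constant for the compound score: s / sqrt(s^2 + alpha),
# the standard valence-sum squashing used by VADER-style scorers.
.COMPOUND_ALPHA <- 15

#' Construct a sentiment lexicon
#'
#' A lexicon maps case-folded tokens to finite real valences. Any backend
#' satisfying this contract can drive the pipeline; the packaged toy
#' lexicon ([toy_lexicon()]) keeps tests hermetic and deterministic.
#'
#' @param entries Named numeric vector, names are tokens.
#' @param name Label for the lexicon.
#' @return A `pleb_lexicon`.
#' @export
lexicon <- function(entries, name = "custom") {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (any(!is.finite(entries))) stop("valences must be finite")
  names(entries) <- tolower(names(entries))
  structure(list(entries = entries, name = as.character(name)),
            class = "pleb_lexicon")
}

#' Read a lexicon from a TSV file (token<TAB>valence per line)
#' @param path Path to the lexicon file.
#' @param name Label; defaults to the file name.
#' @return A `pleb_lexicon`.
#' @export
read_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("token", "valence"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lexicon(stats::setNames(as.numeric(df$valence), df$token), name = name)
}

.toy_cache <- new.env(parent = emptyenv())

#' The built-in toy lexicon
#'
#' Thirty-eight everyday English tokens with valences in \[-3, 3\] on a
#' 0.25 grid, dense enough that the synthetic text renderer can hit any
#' target compound score. Shipped so the whole pipeline runs with no
#' external sentiment backend.
#'
#' @return A `pleb_lexicon`.
#' @export
toy_lexicon <- function() {
  if (is.null(.toy_cache$lex)) {
    path <- system.file("extdata", "toy-lexicon.tsv", package = "plebeian")
    .toy_cache$lex <- read_lexicon(path, name = "toy")
  }
  .toy_cache$lex
}

.tokenize <- function(text) {
  toks <- strsplit(trimws(tolower(text)), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Score one cleaned text against a lexicon
#'
#' The compound score is the normalized sum of matched token valences,
#' `s / sqrt(s^2 + 15)`, so it lies on \[-1, 1\] and its sign equals the
#' sign of the raw valence sum. `pos`, `neu`, `neg` are the fractions of
#' tokens with positive, zero-or-unmatched, and negative valence. A text
#' with zero lexicon hits is inconclusive: the scorer has no evidence, so
#' `compound = 0` and `inconclusive = TRUE`.
#'
#' @param text A cleaned text (output of [clean_text()]).
#' @param lex A `pleb_lexicon`; defaults to the toy lexicon.
#' @return A `pleb_polarity` list: `compound`, `pos`, `neu`, `neg`,
#'   `inconclusive`.
#' @export
score_text <- function(text, lex = toy_lexicon()) {
  stopifnot(inherits(lex, "pleb_lexicon"))
  toks <- .tokenize(text)
  val <- lex$entries[toks]
  hit <- !is.na(val)
  n <- length(toks)
  if (!any(hit)) {
    return(structure(list(compound = 0, pos = 0, neu = 1, neg = 0,
                          inconclusive = TRUE), class = "pleb_polarity"))
  }
  s <- sum(val[hit])
  structure(list(
    compound = s / sqrt(s^2 + .COMPOUND_ALPHA),
    pos = sum(hit & val > 0) / n,
    neu = (sum(!hit) + sum(hit & val == 0)) / n,
    neg = sum(hit & val < 0) / n,
    inconclusive = FALSE
  ), class = "pleb_polarity")
}

#' Clean and score every post of a corpus
#'
#' Runs [clean_text()] then [score_text()] on every post (roots and
#' comments alike). Posts that fail the English check or score
#' inconclusive are excluded from the result; exclusion counts are
#' reported via `message()` and attached as attributes `n_non_english`
#' and `n_inconclusive`.
#'
#' @param x A `pleb_corpus`.
#' @param lex A `pleb_lexicon`.
#' @param wordlist Optional word-list override for the English check.
#' @return A data.frame with columns `post_id`, `thread_id`, `is_root`,
#'   `compound`, `pos`, `neu`, `neg` -- one row per retained post.
#' @export
score_corpus <- function(x, lex = toy_lexicon(), wordlist = NULL) {
  stopifnot(inherits(x, "pleb_corpus"))
  df <- corpus_posts(x)
  cleaned <- clean_text(df$text, wordlist = wordlist)
  if (nrow(df) == 1L) {  # single-post corpus returns a pleb_clean list
    cleaned <- data.frame(text = cleaned$text, english_ok = cleaned$english_ok,
                          stringsAsFactors = FALSE)
  }
  keep_en <- cleaned$english_ok
  scores <- lapply(cleaned$text[keep_en], score_text, lex = lex)
  conclusive <- !vapply(scores, `[[`, NA, "inconclusive")
  out <- data.frame(
    post_id = df$post_id[keep_en][conclusive],
    thread_id = df$thread_id[keep_en][conclusive],
    is_root = df$is_root[keep_en][conclusive],
    compound = vapply(scores[conclusive], `[[`, 0, "compound"),
    pos = vapply(scores[conclusive], `[[`, 0, "pos"),
    neu = vapply(scores[conclusive], `[[`, 0, "neu"),
    neg = vapply(scores[conclusive], `[[`, 0, "neg"),
    stringsAsFactors = FALSE)
  n_non_english <- sum(!keep_en)
  n_inconclusive <- sum(!conclusive)
  if (n_non_english) message(n_non_english, " post(s) excluded: non-English")
  if (n_inconclusive) message(n_inconclusive, " post(s) excluded: inconclusive")
  attr(out, "n_non_english") <- n_non_english
  attr(out, "n_inconclusive") <- n_inconclusive
  out
}
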