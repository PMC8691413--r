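# Compact emoji -> short-name table (demoji-style names, lowercased, no
# colons). Covers the emoji that show up in social-media sentiment work;
# unknown emoji are dropped by the final non-ASCII sweep rather than kept.
.EMOJI_NAMES <- c(
  "\U0001F600" = "grinning face",
  "\U0001F601" = "beaming face with smiling eyes",
  "\U0001F602" = "face with tears of joy",
  "\U0001F603" = "grinning face with big eyes",
  "\U0001F604" = "grinning face with smiling eyes",
  "\U0001F605" = "grinning face with sweat",
  "\U0001F606" = "grinning squinting face",
  "\U0001F609" = "winking face",
  "\U0001F60A" = "smiling face with smiling eyes",
  "\U0001F60D" = "smiling face with heart eyes",
  "\U0001F60E" = "smiling face with sunglasses",
  "\U0001F610" = "neutral face",
  "\U0001F612" = "unamused face",
  "\U0001F614" = "pensive face",
  "\U0001F618" = "face blowing a kiss",
  "\U0001F61E" = "disappointed face",
  "\U0001F620" = "angry face",
  "\U0001F621" = "enraged face",
  "\U0001F622" = "crying face",
  "\U0001F62D" = "loudly crying face",
  "\U0001F62E" = "face with open mouth",
  "\U0001F631" = "face screaming in fear",
  "\U0001F634" = "sleeping face",
  "\U0001F637" = "face with medical mask",
  "\U0001F642" = "slightly smiling face",
  "\U0001F644" = "face with rolling eyes",
  "\U0001F912" = "face with thermometer",
  "\U0001F914" = "thinking face",
  "\U0001F921" = "clown face",
  "\U0001F922" = "nauseated face",
  "\U0001F926" = "person facepalming",
  "\U0001F937" = "person shrugging",
  "\U0001F44D" = "thumbs up",
  "\U0001F44E" = "thumbs down",
  "\U0001F44F" = "clapping hands",
  "\U0001F4AA" = "flexed biceps",
  "\U0001F525" = "fire",
  "\U0001F489" = "syringe",
  "\U0001F9A0" = "microbe",
  "\U0001F499" = "blue heart",
  "\U00002764" = "red heart",
  "\U0001F494" = "broken heart",
  "\U0001F64F" = "folded hands",
  "\U0001F680" = "rocket",
  "\U000026A0" = "warning"
)

.URL_RE <- "(https?://[^[:space:]]+|\\bwww\\.[^[:space:]]+)"
.HANDLE_RE <- "@\\w+"

#' Clean raw social-media text for sentiment scoring
#'
#' Applies, in this fixed order: HTML-tag stripping; URL removal
#' (scheme-prefixed and bare `www.` tokens); `@username` removal; emoji
#' replacement by their space-separated lowercase short names; removal of
#' any remaining non-ASCII symbols; whitespace collapse. An English check
#' (see [is_english()]) is run on the result and recorded, not enforced --
#' callers decide whether to drop non-English posts.
#'
#' The pipeline is a total function (empty input is fine) and idempotent:
#' cleaning already-cleaned text changes nothing.
#'
#' @param raw Character vector of raw texts.
#' @param wordlist Optional character vector overriding the built-in
#'   English word list used for the language check.
#' @param english_threshold Minimum fraction of tokens that must be
#'   dictionary words for `english_ok` (default 0.5).
#' @return For a single input, a `pleb_clean` list with fields `text`,
#'   `removed_url_count`, `removed_username_count`, `emoji_replacements`,
#'   `english_ok`; for a vector, a data.frame with those columns.
#' @export
clean_text <- function(raw, wordlist = NULL, english_threshold = 0.5) {
  if (length(raw) != 1L) {
    rows <- lapply(raw, clean_text, wordlist = wordlist,
                   english_threshold = english_threshold)
    return(data.frame(
      text = vapply(rows, `[[`, "", "text"),
      removed_url_count = vapply(rows, `[[`, 0L, "removed_url_count"),
      removed_username_count = vapply(rows, `[[`, 0L, "removed_username_count"),
      emoji_replacements = vapply(rows, `[[`, 0L, "emoji_replacements"),
      english_ok = vapply(rows, `[[`, NA, "english_ok"),
      stringsAsFactors = FALSE))
  }
  x <- enc2utf8(as.character(raw))
  if (is.na(x)) x <- ""
  # 1. HTML tags (and entities commonly left by scrapes)
  x <- gsub("<[^>]+>", " ", x)
  x <- gsub("&(amp|lt|gt|quot|nbsp|#\\d+);", " ", x)
  # 2. URLs
  n_url <- .count_matches(x, .URL_RE)
  x <- gsub(.URL_RE, " ", x, perl = TRUE)
  # 3. @handles
  n_user <- .count_matches(x, .HANDLE_RE)
  x <- gsub(.HANDLE_RE, " ", x, perl = TRUE)
  # 4. emoji -> short names (skipped entirely for pure-ASCII text)
  n_emoji <- 0L
  if (grepl("[^\\x01-\\x7f]", x, perl = TRUE, useBytes = TRUE)) {
    for (em in names(.EMOJI_NAMES)) {
      if (grepl(em, x, fixed = TRUE)) {
        k <- .count_matches(x, em, fixed = TRUE)
        n_emoji <- n_emoji + k
        x <- gsub(em, paste0(" ", .EMOJI_NAMES[[em]], " "), x, fixed = TRUE)
      }
    }
    # 5. drop whatever non-ASCII symbols remain (unknown emoji, dingbats)
    x <- iconv(x, "UTF-8", "ASCII", sub = " ")
  }
  # 6. collapse whitespace
  x <- trimws(gsub("[[:space:]]+", " ", x))
  structure(list(
    text = x,
    removed_url_count = n_url,
    removed_username_count = n_user,
    emoji_replacements = n_emoji,
    english_ok = is_english(x, wordlist = wordlist,
                            threshold = english_threshold)
  ), class = "pleb_clean")
}

.count_matches <- function(x, pattern, fixed = FALSE) {
  m <- gregexpr(pattern, x, perl = !fixed, fixed = fixed)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

.wordlist_cache <- new.env(parent = emptyenv())

.default_wordlist <- function() {
  if (is.null(.wordlist_cache$words)) {
    path <- system.file("extdata", "english-words.txt", package = "plebeian")
    words <- readLines(path, encoding = "UTF-8", warn = FALSE)
    words <- trimws(sub("#.*$", "", words))
    .wordlist_cache$words <- tolower(words[nzchar(words)])
  }
  .wordlist_cache$words
}

#' Dictionary-ratio English check
#'
#' A text counts as English when at least `threshold` of its whitespace
#' tokens (lowercased, stripped of leading/trailing punctuation) appear in
#' an English word list. Empty text is not English. This is a deliberately
#' simple heuristic standing in for a full spell-checker backend; the word
#' list is overridable per call or via a file of one word per line.
#'
#' @param text Cleaned text (URL/HTML/emoji already handled).
#' @param wordlist Optional character vector of lowercase English words.
#' @param threshold Minimum dictionary-token fraction, default 0.5.
#' @return Logical scalar.
#' @export
is_english <- function(text, wordlist = NULL, threshold = 0.5) {
  if (is.na(text) || !nzchar(trimws(text))) return(FALSE)
  if (is.null(wordlist)) wordlist <- .default_wordlist()
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks))
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(FALSE)
  mean(toks %in% wordlist) >= threshold
}
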