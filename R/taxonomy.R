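# Keyword-category filtering: misinformation terms and the two viral
# naming conventions (locational vs biological nomenclature), with
# per-category sentiment comparison reports.

#' Packaged default term lists
#'
#' Three lists ship with the package: `"misinfo"` (keywords associated
#' with COVID-19 misinformation: "china virus", "bioweapon", "microchip"),
#' `"Locational Taxonomy"` (viral names referring to places) and
#' `"Biological Taxonomy"` (officially approved nomenclature such as
#' "SARS-CoV-2" or "B.1.617"). Only the printed example terms are
#' packaged; real deployments extend them by file.
#'
#' @param which One of `"misinfo"`, `"locational"`, `"biological"`.
#' @return A `pleb_termlist`.
#' @export
default_term_list <- function(which = c("misinfo", "locational", "biological")) {
  which <- match.arg(which)
  file <- switch(which,
    misinfo = "terms-misinfo.txt",
    locational = "terms-locational.txt",
    biological = "terms-biological.txt")
  name <- switch(which,
    misinfo = "Misinformation Keywords",
    locational = "Locational Taxonomy",
    biological = "Biological Taxonomy")
  read_term_list(system.file("extdata", file, package = "plebeian"), name = name)
}

# Word-boundary pattern for a phrase. Hyphen and period count as word
# characters inside a phrase, so "sars-cov-2" and "b.1.617" match as units
# and "chinavirus" does not match "china virus".
.phrase_pattern <- function(phrase) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrase)
  paste0("(?<![A-Za-z0-9_.-])", esc, "(?![A-Za-z0-9_.-])")
}

#' Does a text contain any phrase of a term list?
#'
#' Matching is phrase-level, case-insensitive, and word-boundary
#' delimited; hyphens and periods are treated as word characters inside a
#' phrase so dotted and hyphenated nomenclature matches as a unit.
#'
#' @param text A (cleaned) text.
#' @param termlist A `pleb_termlist`.
#' @return Logical scalar.
#' @export
match_terms <- function(text, termlist) {
  stopifnot(inherits(termlist, "pleb_termlist"))
  text <- tolower(text)
  for (term in termlist$terms) {
    if (grepl(.phrase_pattern(term), text, perl = TRUE)) return(TRUE)
  }
  FALSE
}

#' Partition a corpus into keyword categories
#'
#' Returns the unfiltered corpus under the label `"None"` plus one
#' sub-corpus per term list containing every thread whose root or any
#' comment matches the list. Categories are not exclusive: a thread
#' matching several lists appears in each.
#'
#' @param x A `pleb_corpus`.
#' @param categories List of `pleb_termlist` objects.
#' @param by `"post"` (default) keeps only matching posts in the named
#'   categories (rebuilt as single-post threads); `"thread"` keeps whole
#'   threads any of whose posts match.
#' @return Named list of `pleb_corpus`, `"None"` first.
#' @export
partition_corpus <- function(x, categories, by = c("post", "thread")) {
  stopifnot(inherits(x, "pleb_corpus"), length(categories) >= 1L)
  by <- match.arg(by)
  out <- list("None" = x)
  for (tl in categories) {
    stopifnot(inherits(tl, "pleb_termlist"))
    if (by == "thread") {
      keep <- vapply(x$threads, function(th) {
        any(vapply(c(list(th$root), th$comments),
                   function(p) match_terms(p$text, tl), NA))
      }, NA)
      out[[tl$name]] <- corpus(x$threads[keep],
                               provenance = paste0(x$provenance, " | ", tl$name))
    } else {
      posts <- list()
      for (th in x$threads) {
        for (p in c(list(th$root), th$comments)) {
          if (match_terms(p$text, tl)) posts[[length(posts) + 1L]] <- p
        }
      }
      ths <- lapply(posts, function(p) {
        p$parent_id <- NA_character_  # detached from its thread context
        thread(p)
      })
      out[[tl$name]] <- corpus(ths,
                               provenance = paste0(x$provenance, " | ", tl$name))
    }
  }
  out
}

#' Compare sentiment across keyword categories
#'
#' For each category, reports the score count, mean, median and quartiles
#' (linear interpolation, the default quantile definition), and -- when
#' at least `min_bimodal` scores are available and the sample is actually
#' bimodal -- a full [summarize_distribution()] summary.
#'
#' @param partition Named list mapping category label to a numeric vector
#'   of compound scores; every category must have at least one score.
#' @param min_bimodal Minimum sample size before a bimodal summary is
#'   attempted (default 10, the KDE precondition).
#' @return A list of `pleb_category_report` records sorted by category
#'   name; also a data.frame view via `attr(, "table")`.
#' @export
compare_categories <- function(partition, min_bimodal = 10L) {
  if (!length(partition) || is.null(names(partition))) {
    stop("partition must be a non-empty named list of score vectors")
  }
  reports <- lapply(sort(names(partition)), function(nm) {
    s <- as.numeric(partition[[nm]])
    if (!length(s)) stop("category has no scores: ", nm)
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    summ <- NULL
    if (length(s) >= min_bimodal) {
      summ <- tryCatch(summarize_distribution(s), error = function(e) NULL)
    }
    structure(list(category = nm, n = length(s), mean = mean(s),
                   median = q[2], q1 = q[1], q3 = q[3], summary = summ),
              class = "pleb_category_report")
  })
  tab <- data.frame(
    category = vapply(reports, `[[`, "", "category"),
    n = vapply(reports, `[[`, 0L, "n"),
    mean = vapply(reports, `[[`, 0, "mean"),
    median = vapply(reports, `[[`, 0, "median"),
    q1 = vapply(reports, `[[`, 0, "q1"),
    q3 = vapply(reports, `[[`, 0, "q3"),
    stringsAsFactors = FALSE)
  attr(reports, "table") <- tab
  reports
}

#' Violin-style plot of category score distributions
#'
#' Draws one vertically-oriented KDE silhouette per category with markers
#' for mean, median and quartiles. Headless-safe (base graphics only).
#'
#' @param partition Named list of category score vectors.
#' @param main Title.
#' @return Invisibly, `NULL`.
#' @export
plot_categories <- function(partition, main = "Sentiment by category") {
  nms <- sort(names(partition))
  graphics::plot(NULL, xlim = c(0.5, length(nms) + 0.5), ylim = c(-1, 1),
                 xaxt = "n", xlab = "", ylab = "compound polarity",
                 main = main)
  graphics::axis(1, at = seq_along(nms), labels = nms, las = 2, cex.axis = 0.8)
  for (i in seq_along(nms)) {
    s <- as.numeric(partition[[nms[i]]])
    if (length(s) >= 10 && stats::sd(s) > 0) {
      d <- stats::density(s, from = -1, to = 1, n = 128)
      w <- 0.35 * d$y / max(d$y)
      graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                        col = "grey85", border = "grey40")
    }
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    graphics::segments(i - 0.1, q[c(1, 3)], i + 0.1, q[c(1, 3)], lwd = 1)
    graphics::segments(i - 0.15, q[2], i + 0.15, q[2], lwd = 2)
    graphics::points(i, mean(s), pch = 18, col = "steelblue")
  }
  invisible(NULL)
}
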