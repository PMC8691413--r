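#' @keywords internal
"_PACKAGE"

# Canonical record fields for corpus files (JSONL / CSV). The order is part of
# the on-disk contract; writers emit exactly these keys.
.POST_FIELDS <- c("post_id", "author_id", "timestamp", "text", "views",
                  "parent_id", "platform", "misinfo_label")

#' Construct a single social-media post
#'
#' A post is the atomic record of the corpus model: one message with an
#' opaque identifier, a UTC timestamp, raw text, and a non-negative view
#' count. A post with no `parent_id` is a thread root; any other post is a
#' comment attached (possibly transitively) to a root.
#'
#' @param post_id Opaque string identifier, unique within a corpus.
#' @param text Unicode message text.
#' @param timestamp ISO-8601 instant (assumed UTC when zone-free) or a
#'   `POSIXct`. Defaults to the Unix epoch for fixtures.
#' @param views Non-negative integer view count.
#' @param parent_id Optional `post_id` of the parent post; `NA` for roots.
#' @param author_id,platform Optional opaque labels.
#' @param misinfo_label Optional logical ground-truth label (synthetic
#'   corpora only); `NA` when unknown.
#' @return An object of class `pleb_post` (a named list).
#' @export
post <- function(post_id, text, timestamp = "1970-01-01T00:00:00Z",
                 views = 0L, parent_id = NA_character_,
                 author_id = NA_character_, platform = NA_character_,
                 misinfo_label = NA) {
  post_id <- as.character(post_id)
  stopifnot(length(post_id) == 1L, nzchar(post_id))
  views <- as.integer(views)
  if (is.na(views) || views < 0L) stop("views must be a non-negative integer")
  parent_id <- as.character(parent_id)
  if (!is.na(parent_id) && identical(parent_id, post_id)) {
    stop("parent_id must differ from post_id")
  }
  structure(list(
    post_id = post_id,
    author_id = as.character(author_id),
    timestamp = .parse_timestamp(timestamp),
    text = as.character(text),
    views = views,
    parent_id = parent_id,
    platform = as.character(platform),
    misinfo_label = as.logical(misinfo_label)
  ), class = "pleb_post")
}

.parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  if (is.na(x) || !nzchar(x)) return(as.POSIXct(NA, tz = "UTC"))
  # ISO-8601; zone-free strings are taken as UTC so thread ordering is
  # unambiguous for the interval sweep.
  fmt <- if (grepl("T", x, fixed = TRUE)) "%Y-%m-%dT%H:%M:%S" else "%Y-%m-%d %H:%M:%S"
  out <- as.POSIXct(sub("Z$", "", x), format = fmt, tz = "UTC")
  if (is.na(out)) out <- as.POSIXct(x, format = "%Y-%m-%d", tz = "UTC")
  if (is.na(out)) stop("unparseable timestamp: ", x)
  out
}

#' Construct a thread (root post plus comments)
#'
#' @param root A `pleb_post` with no parent.
#' @param comments List of `pleb_post` comments; every `parent_id` must
#'   resolve within the thread (to the root or another comment). Comment
#'   trees of any depth are flattened into this single list.
#' @param v_act Actual popularity in views; defaults to `root$views`.
#' @return An object of class `pleb_thread` with fields `root`, `comments`,
#'   `v_act`.
#' @export
thread <- function(root, comments = list(), v_act = NULL) {
  stopifnot(inherits(root, "pleb_post"))
  for (cm in comments) stopifnot(inherits(cm, "pleb_post"))
  ids <- c(root$post_id, vapply(comments, `[[`, "", "post_id"))
  parents <- vapply(comments, `[[`, "", "parent_id")
  bad <- !is.na(parents) & !(parents %in% ids)
  if (any(bad)) {
    stop("comment parent_id does not resolve within thread: ",
         paste(parents[bad], collapse = ", "))
  }
  if (is.null(v_act)) v_act <- root$views
  v_act <- as.integer(v_act)
  stopifnot(v_act >= 0L)
  structure(list(root = root, comments = comments, v_act = v_act),
            class = "pleb_thread")
}

#' Number of comments in a thread
#' @param x A `pleb_thread`.
#' @return Integer comment count (the thread's N; the root is excluded).
#' @export
n_comments <- function(x) {
  stopifnot(inherits(x, "pleb_thread"))
  length(x$comments)
}

#' Construct a corpus of threads
#'
#' @param threads List of `pleb_thread` objects. Post ids must be globally
#'   unique across the corpus.
#' @param provenance Free-text metadata describing where the corpus came
#'   from (platform, query, generator settings, ...).
#' @return An object of class `pleb_corpus`.
#' @export
corpus <- function(threads = list(), provenance = "") {
  for (th in threads) stopifnot(inherits(th, "pleb_thread"))
  ids <- unlist(lapply(threads, function(th) {
    c(th$root$post_id, vapply(th$comments, `[[`, "", "post_id"))
  }))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate post_id in corpus: ", paste(unique(dup), collapse = ", "))
  structure(list(threads = threads, provenance = as.character(provenance)),
            class = "pleb_corpus")
}

#' @export
print.pleb_corpus <- function(x, ...) {
  np <- nrow(corpus_posts(x))
  cat(sprintf("<pleb_corpus> %d thread(s), %d post(s)\n",
              length(x$threads), np))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Flatten a corpus into a data frame of posts
#'
#' @param x A `pleb_corpus` or `pleb_thread`.
#' @return A data.frame with one row per post (roots first within each
#'   thread) and columns `post_id`, `author_id`, `timestamp`, `text`,
#'   `views`, `parent_id`, `platform`, `misinfo_label`, `thread_id`,
#'   `is_root`.
#' @export
corpus_posts <- function(x) {
  if (inherits(x, "pleb_thread")) x <- corpus(list(x))
  stopifnot(inherits(x, "pleb_corpus"))
  per_thread <- lapply(x$threads, function(th) c(list(th$root), th$comments))
  posts <- unlist(per_thread, recursive = FALSE)
  if (is.null(posts)) posts <- list()
  tids <- rep(vapply(x$threads, function(th) th$root$post_id, ""),
              vapply(per_thread, length, 0L))
  n <- length(posts)
  chr <- function(field) vapply(posts, `[[`, "", field)
  ts <- as.POSIXct(vapply(posts, function(p) as.numeric(p$timestamp), 0),
                   origin = "1970-01-01", tz = "UTC")
  if (!n) ts <- as.POSIXct(character(), tz = "UTC")
  data.frame(
    post_id = chr("post_id"), author_id = chr("author_id"),
    timestamp = ts, text = chr("text"),
    views = vapply(posts, `[[`, 0L, "views"),
    parent_id = chr("parent_id"), platform = chr("platform"),
    misinfo_label = vapply(posts, `[[`, NA, "misinfo_label"),
    thread_id = tids,
    is_root = is.na(chr("parent_id")),
    stringsAsFactors = FALSE)
}

#' Read a corpus from JSONL or CSV
#'
#' Records are assembled into threads by `parent_id` linkage: a record with
#' no `parent_id` is a thread root, and every other record is attached to
#' the thread whose root it (transitively) points at. A comment whose parent
#' never appears in the file is attached to a synthetic placeholder root
#' (id `orphan-root:<post_id>`, zero views) and reported with a warning, so
#' no record is silently dropped.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON record per line) or `"csv"` (header
#'   row required). Defaults to a guess from the file extension.
#' @return A `pleb_corpus`. The number of placeholder-rooted threads is
#'   available as `attr(x, "n_orphans")`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  recs <- if (format == "jsonl") .read_jsonl(path) else .read_csv_records(path)
  .assemble_corpus(recs, provenance = paste0("file:", path))
}

.read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$post_id) || is.null(rec$text)) {
      stop(sprintf("malformed record at line %d of %s", i, path))
    }
    recs[[i]] <- rec
  }
  recs
}

.read_csv_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  if (!nrow(df)) return(list())
  if (!all(c("post_id", "text") %in% names(df))) {
    stop("csv must have post_id and text columns")
  }
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

.rec_field <- function(rec, name, default = NA) {
  v <- rec[[name]]
  if (is.null(v) || !length(v) || (is.character(v) && !nzchar(v))) default else v
}

.assemble_corpus <- function(recs, provenance = "") {
  if (!length(recs)) return(corpus(provenance = provenance))
  posts <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    posts[[i]] <- tryCatch(post(
      post_id = rec$post_id,
      text = .rec_field(rec, "text", ""),
      timestamp = .rec_field(rec, "timestamp", "1970-01-01T00:00:00Z"),
      views = as.integer(.rec_field(rec, "views", 0L)),
      parent_id = as.character(.rec_field(rec, "parent_id", NA_character_)),
      author_id = as.character(.rec_field(rec, "author_id", NA_character_)),
      platform = as.character(.rec_field(rec, "platform", NA_character_)),
      misinfo_label = as.logical(.rec_field(rec, "misinfo_label", NA))
    ), error = function(e) stop(sprintf("malformed record %d: %s", i, conditionMessage(e))))
  }
  ids <- vapply(posts, `[[`, "", "post_id")
  if (anyDuplicated(ids)) {
    stop("duplicate post_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parents <- vapply(posts, `[[`, "", "parent_id")
  # Resolve each post to its root ancestor; unresolved chains are orphans.
  root_of <- function(i) {
    seen <- integer()
    j <- i
    while (!is.na(parents[j])) {
      k <- match(parents[j], ids)
      if (is.na(k)) return(NA_integer_)  # orphan
      if (k %in% seen) stop("cycle in parent_id linkage at ", ids[j])
      seen <- c(seen, j)
      j <- k
    }
    j
  }
  roots_idx <- vapply(seq_along(posts), root_of, 0L)
  orphans <- which(is.na(roots_idx))
  threads <- list()
  for (r in which(is.na(parents))) {
    kids <- setdiff(which(roots_idx == r), r)
    kids <- kids[order(vapply(posts[kids], function(p) as.numeric(p$timestamp), 0))]
    threads[[length(threads) + 1L]] <- thread(posts[[r]], posts[kids])
  }
  for (o in orphans) {
    p <- posts[[o]]
    ph <- post(post_id = paste0("orphan-root:", p$post_id), text = "",
               timestamp = p$timestamp, views = 0L)
    # reparent the orphan onto the placeholder so the thread invariant holds
    p$parent_id <- ph$post_id
    threads[[length(threads) + 1L]] <- thread(ph, list(p))
  }
  if (length(orphans)) {
    warning(sprintf("%d orphan comment(s) attached to placeholder roots", length(orphans)))
  }
  cp <- corpus(threads, provenance = provenance)
  attr(cp, "n_orphans") <- length(orphans)
  cp
}

#' Write a corpus to JSONL
#'
#' Inverse of [read_corpus()]: emits one JSON record per post with the
#' canonical field set, roots before their comments, so reading the file
#' back reproduces the corpus.
#'
#' @param x A `pleb_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "pleb_corpus"))
  df <- corpus_posts(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    rec <- list(post_id = df$post_id[i])
    if (!is.na(df$author_id[i])) rec$author_id <- df$author_id[i]
    rec$timestamp <- format(df$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    rec$text <- df$text[i]
    rec$views <- df$views[i]
    if (!is.na(df$parent_id[i])) rec$parent_id <- df$parent_id[i]
    if (!is.na(df$platform[i])) rec$platform <- df$platform[i]
    if (!is.na(df$misinfo_label[i])) rec$misinfo_label <- df$misinfo_label[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null", POSIXt = "ISO8601"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write a summary record as deterministic JSON
#'
#' Serializes any summary-like list (a bimodal summary, a category report,
#' a verdict, ...) as JSON with keys sorted at every level, so two writes
#' of the same record are byte-identical and the file round-trips
#' losslessly through [read_summary()].
#'
#' @param summary A named list (or object coercible to one).
#' @param path Output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (!dir.exists(dirname(path))) stop("no such directory: ", dirname(path))
  x <- .sort_keys(unclass(summary))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

.sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x))]
    lapply(x, .sort_keys)
  } else if (is.list(x)) {
    lapply(x, .sort_keys)
  } else x
}

#' Read back a summary written by [write_summary()]
#' @param path Path to a JSON summary file.
#' @return A named list.
#' @export
read_summary <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Read a term list from a plain-text file
#'
#' One phrase per line; blank lines and `#` comments are ignored. Terms are
#' stored case-folded.
#'
#' @param path Path to the term file.
#' @param name Category label; defaults to the file name without extension.
#' @return A `pleb_termlist`.
#' @export
read_term_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  terms <- lines[nzchar(lines)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  term_list(name, terms)
}

#' Construct a term list
#' @param name Category label (e.g. `"Locational Taxonomy"`).
#' @param terms Character vector of phrases; must be non-empty. Stored
#'   case-folded.
#' @return A `pleb_termlist` with fields `name`, `terms`.
#' @export
term_list <- function(name, terms) {
  terms <- tolower(trimws(as.character(terms)))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("term list must be non-empty")
  structure(list(name = as.character(name), terms = unique(terms)),
            class = "pleb_termlist")
}
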