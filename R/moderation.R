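# The democratic moderation engine: a popularity-gated Flag Phase that
# samples comment sentiment, a randomly empanelled Jury Phase that votes on
# removal, and a one-byte-per-thread incremental state (a skip bit plus a
# 7-bit quantized thread sentiment) that lets the flagger run on intervals
# touching only threads with new comments.

# Run code under a temporary seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Flag Phase configuration
#'
#' @param v_thres Positive integer popularity threshold in views; only
#'   threads with `v_act >= v_thres` are eligible for flagging.
#' @param comment_sample_size Number of comments drawn (simple random
#'   sample without replacement) from an eligible thread; default 100.
#' @param negativity_threshold Flag when the mean compound of root plus
#'   sampled comments falls strictly below this value; default 0.
#' @param seed Integer seed making the comment sample reproducible.
#' @return A `pleb_flag_config`.
#' @export
flag_config <- function(v_thres, comment_sample_size = 100L,
                        negativity_threshold = 0, seed = 1L) {
  v_thres <- as.integer(v_thres)
  comment_sample_size <- as.integer(comment_sample_size)
  stopifnot(v_thres >= 1L, comment_sample_size >= 1L)
  structure(list(v_thres = v_thres,
                 comment_sample_size = comment_sample_size,
                 negativity_threshold = as.numeric(negativity_threshold),
                 seed = as.integer(seed)),
            class = "pleb_flag_config")
}

.as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    stats::setNames(as.numeric(scores$compound), scores$post_id)
  } else {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    scores
  }
}

#' Flag Phase: decide whether a thread is potentially misleading
#'
#' A thread is eligible when its actual popularity `v_act` meets the
#' threshold. For an eligible thread, a without-replacement simple random
#' sample of (scored) comments is drawn and the unweighted mean of the
#' root compound and the sampled comment compounds is taken; the thread
#' is flagged when that mean leans negative (falls below the configured
#' negativity threshold).
#'
#' @param th A `pleb_thread`.
#' @param scores Per-post compound scores: a named numeric vector keyed by
#'   `post_id`, or a data.frame with `post_id` and `compound` columns
#'   (e.g. from [score_corpus()]). A missing/NA root score is an error.
#' @param config A `pleb_flag_config`.
#' @return A `pleb_flag_result`: `thread_id`, `eligible`,
#'   `sampled_comment_ids`, `mean_compound`, `flagged`.
#' @export
flag_phase <- function(th, scores, config) {
  stopifnot(inherits(th, "pleb_thread"), inherits(config, "pleb_flag_config"))
  sc <- .as_score_vector(scores)
  root_score <- sc[th$root$post_id]
  if (is.na(root_score)) stop("unscorable root: ", th$root$post_id)
  eligible <- th$v_act >= config$v_thres
  if (!eligible) {
    return(structure(list(thread_id = th$root$post_id, eligible = FALSE,
                          sampled_comment_ids = character(0),
                          mean_compound = NA_real_, flagged = FALSE),
                     class = "pleb_flag_result"))
  }
  cids <- vapply(th$comments, `[[`, "", "post_id")
  cids <- cids[!is.na(sc[cids])]
  k <- min(length(cids), config$comment_sample_size)
  sampled <- if (k > 0L) {
    .with_seed(config$seed, sample(cids, k, replace = FALSE))
  } else character(0)
  mean_compound <- mean(c(root_score, sc[sampled]))
  structure(list(thread_id = th$root$post_id, eligible = TRUE,
                 sampled_comment_ids = sampled,
                 mean_compound = unname(mean_compound),
                 flagged = mean_compound < config$negativity_threshold),
            class = "pleb_flag_result")
}

#' Jury Phase configuration
#'
#' @param participation_prob Probability in \[0, 1\] that an empanelled
#'   juror casts a vote before the deadline (jurors are never forced to
#'   participate).
#' @param deadline Deliberation duration (seconds); bookkeeping only --
#'   counting is triggered by quorum or by deadline expiry.
#' @param quorum Cast-vote count that triggers early counting.
#' @param seed Integer seed for panel selection and simulation.
#' @return A `pleb_jury_config`. The juror fraction is fixed at 0.10 of
#'   the viewers of the post, rounded up.
#' @export
jury_config <- function(participation_prob = 0.5, deadline = 86400,
                        quorum = 10L, seed = 1L) {
  stopifnot(participation_prob >= 0, participation_prob <= 1, quorum >= 1L)
  structure(list(fraction = 0.10, participation_prob = participation_prob,
                 deadline = as.numeric(deadline), quorum = as.integer(quorum),
                 seed = as.integer(seed)),
            class = "pleb_jury_config")
}

#' Panel size for a given viewer count
#' @param viewers Positive integer number of viewers of the post.
#' @return `ceiling(0.10 * viewers)`: exactly 10 percent, rounded up.
#' @export
panel_size <- function(viewers) {
  stopifnot(viewers >= 1)
  as.integer(ceiling(0.10 * as.numeric(viewers)))
}

#' Select a jury panel by simple random sampling without replacement
#'
#' @param viewers Positive viewer count; the panel is exactly 10 percent
#'   of it, rounded up.
#' @param population Character vector of candidate user ids; must be at
#'   least as large as the panel.
#' @param seed Integer seed; the same seed yields the same panel.
#' @return Character vector of juror ids (no repeats).
#' @export
select_jury <- function(viewers, population, seed = 1L) {
  k <- panel_size(viewers)
  if (length(population) < k) {
    stop("population too small: need ", k, ", have ", length(population))
  }
  .with_seed(seed, sample(population, k, replace = FALSE))
}

#' Jury Phase: count votes and decide removal
#'
#' Counting is triggered when the number of cast votes reaches the quorum,
#' otherwise at the deadline. Abstentions are ignored; removal requires a
#' strict majority of cast votes, so a tie (or no votes) keeps the post.
#' Removal is a state flag -- content is removed from feeds, not deleted.
#'
#' @param flag A flagged `pleb_flag_result` (only flagged threads reach
#'   the jury).
#' @param panel Character vector of empanelled juror ids.
#' @param votes Named character vector mapping juror id to `"remove"` or
#'   `"keep"`; omit or set `NA` for abstentions. A vote keyed by an id
#'   outside the panel is an error.
#' @param config A `pleb_jury_config`.
#' @return A `pleb_verdict`: `thread_id`, `panel_size`, `votes_remove`,
#'   `votes_keep`, `terminated_by` (`"quorum"` or `"deadline"`),
#'   `removed`.
#' @export
run_jury <- function(flag, panel, votes, config) {
  stopifnot(inherits(flag, "pleb_flag_result"),
            inherits(config, "pleb_jury_config"))
  if (!isTRUE(flag$flagged)) stop("only flagged threads go to the jury")
  votes <- votes[!is.na(votes)]
  if (length(votes)) {
    bad <- setdiff(names(votes), panel)
    if (length(bad)) stop("non-juror vote: ", paste(bad, collapse = ", "))
    if (!all(votes %in% c("remove", "keep"))) {
      stop("votes must be \"remove\" or \"keep\"")
    }
  }
  votes_remove <- sum(votes == "remove")
  votes_keep <- sum(votes == "keep")
  cast <- votes_remove + votes_keep
  structure(list(
    thread_id = flag$thread_id,
    panel_size = length(panel),
    votes_remove = votes_remove,
    votes_keep = votes_keep,
    terminated_by = if (cast >= config$quorum) "quorum" else "deadline",
    removed = votes_remove > votes_keep
  ), class = "pleb_verdict")
}

## ---- one-byte thread state ------------------------------------------------

#' Quantize a thread mean to the 7-bit sentiment code
#' @param mean_compound Running mean compound in \[-1, 1\].
#' @return Integer in \[0, 127\]: `round(127 * (mean + 1) / 2)`, halves
#'   rounded away from zero.
#' @export
quantize_beta <- function(mean_compound) {
  stopifnot(all(mean_compound >= -1), all(mean_compound <= 1))
  as.integer(floor(127 * (mean_compound + 1) / 2 + 0.5))
}

#' Recover an approximate thread mean from the 7-bit code
#' @param beta Integer in \[0, 127\].
#' @return Numeric in \[-1, 1\]; at most 1/127 away from the exact mean
#'   that was quantized.
#' @export
dequantize_beta <- function(beta) {
  stopifnot(all(beta >= 0), all(beta <= 127))
  2 * as.numeric(beta) / 127 - 1
}

.new_thread_byte <- function(phi_d, shadow_mean, n_seen, n_scored) {
  structure(list(phi_d = as.integer(phi_d),
                 beta = if (n_scored > 0L) quantize_beta(shadow_mean) else 64L,
                 shadow_mean = as.numeric(shadow_mean),
                 n_seen = as.integer(n_seen),
                 n_scored = as.integer(n_scored)),
            class = "pleb_threadbyte")
}

#' Encode the one-byte state of a thread
#'
#' The stored state is a single byte: the high bit is the Flag of Need
#' Determination `phi_d` and the low seven bits are the quantized thread
#' sentiment `beta`. The determination value is
#' `n_d = sgn(v_act - v_thres) * (number of new posts)`, where a post is
#' new when it was not covered by `prior` (all posts are new when `prior`
#' is absent). `phi_d = 1` (skip) exactly when `n_d <= 0`: the thread is
#' unpopular, or nothing new has arrived. The exact running mean over root
#' and all comments is kept alongside (`shadow_mean`) so the recursion
#' never accumulates quantization drift; `beta` is requantized at write
#' time only.
#'
#' @param th A `pleb_thread`.
#' @param scores Named numeric compounds by `post_id` (or a data.frame as
#'   in [flag_phase()]); must cover the scorable new posts.
#' @param v_thres Popularity threshold in views.
#' @param prior Optional previous `pleb_threadbyte` for this thread.
#' @return A `pleb_threadbyte`: `phi_d`, `beta`, `shadow_mean`, `n_seen`,
#'   `n_scored`.
#' @export
encode_thread_byte <- function(th, scores, v_thres, prior = NULL) {
  stopifnot(inherits(th, "pleb_thread"))
  sc <- .as_score_vector(scores)
  ids <- c(th$root$post_id, vapply(th$comments, `[[`, "", "post_id"))
  base_seen <- if (is.null(prior)) 0L else prior$n_seen
  stopifnot(base_seen <= length(ids))
  new_ids <- if (base_seen < length(ids)) ids[(base_seen + 1L):length(ids)] else character(0)
  n_new <- length(new_ids)
  n_d <- sign(th$v_act - v_thres) * n_new
  new_vals <- sc[new_ids]
  new_vals <- new_vals[!is.na(new_vals)]
  if (is.null(prior)) {
    n_scored <- length(new_vals)
    shadow_mean <- if (n_scored > 0L) mean(new_vals) else 0
  } else {
    n_scored <- prior$n_scored + length(new_vals)
    shadow_mean <- prior$shadow_mean
    k <- prior$n_scored
    for (v in new_vals) {  # exact incremental mean
      k <- k + 1L
      shadow_mean <- shadow_mean + (v - shadow_mean) / k
    }
  }
  .new_thread_byte(phi_d = n_d <= 0, shadow_mean = shadow_mean,
                   n_seen = length(ids), n_scored = n_scored)
}

#' Recursive update of the one-byte state with new scores
#'
#' Folds each new compound into the exact running mean (one addition and
#' one division per score), then requantizes `beta`. Equivalent to batch
#' recomputation of the mean to floating-point accuracy.
#'
#' @param state A `pleb_threadbyte`.
#' @param new_scores Numeric vector of new compound scores.
#' @return The updated `pleb_threadbyte` (`n_seen` and `n_scored` advance
#'   by `length(new_scores)`).
#' @export
update_thread_byte <- function(state, new_scores) {
  stopifnot(inherits(state, "pleb_threadbyte"))
  m <- state$shadow_mean
  k <- state$n_scored
  for (v in as.numeric(new_scores)) {
    k <- k + 1L
    m <- m + (v - m) / k
  }
  .new_thread_byte(phi_d = state$phi_d, shadow_mean = m,
                   n_seen = state$n_seen + length(new_scores), n_scored = k)
}

#' Pack a thread-state to its literal byte
#' @param state A `pleb_threadbyte`.
#' @return A length-1 raw vector: `phi_d` in the high bit, `beta` in the
#'   low seven bits.
#' @export
pack_thread_byte <- function(state) {
  stopifnot(inherits(state, "pleb_threadbyte"))
  as.raw(bitwOr(bitwShiftL(state$phi_d, 7L), state$beta))
}

#' Unpack a raw byte into skip bit and sentiment code
#' @param byte A length-1 raw vector.
#' @return List with `phi_d` (0/1) and `beta` (0..127).
#' @export
unpack_thread_byte <- function(byte) {
  b <- as.integer(byte[1])
  list(phi_d = bitwShiftR(b, 7L), beta = bitwAnd(b, 127L))
}

#' Interval sweep over a corpus with incremental thread state
#'
#' Implements the interval-based mode of the flagger: each sweep checks
#' every thread for new comments against the stored state. Threads whose
#' recomputed Flag of Need Determination is high (unpopular, or nothing
#' new since the last sweep) are skipped untouched and their text is never
#' rescored. The remaining threads have their new posts scored, the
#' one-byte state updated, and the Flag Phase run; their stored skip bit
#' is then raised so that a subsequent sweep with no new data analyzes
#' nothing.
#'
#' @param x A `pleb_corpus` (the current snapshot of the platform).
#' @param state Named list of `pleb_threadbyte` keyed by thread id
#'   (root `post_id`); possibly empty for the first sweep.
#' @param config A `pleb_flag_config`.
#' @param lex Lexicon used to score new posts; default [toy_lexicon()].
#' @param wordlist Optional word-list override for cleaning.
#' @return List with `state` (updated map) and `results` (list of
#'   `pleb_flag_result` for analyzed threads only).
#' @export
interval_sweep <- function(x, state = list(), config, lex = toy_lexicon(),
                           wordlist = NULL) {
  stopifnot(inherits(x, "pleb_corpus"), inherits(config, "pleb_flag_config"))
  results <- list()
  for (th in x$threads) {
    tid <- th$root$post_id
    prior <- state[[tid]]
    n_total <- 1L + n_comments(th)
    n_new <- n_total - if (is.null(prior)) 0L else prior$n_seen
    n_d <- sign(th$v_act - config$v_thres) * n_new
    if (n_d <= 0) next  # skip untouched: unpopular or nothing new
    sc <- .score_thread_posts(th, lex = lex, wordlist = wordlist)
    byte <- encode_thread_byte(th, sc, config$v_thres, prior = prior)
    byte$phi_d <- 1L  # analyzed: safe to skip until new comments arrive
    state[[tid]] <- byte
    fr <- tryCatch(flag_phase(th, sc, config), error = function(e) {
      warning("thread ", tid, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(fr)) results[[length(results) + 1L]] <- fr
  }
  list(state = state, results = results)
}

# Clean+score every post of one thread; returns named compound vector with
# NA for non-English or inconclusive posts.
.score_thread_posts <- function(th, lex = toy_lexicon(), wordlist = NULL) {
  posts <- c(list(th$root), th$comments)
  ids <- vapply(posts, `[[`, "", "post_id")
  vals <- vapply(posts, function(p) {
    cl <- clean_text(p$text, wordlist = wordlist)
    if (!cl$english_ok) return(NA_real_)
    s <- score_text(cl$text, lex = lex)
    if (s$inconclusive) NA_real_ else s$compound
  }, 0)
  stats::setNames(vals, ids)
}

#' Persist a thread-state map as one byte per thread plus a JSON sidecar
#'
#' The binary file holds the packed bytes in a fixed order; the sidecar
#' records the thread ids (in that order), exact shadow means and
#' counters, so the state round-trips without quantization loss.
#'
#' @param state Named list of `pleb_threadbyte`.
#' @param path Path for the byte file; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_state <- function(state, path) {
  ids <- names(state)
  bytes <- as.raw(vapply(state, function(s) as.integer(pack_thread_byte(s)), 0L))
  writeBin(bytes, path)
  sidecar <- list(
    thread_ids = as.list(ids),
    shadow_mean = lapply(state, `[[`, "shadow_mean"),
    n_seen = lapply(state, `[[`, "n_seen"),
    n_scored = lapply(state, `[[`, "n_scored"))
  write_summary(sidecar, paste0(path, ".json"))
  invisible(path)
}

#' Load a thread-state map written by [write_state()]
#' @param path Path to the byte file.
#' @return Named list of `pleb_threadbyte`.
#' @export
read_state <- function(path) {
  side <- read_summary(paste0(path, ".json"))
  ids <- unlist(side$thread_ids)
  bytes <- readBin(path, what = "raw", n = length(ids))
  state <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    un <- unpack_thread_byte(bytes[i])
    tb <- .new_thread_byte(un$phi_d, side$shadow_mean[[ids[i]]],
                           side$n_seen[[ids[i]]], side$n_scored[[ids[i]]])
    stopifnot(tb$beta == un$beta)
    state[[ids[i]]] <- tb
  }
  state
}
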