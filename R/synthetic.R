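# Seeded generator of synthetic social-media corpora with the statistical
# structure the analytics assume: root sentiments from a truncated
# two-Gaussian mixture on [-1, 1] (a negative mode near -0.5 and a
# positive one near +0.5), comments that mostly echo their root, heavy
# tailed lognormal view counts, misinformation labels coupled to negative
# sentiment through a logistic link, and optional taxonomy-phrase
# injection with a mode tilt. Text is rendered from the toy lexicon so
# the scoring pipeline recovers each post's target compound.

#' Synthetic corpus configuration
#'
#' Defaults state the world the generator emulates; see the methods
#' vignette for the rationale behind each choice.
#'
#' @param n_threads Number of threads to generate.
#' @param neg_mode,pos_mode Mixture mode centers (defaults -0.5, +0.5).
#' @param mode_sd Within-mode standard deviation (default 0.1).
#' @param neg_weight Probability a root draws from the negative mode.
#' @param comments_mean Poisson mean comment count per thread.
#' @param echo_rho Comment-root sentiment coupling in \[0, 1\]: a comment
#'   target is `rho * root + (1 - rho) * fresh mixture draw` plus noise.
#' @param noise_sd Standard deviation of the additive comment noise.
#' @param views_log_mean,views_log_sd Lognormal parameters for root view
#'   counts (integerized, floored at 1).
#' @param misinfo_intercept,misinfo_slope Logistic link for the
#'   ground-truth label: `P(misinfo) = plogis(intercept + slope * (-compound))`.
#'   The defaults (-2, 3) give a base rate near 12% for neutral posts and
#'   about 73% at compound -1: coupling that is detectable but imperfect.
#' @param term_fraction Fraction of roots that carry a taxonomy phrase.
#' @param locational_bias Added to `neg_weight` for locational-tagged
#'   roots (these lean negative).
#' @param biological_bias Subtracted from `neg_weight` for
#'   biological-tagged roots (these lean positive).
#' @param seed Integer seed; the same config generates the same corpus.
#' @return A `pleb_syn_config`.
#' @export
synthetic_config <- function(n_threads = 200L, neg_mode = -0.5,
                             pos_mode = 0.5, mode_sd = 0.1,
                             neg_weight = 0.5, comments_mean = 4,
                             echo_rho = 0.9, noise_sd = 0.05,
                             views_log_mean = 5, views_log_sd = 1.5,
                             misinfo_intercept = -2, misinfo_slope = 3,
                             term_fraction = 0.15, locational_bias = 0.35,
                             biological_bias = 0.35, seed = 1L) {
  stopifnot(neg_mode > -1, neg_mode < 0, pos_mode > 0, pos_mode < 1,
            mode_sd > 0, neg_weight >= 0, neg_weight <= 1,
            echo_rho >= 0, echo_rho <= 1, comments_mean > 0,
            term_fraction >= 0, term_fraction <= 1)
  structure(as.list(environment()), class = "pleb_syn_config")
}

.FILLER <- c("the", "this", "that", "is", "was", "so", "very", "really",
             "people", "today", "news", "story", "post", "about", "it")

# Draw one value from the truncated two-Gaussian mixture by resampling
# (not clipping, which would pile mass on the boundary and fake modes).
.mixture_draw <- function(cfg, p_neg = cfg$neg_weight) {
  repeat {
    mu <- if (stats::runif(1) < p_neg) cfg$neg_mode else cfg$pos_mode
    x <- stats::rnorm(1, mu, cfg$mode_sd)
    if (x > -1 && x < 1) return(x)
  }
}

#' Render text whose compound score approximates a target
#'
#' Greedy token selection from a lexicon in valence-sum space: the target
#' compound is inverted to a required valence sum through the scorer's
#' normalization, and tokens are chosen whose valences close the residual,
#' with random tie-breaking and neutral filler words interspersed. Stops
#' as soon as the rendered text scores within the tolerance or the token
#' budget is spent; a target unreachable with the given lexicon (e.g. a
#' strongly negative target against an all-positive lexicon) is an error.
#'
#' @param target_compound Target compound in \[-1, 1\].
#' @param lex A `pleb_lexicon` (default toy).
#' @param max_tokens Sentiment-token budget (default 30).
#' @param tol Required agreement between `score_text` on the output and
#'   the target (default 0.1).
#' @param seed Optional seed; when `NULL` the caller's RNG stream is used.
#' @return A character string.
#' @export
render_text <- function(target_compound, lex = toy_lexicon(),
                        max_tokens = 30L, tol = 0.1, seed = NULL) {
  if (!is.null(seed)) {
    return(.with_seed(seed, render_text(target_compound, lex = lex,
                                        max_tokens = max_tokens, tol = tol)))
  }
  stopifnot(target_compound >= -1, target_compound <= 1)
  vals <- lex$entries
  t <- max(min(target_compound, 0.999), -0.999)
  s_star <- t * sqrt(.COMPOUND_ALPHA / (1 - t * t))
  s <- 0
  picks <- character(0)
  for (i in seq_len(max_tokens)) {
    if (length(picks) > 0L &&
        abs(s / sqrt(s * s + .COMPOUND_ALPHA) - target_compound) <= tol / 2) break
    gain <- abs(s + vals - s_star)
    best <- which(gain <= min(gain) + 1e-9)
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    if (length(picks) > 0L && gain[pick] >= abs(s - s_star) - 1e-9) break
    s <- s + vals[pick]
    picks <- c(picks, names(vals)[pick])
  }
  # intersperse neutral filler for lexical realism (score-invariant)
  out <- character(0)
  for (w in picks) {
    if (stats::runif(1) < 0.4) out <- c(out, sample(.FILLER, 1L))
    out <- c(out, w)
  }
  text <- paste(out, collapse = " ")
  got <- score_text(text, lex)$compound
  if (abs(got - target_compound) > tol) {
    stop(sprintf("unreachable target %.3f with lexicon '%s' (best %.3f)",
                 target_compound, lex$name, got))
  }
  text
}

#' Generate a labeled synthetic corpus
#'
#' See [synthetic_config()] for the generative model. Every post carries a
#' ground-truth `misinfo_label`; the generation targets and taxonomy tags
#' are attached as `attr(x, "truth")`, a data.frame with one row per post
#' (`post_id`, `target`, `category`, `misinfo`, `is_root`).
#'
#' @param cfg A `pleb_syn_config`.
#' @param lex Lexicon used to render text (default toy).
#' @return A `pleb_corpus`.
#' @export
generate_corpus <- function(cfg = synthetic_config(), lex = toy_lexicon()) {
  stopifnot(inherits(cfg, "pleb_syn_config"))
  .with_seed(cfg$seed, .generate_corpus_impl(cfg, lex))
}

.generate_corpus_impl <- function(cfg, lex) {
  loc_terms <- default_term_list("locational")$terms
  bio_terms <- default_term_list("biological")$terms
  t0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  threads <- vector("list", cfg$n_threads)
  truth <- vector("list", cfg$n_threads)
  for (i in seq_len(cfg$n_threads)) {
    category <- "None"
    p_neg <- cfg$neg_weight
    if (stats::runif(1) < cfg$term_fraction) {
      if (stats::runif(1) < 0.5) {
        category <- "Locational Taxonomy"
        p_neg <- min(1, cfg$neg_weight + cfg$locational_bias)
      } else {
        category <- "Biological Taxonomy"
        p_neg <- max(0, cfg$neg_weight - cfg$biological_bias)
      }
    }
    root_target <- .mixture_draw(cfg, p_neg)
    root_text <- render_text(root_target, lex)
    if (category == "Locational Taxonomy") {
      root_text <- paste(sample(loc_terms, 1L), root_text)
    } else if (category == "Biological Taxonomy") {
      root_text <- paste(sample(bio_terms, 1L), root_text)
    }
    views <- max(1L, as.integer(round(stats::rlnorm(1, cfg$views_log_mean,
                                                    cfg$views_log_sd))))
    rid <- sprintf("t%05d", i)
    root <- post(post_id = rid, text = root_text,
                 timestamp = t0 + i * 60,
                 views = views,
                 misinfo_label = stats::runif(1) <
                   stats::plogis(cfg$misinfo_intercept +
                                   cfg$misinfo_slope * (-root_target)),
                 platform = "synthetic")
    n_cm <- stats::rpois(1, cfg$comments_mean)
    comments <- vector("list", n_cm)
    targets <- c(root_target, numeric(n_cm))
    cats <- c(category, rep("None", n_cm))
    for (j in seq_len(n_cm)) {
      repeat {
        tgt <- cfg$echo_rho * root_target +
          (1 - cfg$echo_rho) * .mixture_draw(cfg) +
          stats::rnorm(1, 0, cfg$noise_sd)
        if (tgt > -1 && tgt < 1) break
      }
      targets[j + 1L] <- tgt
      comments[[j]] <- post(
        post_id = sprintf("%s-c%03d", rid, j),
        text = render_text(tgt, lex),
        timestamp = t0 + i * 60 + j * 5,
        views = stats::rpois(1, 5),
        parent_id = rid,
        misinfo_label = stats::runif(1) <
          stats::plogis(cfg$misinfo_intercept + cfg$misinfo_slope * (-tgt)),
        platform = "synthetic")
    }
    threads[[i]] <- thread(root, comments)
    ids <- c(rid, vapply(comments, `[[`, "", "post_id"))
    truth[[i]] <- data.frame(
      post_id = ids, target = targets, category = cats,
      misinfo = c(root$misinfo_label,
                  vapply(comments, `[[`, NA, "misinfo_label")),
      is_root = c(TRUE, rep(FALSE, n_cm)), stringsAsFactors = FALSE)
  }
  out <- corpus(threads, provenance = sprintf(
    "synthetic(seed=%d, n_threads=%d, neg_weight=%.2f)",
    cfg$seed, cfg$n_threads, cfg$neg_weight))
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
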