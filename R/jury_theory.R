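# Condorcet jury-theorem calculations: the probability that a simple
# majority of independent, equally competent jurors reaches the correct
# decision, in closed form and by Monte-Carlo simulation. The theorem is
# what justifies empanelling many jurors: with competence above 1/2,
# majority accuracy increases with panel size; below 1/2 it decreases and
# a single juror would be optimal.

#' Juror behaviour model
#' @param competence Probability in \[0, 1\] that a voting juror votes
#'   correctly.
#' @param participation Probability in \[0, 1\] that an empanelled juror
#'   casts a vote at all.
#' @return A `pleb_juror_model`.
#' @export
juror_model <- function(competence, participation = 1) {
  stopifnot(competence >= 0, competence <= 1,
            participation >= 0, participation <= 1)
  structure(list(competence = competence, participation = participation),
            class = "pleb_juror_model")
}

#' Exact majority-correct probability for an odd panel
#'
#' The binomial tail `sum_{k > n/2} C(n, k) p^k (1-p)^(n-k)`: the
#' probability that more than half of `panel` independent jurors, each
#' correct with probability `competence`, vote correctly. Panels must be
#' odd so that a majority is unambiguous; the operational tie rule for
#' even cast-vote counts lives in [run_jury()].
#'
#' @param panel Odd positive integer panel size.
#' @param competence Per-juror probability of a correct vote.
#' @return Numeric probability.
#' @export
condorcet_majority_prob <- function(panel, competence) {
  panel <- as.integer(panel)
  if (panel < 1L || panel %% 2L == 0L) stop("panel must be odd and positive")
  stopifnot(competence >= 0, competence <= 1)
  stats::pbinom(panel %/% 2L, panel, competence, lower.tail = FALSE)
}

#' Monte-Carlo jury accuracy under optional participation
#'
#' Each rep empanels `panel` jurors; each participates with probability
#' `model$participation` and, if voting, is correct with probability
#' `model$competence`. The majority of cast votes is scored against the
#' truth; a tie among cast votes -- including zero votes -- defaults to
#' "keep", matching the operational tie rule, so when the truth is
#' "remove" a deadlocked jury counts as incorrect.
#'
#' @param panel Positive integer panel size.
#' @param model A `pleb_juror_model`.
#' @param reps Number of Monte-Carlo replicates, at least 100.
#' @param seed Integer seed.
#' @param truth `"remove"` (default: the flagged post really is
#'   misinformative) or `"keep"`.
#' @return List with `accuracy`, `se` (binomial Monte-Carlo standard
#'   error), `reps`.
#' @export
simulate_jury_accuracy <- function(panel, model, reps = 1e4L, seed = 1L,
                                   truth = c("remove", "keep")) {
  stopifnot(inherits(model, "pleb_juror_model"), reps >= 100L, panel >= 1L)
  truth <- match.arg(truth)
  correct <- .with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      voting <- stats::runif(panel) < model$participation
      n_cast <- sum(voting)
      n_correct <- if (n_cast > 0L) {
        sum(stats::runif(n_cast) < model$competence)
      } else 0L
      n_wrong <- n_cast - n_correct
      # correct votes side with the truth; decision is strict majority
      # for "remove", ties keep
      remove_votes <- if (truth == "remove") n_correct else n_wrong
      keep_votes <- n_cast - remove_votes
      decided_remove <- remove_votes > keep_votes
      decided_remove == (truth == "remove")
    }, NA)
  })
  acc <- mean(correct)
  list(accuracy = acc, se = sqrt(acc * (1 - acc) / reps), reps = reps)
}

#' Tabulate majority accuracy over a range of odd panel sizes
#' @param panels Integer vector of odd panel sizes.
#' @param competence Per-juror correctness probability.
#' @return data.frame with `panel` and `majority_prob`.
#' @export
condorcet_table <- function(panels = seq(1L, 31L, by = 2L), competence = 0.6) {
  data.frame(panel = panels,
             majority_prob = vapply(panels, condorcet_majority_prob, 0,
                                    competence = competence))
}
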