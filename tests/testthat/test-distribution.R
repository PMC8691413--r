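test_that("estimate_kde guards its preconditions", {
  expect_error(estimate_kde(runif(5)), "insufficient sample")
  expect_error(estimate_kde(rep(0.3, 50)), "degenerate bandwidth")
  expect_error(estimate_kde(c(rep(0.5, 10), 1.5)), "\\[-1, 1\\]")
})

test_that("KDE recovers a known unimodal center and normalizes", {
  set.seed(101)
  x <- rnorm(10000, 0, 0.2)
  x <- x[x > -1 & x < 1]
  kde <- estimate_kde(x)
  expect_equal(kde$grid[which.max(kde$density)], 0, tolerance = 0.05)
  expect_equal(kde_integral(kde), 1, tolerance = 0.02)
  expect_true(all(kde$density >= 0))
  expect_length(kde$grid, 512L)
})

test_that("find_modes recovers mixture centers and rejects unimodal input", {
  set.seed(202)
  x <- mixture_scores(10000, neg_weight = 0.5)
  m <- find_modes(estimate_kde(x))
  expect_equal(m$mu_minus, -0.5, tolerance = 0.05)
  expect_equal(m$mu_plus, 0.5, tolerance = 0.05)
  expect_equal(m$f_minus, m$f_plus, tolerance = 0.05 * m$f_plus)

  # all-positive sample has no negative peak
  set.seed(203)
  pos <- rnorm(1000, 0.5, 0.1)
  pos <- pos[pos > 0 & pos < 1]
  expect_error(find_modes(estimate_kde(pos)), "not bimodal")
})

test_that("mode recovery holds across 20 seeded mixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- find_modes(estimate_kde(mixture_scores(10000)))
    expect_lt(abs(m$mu_minus + 0.5), 0.05)
    expect_lt(abs(m$mu_plus - 0.5), 0.05)
  }
})

test_that("compute_gamma matches the log height-ratio and its contract", {
  expect_equal(compute_gamma(0.45, 0.9), log(2))
  expect_equal(compute_gamma(0.7, 0.7), 0)
  expect_gt(compute_gamma(0.5, 0.9), 0)   # positive peak major -> gamma > 0
  expect_lt(compute_gamma(0.9, 0.5), 0)
  expect_error(compute_gamma(0, 1), "positive")
  # pluggable functional
  expect_equal(compute_gamma(2, 1, functional = function(fm, fp) fp - fm), -1)
})

test_that("summarize_distribution composes the pieces", {
  set.seed(301)
  sm <- summarize_distribution(mixture_scores(10000, neg_weight = 0.6))
  expect_lt(sm$gamma, 0)  # heavier negative mode

  set.seed(302)
  sm2 <- summarize_distribution(mixture_scores(10000, neg_weight = 0.5))
  expect_lt(abs(sm2$gamma), 0.1)

  # histogram conservation, 30 bins by default, zero scores dropped
  set.seed(303)
  x <- c(mixture_scores(500), 0, 0)
  sm3 <- summarize_distribution(x)
  expect_equal(sm3$n, 500L)
  expect_equal(sum(sm3$histogram$counts), 500L)
  expect_length(sm3$histogram$bin_edges, 31L)
})

test_that("gamma is antisymmetric over a grid of height pairs", {
  hs <- seq(0.1, 2, length.out = 25)
  for (a in hs) for (b in hs) {
    expect_equal(compute_gamma(a, b), -compute_gamma(b, a), tolerance = 1e-12)
  }
})
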