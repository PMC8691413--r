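test_that("match_terms is phrase-level, case-insensitive, boundary-aware", {
  loc <- default_term_list("locational")
  bio <- default_term_list("biological")
  expect_true(match_terms("the china virus is here", loc))
  expect_true(match_terms("The CHINA VIRUS again", loc))
  expect_true(match_terms("SARS-CoV-2 update today", bio))
  expect_true(match_terms("tracking B.1.617 cases", bio))
  # no word boundary -> no match
  expect_false(match_terms("chinavirus", loc))
  expect_false(match_terms("sars-cov-25 genome", bio))
  expect_false(match_terms("", loc))
})

test_that("partition_corpus keeps None as the whole corpus, categories overlap", {
  texts <- c("china virus nonsense", "sars-cov-2 data", "nice weather",
             "wuhan virus and sars-cov-2 both")
  threads <- lapply(seq_along(texts), function(i) {
    make_thread(paste0("t", i), root_text = texts[[i]])
  })
  cp <- corpus(threads)
  parts <- partition_corpus(cp, list(default_term_list("locational"),
                                     default_term_list("biological")))
  expect_named(parts, c("None", "Locational Taxonomy", "Biological Taxonomy"))
  expect_length(parts$None$threads, 4L)
  expect_length(parts[["Locational Taxonomy"]]$threads, 2L)
  expect_length(parts[["Biological Taxonomy"]]$threads, 2L)
  # the double-matching post appears in both named categories
  loc_ids <- corpus_posts(parts[["Locational Taxonomy"]])$post_id
  bio_ids <- corpus_posts(parts[["Biological Taxonomy"]])$post_id
  expect_true("t4" %in% loc_ids && "t4" %in% bio_ids)
})

test_that("compare_categories computes order statistics and sorts labels", {
  reps <- compare_categories(list(B = c(-1, 0.5, 1), A = c(-1, 0.5, 1)))
  tab <- attr(reps, "table")
  expect_equal(tab$category, c("A", "B"))  # sorted
  expect_equal(tab$median, c(0.5, 0.5))
  expect_equal(tab$q1, c(-0.25, -0.25))    # linear interpolation
  # identical score sets -> identical reports except label
  expect_equal(tab$mean[1], tab$mean[2])
  expect_error(compare_categories(list()), "non-empty")
  expect_error(compare_categories(list(A = numeric(0))), "no scores")
})

test_that("taxonomy ordering holds on the synthetic demo corpus", {
  cp <- generate_corpus(synthetic_config(n_threads = 400, seed = 5,
                                         term_fraction = 0.3))
  sc <- suppressMessages(score_corpus(cp))
  truth <- attr(cp, "truth")
  cat_of <- stats::setNames(truth$category, truth$post_id)
  parts <- list(
    "None" = sc$compound,
    "Locational Taxonomy" = sc$compound[cat_of[sc$post_id] == "Locational Taxonomy"],
    "Biological Taxonomy" = sc$compound[cat_of[sc$post_id] == "Biological Taxonomy"])
  reps <- compare_categories(parts)
  tab <- attr(reps, "table")
  m <- stats::setNames(tab$mean, tab$category)
  expect_lt(m["Locational Taxonomy"], m["None"])
  expect_gt(m["Biological Taxonomy"], m["Locational Taxonomy"])
  # counts: None holds all scored posts, named categories are subsets
  expect_equal(tab$n[tab$category == "None"], nrow(sc))
  expect_true(all(tab$n <= nrow(sc)))
})
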