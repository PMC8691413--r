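test_that("read_corpus assembles threads by parent_id linkage", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(list(
    list(post_id = "r1", text = "good day", views = 10),
    list(post_id = "c1", text = "nice", parent_id = "r1"),
    list(post_id = "c2", text = "bad", parent_id = "c1")  # nested, flattened
  ), f)
  cp <- read_corpus(f)
  expect_length(cp$threads, 1L)
  expect_equal(n_comments(cp$threads[[1]]), 2L)
  expect_equal(cp$threads[[1]]$v_act, 10L)

  # empty file -> empty corpus
  writeLines(character(0), f)
  expect_length(read_corpus(f)$threads, 0L)
})

test_that("orphan comments get a placeholder root and a warning", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(list(list(post_id = "c9", text = "lost", parent_id = "nope")), f)
  expect_warning(cp <- read_corpus(f), "orphan")
  expect_length(cp$threads, 1L)
  expect_equal(attr(cp, "n_orphans"), 1L)
  expect_match(cp$threads[[1]]$root$post_id, "^orphan-root:")
})

test_that("malformed and duplicate records error with context", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"post_id":"a","text":"x"}', "{nope"), f)
  expect_error(read_corpus(f), "line 2")
  write_jsonl(list(list(post_id = "a", text = "x"),
                   list(post_id = "a", text = "y")), f)
  expect_error(read_corpus(f), "duplicate post_id")
})

test_that("csv input and corpus round-trip preserve all fields", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("post_id,text,views,parent_id,timestamp",
               "r1,good news,42,,2021-06-01T10:00:00Z",
               "c1,sad story,1,r1,2021-06-01T10:05:00Z"), f)
  cp <- read_corpus(f)
  expect_length(cp$threads, 1L)
  expect_equal(cp$threads[[1]]$root$views, 42L)

  g <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(cp, g)
  cp2 <- read_corpus(g)
  expect_equal(corpus_posts(cp2), corpus_posts(cp))
})

test_that("post and thread invariants are enforced", {
  expect_error(post("p1", "x", views = -1), "non-negative")
  expect_error(post("p1", "x", parent_id = "p1"), "differ")
  expect_error(thread(post("r", "x"),
                      list(post("c", "y", parent_id = "ghost"))),
               "resolve")
  expect_error(corpus(list(make_thread("a"), make_thread("a"))), "duplicate")
})

test_that("write_summary is deterministic and round-trips", {
  d <- withr::local_tempdir()
  s <- list(gamma = -0.03214, mu_plus = 0.48, mu_minus = -0.54, n = 100L)
  p1 <- file.path(d, "a.json"); p2 <- file.path(d, "b.json")
  write_summary(s, p1)
  write_summary(s[c(3, 1, 4, 2)], p2)  # different key order, same content
  expect_identical(readBin(p1, "raw", 1e5), readBin(p2, "raw", 1e5))
  back <- read_summary(p1)
  expect_equal(back$gamma, s$gamma)
  expect_equal(back$n, s$n)
  expect_error(write_summary(s, file.path(d, "no", "such", "dir.json")),
               "no such directory")
})

test_that("term lists case-fold, skip comments, and reject empties", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "China Virus", "", "  BIOWEAPON  "), f)
  tl <- read_term_list(f, name = "x")
  expect_setequal(tl$terms, c("china virus", "bioweapon"))
  expect_error(term_list("empty", character(0)), "non-empty")
})
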