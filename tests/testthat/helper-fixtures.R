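# Fixtures are built in code; nothing binary ships with the tests.

# A tiny thread: one root plus n scored comments with prescribed texts.
make_thread <- function(id = "t1", root_text = "good day", comment_texts = character(0),
                        views = 100L) {
  comments <- lapply(seq_along(comment_texts), function(j) {
    post(post_id = sprintf("%s-c%d", id, j), text = comment_texts[[j]],
         parent_id = id, views = 1L,
         timestamp = sprintf("2021-01-01T00:%02d:00Z", j))
  })
  thread(post(post_id = id, text = root_text, views = views,
              timestamp = "2021-01-01T00:00:00Z"), comments)
}

# Named compound-score vector for a thread via the real pipeline.
thread_scores <- function(th) {
  posts <- c(list(th$root), th$comments)
  vals <- vapply(posts, function(p) score_text(clean_text(p$text)$text)$compound, 0)
  stats::setNames(vals, vapply(posts, `[[`, "", "post_id"))
}

# Write a small JSONL corpus file; records is a list of named lists.
write_jsonl <- function(records, path) {
  writeLines(vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, ""), path)
  path
}

# Draw n compounds from the truncated two-Gaussian mixture directly
# (independent of the corpus generator).
mixture_scores <- function(n, neg_weight = 0.5, centers = c(-0.5, 0.5),
                           sd = 0.1) {
  out <- numeric(0)
  while (length(out) < n) {
    k <- n - length(out)
    mu <- ifelse(stats::runif(k) < neg_weight, centers[1], centers[2])
    x <- stats::rnorm(k, mu, sd)
    out <- c(out, x[x > -1 & x < 1])
  }
  out[seq_len(n)]
}
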