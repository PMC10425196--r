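test_that("topic indicators use the strict 1/K cutoff", {
  ind <- topic_indicators(c(0.1, 0.02, 0.7, 0.18), K = 4)
  expect_equal(attr(ind, "cutoff"), 0.25)
  expect_equal(as.integer(ind), c(0L, 0L, 1L, 0L))
  # uniform vector: strict inequality flags nothing
  expect_equal(as.integer(topic_indicators(rep(0.25, 4))), rep(0L, 4))
  expect_equal(as.integer(topic_indicators(c(0.4, 0.35, 0.25))), c(1L, 1L, 0L))
  expect_error(topic_indicators(c(0.5, 0.5), K = 3), "length K")
  expect_error(topic_indicators(c(0.6, 0.6)), "sum to 1")

  set.seed(50)
  for (i in 1:50) {
    K <- sample(2:8, 1)
    g <- rgamma(K, 1); pi <- g / sum(g)
    expect_equal(as.integer(topic_indicators(pi)),
                 as.integer(vapply(pi, function(q) q > 1 / K, logical(1))))
  }
})

test_that("dominant topic is the 0-based argmax with low-index ties", {
  expect_identical(dominant_topic(c(0.1, 0.02, 0.7, 0.18)), 2L)
  expect_identical(dominant_topic(c(0.5, 0.5)), 0L)
  expect_error(dominant_topic(numeric(0)), "empty")
  set.seed(51)
  for (i in 1:50) {
    g <- rgamma(5, 1); pi <- g / sum(g)
    expect_identical(dominant_topic(pi), which(pi == max(pi))[1] - 1L)
  }
})

test_that("prior sentiment averages strictly earlier same-topic reviews", {
  expect_equal(prior_sentiment(c(0.5, -0.1, 0.3, 0.2), c(2, 2, 1, 2), 1:4),
               c(0, 0.5, 0, 0.2))
  expect_equal(prior_sentiment(0.4, 1, 1), 0)
  expect_equal(prior_sentiment(c(0.3, -0.2, 0.9), c(1, 2, 3), 1:3), c(0, 0, 0))
  expect_error(prior_sentiment(c(0.1, 0.2), c(1, 1), c(2, 1)), "order")
  expect_error(prior_sentiment(c(2, 0), c(1, 1), 1:2), "\\[-1, 1\\]")

  # causality: permuting later reviews never changes earlier values
  set.seed(52)
  s <- runif(10, -1, 1); d <- sample(1:3, 10, replace = TRUE)
  base <- prior_sentiment(s, d, 1:10)
  i <- 6
  perm <- c(seq_len(i), i + sample(10 - i))
  expect_equal(prior_sentiment(s[perm], d[perm], 1:10)[seq_len(i)],
               base[seq_len(i)])
})

test_that("design vectors follow the fixed layout and round-trip by name", {
  spec <- feature_spec(K = 4)
  v <- build_design(list(gender = 1, age_group = 6, treatment_group = 3,
                         indicators = c(0, 0, 1, 0), prior_sentiment = 0.2),
                    spec)
  expect_equal(unname(v), c(1, 6, 36, 3, 9, 0, 0, 1, 0, 0.2))
  expect_named(v, c("gender", "age", "age2", "treatment", "treatment2",
                    paste0("topic", 0:3), "prior_sentiment"))
  expect_equal(v[["age2"]], v[["age"]]^2)
  expect_equal(v[["treatment2"]], v[["treatment"]]^2)
  # decode by name recovers the inputs
  expect_equal(v[["gender"]], 1)
  expect_equal(as.numeric(v[paste0("topic", 0:3)]), c(0, 0, 1, 0))

  # indicators derivable from topic probabilities
  v2 <- build_design(list(gender = 0, age_group = 2, treatment_group = 1,
                          topic_probs = c(0.1, 0.02, 0.7, 0.18),
                          prior_sentiment = 0), spec)
  expect_equal(as.numeric(v2[paste0("topic", 0:3)]), c(0, 0, 1, 0))

  expect_error(build_design(list(age_group = 2, treatment_group = 1,
                                 indicators = rep(0, 4), prior_sentiment = 0),
                            spec), "gender")
  # optional age recode map
  spec9 <- feature_spec(K = 2, age_recode = c("10" = 9))
  v3 <- build_design(list(gender = 0, age_group = 10, treatment_group = 2,
                          indicators = c(1, 0), prior_sentiment = 0), spec9)
  expect_equal(v3[["age"]], 9)
})

test_that("new-patient imputation takes per-topic modes with ties to zero", {
  hist <- rbind(c(1, 0), c(1, 0), c(0, 0))
  expect_equal(impute_new_patient(hist)$indicators, c(1L, 0L))
  tie <- rbind(c(1, 1), c(0, 0))
  expect_equal(impute_new_patient(tie)$indicators, c(0L, 0L))
  expect_equal(impute_new_patient(hist)$prior_sentiment, 0)
  expect_warning(out <- impute_new_patient(matrix(0, 0, 3)), "empty")
  expect_equal(out$indicators, rep(0L, 3))

  set.seed(53)
  for (i in 1:20) {
    h <- matrix(rbinom(35, 1, runif(1)), 7, 5)
    got <- impute_new_patient(h)$indicators
    want <- apply(h, 2, function(col) as.integer(sum(col) > length(col) / 2))
    expect_equal(got, want)
  }
})

test_that("topic-count selection is an argmax over adapter coherence scores", {
  fit_fun <- function(texts, K) list(K = K)
  scores <- c(`4` = 0.3, `7` = 0.5, `10` = 0.4)
  coh <- function(model, texts) scores[[as.character(model$K)]]
  out <- select_topic_count(letters, candidates = c(4, 7, 10),
                            fit_fun = fit_fun, coherence_fun = coh)
  expect_equal(out$K, 7)
  expect_equal(nrow(out$scores), 3)
  # coherence tie goes to the smaller count
  coh2 <- function(model, texts) if (model$K %in% c(7, 10)) 0.5 else 0.1
  expect_equal(select_topic_count(letters, c(4, 7, 10), fit_fun, coh2)$K, 7)
  expect_error(select_topic_count(letters), "external")
})

test_that("review CSV reading validates schema and reports bad lines", {
  sim <- simulate_review_stream(n = 20, K = 3, seed = 54)
  f <- tempfile(fileext = ".csv")
  write_reviews(sim$records, f)
  back <- read_reviews(f)
  expect_equal(nrow(back), 20)
  expect_equal(back$rating_satisfaction, sim$records$rating_satisfaction)

  bad <- sim$records
  bad$rating_ease[3] <- 9
  write_reviews(bad, f)
  expect_error(read_reviews(f), "line\\(s\\): 4")

  nocol <- sim$records[, setdiff(names(sim$records), "gender")]
  write_reviews(nocol, f)
  expect_error(read_reviews(f), "gender")
  unlink(f)
})

test_that("review records assemble into a panel with the feature rules applied", {
  sim <- simulate_review_stream(n = 40, K = 3, seed = 55)
  built <- reviews_to_panel(sim$records, feature_spec(K = 3))
  pan <- built$panel
  expect_s3_class(pan, "ordinal_panel")
  expect_equal(pan$n, 40)
  expect_equal(pan$J, 3)
  expect_equal(pan$p, 9)   # 5 demographic terms + 3 topics + prior_sentiment
  # spot-check one row against the atomic operations
  i <- 17
  P <- as.numeric(sim$records[i, paste0("topic_prob_", 0:2)])
  expect_equal(as.numeric(pan$x[i, paste0("topic", 0:2)]),
               as.numeric(topic_indicators(P, 3)))
  dom <- vapply(seq_len(40), function(r)
    dominant_topic(as.numeric(sim$records[r, paste0("topic_prob_", 0:2)])),
    integer(1))
  ps <- prior_sentiment(sim$records$sentiment, dom, sim$records$order)
  expect_equal(unname(pan$x[, "prior_sentiment"]), ps)
  expect_false(is.null(built$spec$imputation))

  two <- rbind(sim$records, transform(sim$records, drug = "other"))
  expect_error(reviews_to_panel(two, feature_spec(K = 3)), "single drug")
})
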