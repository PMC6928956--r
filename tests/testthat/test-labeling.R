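# Ensemble whose confidence for predicted class "a" is prescribed per window.
conf_ensemble <- function(conf, origin = "personal") {
  post <- cbind(a = conf, b = 1 - conf)
  fixed_posterior_ensemble(post, c("a", "b"), origin = origin)
}

truth_oracle <- function(truth, w = seq_along(truth), subject = "S01") {
  lookup <- setNames(truth, w)
  function(subject_id, w) unname(lookup[[as.character(w)]])
}

test_that("the threshold follows the ensemble composition", {
  ui3 <- learnpp_ensemble()
  for (i in 1:3) {
    ui3 <- add_base_model(ui3, persohar:::custom_base_model(
      function(X) matrix(0.5, nrow(X), 2), c("a", "b"),
      origin = "user_independent"))
  }
  pol <- labeling_policy("semi_supervised")
  expect_equal(select_threshold(ui3, pol), 0.95)
  ui1 <- add_base_model(learnpp_ensemble(), persohar:::custom_base_model(
    function(X) matrix(0.5, nrow(X), 2), c("a", "b"),
    origin = "user_independent"))
  expect_equal(select_threshold(ui1, pol), 0.95)
  mixed <- add_base_model(ui3, persohar:::custom_base_model(
    function(X) matrix(0.5, nrow(X), 2), c("a", "b"), origin = "personal"))
  expect_equal(select_threshold(mixed, pol), 0.75)
  expect_error(select_threshold(ui3, labeling_policy("supervised")),
               "contract error")
})

test_that("one query propagates its label exactly two windows each way", {
  n <- 20
  conf <- rep(0.99, n)
  conf[10] <- 0.6   # only window 10 is uncertain
  ens <- conf_ensemble(conf)
  truth <- rep("b", n)  # oracle disagrees with the predicted "a"
  lc <- label_chunk(ens, confidence_chunk(conf, truth), labeling_policy("semi_supervised"),
                    truth_oracle(truth))
  expect_identical(lc$source[10], "queried")
  expect_identical(lc$labels[10], "b")
  expect_identical(lc$source[c(8, 9, 11, 12)], rep("propagated", 4))
  expect_identical(lc$labels[c(8, 9, 11, 12)], rep("b", 4))
  expect_identical(unique(lc$source[c(1:7, 13:20)]), "predicted")
  expect_identical(unique(lc$labels[c(1:7, 13:20)]), "a")
  expect_equal(lc$query_fraction, 1 / 20)
  expect_equal(lc$replaced_fraction, 5 / 20)
})

test_that("a fully confident chunk reduces semi-supervised to non-supervised labeling", {
  conf <- rep(0.99, 10)
  truth <- rep("b", 10)
  ens <- conf_ensemble(conf)
  chunk <- confidence_chunk(conf, truth)
  semi <- label_chunk(ens, chunk, labeling_policy("semi_supervised"),
                      truth_oracle(truth))
  nonsup <- label_chunk(ens, chunk, labeling_policy("non_supervised"))
  expect_identical(semi$labels, nonsup$labels)
  expect_identical(semi$source, nonsup$source)
  expect_equal(semi$query_fraction, 0)
  expect_equal(semi$replaced_fraction, 0)
})

test_that("alternating confidences reproduce the brute-force labeling policy", {
  n <- 20
  conf <- rep(c(0.9, 0.6), n / 2)  # uncertain at even w with th = 0.75
  set.seed(4)
  truth <- sample(c("a", "b"), n, replace = TRUE)
  ens <- conf_ensemble(conf)
  lc <- label_chunk(ens, confidence_chunk(conf, truth),
                    labeling_policy("semi_supervised"), truth_oracle(truth))
  expect_equal(which(lc$source == "queried"), seq(2, n, by = 2))
  want <- bf_label_semi(seq_len(n), rep("a", n), conf, truth, 0.75, 2)
  expect_identical(lc$labels, want$labels)
  expect_identical(lc$source, want$source)
})

test_that("threshold limits collapse semi-supervised onto the pure policies", {
  set.seed(21)
  n <- 30
  conf <- runif(n, 0.4, 1)
  truth <- sample(c("a", "b"), n, replace = TRUE)
  ens <- conf_ensemble(conf)
  chunk <- confidence_chunk(conf, truth)
  oracle <- truth_oracle(truth)

  zero <- label_chunk(ens, chunk,
                      labeling_policy("semi_supervised", th_ui = 0, th_personal = 0),
                      oracle)
  nonsup <- label_chunk(ens, chunk, labeling_policy("non_supervised"))
  expect_identical(zero$labels, nonsup$labels)
  expect_identical(zero$source, nonsup$source)

  full <- label_chunk(ens, chunk,
                      labeling_policy("semi_supervised", th_ui = 1.01,
                                      th_personal = 1.01), oracle)
  sup <- label_chunk(ens, chunk, labeling_policy("supervised"), oracle)
  expect_identical(full$labels, sup$labels)
  expect_identical(full$labels, truth)
  expect_equal(full$query_fraction, 1)
  expect_equal(sup$query_fraction, 1)
})

test_that("oracle failures name the subject and window", {
  conf <- c(0.99, 0.5, 0.99)
  ens <- conf_ensemble(conf)
  bad_oracle <- function(subject_id, w) NA
  expect_error(label_chunk(ens, confidence_chunk(conf, rep("a", 3)),
                           labeling_policy("semi_supervised"), bad_oracle),
               "labeling error.*S01.*2")
  expect_error(label_chunk(ens, confidence_chunk(conf, rep("a", 3)),
                           labeling_policy("semi_supervised")),
               "oracle")
})

test_that("query summaries aggregate fractions per round", {
  mk <- function(q, p, n) {
    src <- c(rep("queried", q), rep("propagated", p), rep("predicted", n - q - p))
    structure(list(labels = rep("a", n), source = src,
                   query_fraction = q / n, replaced_fraction = (q + p) / n),
              class = "labeled_chunk")
  }
  s <- summarize_queries(list(mk(2, 6, 20), mk(20, 0, 20), mk(0, 0, 20)),
                         rounds = c(1, 2, 2))
  expect_equal(s$per_round$query_fraction, c(0.10, 0.5))
  expect_equal(s$per_round$replaced_fraction, c(0.40, 0.5))
  expect_equal(unname(s$overall["query_fraction"]), mean(c(0.1, 1, 0)))
})
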