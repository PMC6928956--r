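fit_random_member <- function(classes, seed, origin = "user_independent",
                              p = 4) {
  set.seed(seed)
  n <- 12 * length(classes)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(classes, each = 12)
  kind <- c("lda", "qda", "cart")[(seed %% 3) + 1]
  fit_base(kind, x, y, origin = origin)
}

test_that("ensemble growth is append-only with uniform weights", {
  ens <- learnpp_ensemble()
  expect_equal(n_members(ens), 0)
  expect_false(has_personal(ens))
  expect_error(ensemble_weights(ens), "contract error")
  expect_error(predict(ens, matrix(0, 1, 4)), "contract error")
  expect_error(add_base_model(ens, list()), "contract error")

  ens <- add_base_model(ens, fit_random_member(c("a", "b"), 1))
  expect_equal(ensemble_weights(ens), 1)
  for (i in 2:4) ens <- add_base_model(ens, fit_random_member(c("a", "b"), i))
  expect_equal(ensemble_weights(ens), rep(0.25, 4))
  expect_equal(sum(ensemble_weights(ens)), 1, tolerance = 1e-12)
})

test_that("soft voting averages member posteriors", {
  post1 <- matrix(c(0.6, 0.4), 1)
  post2 <- matrix(c(0.8, 0.2), 1)
  ens <- fixed_posterior_ensemble(post1, c("a", "b"))
  ens <- add_base_model(ens, persohar:::custom_base_model(
    function(X) post2[rep(1, nrow(X)), , drop = FALSE], c("a", "b")))
  got <- ensemble_posterior(ens, matrix(0, 1, 1))
  expect_equal(unname(got[1, ]), c(0.7, 0.3), tolerance = 1e-12)

  # single member: identity
  one <- fixed_posterior_ensemble(post1, c("a", "b"))
  expect_equal(unname(ensemble_posterior(one, matrix(0, 1, 1))[1, ]),
               c(0.6, 0.4), tolerance = 1e-12)
})

test_that("ensemble posterior equals the brute-force loop, including class-list unions", {
  members <- list(
    fit_random_member(c("a", "b"), 1),
    fit_random_member(c("b", "c"), 2),
    fit_random_member(c("a", "c"), 3),
    fit_random_member(c("a", "b", "c"), 4),
    fit_random_member(c("a", "b"), 5, origin = "personal")
  )
  ens <- learnpp_ensemble()
  for (m in members) ens <- add_base_model(ens, m)
  expect_identical(ensemble_classes(ens), c("a", "b", "c"))
  set.seed(99)
  X <- matrix(rnorm(40), 10, 4)
  got <- ensemble_posterior(ens, X)
  want <- bf_soft_vote(members, X)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(rowSums(got), rep(1, 10), tolerance = 1e-12)
})

test_that("member order does not change ensemble posteriors", {
  members <- lapply(1:4, function(i) fit_random_member(c("a", "b", "c"), i))
  set.seed(1)
  X <- matrix(rnorm(20), 5, 4)
  build <- function(ms) {
    ens <- learnpp_ensemble()
    for (m in ms) ens <- add_base_model(ens, m)
    ens
  }
  expect_equal(ensemble_posterior(build(members), X),
               ensemble_posterior(build(rev(members)), X), tolerance = 1e-12)
})

test_that("predictions carry max-posterior confidence and lexicographic tie-break", {
  # perfectly contradicting members: posterior (0.5, 0.5)
  ens <- fixed_posterior_ensemble(matrix(c(1, 0), 1), c("run", "walk"))
  ens <- add_base_model(ens, persohar:::custom_base_model(
    function(X) matrix(c(0, 1), nrow(X), 2, byrow = TRUE), c("run", "walk")))
  pr <- predict(ens, matrix(0, 1, 1))
  expect_equal(pr$confidence, 0.5, tolerance = 1e-12)
  expect_identical(pr$label, "run")

  # unanimous members
  ens2 <- fixed_posterior_ensemble(matrix(c(0.9, 0.1), 1), c("run", "walk"))
  ens2 <- add_base_model(ens2, persohar:::custom_base_model(
    function(X) matrix(c(0.8, 0.2), nrow(X), 2, byrow = TRUE), c("run", "walk")))
  pr2 <- predict(ens2, matrix(0, 1, 1))
  expect_identical(pr2$label, "run")
  expect_equal(pr2$confidence, 0.85, tolerance = 1e-12)

  # batch predictions equal row-wise predictions
  m <- fit_random_member(c("a", "b"), 7)
  ens3 <- add_base_model(learnpp_ensemble(), m)
  set.seed(2)
  X <- matrix(rnorm(24), 6, 4)
  batch <- predict(ens3, X)
  single <- vapply(1:6, function(i) predict(ens3, X[i, ])$label, character(1))
  expect_identical(batch$label, single)
})

test_that("has_personal reflects member origins", {
  ens <- learnpp_ensemble()
  for (i in 1:3) ens <- add_base_model(ens, fit_random_member(c("a", "b"), i))
  expect_false(has_personal(ens))
  ens <- add_base_model(ens, fit_random_member(c("a", "b"), 9,
                                               origin = "personal"))
  expect_true(has_personal(ens))
})

test_that("ensembles survive a save/load round trip", {
  ens <- add_base_model(learnpp_ensemble(), fit_random_member(c("a", "b"), 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  set.seed(3)
  X <- matrix(rnorm(8), 2, 4)
  expect_equal(ensemble_posterior(back, X), ensemble_posterior(ens, X))
  saveRDS(list(a = 1), path)
  expect_error(load_ensemble(path), "format error")
})
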