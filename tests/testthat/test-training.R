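test_that("noise injection preserves labels and scales with the per-feature sd", {
  fs <- random_fs(200, 5, seed = 1)
  fs$x <- sweep(fs$x, 2, c(1, 2, 4, 8, 16), `*`)  # distinct per-feature sds

  expect_identical(noise_inject(fs, copies = 0, scale = 0.1), fs)

  set.seed(2)
  silent <- noise_inject(fs, copies = 2, scale = 0)
  expect_equal(n_windows(silent), 600)
  expect_identical(silent$x[201:400, ], fs$x)
  expect_identical(silent$label, rep(fs$label, 3))
  expect_identical(silent$w, rep(fs$w, 3))

  set.seed(3)
  aug <- noise_inject(fs, copies = 50, scale = 0.1)
  sds <- apply(fs$x, 2, sd)
  for (f in 1:5) {
    diffs <- aug$x[-(1:200), f] - rep(fs$x[, f], 50)
    expect_lt(abs(sd(diffs) - 0.1 * sds[f]), 0.01 * sds[f])
  }
  expect_error(noise_inject(fs, copies = 2, scale = -1), "scale")
})

test_that("bootstrap sampling is uniform with replacement and seed-stable", {
  one <- random_fs(1, 3, seed = 1)
  expect_identical(bootstrap_sample(one, 1)$x, one$x)

  fs <- random_fs(4, 3, seed = 2)
  set.seed(10)
  a <- bootstrap_sample(fs, 50)
  set.seed(10)
  b <- bootstrap_sample(fs, 50)
  expect_identical(a, b)

  set.seed(11)
  big <- bootstrap_sample(fs, 10000)
  freq <- table(factor(big$w, levels = 1:4)) / 10000
  sd3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < sd3))

  expect_error(bootstrap_sample(structure(list(x = matrix(nrow = 0, ncol = 1),
                                               label = character(0),
                                               subject_id = character(0),
                                               w = integer(0)),
                                          class = "feature_set"), 1),
               "contract error")
})

test_that("SFS finds the single separating feature first and ignores duplicates", {
  set.seed(20)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1] <- ifelse(y == "a", 0, 8) + rnorm(n, sd = 0.1)
  set.seed(21)
  sel <- sfs_select(X, y, "lda", train_config(sfs_max_features = 3))
  expect_equal(sel[1], 1)
  # exhaustive confirmation: no other single feature separates as well
  acc1 <- vapply(1:10, function(j) {
    m <- MASS::lda(X[, j, drop = FALSE], grouping = factor(y))
    mean(predict(m, X[, j, drop = FALSE])$class == y)
  }, numeric(1))
  expect_equal(which.max(acc1), 1L)

  # a duplicated informative feature is picked once, smallest index first
  X2 <- cbind(rnorm(n), rnorm(n), rnorm(n), X[, 1], rnorm(n), rnorm(n),
              rnorm(n), X[, 1])
  set.seed(22)
  sel2 <- sfs_select(X2, y, "lda", train_config(sfs_max_features = 4))
  expect_true(4 %in% sel2)
  expect_false(8 %in% sel2)

  set.seed(23)
  expect_length(sfs_select(X, y, "lda", train_config(sfs_max_features = 1)), 1)
  expect_error(sfs_select(X, rep("a", n), "lda", train_config()),
               "degenerate")
})

test_that("the QDA and CART wrapper criteria run and find informative features", {
  set.seed(30)
  n <- 48
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 3] <- ifelse(y == "a", -3, 3) + rnorm(n, sd = 0.3)
  for (kind in c("qda", "cart")) {
    set.seed(31)
    sel <- sfs_select(X, y, kind, train_config(sfs_max_features = 2))
    expect_equal(sel[1], 3, label = kind)
  }
})

test_that("chunk training is seed-reproducible and follows inject->sample->select->fit", {
  fs <- random_fs(60, 8, classes = c("a", "b", "c"), seed = 5)
  fs$x[, 2] <- match(fs$label, c("a", "b", "c")) * 4 + rnorm(60, sd = 0.2)

  m1 <- train_base_model(fs, "lda", "personal", train_config(sfs_max_features = 3),
                         seed = 77)
  m2 <- train_base_model(fs, "lda", "personal", train_config(sfs_max_features = 3),
                         seed = 77)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_equal(predict_posterior(m1, fs$x), predict_posterior(m2, fs$x))

  post <- predict_posterior(m1, fs$x)
  pred <- colnames(post)[max.col(post, "first")]
  expect_equal(balanced_accuracy(fs$label, pred), 1)

  steps <- character(0)
  withr::local_options(persohar.train_hook = function(s) {
    steps <<- c(steps, s)
  })
  train_base_model(fs, "lda", "personal", train_config(sfs_max_features = 2),
                   seed = 1)
  expect_identical(steps, c("noise_inject", "bootstrap_sample", "sfs_select",
                            "fit_base"))
  steps <- character(0)
  train_base_model(fs, "lda", "user_independent",
                   train_config(sfs_max_features = 2), seed = 1)
  expect_identical(steps, c("bootstrap_sample", "sfs_select", "fit_base"))
})

test_that("augmentation and bootstrap sizes compose as configured", {
  fs <- random_fs(40, 6, seed = 6)
  fs$x[, 1] <- ifelse(fs$label == "a", 0, 5) + rnorm(40, sd = 0.1)
  set.seed(1)
  aug <- noise_inject(fs, 2, 0.1)
  expect_equal(n_windows(aug), 120)  # (R + 1) * n
  expect_equal(n_windows(bootstrap_sample(aug, n_windows(fs))), 40)
  cfg_orig <- train_config(sfs_max_features = 1, noise_copies = 2,
                           bootstrap_size_rule = "original_size")
  cfg_pool <- train_config(sfs_max_features = 1, noise_copies = 2,
                           bootstrap_size_rule = "pool_size")
  expect_s3_class(train_base_model(fs, "lda", "personal", cfg_orig, seed = 3),
                  "base_model")
  expect_s3_class(train_base_model(fs, "lda", "personal", cfg_pool, seed = 3),
                  "base_model")
})

test_that("replicate models on one noisy chunk are diverse across seeds", {
  set.seed(40)
  fs <- random_fs(60, 50, classes = c("a", "b"), seed = 41)
  fs$x[, 5] <- ifelse(fs$label == "a", -1, 1) + rnorm(60, sd = 1.5)
  fs$x[, 9] <- ifelse(fs$label == "a", -1, 1) + rnorm(60, sd = 1.5)
  cfgt <- train_config(sfs_max_features = 3)
  identical_triples <- vapply(1:10, function(seed) {
    sels <- lapply(1:3, function(r) {
      train_base_model(fs, "lda", "personal", cfgt,
                       seed = derive_seed(seed, 1, 1, r))$selected_features
    })
    identical(sels[[1]], sels[[2]]) && identical(sels[[2]], sels[[3]])
  }, logical(1))
  expect_false(all(identical_triples))
})
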