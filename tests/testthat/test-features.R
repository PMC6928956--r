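test_that("derived signals include triad and pairwise magnitudes with Pythagorean values", {
  n <- 16
  tri <- list(acc_x = rep(3, n), acc_y = rep(4, n), acc_z = rep(0, n))
  ds <- derive_signals(tri)
  expect_length(ds, 7)
  expect_identical(names(ds), c("acc_x", "acc_y", "acc_z", "acc_mag",
                                "acc_xy", "acc_xz", "acc_yz"))
  expect_equal(unique(ds$acc_mag), 5)
  expect_equal(unique(ds$acc_xy), 5)
  expect_equal(unique(ds$acc_xz), 3)
  expect_equal(unique(ds$acc_yz), 4)

  plain <- feature_config(include_magnitude = FALSE, include_pairwise = FALSE)
  expect_identical(derive_signals(tri, plain), tri)

  expect_error(derive_signals(tri[1:2]), "configuration error")
})

test_that("constant and tiny sequences hit the degenerate feature values", {
  f <- extract_features(rep(2.5, 64))
  expect_equal(unname(f["std"]), 0)
  expect_true(all(f[c("min", "max", "median", "p10", "p25", "p75", "p90")] == 2.5))
  expect_true(all(f[paste0("cross_p", c(10, 25, 75, 90))] == 0))
  expect_true(all(f[sprintf("band%02d", 1:10)] == 0))
  # strict tails of a constant signal are empty
  expect_true(all(f[c("sum_below_p10", "sum_above_p90")] == 0))

  g <- extract_features(c(1, 2, 3, 4, 5))
  expect_equal(unname(g[c("min", "median", "max")]), c(1, 3, 5))
})

test_that("all 30 per-signal features match the brute-force oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(c(64, 128, 210), 1)
    x <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
    got <- unname(extract_features(x))
    want <- bf_extract_features(x)
    expect_true(all(abs(got - want) <= 1e-9 * pmax(abs(want), 1)),
                label = sprintf("oracle equivalence (n=%d, rep %d)", n, i))
  }
})

test_that("features transform predictably under signal rescaling", {
  set.seed(5)
  x <- rnorm(100)
  a <- 2.5
  f1 <- extract_features(x)
  f2 <- extract_features(a * x)
  lin <- c("min", "max", "median", "p10", "p25", "p75", "p90")
  expect_equal(unname(f2[lin]), unname(a * f1[lin]), tolerance = 1e-12)
  expect_equal(unname(f2["std"]), unname(a * f1["std"]), tolerance = 1e-12)
  expect_equal(unname(extract_features(-1.5 * x)["std"]),
               unname(1.5 * f1["std"]), tolerance = 1e-12)
  # crossing counts are invariant under strictly increasing transforms
  f3 <- extract_features(x^3 + 2 * x)
  crosses <- paste0("cross_p", c(10, 25, 75, 90))
  expect_identical(unname(f1[crosses]), unname(f3[crosses]))
})

test_that("feature order and names are stable", {
  expected30 <- c("std", "min", "max", "median", "p10", "p25", "p75", "p90",
                  "sum_below_p10", "sum_below_p25", "sum_above_p75",
                  "sum_above_p90", "sqsum_below_p10", "sqsum_below_p25",
                  "sqsum_above_p75", "sqsum_above_p90", "cross_p10",
                  "cross_p25", "cross_p75", "cross_p90",
                  sprintf("band%02d", 1:10))
  expect_identical(names(extract_features(rnorm(32))), expected30)

  rec <- raw_recording("S01", 50,
                       list(acc_x = rnorm(300), acc_y = rnorm(300),
                            acc_z = rnorm(300)),
                       rep("walk", 300))
  fs <- featurize(segment_windows(rec, window_spec(4.2, 1.4)))
  expect_equal(ncol(fs$x), 210)
  expect_identical(colnames(fs$x)[1:4],
                   paste("acc_x", expected30[1:4], sep = "."))
  expect_identical(colnames(fs$x)[181:183],
                   paste("acc_yz", expected30[1:3], sep = "."))
})

test_that("featurize agrees with window-by-window extract_features composition", {
  set.seed(9)
  rec <- raw_recording("S01", 50,
                       list(acc_x = rnorm(400), acc_y = rnorm(400),
                            acc_z = rnorm(400)),
                       rep("walk", 400))
  wins <- segment_windows(rec, window_spec(4.2, 1.4))
  fs <- featurize(wins)
  ref <- t(vapply(wins, function(w) {
    unlist(lapply(derive_signals(w$samples), extract_features),
           use.names = FALSE)
  }, numeric(210)))
  expect_equal(unname(fs$x), unname(ref), tolerance = 1e-10)
  # determinism: windows with identical samples give identical rows
  dup <- wins[c(1, 1)]
  dup[[2]]$w <- dup[[1]]$w + 1L
  fs2 <- featurize(dup)
  expect_identical(fs2$x[1, ], fs2$x[2, ])
})

test_that("two sensor triads double the feature count", {
  n <- 300
  set.seed(3)
  chans <- setNames(lapply(1:6, function(i) rnorm(n)),
                    c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"))
  rec <- raw_recording("S01", 50, chans, rep("walk", n))
  fs <- featurize(segment_windows(rec, window_spec(4.2, 1.4)))
  expect_equal(ncol(fs$x), 420)
})

test_that("feature sets round-trip through CSV and bind consistently", {
  fs <- random_fs(10, 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_set(fs, path)
  back <- read_feature_set(path)
  expect_identical(back$label, fs$label)
  expect_identical(back$w, fs$w)
  expect_equal(back$x, fs$x, tolerance = 1e-12)

  both <- fs_bind(list(fs, random_fs(5, 4, seed = 2, subject = "S02")))
  expect_equal(n_windows(both), 15)
  expect_error(fs_bind(list(fs, random_fs(5, 3, seed = 3))), "inconsistent")
})
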