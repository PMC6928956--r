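# Independent brute-force reference implementations used as oracles. These
# are deliberately written with plain loops (and a direct DFT) so they share
# no code with the package's vectorized/compiled paths.

bf_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

bf_extract_features <- function(x, percentiles = c(10, 25, 75, 90), nb = 10) {
  n <- length(x)
  q <- vapply(percentiles / 100, bf_percentile, numeric(1), x = x)
  m <- sum(x) / n
  std <- sqrt(sum((x - m)^2) / (n - 1))
  low <- which(percentiles < 50)
  high <- which(percentiles > 50)
  tsum <- c(vapply(q[low], function(l) sum(x[x < l]), numeric(1)),
            vapply(q[high], function(l) sum(x[x > l]), numeric(1)))
  tsq <- c(vapply(q[low], function(l) sum(x[x < l]^2), numeric(1)),
           vapply(q[high], function(l) sum(x[x > l]^2), numeric(1)))
  cross <- vapply(q, function(l) {
    cnt <- 0
    prev <- 0
    for (v in x) {
      s <- sign(v - l)
      if (s != 0) {
        if (prev != 0 && s != prev) cnt <- cnt + 1
        prev <- s
      }
    }
    cnt
  }, numeric(1))
  mags <- vapply(seq_len(n %/% 2), function(k) {
    ang <- -2 * pi * k * (0:(n - 1)) / n
    sqrt(sum(x * cos(ang))^2 + sum(x * sin(ang))^2)
  }, numeric(1))
  edges <- floor(length(mags) * (0:nb) / nb)
  bands <- vapply(seq_len(nb), function(i) {
    if (edges[i + 1] > edges[i]) sum(mags[(edges[i] + 1):edges[i + 1]]) else 0
  }, numeric(1))
  c(std, min(x), max(x), bf_percentile(x, 0.5), q, tsum, tsq, cross, bands)
}

bf_balanced_accuracy <- function(y_true, y_pred) {
  classes <- unique(y_true)
  total <- 0
  for (cl in classes) {
    hits <- 0
    n_cl <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == cl) {
        n_cl <- n_cl + 1
        if (y_pred[i] == cl) hits <- hits + 1
      }
    }
    total <- total + hits / n_cl
  }
  total / length(classes)
}

bf_soft_vote <- function(members, X) {
  classes <- sort(unique(unlist(lapply(members, `[[`, "class_list"))))
  out <- matrix(0, nrow(X), length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nrow(X))) {
    acc <- setNames(numeric(length(classes)), classes)
    for (mb in members) {
      p <- predict_posterior(mb, X[i, , drop = FALSE])
      for (cl in mb$class_list) acc[cl] <- acc[cl] + p[1, cl]
    }
    acc <- acc / length(members)
    out[i, ] <- acc / sum(acc)
  }
  out
}

# Reference semi-supervised labeling: explicit nearest-query scan per window.
bf_label_semi <- function(w, pred, conf, truth, th, radius) {
  n <- length(w)
  queried <- conf < th
  lab <- pred
  src <- rep("predicted", n)
  lab[queried] <- truth[queried]
  src[queried] <- "queried"
  for (i in which(!queried)) {
    qs <- which(queried)
    if (!length(qs)) next
    d <- abs(w[qs] - w[i])
    ok <- d > 0 & d <= radius
    if (!any(ok)) next
    qs <- qs[ok]
    d <- d[ok]
    best <- qs[order(d, w[qs])][1]
    lab[i] <- truth[best]
    src[i] <- "propagated"
  }
  list(labels = lab, source = src)
}

# --- small fixture builders -------------------------------------------------

tiny_cohort <- function(seed = 1, n_subjects = 3, seconds_per_class = 30) {
  generate_cohort(synthetic_config(n_subjects = n_subjects,
                                   seconds_per_class = seconds_per_class,
                                   seed = seed))
}

tiny_cfg <- function(seed = 1, policy = labeling_policy("semi_supervised"), ...) {
  experiment_config(policy = policy,
                    train = train_config(sfs_max_features = 3),
                    seed = seed, ...)
}

random_fs <- function(n, p, classes = c("a", "b"), seed = NULL,
                      subject = "S01") {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  feature_set(x, sample(classes, n, replace = TRUE), rep(subject, n),
              seq_len(n))
}

# Ensemble of one "custom" member emitting a prescribed posterior matrix for
# a chunk of exactly nrow(post) windows.
fixed_posterior_ensemble <- function(post, classes,
                                     origin = "personal") {
  colnames(post) <- classes
  member <- persohar:::custom_base_model(function(X) {
    post[seq_len(nrow(X)), , drop = FALSE]
  }, classes, origin = origin)
  add_base_model(learnpp_ensemble(), member)
}

# Chunk of n windows with the given confidence for the predicted class "a"
# (remaining mass on "b"), plus truth labels.
confidence_chunk <- function(conf, truth, w = seq_along(conf),
                             subject = "S01") {
  n <- length(conf)
  x <- matrix(seq_len(n), n, 1, dimnames = list(NULL, "f1"))
  feature_set(x, truth, rep(subject, n), w)
}
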