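# Building one base model from a (possibly small) labeled chunk:
# noise-injection augmentation -> bootstrap sampling -> sequential forward
# feature selection -> fit. Personal chunks are small, so augmentation and
# per-replicate resampling keep the three models per chunk from collapsing
# onto the same over-fitted solution.

#' Chunk-training configuration
#'
#' @param n_models_per_chunk base models trained per personal chunk.
#' @param bootstrap_size_rule `"original_size"` draws as many instances as the
#'   raw chunk holds (the default); `"pool_size"` draws as many as the
#'   noise-augmented pool holds.
#' @param noise_copies number of noisy copies R appended per window.
#' @param noise_scale alpha: per-feature noise sd as a fraction of that
#'   feature's within-chunk sd.
#' @param sfs_max_features cap on the number of features selected.
#' @param sfs_folds stratified CV folds used by the SFS wrapper criterion.
#' @param sfs_min_gain minimum balanced-accuracy gain to keep adding features.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_models_per_chunk = 3,
                         bootstrap_size_rule = c("original_size", "pool_size"),
                         noise_copies = 2, noise_scale = 0.1,
                         sfs_max_features = 10, sfs_folds = 3,
                         sfs_min_gain = 0) {
  n_models_per_chunk <- check_count(n_models_per_chunk, "n_models_per_chunk", min = 1)
  bootstrap_size_rule <- match.arg(bootstrap_size_rule)
  noise_copies <- check_count(noise_copies, "noise_copies", min = 0)
  check_scalar_number(noise_scale, "noise_scale", min = 0)
  sfs_max_features <- check_count(sfs_max_features, "sfs_max_features", min = 1)
  sfs_folds <- check_count(sfs_folds, "sfs_folds", min = 2)
  check_scalar_number(sfs_min_gain, "sfs_min_gain")
  structure(list(n_models_per_chunk = n_models_per_chunk,
                 bootstrap_size_rule = bootstrap_size_rule,
                 noise_copies = noise_copies, noise_scale = noise_scale,
                 sfs_max_features = sfs_max_features, sfs_folds = sfs_folds,
                 sfs_min_gain = sfs_min_gain),
            class = "train_config")
}

# optional instrumentation: options(persohar.train_hook = function(step) ...)
train_hook <- function(step) {
  hook <- getOption("persohar.train_hook")
  if (is.function(hook)) hook(step)
  invisible(NULL)
}

#' Augment a chunk with noisy copies of its windows
#'
#' Appends `copies` noisy replicates of every window: replicate features are
#' the originals plus N(0, `scale * sd_f`) noise, where `sd_f` is the
#' feature's standard deviation within the chunk. Labels, subjects and window
#' indices are copied unchanged. Operates in feature space: chunks are
#' augmented after feature extraction, so no re-featurization is needed.
#'
#' @param fs a non-empty `feature_set`.
#' @param copies number of noisy copies R (>= 0).
#' @param scale noise sd as a fraction of the per-feature sd (>= 0).
#' @return A `feature_set` with `(copies + 1) * n` windows, originals first.
#' @export
noise_inject <- function(fs, copies = 2, scale = 0.1) {
  if (!inherits(fs, "feature_set") || n_windows(fs) < 1L) {
    stop_invalid("fs", "must be a non-empty feature_set")
  }
  copies <- check_count(copies, "copies", min = 0)
  check_scalar_number(scale, "scale", min = 0)
  train_hook("noise_inject")
  if (copies == 0L) return(fs)
  n <- n_windows(fs)
  p <- ncol(fs$x)
  sds <- apply(fs$x, 2L, stats::sd)
  sds[!is.finite(sds)] <- 0
  blocks <- vector("list", copies + 1L)
  blocks[[1L]] <- fs$x
  for (r in seq_len(copies)) {
    noise <- matrix(rnorm(n * p), nrow = n, ncol = p)
    blocks[[r + 1L]] <- fs$x + noise * rep(scale * sds, each = n)
  }
  structure(
    list(x = do.call(rbind, blocks),
         label = rep(fs$label, copies + 1L),
         subject_id = rep(fs$subject_id, copies + 1L),
         w = rep(fs$w, copies + 1L)),
    class = "feature_set"
  )
}

#' Bootstrap-sample windows from a pool
#'
#' Draws `size` windows uniformly with replacement; each drawn row keeps its
#' original stream-order index.
#'
#' @param fs a non-empty `feature_set`.
#' @param size number of draws (>= 1).
#' @return A `feature_set` of `size` windows.
#' @export
bootstrap_sample <- function(fs, size) {
  if (!inherits(fs, "feature_set") || n_windows(fs) < 1L) {
    stop("contract error: pool must be a non-empty feature_set", call. = FALSE)
  }
  size <- check_count(size, "size", min = 1)
  train_hook("bootstrap_sample")
  idx <- sample.int(n_windows(fs), size, replace = TRUE)
  structure(
    list(x = fs$x[idx, , drop = FALSE], label = fs$label[idx],
         subject_id = fs$subject_id[idx], w = fs$w[idx]),
    class = "feature_set"
  )
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin over the folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# balanced accuracy from integer-coded truth/prediction over K classes,
# averaging recall over classes present in the truth
ba_int <- function(truth, pred, K) {
  den <- tabulate(truth, K)
  num <- tabulate(truth[truth == pred], K)
  mean((num / den)[den > 0L])
}

# Gaussian-discriminant CV scorer for the SFS wrapper. Per fold it caches the
# training-side class counts, means, per-class crossproducts and (for LDA) the
# pooled within-class scatter over ALL features once; scoring a candidate
# subset then only subsets these moments, so the per-candidate cost does not
# depend on n. Classifier structure (shared vs per-class shrunk covariance)
# matches fit_base's LDA/QDA.
make_gaussian_scorer <- function(X, y, fold, kind, lambda) {
  K <- nlevels(y)
  p <- ncol(X)
  nf <- max(fold)
  yi <- as.integer(y)

  tot_n <- tabulate(yi, K)
  tot_s <- matrix(0, K, p)
  tot_C <- vector("list", K)
  fold_n <- matrix(0L, nf, K)
  fold_s <- lapply(seq_len(nf), function(f) matrix(0, K, p))
  fold_C <- lapply(seq_len(nf), function(f) vector("list", K))
  for (c in seq_len(K)) {
    tot_C[[c]] <- matrix(0, p, p)
    for (f in seq_len(nf)) {
      Xi <- X[yi == c & fold == f, , drop = FALSE]
      fold_n[f, c] <- nrow(Xi)
      if (nrow(Xi)) {
        fold_s[[f]][c, ] <- colSums(Xi)
        fold_C[[f]][[c]] <- crossprod(Xi)
      } else {
        fold_C[[f]][[c]] <- matrix(0, p, p)
      }
      tot_s[c, ] <- tot_s[c, ] + fold_s[[f]][c, ]
      tot_C[[c]] <- tot_C[[c]] + fold_C[[f]][[c]]
    }
  }

  min_train <- if (kind == "qda") 2L else 1L
  folds <- lapply(seq_len(nf), function(f) {
    tn <- tot_n - fold_n[f, ]
    pres <- which(tn >= min_train)
    M <- (tot_s - fold_s[[f]]) / pmax(tn, 1L)        # K x p class means
    tC <- lapply(seq_len(K), function(c) tot_C[[c]] - fold_C[[f]][[c]])
    SW <- NULL
    if (kind == "lda") {
      SW <- matrix(0, p, p)
      for (c in pres) SW <- SW + tC[[c]] - tn[c] * tcrossprod(M[c, ])
    }
    list(tn = tn, pres = pres, M = M, tC = tC, SW = SW,
         logprior = log(tn[pres] / sum(tn[pres])),
         Xtest = X[fold == f, , drop = FALSE],
         ytest = yi[fold == f])
  })

  score_qda <- function(fd, Fidx) {
    q <- length(Fidx)
    Xt <- fd$Xtest[, Fidx, drop = FALSE]
    LL <- matrix(-Inf, nrow(Xt), length(fd$pres))
    for (j in seq_along(fd$pres)) {
      c <- fd$pres[j]
      m <- fd$M[c, Fidx]
      S <- (fd$tC[[c]][Fidx, Fidx, drop = FALSE] - fd$tn[c] * tcrossprod(m)) /
        (fd$tn[c] - 1L)
      S <- shrink_cov(S, lambda)
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) next
      centered <- t(Xt) - m
      maha <- colSums(backsolve(ch, centered, transpose = TRUE)^2)
      LL[, j] <- -0.5 * maha - sum(log(diag(ch))) + fd$logprior[j]
    }
    ba_int(fd$ytest, fd$pres[max.col(LL, ties.method = "first")], K)
  }

  if (kind == "lda") {
    # compiled candidate loop: rebuilds the LDA discriminant for every
    # candidate subset from the cached fold moments
    function(selected, candidates) {
      sums <- numeric(length(candidates))
      for (fd in folds) {
        denom <- max(sum(fd$tn[fd$pres]) - length(fd$pres), 1L)
        sums <- sums + lda_score_candidates(
          fd$SW, fd$M[fd$pres, , drop = FALSE], fd$logprior, fd$Xtest,
          as.integer(fd$ytest), as.integer(fd$pres), K,
          as.integer(selected), as.integer(candidates), denom)
      }
      sums / nf
    }
  } else {
    function(selected, candidates) {
      sums <- numeric(length(candidates))
      for (fd in folds) {
        for (ci in seq_along(candidates)) {
          sums[ci] <- sums[ci] + score_qda(fd, c(selected, candidates[ci]))
        }
      }
      sums / nf
    }
  }
}

# CART CV scorer: refits rpart per candidate per fold. Only sensible for
# small chunks / feature counts; the Gaussian kinds use the moment cache.
make_cart_scorer <- function(X, y, fold, control) {
  nf <- max(fold)
  K <- nlevels(y)
  yi <- as.integer(y)
  rc <- rpart::rpart.control(maxdepth = control$cart_maxdepth,
                             minbucket = control$cart_minbucket,
                             minsplit = 2L * control$cart_minbucket,
                             cp = 0, xval = 0)
  function(selected, candidates) {
    sums <- numeric(length(candidates))
    for (f in seq_len(nf)) {
      tr <- fold != f
      for (ci in seq_along(candidates)) {
        Fidx <- c(selected, candidates[ci])
        df <- as.data.frame(X[tr, Fidx, drop = FALSE])
        names(df) <- paste0("f", seq_along(Fidx))
        df$.y <- y[tr]
        fit <- rpart::rpart(.y ~ ., data = df, method = "class", control = rc)
        nd <- as.data.frame(X[!tr, Fidx, drop = FALSE])
        names(nd) <- paste0("f", seq_along(Fidx))
        pred <- as.integer(stats::predict(fit, nd, type = "class"))
        sums[ci] <- sums[ci] + ba_int(yi[!tr], pred, K)
      }
    }
    sums / nf
  }
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: starting from the empty set, repeatedly add the
#' feature that maximizes the mean stratified k-fold CV balanced accuracy of
#' the candidate classifier; stop when the gain drops to `sfs_min_gain` or
#' below, or when `sfs_max_features` is reached. Score ties go to the
#' smallest feature index. At least one feature is always returned.
#'
#' @param X numeric feature matrix.
#' @param y class labels (>= 2 classes; `n >= 2 * sfs_folds`).
#' @param kind base classifier kind used as the wrapper criterion.
#' @param cfg a [train_config()].
#' @param control a [base_control()] (shrinkage / tree options for the
#'   wrapper classifier).
#' @return Integer vector of selected feature indices, in selection order.
#' @export
sfs_select <- function(X, y, kind = c("lda", "qda", "cart"),
                       cfg = train_config(), control = base_control()) {
  kind <- match.arg(kind)
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) {
    stop("training error: degenerate labels for feature selection", call. = FALSE)
  }
  if (nrow(X) < 2L * cfg$sfs_folds) {
    stop("training error: too few samples for the CV wrapper", call. = FALSE)
  }
  train_hook("sfs_select")
  fold <- stratified_folds(y, cfg$sfs_folds)
  scorer <- if (kind == "cart") {
    make_cart_scorer(X, y, fold, control)
  } else {
    make_gaussian_scorer(X, y, fold, kind, control$qda_shrinkage)
  }
  selected <- integer(0)
  remaining <- seq_len(ncol(X))
  current <- 0
  while (length(selected) < cfg$sfs_max_features && length(remaining)) {
    scores <- scorer(selected, remaining)
    best <- which.max(scores)  # ties -> first, i.e. smallest index
    if (length(selected) >= 1L && scores[best] - current <= cfg$sfs_min_gain) break
    selected <- c(selected, remaining[best])
    current <- scores[best]
    remaining <- remaining[-best]
  }
  selected
}

#' Train one base model from a labeled chunk or pool
#'
#' Personal chunks follow inject -> sample -> select -> fit: the chunk is
#' augmented with noisy copies, a bootstrap sample is drawn (sized per
#' `bootstrap_size_rule`), SFS picks the features and [fit_base()] fits the
#' model. User-independent pools skip noise injection and bootstrap as many
#' instances as the pool holds.
#'
#' @param chunk a `labeled_chunk` (its assigned labels are used) or a
#'   `feature_set` (its true labels are used).
#' @param kind base classifier kind.
#' @param origin `"personal"` or `"user_independent"`.
#' @param cfg a [train_config()].
#' @param seed optional integer; if given, seeds this model's private RNG
#'   stream so training is bit-reproducible.
#' @param control a [base_control()].
#' @return A fitted `base_model` carrying `origin` and `selected_features`.
#' @export
train_base_model <- function(chunk, kind = c("lda", "qda", "cart"),
                             origin = c("personal", "user_independent"),
                             cfg = train_config(), seed = NULL,
                             control = base_control()) {
  kind <- match.arg(kind)
  origin <- match.arg(origin)
  if (inherits(chunk, "labeled_chunk")) {
    fs <- chunk$features
    y <- chunk$labels
  } else if (inherits(chunk, "feature_set")) {
    fs <- chunk
    y <- fs$label
  } else {
    stop_invalid("chunk", "must be a labeled_chunk or feature_set")
  }
  if (length(unique(y)) < 2L) {
    stop("training error: degenerate chunk (single-class labels)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fs_train <- structure(list(x = fs$x, label = y, subject_id = fs$subject_id,
                             w = fs$w), class = "feature_set")
  if (origin == "personal") {
    n_orig <- n_windows(fs_train)
    aug <- noise_inject(fs_train, cfg$noise_copies, cfg$noise_scale)
    size <- if (cfg$bootstrap_size_rule == "original_size") n_orig else n_windows(aug)
    boot <- bootstrap_sample(aug, size)
  } else {
    boot <- bootstrap_sample(fs_train, n_windows(fs_train))
  }
  sel <- sfs_select(boot$x, boot$label, kind, cfg, control)
  train_hook("fit_base")
  fit_base(kind, boot$x, boot$label, selected_features = sel,
           origin = origin, control = control)
}
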