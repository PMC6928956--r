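# Base classifiers with a uniform posterior-producing contract. LDA wraps
# MASS::lda; QDA is a shrinkage-regularized Gaussian discriminant (small noisy
# personal chunks routinely make raw per-class covariances singular); CART
# wraps rpart with Laplace-smoothed leaf proportions so posteriors are never
# exactly 0/1 and confidence thresholds keep their meaning.

#' Options for base-model fitting
#'
#' @param qda_shrinkage shrinkage weight lambda in `[0, 1]` applied as
#'   `(1 - lambda) * Sigma_c + lambda * diag(Sigma_c)` per class.
#' @param cart_maxdepth maximum tree depth.
#' @param cart_minbucket minimum samples per leaf.
#' @return An object of class `base_control`.
#' @export
base_control <- function(qda_shrinkage = 0.1, cart_maxdepth = 6, cart_minbucket = 3) {
  check_scalar_number(qda_shrinkage, "qda_shrinkage", min = 0)
  if (qda_shrinkage > 1) stop_invalid("qda_shrinkage", "must be in [0, 1]")
  cart_maxdepth <- check_count(cart_maxdepth, "cart_maxdepth", min = 1)
  cart_minbucket <- check_count(cart_minbucket, "cart_minbucket", min = 1)
  structure(list(qda_shrinkage = qda_shrinkage, cart_maxdepth = cart_maxdepth,
                 cart_minbucket = cart_minbucket),
            class = "base_control")
}

# shrunk, ridge-stabilized per-class covariance
shrink_cov <- function(S, lambda) {
  S <- (1 - lambda) * S + lambda * diag(diag(S), nrow(S))
  S + diag(1e-8 * (mean(diag(S)) + 1e-12), nrow(S))
}

fit_qda_gaussian <- function(X, y, lambda) {
  n <- nrow(X)
  per_class <- lapply(levels(y), function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    ni <- nrow(Xi)
    if (ni < 2L) {
      stop(sprintf("training error: class '%s' has %d sample(s); QDA needs >= 2 per class",
                   cl, ni), call. = FALSE)
    }
    S <- shrink_cov(stats::cov(Xi), lambda)
    R <- chol(S)
    list(mean = colMeans(Xi), chol = R, logdet = 2 * sum(log(diag(R))),
         logprior = log(ni / n))
  })
  names(per_class) <- levels(y)
  per_class
}

predict_qda_gaussian <- function(fit, X) {
  loglik <- vapply(fit, function(cl) {
    centered <- t(X) - cl$mean
    maha <- colSums(backsolve(cl$chol, centered, transpose = TRUE)^2)
    -0.5 * maha - 0.5 * cl$logdet + cl$logprior
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) loglik <- matrix(loglik, nrow = 1L)
  m <- apply(loglik, 1L, max)
  p <- exp(loglik - m)
  p / rowSums(p)
}

#' Fit a base classifier
#'
#' Trains one weak base model of the requested kind on the feature columns in
#' `selected_features`, storing the selection so that later predictions can be
#' fed the full feature matrix. Class priors are estimated from training
#' frequencies for all kinds.
#'
#' @param kind one of `"lda"`, `"qda"`, `"cart"`.
#' @param X numeric feature matrix (windows x all features).
#' @param y class labels (>= 2 distinct values).
#' @param selected_features ordered integer indices into the columns of `X`;
#'   `NULL` uses all columns.
#' @param origin `"user_independent"` or `"personal"`.
#' @param control a [base_control()].
#' @return An object of class `base_model` exposing [predict_posterior()].
#' @export
fit_base <- function(kind = c("lda", "qda", "cart"), X, y,
                     selected_features = NULL,
                     origin = c("user_independent", "personal"),
                     control = base_control()) {
  kind <- match.arg(kind)
  origin <- match.arg(origin)
  if (!is.matrix(X) || !is.numeric(X)) stop_invalid("X", "must be a numeric matrix")
  y <- factor(as.character(y))
  if (length(y) != nrow(X)) stop_invalid("y", "must match the rows of X")
  if (nrow(X) < 2L) stop("training error: need at least 2 samples", call. = FALSE)
  if (nlevels(y) < 2L) {
    stop("training error: degenerate chunk (single-class labels)", call. = FALSE)
  }
  if (nrow(X) < nlevels(y)) {
    stop("training error: fewer samples than classes", call. = FALSE)
  }
  sel <- selected_features %||% seq_len(ncol(X))
  sel <- as.integer(sel)
  if (length(sel) < 1L || anyDuplicated(sel) ||
      any(sel < 1L | sel > ncol(X))) {
    stop_invalid("selected_features", "must be unique in-range column indices")
  }
  Xs <- X[, sel, drop = FALSE]

  fit <- switch(kind,
    lda = MASS::lda(Xs, grouping = y),
    qda = fit_qda_gaussian(Xs, y, control$qda_shrinkage),
    cart = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_along(sel))
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = control$cart_maxdepth,
                     minbucket = control$cart_minbucket,
                     minsplit = 2L * control$cart_minbucket,
                     cp = 0, xval = 0))
    })

  structure(
    list(kind = kind, origin = origin, selected_features = sel,
         class_list = levels(y), n_features_total = ncol(X),
         control = control, fit = fit),
    class = "base_model"
  )
}

#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model> %s (%s), %d selected feature(s), classes: %s\n",
              toupper(x$kind), x$origin, length(x$selected_features),
              paste(x$class_list, collapse = ", ")))
  invisible(x)
}

# Internal: a base model whose posteriors come from a user-supplied function
# of the full feature matrix. Used to build ensembles with exactly controlled
# confidences in tests and diagnostics.
custom_base_model <- function(posterior_fn, class_list,
                              origin = c("personal", "user_independent")) {
  origin <- match.arg(origin)
  structure(
    list(kind = "custom", origin = origin, selected_features = NA_integer_,
         class_list = class_list, n_features_total = NA_integer_,
         control = NULL, fit = list(posterior_fn = posterior_fn)),
    class = "base_model"
  )
}

#' Posterior class probabilities of a base model
#'
#' Accepts the full feature matrix (or a single feature vector); the model
#' applies its own `selected_features` subset. Returns a valid probability
#' vector per row over the model's `class_list`; the hard prediction is its
#' argmax.
#'
#' @param model a `base_model`.
#' @param X numeric matrix (rows = windows) or a single feature vector, with
#'   as many columns as the matrix the model was fitted on.
#' @return Numeric matrix `nrow(X) x length(class_list)`, rows summing to 1.
#' @export
predict_posterior <- function(model, X) {
  if (!inherits(model, "base_model")) stop_invalid("model", "must be a base_model")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (!is.na(model$n_features_total) && ncol(X) != model$n_features_total) {
    stop(sprintf("contract error: model expects %d features, got %d",
                 model$n_features_total, ncol(X)), call. = FALSE)
  }
  K <- length(model$class_list)
  post <- switch(model$kind,
    lda = {
      Xs <- X[, model$selected_features, drop = FALSE]
      stats::predict(model$fit, Xs)$posterior
    },
    qda = predict_qda_gaussian(model$fit,
                               X[, model$selected_features, drop = FALSE]),
    cart = {
      df <- as.data.frame(X[, model$selected_features, drop = FALSE])
      names(df) <- paste0("f", seq_along(model$selected_features))
      single <- nrow(df) == 1L  # predict.rpart(type = "matrix") needs >= 2 rows
      if (single) df <- df[c(1L, 1L), , drop = FALSE]
      m <- stats::predict(model$fit, df, type = "matrix")
      counts <- m[, 2L:(K + 1L), drop = FALSE]
      post <- (counts + 1) / (rowSums(counts) + K)
      if (single) post[1L, , drop = FALSE] else post
    },
    custom = model$fit$posterior_fn(X),
    stop_invalid("model$kind", "unknown base model kind"))
  post <- matrix(as.numeric(post), nrow = nrow(X), ncol = K)
  post <- post / rowSums(post)
  colnames(post) <- model$class_list
  post
}
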