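# Learn++-style incremental ensemble: base models accumulate chunk by chunk
# (append-only) and are combined by equal-weight soft voting. The original
# Learn++ error-based member weighting is deliberately not used: with
# non-supervised and semi-supervised labeling there are no trustworthy labels
# to estimate member accuracies from, so every member gets weight 1/m.

#' Create an empty incremental ensemble
#'
#' @return An object of class `learnpp_ensemble` with no members.
#' @export
learnpp_ensemble <- function() {
  structure(list(members = list()), class = "learnpp_ensemble")
}

#' Number of ensemble members
#' @param ens a `learnpp_ensemble`.
#' @return Integer count.
#' @export
n_members <- function(ens) length(ens$members)

#' Equal member weights
#' @param ens a non-empty `learnpp_ensemble`.
#' @return Numeric vector of `1/m` repeated `m` times.
#' @export
ensemble_weights <- function(ens) {
  m <- n_members(ens)
  if (m < 1L) stop("contract error: ensemble has no members", call. = FALSE)
  rep(1 / m, m)
}

#' Union of member class lists, sorted lexicographically
#' @param ens a `learnpp_ensemble`.
#' @return Character vector of class labels.
#' @export
ensemble_classes <- function(ens) {
  sort(unique(unlist(lapply(ens$members, `[[`, "class_list"))))
}

#' Append a fitted base model to the ensemble
#'
#' Growth is append-only: members are never removed or re-weighted
#' individually; adding a member rebalances all weights to uniform.
#'
#' @param ens a `learnpp_ensemble`.
#' @param model a fitted `base_model`.
#' @return The grown ensemble.
#' @export
add_base_model <- function(ens, model) {
  if (!inherits(ens, "learnpp_ensemble")) {
    stop_invalid("ens", "must be a learnpp_ensemble")
  }
  if (!inherits(model, "base_model") || is.null(model$fit)) {
    stop("contract error: model must be a fitted base_model", call. = FALSE)
  }
  ens$members[[n_members(ens) + 1L]] <- model
  ens
}

#' Does the ensemble contain any personal member?
#'
#' Drives the dual-threshold rule of the semi-supervised labeling policy:
#' user-independent-only ensembles produce optimistic posteriors and get the
#' high threshold, ensembles with at least one personal member the low one.
#'
#' @param ens a `learnpp_ensemble`.
#' @return `TRUE` iff any member has origin `"personal"`; `FALSE` for an
#'   empty ensemble.
#' @export
has_personal <- function(ens) {
  any(vapply(ens$members, function(m) identical(m$origin, "personal"), logical(1)))
}

#' Equal-weight soft-vote posterior of the ensemble
#'
#' Each member's posterior is embedded into the global class list (zero for
#' classes the member does not know, so its probability mass stays on what it
#' was trained to see) and the embedded posteriors are averaged with equal
#' weights, then renormalized.
#'
#' @param ens a non-empty `learnpp_ensemble`.
#' @param X feature matrix (or single feature vector).
#' @return Matrix `nrow(X) x n_classes` of row-stochastic posteriors over
#'   [ensemble_classes()].
#' @export
ensemble_posterior <- function(ens, X) {
  m <- n_members(ens)
  if (m < 1L) stop("contract error: ensemble has no members", call. = FALSE)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  classes <- ensemble_classes(ens)
  acc <- matrix(0, nrow = nrow(X), ncol = length(classes),
                dimnames = list(NULL, classes))
  for (member in ens$members) {
    p <- predict_posterior(member, X)
    acc[, match(member$class_list, classes)] <-
      acc[, match(member$class_list, classes), drop = FALSE] + p
  }
  acc <- acc / m
  acc / rowSums(acc)
}

#' Predict labels and confidences with the ensemble
#'
#' The hard label is the argmax of the soft-vote posterior (ties broken by
#' lexicographic class order) and the confidence is the maximum posterior
#' entry — the quantity the semi-supervised labeling policy thresholds.
#'
#' @param object a non-empty `learnpp_ensemble`.
#' @param X feature matrix (rows = windows) or single feature vector.
#' @param ... unused.
#' @return An object of class `ensemble_prediction`: list with `label`
#'   (character), `confidence` (numeric, `max(posterior)` per row) and
#'   `posterior` (matrix).
#' @export
predict.learnpp_ensemble <- function(object, X, ...) {
  post <- ensemble_posterior(object, X)
  j <- max.col(post, ties.method = "first")
  structure(
    list(label = colnames(post)[j],
         confidence = post[cbind(seq_len(nrow(post)), j)],
         posterior = post),
    class = "ensemble_prediction"
  )
}

#' @export
print.learnpp_ensemble <- function(x, ...) {
  origins <- vapply(x$members, `[[`, character(1), "origin")
  cat(sprintf("<learnpp_ensemble> %d member(s): %d user-independent, %d personal\n",
              n_members(x), sum(origins == "user_independent"),
              sum(origins == "personal")))
  invisible(x)
}

#' Save / load an ensemble
#'
#' Versioned package serialization; not a public file format.
#'
#' @param ens a `learnpp_ensemble`.
#' @param path file path.
#' @return `save_ensemble` invisibly returns `path`; `load_ensemble` returns
#'   the ensemble.
#' @export
save_ensemble <- function(ens, path) {
  if (!inherits(ens, "learnpp_ensemble")) {
    stop_invalid("ens", "must be a learnpp_ensemble")
  }
  saveRDS(list(format = "persohar_ensemble", version = 1L, ensemble = ens), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "persohar_ensemble")) {
    stop(sprintf("format error: %s is not a persohar ensemble file", path),
         call. = FALSE)
  }
  obj$ensemble
}
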