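# Shared internal helpers: argument validation and deterministic seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (strict) {
    if (x <= min) stop_invalid(field, sprintf("must be > %s", min))
  } else if (x < min) {
    stop_invalid(field, sprintf("must be >= %s", min))
  }
  invisible(x)
}

check_count <- function(x, field, min = 0) {
  check_scalar_number(x, field, min = min)
  if (x != as.integer(x)) stop_invalid(field, "must be a whole number")
  as.integer(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

#' Derive a reproducible seed from a tuple of integers
#'
#' Mixes an experiment seed with structural indices (subject, update round,
#' replicate) into a single value strictly below 2^31, so every base model and
#' every synthetic subject gets its own reproducible pseudo-random stream that
#' does not depend on iteration order.
#'
#' @param ... integers identifying the stream (seed first, then indices).
#' @return A single integer suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, 4, 2, 3)
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  if (length(parts) == 0L || any(!is.finite(parts))) {
    stop_invalid("...", "seed components must be finite numbers")
  }
  s <- 104729
  for (v in parts) s <- (s * 69069 + abs(v) + 1) %% 2147483629
  as.integer(s)
}
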