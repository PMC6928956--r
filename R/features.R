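# Per-window feature bank: derived signals (magnitude + pairwise magnitudes
# per sensor triad) expanded into order statistics, tail sums, level-crossing
# counts and banded Fourier magnitude sums.

#' Feature extraction configuration
#'
#' @param percentiles percentile levels in (0, 100), strictly increasing.
#'   Levels below 50 contribute "below" tail sums, levels above 50 "above"
#'   tail sums; all levels contribute a crossing count. The default
#'   `c(10, 25, 75, 90)` gives the standard 30-feature bank per signal.
#' @param n_freq_bands number of equal contiguous bins the non-negative
#'   (zero-frequency-excluded) FFT magnitude spectrum is summed over.
#' @param include_pairwise add, per triad, the three two-axis magnitudes
#'   `sqrt(a^2 + b^2)`.
#' @param include_magnitude add, per triad, the magnitude `sqrt(x^2+y^2+z^2)`.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(percentiles = c(10, 25, 75, 90), n_freq_bands = 10,
                           include_pairwise = TRUE, include_magnitude = TRUE) {
  if (!is.numeric(percentiles) || length(percentiles) < 1L ||
      any(percentiles <= 0) || any(percentiles >= 100) ||
      any(diff(percentiles) <= 0)) {
    stop_invalid("percentiles", "must be strictly increasing values in (0, 100)")
  }
  n_freq_bands <- check_count(n_freq_bands, "n_freq_bands", min = 1)
  check_flag(include_pairwise, "include_pairwise")
  check_flag(include_magnitude, "include_magnitude")
  structure(list(percentiles = percentiles, n_freq_bands = n_freq_bands,
                 include_pairwise = include_pairwise,
                 include_magnitude = include_magnitude),
            class = "feature_config")
}

longest_common_prefix <- function(nms) {
  p <- nms[1]
  for (nm in nms[-1]) {
    while (nzchar(p) && substr(nm, 1, nchar(p)) != p) {
      p <- substr(p, 1, nchar(p) - 1L)
    }
  }
  sub("[._-]+$", "", p)
}

#' Expand raw channels into derived signals
#'
#' Channels are grouped into sensor triads (x, y, z) of three consecutive
#' channels. Per triad the output contains the three raw axes, the triad
#' magnitude `sqrt(x^2+y^2+z^2)` (if `include_magnitude`) and the three
#' pairwise magnitudes `sqrt(a^2+b^2)` (if `include_pairwise`) - seven derived
#' signals per triad with the defaults.
#'
#' @param samples named list of equal-length numeric vectors (one per channel).
#' @param cfg a [feature_config()].
#' @return Named list of derived signals.
#' @export
derive_signals <- function(samples, cfg = feature_config()) {
  if (!cfg$include_magnitude && !cfg$include_pairwise) return(samples)
  k <- length(samples)
  if (k %% 3L != 0L) {
    stop(sprintf("configuration error: %d channel(s) cannot be grouped into (x,y,z) triads; triad features need a multiple of 3", k),
         call. = FALSE)
  }
  out <- list()
  for (t in seq_len(k %/% 3L)) {
    tri <- samples[(3L * t - 2L):(3L * t)]
    prefix <- longest_common_prefix(names(tri))
    if (!nzchar(prefix)) prefix <- paste0("t", t)
    out <- c(out, tri)
    if (cfg$include_magnitude) {
      out[[paste0(prefix, "_mag")]] <-
        sqrt(tri[[1]]^2 + tri[[2]]^2 + tri[[3]]^2)
    }
    if (cfg$include_pairwise) {
      out[[paste0(prefix, "_xy")]] <- sqrt(tri[[1]]^2 + tri[[2]]^2)
      out[[paste0(prefix, "_xz")]] <- sqrt(tri[[1]]^2 + tri[[3]]^2)
      out[[paste0(prefix, "_yz")]] <- sqrt(tri[[2]]^2 + tri[[3]]^2)
    }
  }
  out
}

# Number of sign changes of (x - level); zeros carry the previous nonzero
# sign, which is equivalent to dropping them before counting changes.
count_level_crossings <- function(x, level) {
  s <- sign(x - level)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Per-signal feature sub-vector
#'
#' Computes, in fixed order: standard deviation, min, max, median; the
#' configured percentiles (linear interpolation, R type 7); sums of values
#' below each low percentile and above each high percentile; the analogous
#' square sums; level-crossing counts of every percentile; and sums of the
#' magnitude spectrum over `n_freq_bands` equal contiguous bins of the
#' non-negative-frequency FFT magnitudes, excluding the zero-frequency term.
#' 30 features per signal with the default configuration.
#'
#' @param x numeric sequence of length >= 2.
#' @param cfg a [feature_config()].
#' @return Named numeric feature vector.
#' @export
extract_features <- function(x, cfg = feature_config()) {
  if (length(x) < 2L) stop_invalid("x", "needs at least 2 samples")
  if (any(!is.finite(x))) {
    stop("data error: signal contains non-finite values", call. = FALSE)
  }
  q <- stats::quantile(x, probs = cfg$percentiles / 100, names = FALSE, type = 7)
  low <- cfg$percentiles < 50
  high <- cfg$percentiles > 50

  tail_sum <- c(
    vapply(q[low], function(l) sum(x[x < l]), numeric(1)),
    vapply(q[high], function(l) sum(x[x > l]), numeric(1))
  )
  tail_sqsum <- c(
    vapply(q[low], function(l) sum(x[x < l]^2), numeric(1)),
    vapply(q[high], function(l) sum(x[x > l]^2), numeric(1))
  )
  crossings <- vapply(q, function(l) as.numeric(count_level_crossings(x, l)),
                      numeric(1))

  mag <- Mod(stats::fft(x))
  pos <- mag[seq(2L, length.out = length(x) %/% 2L)]
  nb <- cfg$n_freq_bands
  edges <- floor(length(pos) * (0:nb) / nb)
  bands <- vapply(seq_len(nb), function(i) {
    if (edges[i + 1L] > edges[i]) sum(pos[(edges[i] + 1L):edges[i + 1L]]) else 0
  }, numeric(1))

  vals <- c(sd(x), min(x), max(x), median(x), q, tail_sum, tail_sqsum,
            crossings, bands)
  names(vals) <- c(
    "std", "min", "max", "median",
    paste0("p", cfg$percentiles),
    paste0("sum_below_p", cfg$percentiles[low]),
    paste0("sum_above_p", cfg$percentiles[high]),
    paste0("sqsum_below_p", cfg$percentiles[low]),
    paste0("sqsum_above_p", cfg$percentiles[high]),
    paste0("cross_p", cfg$percentiles),
    sprintf("band%02d", seq_len(nb))
  )
  vals
}

#' A set of feature windows
#'
#' Thin container pairing a numeric feature matrix with per-window metadata.
#' Rows are windows in stream order; `w` indices are strictly increasing
#' within a subject.
#'
#' @param x numeric feature matrix (windows x features) with column names.
#' @param label per-window class labels.
#' @param subject_id per-window subject ids.
#' @param w per-window stream-order indices.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(x, label, subject_id, w) {
  if (!is.matrix(x) || !is.numeric(x) || is.null(colnames(x))) {
    stop_invalid("x", "must be a numeric matrix with column names")
  }
  n <- nrow(x)
  label <- as.character(label)
  subject_id <- as.character(subject_id)
  w <- as.integer(w)
  if (length(label) != n || length(subject_id) != n || length(w) != n) {
    stop_invalid("label", "metadata must match the number of rows")
  }
  for (s in unique(subject_id)) {
    if (is.unsorted(w[subject_id == s], strictly = TRUE)) {
      stop_invalid("w", "indices must be strictly increasing within a subject")
    }
  }
  structure(list(x = x, label = label, subject_id = subject_id, w = w),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d windows x %d features, %d subject(s), classes: %s\n",
              nrow(x$x), ncol(x$x), length(unique(x$subject_id)),
              paste(sort(unique(x$label)), collapse = ", ")))
  invisible(x)
}

#' Number of windows in a feature set
#' @param fs a `feature_set`.
#' @return Integer count.
#' @export
n_windows <- function(fs) nrow(fs$x)

#' Subset a feature set by row
#' @param fs a `feature_set`.
#' @param idx row indices (logical or integer).
#' @return A `feature_set` with the selected windows.
#' @export
fs_subset <- function(fs, idx) {
  feature_set(fs$x[idx, , drop = FALSE], fs$label[idx],
              fs$subject_id[idx], fs$w[idx])
}

#' Bind feature sets row-wise
#'
#' All sets must share an identical feature-name vector.
#'
#' @param sets list of `feature_set` objects.
#' @return A single `feature_set`.
#' @export
fs_bind <- function(sets) {
  stopifnot(length(sets) >= 1L)
  nm <- colnames(sets[[1]]$x)
  for (s in sets) {
    if (!identical(colnames(s$x), nm)) {
      stop("data error: feature sets have inconsistent feature names", call. = FALSE)
    }
  }
  feature_set(do.call(rbind, lapply(sets, `[[`, "x")),
              unlist(lapply(sets, `[[`, "label"), use.names = FALSE),
              unlist(lapply(sets, `[[`, "subject_id"), use.names = FALSE),
              unlist(lapply(sets, `[[`, "w"), use.names = FALSE))
}

per_signal_feature_names <- function(cfg) {
  p <- cfg$percentiles
  low <- p[p < 50]
  high <- p[p > 50]
  c("std", "min", "max", "median", paste0("p", p),
    paste0("sum_below_p", low), paste0("sum_above_p", high),
    paste0("sqsum_below_p", low), paste0("sqsum_above_p", high),
    paste0("cross_p", p), sprintf("band%02d", seq_len(cfg$n_freq_bands)))
}

# Banded Fourier magnitude sums for a batch of signals (columns of xmat):
# non-negative frequencies excluding the zero term, split into n_freq_bands
# equal contiguous bins and summed. Matches the band block of
# extract_features() exactly (mvfft computes the same per-column DFT).
band_features_batch <- function(xmat, nb) {
  m <- nrow(xmat) %/% 2L
  mag <- Mod(stats::mvfft(xmat))
  pos <- mag[seq(2L, length.out = m), , drop = FALSE]
  edges <- floor(m * (0:nb) / nb)
  out <- matrix(0, ncol(xmat), nb)
  for (i in seq_len(nb)) {
    if (edges[i + 1L] > edges[i]) {
      out[, i] <- colSums(pos[(edges[i] + 1L):edges[i + 1L], , drop = FALSE])
    }
  }
  out
}

#' Compute the feature bank for a list of windows
#'
#' Expands every window with [derive_signals()] and computes the
#' [extract_features()] bank for each derived signal, concatenated in fixed
#' signal order. A 3-channel triad with the default configuration yields 7
#' signals x 30 features = 210 features per window. The computation is
#' batched per signal through a compiled kernel; it agrees with composing
#' [extract_features()] window by window.
#'
#' @param windows list of `sensor_window` objects (from [segment_windows()]).
#' @param cfg a [feature_config()].
#' @return A [feature_set()].
#' @export
featurize <- function(windows, cfg = feature_config()) {
  if (length(windows) == 0L) stop_invalid("windows", "must be non-empty")
  ch_names <- names(windows[[1]]$samples)
  n <- length(windows)
  derived1 <- derive_signals(windows[[1]]$samples, cfg)
  sig_names <- names(derived1)
  W <- length(derived1[[1]])
  if (any(!vapply(derived1, function(v) all(is.finite(v)), logical(1)))) {
    stop("data error: signal contains non-finite values (window 1)", call. = FALSE)
  }
  sig_mats <- lapply(sig_names, function(s) matrix(0, W, n))
  names(sig_mats) <- sig_names
  for (s in sig_names) sig_mats[[s]][, 1L] <- derived1[[s]]
  for (i in seq_len(n)[-1L]) {
    win <- windows[[i]]
    if (!identical(names(win$samples), ch_names)) {
      stop("data error: inconsistent channel sets across windows", call. = FALSE)
    }
    derived <- derive_signals(win$samples, cfg)
    for (s in sig_names) {
      v <- derived[[s]]
      if (any(!is.finite(v))) {
        stop(sprintf("data error: signal contains non-finite values (window %d)", i),
             call. = FALSE)
      }
      sig_mats[[s]][, i] <- v
    }
  }
  blocks <- lapply(sig_mats, function(mat) {
    cbind(time_features_batch(mat, cfg$percentiles / 100),
          band_features_batch(mat, cfg$n_freq_bands))
  })
  x <- do.call(cbind, blocks)
  colnames(x) <- unlist(lapply(sig_names, function(s) {
    paste(s, per_signal_feature_names(cfg), sep = ".")
  }), use.names = FALSE)
  feature_set(x,
              label = vapply(windows, `[[`, character(1), "label"),
              subject_id = vapply(windows, `[[`, character(1), "subject_id"),
              w = vapply(windows, function(z) as.integer(z$w), integer(1)))
}

#' Write a feature set to CSV
#'
#' Schema: `subject_id,w,label,<feature_1>,...,<feature_p>`.
#'
#' @param fs a `feature_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_set <- function(fs, path) {
  df <- data.frame(subject_id = fs$subject_id, w = fs$w, label = fs$label,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fs$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature set from CSV
#' @param path CSV path written by [write_feature_set()].
#' @return A `feature_set`.
#' @export
read_feature_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "w", "label")
  if (!all(meta %in% names(df))) {
    stop(sprintf("format error: %s is missing subject_id/w/label columns", path),
         call. = FALSE)
  }
  x <- as.matrix(df[setdiff(names(df), meta)])
  feature_set(x, df$label, df$subject_id, df$w)
}
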