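# Reading/writing labeled sensor recordings and segmenting them into
# fixed-length overlapping windows.

#' A labeled multi-channel sensor recording
#'
#' @param subject_id subject identifier.
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param channels named list of equal-length numeric vectors, one per channel.
#' @param labels per-sample class labels (same length as the channels).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(subject_id, sampling_rate_hz, channels, labels) {
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", min = 0, strict = TRUE)
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop_invalid("channels", "must be a non-empty named list of numeric vectors")
  }
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L) {
    stop_invalid("channels", "all channel sequences must have identical length")
  }
  labels <- as.character(labels)
  if (length(labels) != lens[1]) {
    stop_invalid("labels", "label sequence must match channel length")
  }
  structure(
    list(subject_id = as.character(subject_id)[1],
         sampling_rate_hz = sampling_rate_hz,
         channels = lapply(channels, as.numeric),
         labels = labels),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %d samples x %d channels @ %g Hz, %d classes\n",
              x$subject_id, length(x$labels), length(x$channels),
              x$sampling_rate_hz, length(unique(x$labels))))
  invisible(x)
}

#' Write a recording to CSV
#'
#' Schema: `timestamp,<ch1>,...,<chk>,label,subject_id`, UTF-8, decimal point.
#' Timestamps are seconds from the start of the recording.
#'
#' @param rec a `raw_recording`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  n <- length(rec$labels)
  df <- data.frame(timestamp = (seq_len(n) - 1) / rec$sampling_rate_hz,
                   check.names = FALSE)
  for (nm in names(rec$channels)) df[[nm]] <- rec$channels[[nm]]
  df$label <- rec$labels
  df$subject_id <- rec$subject_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled recording from CSV
#'
#' Expects a header with `timestamp`, one column per channel, `label`, and an
#' optional `subject_id` column. The sampling rate is taken from
#' `sampling_rate_hz` if given, otherwise inferred from the median timestamp
#' spacing.
#'
#' @param path CSV file path.
#' @param channels channel column names in order; `NULL` uses every column
#'   except `timestamp`, `label` and `subject_id`, in file order.
#' @param sampling_rate_hz optional known sampling rate in Hz.
#' @param subject_id optional subject id override; defaults to the file's
#'   `subject_id` column or, failing that, the file name.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path, channels = NULL, sampling_rate_hz = NULL,
                           subject_id = NULL) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop(sprintf("format error reading %s: %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  if (nrow(df) == 0L) stop(sprintf("format error: %s is empty", path), call. = FALSE)
  for (col in c("timestamp", "label")) {
    if (!col %in% names(df)) {
      stop(sprintf("format error: %s is missing required column '%s'", path, col),
           call. = FALSE)
    }
  }
  channels <- channels %||% setdiff(names(df), c("timestamp", "label", "subject_id"))
  missing <- setdiff(channels, names(df))
  if (length(missing)) {
    stop(sprintf("format error: %s is missing channel column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(channels) < 1L) {
    stop(sprintf("format error: %s has no channel columns", path), call. = FALSE)
  }
  ts <- df$timestamp
  if (nrow(df) > 1L && any(diff(ts) <= 0)) {
    stop(sprintf("format error: non-monotone timestamps in %s", path), call. = FALSE)
  }
  rate <- sampling_rate_hz %||%
    (if (nrow(df) > 1L) 1 / stats::median(diff(ts)) else
      stop(sprintf("format error: cannot infer sampling rate from %s", path),
           call. = FALSE))
  sid <- subject_id %||%
    (if ("subject_id" %in% names(df)) as.character(df$subject_id[1]) else
      sub("\\.[^.]*$", "", basename(path)))
  raw_recording(sid, rate, as.list(df[channels]), as.character(df$label))
}

#' Windowing specification
#'
#' @param window_seconds window length in seconds.
#' @param slide_seconds slide between window starts in seconds
#'   (0 < slide <= window).
#' @param min_purity minimum fraction of samples that must carry the window's
#'   majority label for the window to be retained, in (0, 1]. The default 1
#'   drops every window spanning an activity transition; lower it for real
#'   recordings with fuzzy boundaries.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_seconds = 4.2, slide_seconds = 1.4, min_purity = 1) {
  check_scalar_number(window_seconds, "window_seconds", min = 0, strict = TRUE)
  check_scalar_number(slide_seconds, "slide_seconds", min = 0, strict = TRUE)
  if (slide_seconds > window_seconds) {
    stop_invalid("slide_seconds", "must satisfy 0 < slide_seconds <= window_seconds")
  }
  check_scalar_number(min_purity, "min_purity", min = 0, strict = TRUE)
  if (min_purity > 1) stop_invalid("min_purity", "must be in (0, 1]")
  structure(list(window_seconds = window_seconds, slide_seconds = slide_seconds,
                 min_purity = min_purity),
            class = "window_spec")
}

# Majority label with ties broken by the first-occurring class in the window.
modal_label <- function(labels) {
  f <- factor(labels)
  counts <- tabulate(f, nbins = nlevels(f))
  top <- max(counts)
  cands <- levels(f)[counts == top]
  if (length(cands) > 1L) {
    cands <- cands[which.min(match(cands, labels))]
  }
  list(label = cands, purity = top / length(labels))
}

#' Segment a recording into fixed-length overlapping windows
#'
#' Window length is `W = round(window_seconds * rate)` samples and the slide is
#' `d = round(slide_seconds * rate)` samples; windows start at samples
#' 0, d, 2d, ... (0-based, half-open intervals), giving exactly
#' `floor((L - W) / d) + 1` windows for a recording of `L >= W` samples.
#' Each window's label is the majority per-sample label; windows whose purity
#' falls below `spec$min_purity` are dropped and the survivors are re-indexed
#' with consecutive stream-order indices `w = 1, 2, ...`.
#'
#' @param rec a `raw_recording`.
#' @param spec a [window_spec()].
#' @return A list of `sensor_window` objects, each with fields `subject_id`,
#'   `w`, `start_sample`, `end_sample`, `samples` (per-channel list), `label`
#'   and `purity`. A recording shorter than one window yields an empty list
#'   with a warning.
#' @export
segment_windows <- function(rec, spec) {
  if (!inherits(rec, "raw_recording")) stop_invalid("rec", "must be a raw_recording")
  if (!inherits(spec, "window_spec")) stop_invalid("spec", "must be a window_spec")
  W <- as.integer(round(spec$window_seconds * rec$sampling_rate_hz))
  d <- as.integer(round(spec$slide_seconds * rec$sampling_rate_hz))
  if (W < 1L || d < 1L) stop_invalid("spec", "window/slide shorter than one sample")
  L <- length(rec$labels)
  if (L < W) {
    warning(sprintf("recording %s (%d samples) is shorter than one window (%d samples); no windows produced",
                    rec$subject_id, L, W))
    return(list())
  }
  starts <- seq.int(0L, L - W, by = d)
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    idx <- (s + 1L):(s + W)
    m <- modal_label(rec$labels[idx])
    keep[i] <- m$purity >= spec$min_purity
    if (keep[i]) {
      out[[i]] <- structure(
        list(subject_id = rec$subject_id, w = NA_integer_,
             start_sample = s, end_sample = s + W,
             samples = lapply(rec$channels, function(ch) ch[idx]),
             label = m$label, purity = m$purity),
        class = "sensor_window"
      )
    }
  }
  out <- out[keep]
  for (i in seq_along(out)) out[[i]]$w <- i
  out
}
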