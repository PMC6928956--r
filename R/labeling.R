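# Labeling policies for an incoming personal chunk: non-supervised (predicted
# labels only), semi-supervised (predicted labels, but windows predicted with
# low ensemble confidence are queried from the user and the answer is
# propagated to the +-2 neighbouring windows), and supervised (user labels
# everything).

#' Labeling policy for personal chunks
#'
#' In semi-supervised mode the confidence threshold depends on the ensemble's
#' composition: `th_ui` (default 0.95) while the ensemble contains only
#' user-independent members — those produce optimistic posteriors, so few
#' windows fall below even a high cutoff — and `th_personal` (default 0.75)
#' once any personal member exists and posteriors spread out. Thresholds may
#' exceed 1 (up to 1.01) so that "query everything" is expressible with the
#' strict `confidence < th` rule.
#'
#' @param mode `"non_supervised"`, `"semi_supervised"` or `"supervised"`.
#' @param th_ui threshold while the ensemble is user-independent-only.
#' @param th_personal threshold once a personal member exists.
#' @param propagation_radius how many windows on each side of a queried
#'   window inherit its label (default 2).
#' @return An object of class `labeling_policy`.
#' @export
labeling_policy <- function(mode = c("semi_supervised", "non_supervised", "supervised"),
                            th_ui = 0.95, th_personal = 0.75,
                            propagation_radius = 2) {
  mode <- match.arg(mode)
  for (nm in c("th_ui", "th_personal")) {
    v <- get(nm)
    check_scalar_number(v, nm, min = 0)
    if (v > 1.01) stop_invalid(nm, "must be in [0, 1.01]")
  }
  propagation_radius <- check_count(propagation_radius, "propagation_radius", min = 0)
  structure(list(mode = mode, th_ui = th_ui, th_personal = th_personal,
                 propagation_radius = propagation_radius),
            class = "labeling_policy")
}

#' Threshold in effect for a semi-supervised labeling round
#'
#' @param ens a `learnpp_ensemble`.
#' @param policy a semi-supervised [labeling_policy()].
#' @return `policy$th_ui` if the ensemble has no personal member, otherwise
#'   `policy$th_personal`.
#' @export
select_threshold <- function(ens, policy) {
  if (!inherits(policy, "labeling_policy") ||
      !identical(policy$mode, "semi_supervised")) {
    stop("contract error: select_threshold applies only to the semi-supervised policy",
         call. = FALSE)
  }
  if (has_personal(ens)) policy$th_personal else policy$th_ui
}

# Query the oracle for one (subject, window) pair, validating the answer.
oracle_label <- function(oracle, subject_id, w) {
  res <- tryCatch(oracle(subject_id, w), error = function(e) NULL)
  if (is.null(res) || length(res) != 1L || is.na(res)) {
    stop(sprintf("labeling error: oracle failed for subject %s, window %d",
                 subject_id, w), call. = FALSE)
  }
  as.character(res)
}

#' Label a personal chunk under a labeling policy
#'
#' Non-supervised: every window keeps the ensemble prediction. Supervised:
#' every window is labeled by the oracle (query fraction 1). Semi-supervised:
#' windows predicted with `confidence < select_threshold(ens, policy)` are
#' queried from the oracle; each queried window `w` then propagates its oracle
#' label to the in-chunk windows `w-2, w-1, w+1, w+2` (for radius 2) unless
#' those were themselves queried. A window inside the radius of two queried
#' windows takes the label of the nearest one, with distance ties going to the
#' earlier (smaller `w`) query; propagation never crosses chunk boundaries.
#'
#' @param ens a non-empty `learnpp_ensemble`.
#' @param chunk a `feature_set` in stream order (strictly increasing `w`).
#' @param policy a [labeling_policy()].
#' @param oracle a function `(subject_id, w) -> label` providing the true
#'   label; required unless `policy$mode == "non_supervised"`.
#' @return An object of class `labeled_chunk`: list with `features` (the
#'   chunk), `labels` (assigned labels), `source` (per window: `"predicted"`,
#'   `"queried"` or `"propagated"`), `threshold` (the value applied, `NA`
#'   outside semi-supervised mode), `query_fraction` (queried / n) and
#'   `replaced_fraction` ((queried + propagated) / n).
#' @export
label_chunk <- function(ens, chunk, policy, oracle = NULL) {
  if (!inherits(chunk, "feature_set") || n_windows(chunk) < 1L) {
    stop_invalid("chunk", "must be a non-empty feature_set")
  }
  if (n_members(ens) < 1L) stop("contract error: ensemble has no members", call. = FALSE)
  if (!inherits(policy, "labeling_policy")) {
    stop_invalid("policy", "must be a labeling_policy")
  }
  if (!identical(policy$mode, "non_supervised") && !is.function(oracle)) {
    stop_invalid("oracle", "must be supplied for supervised/semi-supervised labeling")
  }
  n <- n_windows(chunk)
  pred <- predict(ens, chunk$x)
  assigned <- pred$label
  src <- rep("predicted", n)
  th <- NA_real_

  if (identical(policy$mode, "supervised")) {
    for (i in seq_len(n)) {
      assigned[i] <- oracle_label(oracle, chunk$subject_id[i], chunk$w[i])
    }
    src[] <- "queried"
  } else if (identical(policy$mode, "semi_supervised")) {
    th <- select_threshold(ens, policy)
    queried <- pred$confidence < th
    qpos <- which(queried)
    for (i in qpos) {
      assigned[i] <- oracle_label(oracle, chunk$subject_id[i], chunk$w[i])
    }
    src[qpos] <- "queried"
    # nearest query wins; ties at equal distance go to the smaller-w query,
    # so for each distance d the left-hand source (target = q + d) is
    # applied before the right-hand one (target = q - d)
    if (length(qpos) && policy$propagation_radius > 0L) {
      for (d in seq_len(policy$propagation_radius)) {
        for (side in c(1L, -1L)) {
          rows <- match(chunk$w[qpos] + side * d, chunk$w)
          ok <- !is.na(rows)
          rows_ok <- rows[ok]
          sources <- qpos[ok]
          open <- src[rows_ok] == "predicted"
          assigned[rows_ok[open]] <- assigned[sources[open]]
          src[rows_ok[open]] <- "propagated"
        }
      }
    }
  }

  structure(
    list(features = chunk, labels = assigned, source = src, threshold = th,
         query_fraction = mean(src == "queried"),
         replaced_fraction = mean(src != "predicted")),
    class = "labeled_chunk"
  )
}

#' @export
print.labeled_chunk <- function(x, ...) {
  cat(sprintf("<labeled_chunk> %d windows: %.1f%% queried, %.1f%% replaced (th = %s)\n",
              length(x$labels), 100 * x$query_fraction,
              100 * x$replaced_fraction,
              if (is.na(x$threshold)) "-" else format(x$threshold)))
  invisible(x)
}

#' Summarize query load over labeling rounds
#'
#' @param chunks list of `labeled_chunk` objects.
#' @param rounds integer round tag per chunk (defaults to chunk position).
#' @return A list with `per_round` (data.frame of mean query and replaced
#'   fractions per round) and `overall` (means over all chunks).
#' @export
summarize_queries <- function(chunks, rounds = seq_along(chunks)) {
  stopifnot(length(chunks) == length(rounds))
  qf <- vapply(chunks, `[[`, numeric(1), "query_fraction")
  rf <- vapply(chunks, `[[`, numeric(1), "replaced_fraction")
  per_round <- do.call(rbind, lapply(sort(unique(rounds)), function(r) {
    data.frame(round = r, n_chunks = sum(rounds == r),
               query_fraction = mean(qf[rounds == r]),
               replaced_fraction = mean(rf[rounds == r]))
  }))
  list(per_round = per_round,
       overall = c(query_fraction = mean(qf), replaced_fraction = mean(rf)))
}

#' Export a labeled chunk as a data.frame
#'
#' @param x a `labeled_chunk`.
#' @param ... unused.
#' @return data.frame with columns `w`, `assigned_label`, `source`.
#' @export
as.data.frame.labeled_chunk <- function(x, ...) {
  data.frame(w = x$features$w, assigned_label = x$labels, source = x$source)
}
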