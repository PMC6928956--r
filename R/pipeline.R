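# The leave-one-subject-out experimental protocol: pooled user-independent
# training, three-way personal split, phased ensemble growth (3 UI + 3 + 3
# personal models), per-step evaluation, and the UI-only growth control.

#' Experiment configuration
#'
#' @param classifier_kind base classifier used throughout (`"lda"`, `"qda"`,
#'   `"cart"`).
#' @param policy a [labeling_policy()] for the personal chunks.
#' @param window a [window_spec()].
#' @param features a [feature_config()].
#' @param train a [train_config()].
#' @param control a [base_control()].
#' @param n_ui_models user-independent base models trained in Step 1.
#' @param part_roles permutation of `c("part1", "part2", "test")` assigning
#'   roles to the three temporal thirds of each class block; the default uses
#'   temporal order (first third personalization round 1, second round 2,
#'   last third testing).
#' @param seed experiment seed; every base model derives a private stream
#'   from it via [derive_seed()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(classifier_kind = c("lda", "qda", "cart"),
                              policy = labeling_policy("semi_supervised"),
                              window = window_spec(4.2, 1.4),
                              features = feature_config(),
                              train = train_config(),
                              control = base_control(),
                              n_ui_models = 3,
                              part_roles = c("part1", "part2", "test"),
                              seed = 1) {
  classifier_kind <- match.arg(classifier_kind)
  stopifnot(inherits(policy, "labeling_policy"), inherits(window, "window_spec"),
            inherits(features, "feature_config"), inherits(train, "train_config"),
            inherits(control, "base_control"))
  n_ui_models <- check_count(n_ui_models, "n_ui_models", min = 1)
  if (!setequal(part_roles, c("part1", "part2", "test")) || length(part_roles) != 3L) {
    stop_invalid("part_roles", "must be a permutation of part1, part2, test")
  }
  seed <- check_count(seed, "seed")
  structure(list(classifier_kind = classifier_kind, policy = policy,
                 window = window, features = features, train = train,
                 control = control, n_ui_models = n_ui_models,
                 part_roles = part_roles, seed = seed),
            class = "experiment_config")
}

#' Split one subject's recording into two personalization parts and a test part
#'
#' Each class's contiguous raw-signal block is cut into three equal-length
#' contiguous thirds at sample resolution, windows are computed independently
#' inside each third (so windows never straddle a cut and the parts share no
#' raw samples), and the thirds are assigned to `(part1, part2, test)` per
#' `cfg$part_roles`. Window indices `w` are global and consecutive over the
#' subject's segments in temporal order, so every window has a unique `(subject,
#' w)` identity across parts.
#'
#' @param rec the subject's `raw_recording`; every class must occupy one
#'   contiguous block.
#' @param cfg an [experiment_config()] (its window/feature configs are used).
#' @return An object of class `personal_split`: list of three `feature_set`s
#'   named `part1`, `part2`, `test`.
#' @export
split_personal <- function(rec, cfg) {
  runs <- rle(rec$labels)
  if (anyDuplicated(runs$values)) {
    dup <- runs$values[duplicated(runs$values)][1]
    stop(sprintf("protocol error: class '%s' of subject %s is not one contiguous block",
                 dup, rec$subject_id), call. = FALSE)
  }
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths  # 0-based
  windows_by_role <- list(part1 = list(), part2 = list(), test = list())
  w_next <- 1L
  for (ri in seq_along(runs$values)) {
    len <- runs$lengths[ri]
    cuts <- run_starts[ri] + round(len * (0:3) / 3)
    for (k in 1:3) {
      idx <- (cuts[k] + 1L):cuts[k + 1L]
      seg <- raw_recording(rec$subject_id, rec$sampling_rate_hz,
                           lapply(rec$channels, function(ch) ch[idx]),
                           rec$labels[idx])
      wins <- withCallingHandlers(
        segment_windows(seg, cfg$window),
        warning = function(w) invokeRestart("muffleWarning"))
      if (length(wins) == 0L) {
        stop(sprintf("protocol error: class '%s' of subject %s is too short for a window in each third",
                     runs$values[ri], rec$subject_id), call. = FALSE)
      }
      for (i in seq_along(wins)) {
        wins[[i]]$w <- w_next
        w_next <- w_next + 1L
      }
      role <- cfg$part_roles[k]
      windows_by_role[[role]] <- c(windows_by_role[[role]], wins)
    }
  }
  parts <- lapply(windows_by_role, function(ws) {
    ws <- ws[order(vapply(ws, `[[`, integer(1), "w"))]
    featurize(ws, cfg$features)
  })
  structure(parts, class = "personal_split")
}

# Ground-truth oracle over a subject's split: label lookup by (subject, w),
# mirroring how user inputs are simulated in the experiments.
make_oracle <- function(split) {
  sid <- split$part1$subject_id[1]
  all_w <- c(split$part1$w, split$part2$w, split$test$w)
  all_lab <- c(split$part1$label, split$part2$label, split$test$label)
  lookup <- setNames(all_lab, all_w)
  function(subject_id, w) {
    if (!identical(as.character(subject_id), sid)) {
      stop(sprintf("oracle knows subject %s, asked about %s", sid, subject_id))
    }
    unname(lookup[[as.character(w)]])
  }
}

featurize_full <- function(rec, cfg) {
  featurize(segment_windows(rec, cfg$window), cfg$features)
}

eval_step <- function(ens, test_fs) {
  ba <- balanced_accuracy(test_fs$label, predict(ens, test_fs$x)$label)
  c(balanced_accuracy = ba, error_rate = 1 - ba, macro_fnr = 1 - ba)
}

trace_row <- function(step, ens, origin, metrics, skipped = FALSE) {
  data.frame(step = step, n_members = n_members(ens), origin = origin,
             balanced_accuracy = metrics[["balanced_accuracy"]],
             error_rate = metrics[["error_rate"]],
             macro_fnr = metrics[["macro_fnr"]],
             skipped = skipped)
}

# Core per-subject protocol. `pool` is the pooled user-independent feature
# set, `split` the held-out subject's personal_split. When `ui_members` is
# given the Step 1 models are reused instead of retrained (they depend only on
# (seed, subject, pool), so sharing them across policies changes nothing).
personalize_subject <- function(pool, split, cfg, subject_index,
                                ui_members = NULL, ui_control = FALSE) {
  ens <- learnpp_ensemble()
  test_fs <- split$test
  steps <- list()
  queries <- list()
  step <- 0L

  # Step 1: user-independent phase
  for (r in seq_len(cfg$n_ui_models)) {
    model <- if (!is.null(ui_members)) {
      ui_members[[r]]
    } else {
      train_base_model(pool, cfg$classifier_kind, "user_independent",
                       cfg$train, seed = derive_seed(cfg$seed, subject_index, 0, r),
                       control = cfg$control)
    }
    ens <- add_base_model(ens, model)
    step <- step + 1L
    steps[[step]] <- trace_row(step, ens, "user_independent",
                               eval_step(ens, test_fs))
  }
  baseline <- steps[[step]]$balanced_accuracy

  # Steps 2-3: two personalization rounds (or the UI-only growth control)
  chunks <- list(split$part1, split$part2)
  oracle <- make_oracle(split)
  for (round in 1:2) {
    if (ui_control) {
      for (r in seq_len(cfg$train$n_models_per_chunk)) {
        model <- train_base_model(pool, cfg$classifier_kind, "user_independent",
                                  cfg$train,
                                  seed = derive_seed(cfg$seed, subject_index,
                                                     10 + round, r),
                                  control = cfg$control)
        ens <- add_base_model(ens, model)
        step <- step + 1L
        steps[[step]] <- trace_row(step, ens, "user_independent",
                                   eval_step(ens, test_fs))
      }
      next
    }
    labeled <- label_chunk(ens, chunks[[round]], cfg$policy, oracle)
    queries[[round]] <- data.frame(round = round, threshold = labeled$threshold,
                                   query_fraction = labeled$query_fraction,
                                   replaced_fraction = labeled$replaced_fraction)
    if (length(unique(labeled$labels)) < 2L) {
      warning(sprintf("subject %s, round %d: degenerate labeled chunk (single class); round skipped",
                      test_fs$subject_id[1], round))
      for (r in seq_len(cfg$train$n_models_per_chunk)) {
        step <- step + 1L
        steps[[step]] <- trace_row(step, ens, "personal",
                                   c(balanced_accuracy = NA_real_,
                                     error_rate = NA_real_, macro_fnr = NA_real_),
                                   skipped = TRUE)
      }
      next
    }
    for (r in seq_len(cfg$train$n_models_per_chunk)) {
      model <- tryCatch(
        train_base_model(labeled, cfg$classifier_kind, "personal", cfg$train,
                         seed = derive_seed(cfg$seed, subject_index, round, r),
                         control = cfg$control),
        error = function(e) {
          warning(sprintf("subject %s, round %d, model %d: %s; model skipped",
                          test_fs$subject_id[1], round, r, conditionMessage(e)))
          NULL
        })
      step <- step + 1L
      if (is.null(model)) {
        steps[[step]] <- trace_row(step, ens, "personal",
                                   c(balanced_accuracy = NA_real_,
                                     error_rate = NA_real_, macro_fnr = NA_real_),
                                   skipped = TRUE)
      } else {
        ens <- add_base_model(ens, model)
        steps[[step]] <- trace_row(step, ens, "personal", eval_step(ens, test_fs))
      }
    }
  }

  structure(
    list(subject_id = test_fs$subject_id[1],
         steps = do.call(rbind, steps),
         queries = if (length(queries)) do.call(rbind, queries) else NULL,
         baseline = baseline,
         ensemble = ens),
    class = "experiment_trace"
  )
}

#' @export
print.experiment_trace <- function(x, ...) {
  cat(sprintf("<experiment_trace> subject %s: baseline BA %.3f, final BA %.3f (%d steps)\n",
              x$subject_id, x$baseline,
              rev(x$steps$balanced_accuracy[!is.na(x$steps$balanced_accuracy)])[1],
              nrow(x$steps)))
  invisible(x)
}

prepare_cohort <- function(cohort, cfg) {
  list(full = lapply(cohort, featurize_full, cfg = cfg),
       splits = lapply(cohort, split_personal, cfg = cfg))
}

pool_for_subject <- function(prepared, x) {
  fs_bind(prepared$full[-x])
}

#' Personalize the ensemble for one held-out subject
#'
#' Runs the full per-subject protocol: Step 1 trains `n_ui_models`
#' user-independent base models from the pooled features of every other
#' subject (bootstrap size = pool size), evaluating on the held-out subject's
#' test part after each addition. Steps 2 and 3 label personalization parts 1
#' and 2 with the configured policy (the oracle is a ground-truth label
#' lookup), train `n_models_per_chunk` personal models per part, and evaluate
#' after each addition — nine evaluation points with the defaults.
#'
#' @param subject index (or id) of the held-out subject in `cohort`.
#' @param cohort list of `raw_recording` objects (>= 2 subjects).
#' @param cfg an [experiment_config()].
#' @return An `experiment_trace` with per-step metrics (`error_rate` is
#'   `1 - balanced_accuracy` at every step), per-round query summaries, the
#'   static user-independent `baseline` score (the ensemble after Step 1),
#'   and the final ensemble.
#' @export
run_personalization <- function(subject, cohort, cfg = experiment_config()) {
  x <- resolve_subject(subject, cohort)
  prepared <- prepare_cohort(cohort, cfg)
  personalize_subject(pool_for_subject(prepared, x), prepared$splits[[x]],
                      cfg, x)
}

#' UI-only growth control for one held-out subject
#'
#' Identical to [run_personalization()] except that Steps 2-3 train their
#' models from fresh bootstrap samples of the user-independent pool instead of
#' the subject's personal chunks. Comparing this trace with the personalized
#' one isolates the effect of personal data from the effect of mere ensemble
#' growth.
#'
#' @inheritParams run_personalization
#' @return An `experiment_trace`; all members have origin `user_independent`.
#' @export
run_ui_only_control <- function(subject, cohort, cfg = experiment_config()) {
  x <- resolve_subject(subject, cohort)
  prepared <- prepare_cohort(cohort, cfg)
  personalize_subject(pool_for_subject(prepared, x), prepared$splits[[x]],
                      cfg, x, ui_control = TRUE)
}

resolve_subject <- function(subject, cohort) {
  if (is.character(subject)) {
    ids <- vapply(cohort, `[[`, character(1), "subject_id")
    x <- match(subject, ids)
    if (is.na(x)) stop_invalid("subject", "not found in cohort")
    x
  } else {
    check_count(subject, "subject", min = 1)
  }
}

aggregate_traces <- function(traces) {
  steps <- lapply(traces, `[[`, "steps")
  n_steps <- nrow(steps[[1]])
  do.call(rbind, lapply(seq_len(n_steps), function(s) {
    ba <- vapply(steps, function(df) df$balanced_accuracy[s], numeric(1))
    data.frame(step = s, n_members = steps[[1]]$n_members[s],
               mean_balanced_accuracy = mean(ba, na.rm = TRUE),
               sd_balanced_accuracy = stats::sd(ba[!is.na(ba)]),
               mean_error_rate = 1 - mean(ba, na.rm = TRUE))
  }))
}

#' Leave-one-subject-out evaluation over a cohort
#'
#' Holds out each subject in turn and runs the personalization protocol,
#' optionally under several labeling policies at once. The Step 1
#' user-independent models depend only on the pool and the experiment seed,
#' so they are trained once per held-out subject and shared across policies
#' (and the UI-only control), exactly as retraining them would produce.
#'
#' @param cohort list of `raw_recording` objects (>= 2 subjects).
#' @param cfg an [experiment_config()].
#' @param policies character vector of labeling modes to run
#'   (default: just `cfg$policy$mode`).
#' @param include_ui_control also run the UI-only growth control per subject.
#' @return An object of class `loso_result`: list with `policies` (per policy:
#'   `traces` per subject and an `aggregate` data.frame of mean/sd balanced
#'   accuracy per step), optional `ui_control`, and `baseline` (per-subject
#'   static user-independent scores).
#' @export
run_loso <- function(cohort, cfg = experiment_config(), policies = NULL,
                     include_ui_control = FALSE) {
  if (length(cohort) < 2L) stop_invalid("cohort", "needs >= 2 subjects")
  policies <- policies %||% cfg$policy$mode
  prepared <- prepare_cohort(cohort, cfg)
  per_policy <- setNames(lapply(policies, function(p) list(traces = list())),
                         policies)
  control_traces <- list()
  baselines <- numeric(length(cohort))

  for (x in seq_along(cohort)) {
    pool <- pool_for_subject(prepared, x)
    ui_members <- lapply(seq_len(cfg$n_ui_models), function(r) {
      train_base_model(pool, cfg$classifier_kind, "user_independent", cfg$train,
                       seed = derive_seed(cfg$seed, x, 0, r),
                       control = cfg$control)
    })
    ui_ens <- learnpp_ensemble()
    for (m in ui_members) ui_ens <- add_base_model(ui_ens, m)
    baselines[x] <- eval_step(ui_ens, prepared$splits[[x]]$test)[["balanced_accuracy"]]
    for (p in policies) {
      cfg_p <- cfg
      cfg_p$policy <- labeling_policy(p, th_ui = cfg$policy$th_ui,
                                      th_personal = cfg$policy$th_personal,
                                      propagation_radius = cfg$policy$propagation_radius)
      tr <- personalize_subject(pool, prepared$splits[[x]], cfg_p, x,
                                ui_members = ui_members)
      per_policy[[p]]$traces[[x]] <- tr
    }
    if (include_ui_control) {
      control_traces[[x]] <- personalize_subject(pool, prepared$splits[[x]],
                                                 cfg, x, ui_members = ui_members,
                                                 ui_control = TRUE)
    }
  }

  for (p in policies) {
    per_policy[[p]]$aggregate <- aggregate_traces(per_policy[[p]]$traces)
  }
  structure(
    list(policies = per_policy,
         ui_control = if (include_ui_control) {
           list(traces = control_traces, aggregate = aggregate_traces(control_traces))
         },
         baseline = data.frame(
           subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
           balanced_accuracy = baselines)),
    class = "loso_result"
  )
}

#' Final-step policy comparison table
#'
#' One row summarizing a LOSO run in the conventional layout: mean balanced
#' accuracy of the static user-independent ensemble and of the final
#' (9-member) ensemble per labeling policy.
#'
#' @param res a `loso_result` run with the policies of interest.
#' @return A one-row data.frame with columns `user_independent` and one per
#'   policy present in `res`.
#' @export
policy_table <- function(res) {
  out <- data.frame(user_independent = mean(res$baseline$balanced_accuracy))
  for (p in names(res$policies)) {
    agg <- res$policies[[p]]$aggregate
    out[[p]] <- agg$mean_balanced_accuracy[nrow(agg)]
  }
  out
}
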