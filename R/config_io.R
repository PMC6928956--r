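# YAML experiment configuration. Sections mirror the constructor arguments;
# omitted fields fall back to the documented defaults.

build_from_yaml <- function(section, constructor) {
  if (is.null(section)) return(constructor())
  known <- names(formals(constructor))
  unknown <- setdiff(names(section), known)
  if (length(unknown)) {
    stop_invalid("config", paste("unknown field(s):", paste(unknown, collapse = ", ")))
  }
  do.call(constructor, section)
}

#' Read a synthetic-cohort configuration from YAML
#'
#' Reads the `synthetic:` section of a config file (or the whole file if the
#' section is absent) into a [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  section <- y$synthetic %||% y
  if (!is.null(section$class_params)) {
    section$class_params <- as.data.frame(
      do.call(rbind, lapply(section$class_params, as.data.frame)))
  }
  build_from_yaml(section, synthetic_config)
}

#' Read an experiment configuration from YAML
#'
#' Recognized sections: `window`, `features`, `train`, `policy`, `control`
#' and `experiment` (for `classifier_kind`, `n_ui_models`, `part_roles`,
#' `seed`). Missing sections use the package defaults.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  top <- y$experiment %||% list()
  experiment_config(
    classifier_kind = top$classifier_kind %||% "lda",
    policy = build_from_yaml(y$policy, labeling_policy),
    window = build_from_yaml(y$window, window_spec),
    features = build_from_yaml(y$features, feature_config),
    train = build_from_yaml(y$train, train_config),
    control = build_from_yaml(y$control, base_control),
    n_ui_models = top$n_ui_models %||% 3,
    part_roles = unlist(top$part_roles %||% c("part1", "part2", "test")),
    seed = top$seed %||% 1
  )
}
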