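# Run configuration: YAML-backed, defaulting to the published protocol
# constants (production 10,000 t.u. at theta = 0.10 with exchange 0.1/t.u.,
# snapshots every 10 t.u., 5 clusters, 20 iterations).

#' Default run configuration
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    preset = "mg",
    n_iterations = 20L,
    k_clusters = 5L,
    seed = 1L,
    coordination_cutoff = 2.6,
    constraint_half_width = 0.01,
    production_temperature = 0.10,
    production_duration = 10000,
    save_interval = 10,
    heat_exchange_rate = 0.1,
    anneal_start = 0.20,
    anneal_steps = 5L,
    anneal_step_duration = 500,
    clash_duration = 1000,
    clash_exchange_rate = 10,
    arm_length = 2L,
    distort_sigma = 0,
    output_dir = "out"
  )
}

#' Load and validate a run configuration
#'
#' Unknown keys and duplicate keys are errors (never silently ignored);
#' values are range-checked; the fully resolved configuration is returned
#' with overrides applied over the protocol defaults.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return resolved configuration list with attribute `overrides`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  overrides <- character(0)
  if (!is.null(path)) {
    lines <- readLines(path)
    keys <- sub(":.*$", "", grep("^[A-Za-z_][A-Za-z0-9_]*\\s*:", lines, value = TRUE))
    keys <- trimws(keys)
    if (anyDuplicated(keys)) {
      stop("duplicate configuration key(s): ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
    }
    user <- yaml::read_yaml(path)
    if (length(user) > 0) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown) > 0) {
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
      }
      for (k in names(user)) cfg[[k]] <- user[[k]]
      overrides <- names(user)
    }
  }
  check_pos <- function(k) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("configuration key '", k, "' must be a positive number, got ", cfg[[k]])
    }
  }
  for (k in c("n_iterations", "k_clusters", "production_temperature",
              "production_duration", "save_interval", "heat_exchange_rate",
              "anneal_start", "anneal_steps", "anneal_step_duration",
              "clash_duration", "clash_exchange_rate", "constraint_half_width",
              "coordination_cutoff")) {
    check_pos(k)
  }
  if (!cfg$preset %in% c("mg", "ca", "fe2", "fe3")) {
    stop("configuration key 'preset' must be one of mg, ca, fe2, fe3")
  }
  attr(cfg, "overrides") <- overrides
  cfg
}

#' Write the resolved configuration next to the run outputs
#'
#' @param cfg resolved configuration from [load_config()].
#' @param dir output directory.
#' @return path of the written file, invisibly.
#' @export
echo_config <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "config_resolved.yml")
  yaml::write_yaml(cfg[order(names(cfg))], path)
  invisible(path)
}
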