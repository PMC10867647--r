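#' Default pipeline configuration
#'
#' Returns the nested configuration list used by every pipeline stage.
#' Values can be overridden from a YAML file via [load_config()] or by
#' modifying the returned list directly. Sections mirror the pipeline
#' stages: `io`, `preprocess`, `differential`, `cluster`, `patterns`,
#' `lmm`, `enrich`, `simulate`.
#'
#' @return A named nested list of configuration values.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$cluster$m
default_config <- function() {
  list(
    io = list(
      # study day grid; a configurable default, not a hard constant
      day_set = c(0L, 14L, 28L, 63L, 91L),
      float_digits = 6L
    ),
    preprocess = list(
      ms2_threshold = 0.5,
      collapse = "elementwise_max",   # or "best_feature"
      max_qc_cv = NULL                # optional CV-based removal, off by default
    ),
    differential = list(
      test = "t",                     # or "wilcoxon"
      day_ref = 0L,
      day_cmp = 63L,
      p_threshold = 0.05,
      lfc_threshold = 1
    ),
    cluster = list(
      m = 2,                          # fuzzifier; "estimate" for data-driven
      c_min = 2L,
      c_max = 8L,
      repeats = 3L,
      delta = 0.2,                    # relative Dmin drop for the elbow rule
      force_c = NULL,                 # manual override of the cluster number
      membership_threshold = 0.7,
      tol = 1e-6,
      max_iter = 300L
    ),
    patterns = list(
      library = "default5",
      peak_day = 28
    ),
    lmm = list(
      alpha = 0.05,
      select = "lrt",                 # or "aic"
      concordance = "direction",      # or "class"
      model2_direction = "quad_sign"  # or "end_minus_start"
    ),
    enrich = list(
      min_k = 1L,
      universe = "preprocessed"
    ),
    simulate = list(
      n_subjects_per_group = 15L,
      days = c(0L, 14L, 28L, 63L, 91L),
      groups = c("C", "A", "AE"),
      ion_modes = c("POS", "NEG"),
      template_library = "default5",
      n_metabolites_per_archetype = c(`1` = 6L, `2` = 6L, `3` = 6L,
                                      `4` = 6L, `5` = 6L),
      n_null_metabolites = 15L,
      n_concordant = 10L,
      crossgroup_change_frac = 0.1,
      effect_size = 1.0,
      subject_sd = 0.3,
      resid_sd = 0.3,
      baseline_log2_mean = 15,
      baseline_log2_sd = 2,
      n_features_per_metabolite = 2L,
      feature_jitter_sd = 0.05,
      ms2_score_range = c(0.05, 0.95),
      qc_n = 5L,
      qc_sd = 0.1,
      day63_missing_frac = 0.1,
      seed = 1L
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]:
#' keys present in the file replace defaults, everything else keeps its
#' default value.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("chronomet.log_level", "info")
  options(chronomet.log_level = level)
  invisible(old)
}

cm_log <- function(level, ...) {
  cur <- getOption("chronomet.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[cur]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}
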