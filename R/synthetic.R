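# Synthetic longitudinal study generator: planted trajectory archetypes,
# subject random intercepts, lognormal noise, duplicate features with MS2
# scores straddling the filter, QC samples, day-63 dropout, and ground
# truth for recovery tests.

#' Build a simulation configuration
#'
#' Starts from the `simulate` section of [default_config()] and applies
#' overrides. Key fields: `n_subjects_per_group` (15), `days`
#' (0,14,28,63,91), `groups` (C/A/AE), `ion_modes`,
#' `template_library` (`"default5"` or `"trend4"`),
#' `n_metabolites_per_archetype` (named by pattern id),
#' `n_null_metabolites`, `n_concordant` (planted with
#' direction C = AE = -A), `crossgroup_change_frac` (fraction of
#' archetype metabolites re-assigned a different archetype in group A),
#' `effect_size` (standardized trajectory amplitude on log2 scale),
#' `subject_sd`, `resid_sd`, `baseline_log2_mean`/`_sd`,
#' `n_features_per_metabolite`, `feature_jitter_sd`, `ms2_score_range`,
#' `qc_n`, `qc_sd`, `day63_missing_frac`, `seed`.
#'
#' @param ... overrides of the default simulate settings.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(...) {
  cfg <- modify_list_deep(default_config()$simulate, list(...))
  stopifnot(cfg$n_subjects_per_group >= 1,
            length(cfg$days) >= 3,
            all(diff(cfg$days) > 0),
            cfg$subject_sd > 0, cfg$resid_sd > 0,
            cfg$baseline_log2_sd > 0,
            cfg$n_features_per_metabolite >= 1,
            cfg$day63_missing_frac >= 0, cfg$day63_missing_frac < 1,
            length(cfg$ms2_score_range) == 2,
            cfg$ms2_score_range[1] >= 0, cfg$ms2_score_range[2] <= 1)
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Generate a complete synthetic study
#'
#' Per ion mode, plants metabolites of three kinds: archetype
#' metabolites following a standardized template shape (shared across
#' groups, except a configured fraction re-assigned a different
#' archetype in group A), null metabolites with no time effect, and
#' concordant metabolites trending up (or down) in C and AE and
#' oppositely in A. The log2 intensity of metabolite i in subject s at
#' day d is
#' `baseline_i + effect_size * shape_ig(d) + b_is + e`, with
#' `b_is ~ N(0, subject_sd^2)` and `e ~ N(0, resid_sd^2)`; intensities
#' are `2^log2`, hence lognormal. Each metabolite yields
#' `n_features_per_metabolite` features sharing the signal with small
#' jitter; the first feature's MS2 score lies above 0.5 and the rest
#' straddle it, so the MS2 filter is exercised without losing the
#' metabolite. QC samples are drawn around the per-metabolite baseline.
#' A configured fraction of non-QC day-63 samples is deleted and
#' recorded. Fully reproducible from `config$seed`.
#'
#' @param config a `SimConfig`.
#' @return list: `features` (a `FeatureTable`), `samples` (metadata),
#'   `truth` (list: `metabolites` data.frame with per-group archetype /
#'   direction / kind, `features` with planted MS2 scores,
#'   `missing_samples`).
#' @export
generate_study <- function(config = sim_config()) {
  if (!inherits(config, "SimConfig")) config <- do.call(sim_config, config)
  withr::with_seed(as.integer(config$seed), generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  days <- cfg$days
  groups <- cfg$groups
  templates <- archetype_templates(days, library = cfg$template_library)
  tm <- template_matrix(templates)          # pattern x day
  # monotone standardized shape for the planted concordant metabolites
  lin_up <- (days - mean(days)) / sd(days)

  meta_list <- list()
  feat_ann_list <- list()
  int_list <- list()
  truth_met <- list()
  missing_samples <- character(0)

  for (mode in cfg$ion_modes) {
    # ---- sample metadata for this mode
    grid <- expand.grid(subject = seq_len(cfg$n_subjects_per_group),
                        day = days, group = groups,
                        stringsAsFactors = FALSE)
    grid$subject_id <- sprintf("%s%02d", grid$group, grid$subject)
    grid$sample_id <- sprintf("%s_d%02d_%s", grid$subject_id, grid$day,
                              mode)
    meta <- data.frame(sample_id = grid$sample_id,
                       subject_id = grid$subject_id,
                       group = grid$group, day = grid$day,
                       ion_mode = mode, is_qc = FALSE,
                       stringsAsFactors = FALSE)
    if (cfg$qc_n > 0) {
      meta <- rbind(meta, data.frame(
        sample_id = sprintf("QC%02d_%s", seq_len(cfg$qc_n), mode),
        subject_id = NA_character_, group = NA_character_,
        day = NA_integer_, ion_mode = mode, is_qc = TRUE,
        stringsAsFactors = FALSE))
    }

    # ---- metabolite panel and ground truth for this mode
    arch_ids <- rep(as.integer(names(cfg$n_metabolites_per_archetype)),
                    times = unlist(cfg$n_metabolites_per_archetype))
    kinds <- c(rep("archetype", length(arch_ids)),
               rep("null", cfg$n_null_metabolites),
               rep("concordant", cfg$n_concordant))
    n_met <- length(kinds)
    met_names <- sprintf("M_%s_%03d", mode, seq_len(n_met))
    # per-group archetype: shared, except flips in group A
    arch_by_group <- matrix(NA_integer_, nrow = n_met,
                            ncol = length(groups),
                            dimnames = list(met_names, groups))
    arch_by_group[kinds == "archetype", ] <- arch_ids
    n_arch <- sum(kinds == "archetype")
    n_flip <- round(cfg$crossgroup_change_frac * n_arch)
    if (n_flip > 0 && "A" %in% groups && nrow(tm) > 1) {
      flip_idx <- which(kinds == "archetype")[sample.int(n_arch, n_flip)]
      for (i in flip_idx) {
        cur <- arch_by_group[i, "A"]
        arch_by_group[i, "A"] <- sample(setdiff(seq_len(nrow(tm)), cur), 1)
      }
    }
    conc_dir <- rep(NA_character_, n_met)
    conc_idx <- which(kinds == "concordant")
    if (length(conc_idx)) {
      conc_dir[conc_idx] <- sample(c("up", "down"), length(conc_idx),
                                   replace = TRUE)
    }

    # ---- per-metabolite x sample log2 signal
    baseline <- rnorm(n_met, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    non_qc <- meta[!meta$is_qc, ]
    log2m <- matrix(NA_real_, n_met, nrow(meta),
                    dimnames = list(met_names, meta$sample_id))
    day_idx <- match(non_qc$day, days)
    for (i in seq_len(n_met)) {
      shape <- numeric(nrow(non_qc))
      if (kinds[i] == "archetype") {
        for (g in groups) {
          gi <- non_qc$group == g
          shape[gi] <- tm[arch_by_group[i, g], day_idx[gi]]
        }
      } else if (kinds[i] == "concordant") {
        sgn <- if (conc_dir[i] == "up") 1 else -1
        for (g in groups) {
          gi <- non_qc$group == g
          gs <- if (g == "A") -sgn else sgn
          shape[gi] <- gs * lin_up[day_idx[gi]]
        }
      }
      b_subj <- rnorm(length(unique(non_qc$subject_id)), 0, cfg$subject_sd)
      names(b_subj) <- unique(non_qc$subject_id)
      log2m[i, non_qc$sample_id] <-
        baseline[i] + cfg$effect_size * shape +
        b_subj[non_qc$subject_id] +
        rnorm(nrow(non_qc), 0, cfg$resid_sd)
      if (cfg$qc_n > 0) {
        qc_ids <- meta$sample_id[meta$is_qc]
        log2m[i, qc_ids] <- baseline[i] + rnorm(cfg$qc_n, 0, cfg$qc_sd)
      }
    }

    # ---- day-63 dropout
    d63 <- meta$sample_id[!meta$is_qc & meta$day == 63]
    n_drop <- round(cfg$day63_missing_frac * length(d63))
    if (n_drop > 0) {
      drop_ids <- sample(d63, n_drop)
      keep <- !meta$sample_id %in% drop_ids
      meta <- meta[keep, , drop = FALSE]
      log2m <- log2m[, meta$sample_id, drop = FALSE]
      missing_samples <- c(missing_samples, drop_ids)
    }

    # ---- expand metabolites to duplicate features with MS2 scores
    nf <- cfg$n_features_per_metabolite
    lo <- cfg$ms2_score_range[1]
    hi <- cfg$ms2_score_range[2]
    feat_rows <- list()
    feat_int <- list()
    fcount <- 0L
    for (i in seq_len(n_met)) {
      for (j in seq_len(nf)) {
        fcount <- fcount + 1L
        score <- if (j == 1L) {
          runif(1, max(0.55, lo), hi)
        } else {
          runif(1, lo, hi)
        }
        jitter <- if (j == 1L) 0 else rnorm(ncol(log2m), 0,
                                            cfg$feature_jitter_sd)
        feat_rows[[fcount]] <- data.frame(
          feature_id = sprintf("F_%s_%05d", mode, fcount),
          metabolite_name = met_names[i],
          ms2_score = score, stringsAsFactors = FALSE)
        feat_int[[fcount]] <- 2^(log2m[i, ] + jitter)
      }
    }
    ann <- do.call(rbind, feat_rows)
    intensity <- do.call(rbind, feat_int)
    rownames(intensity) <- ann$feature_id

    meta_list[[mode]] <- meta
    feat_ann_list[[mode]] <- ann
    int_list[[mode]] <- intensity
    truth_met[[mode]] <- do.call(rbind, lapply(groups, function(g) {
      data.frame(metabolite = met_names, ion_mode = mode, group = g,
                 kind = kinds,
                 archetype = arch_by_group[, g],
                 direction = ifelse(kinds == "concordant",
                                    ifelse(g == "A",
                                           ifelse(conc_dir == "up",
                                                  "down", "up"),
                                           conc_dir),
                                    NA_character_),
                 stringsAsFactors = FALSE)
    }))
  }

  # ---- merge modes into one study (intensity blocks are mode-specific;
  # cells of the other mode's samples stay missing)
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  all_samples <- meta$sample_id
  blocks <- lapply(names(int_list), function(mode) {
    m <- matrix(NA_real_, nrow(int_list[[mode]]), length(all_samples),
                dimnames = list(rownames(int_list[[mode]]), all_samples))
    m[, colnames(int_list[[mode]])] <- int_list[[mode]]
    m
  })
  intensity <- do.call(rbind, blocks)
  ann <- do.call(rbind, feat_ann_list)
  rownames(ann) <- NULL
  ft <- feature_table(ann, intensity)
  truth <- list(
    metabolites = {
      tm_df <- do.call(rbind, truth_met); rownames(tm_df) <- NULL; tm_df
    },
    features = ann,
    missing_samples = missing_samples,
    config = cfg
  )
  list(features = ft, samples = validate_samples(meta), truth = truth)
}

#' Named fixture presets
#'
#' `"tiny"` (<= 30 metabolites per ion mode, one mode, 6 subjects) for
#' fast unit tests; `"default"` (the full study design: 3 groups x 15
#' subjects x 5 days, two ion modes) for end-to-end runs; `"null"`
#' (no planted time effects) for type-I-error checks.
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @return A `SimConfig`.
#' @export
fixture_config <- function(name = c("tiny", "default", "null"),
                           seed = 42L) {
  name <- match.arg(name)
  switch(name,
    tiny = sim_config(
      n_subjects_per_group = 6L, ion_modes = "POS",
      n_metabolites_per_archetype = c(`1` = 3L, `2` = 3L, `3` = 3L,
                                      `4` = 3L, `5` = 3L),
      n_null_metabolites = 5L, n_concordant = 4L, qc_n = 3L,
      seed = seed),
    default = sim_config(seed = seed),
    null = sim_config(
      n_subjects_per_group = 10L, ion_modes = "POS",
      n_metabolites_per_archetype = setNames(integer(0), character(0)),
      n_null_metabolites = 60L, n_concordant = 0L,
      crossgroup_change_frac = 0, seed = seed)
  )
}

#' Generate a fixture study and write it to disk
#'
#' Writes `features.tsv`, `samples.tsv`, `truth.tsv`, and the packaged
#' toy `annotation.tsv` / `classes.tsv` under `dir`.
#'
#' @param name fixture name (see [fixture_config()]).
#' @param dir output directory.
#' @param seed RNG seed.
#' @return The generated study (invisibly), as from [generate_study()].
#' @export
make_fixture <- function(name = c("tiny", "default", "null"), dir,
                         seed = 42L) {
  name <- match.arg(name)
  study <- generate_study(fixture_config(name, seed = seed))
  write_study(study$features, study$samples, dir)
  write_table(study$truth$metabolites, file.path(dir, "truth.tsv"))
  ann <- toy_annotation(unique(study$truth$metabolites$metabolite))
  write_table(ann$pathways, file.path(dir, "annotation.tsv"))
  write_table(data.frame(metabolite_name = names(ann$class_map),
                         compound_class = unname(ann$class_map),
                         stringsAsFactors = FALSE),
              file.path(dir, "classes.tsv"))
  invisible(study)
}
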