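# Simulated studies for trend fitting: the generator's "trend4" template
# library plants linear and quadratic log2 trajectories.

trend_study <- function(n_per_class, n_null = 0L, n_subjects = 15L,
                        seed = 1L, groups = "C") {
  cfg <- sim_config(
    n_subjects_per_group = n_subjects, ion_modes = "POS",
    groups = groups, template_library = "trend4",
    n_metabolites_per_archetype = setNames(rep(n_per_class, 4),
                                           as.character(1:4)),
    n_null_metabolites = n_null, n_concordant = 0L,
    crossgroup_change_frac = 0, n_features_per_metabolite = 1L,
    qc_n = 0L, seed = seed)
  generate_study(cfg)
}

trend_label_for <- function(archetype) {
  c("model1_up", "model1_down", "model2_up", "model2_down")[archetype]
}

test_that("near-noiseless linear data recovers its slope with tiny p", {
  cfg <- sim_config(ion_modes = "POS", groups = "C",
                    template_library = "trend4",
                    n_metabolites_per_archetype = c(`1` = 3L),
                    n_null_metabolites = 0L, n_concordant = 0L,
                    crossgroup_change_frac = 0,
                    n_features_per_metabolite = 1L, qc_n = 0L,
                    subject_sd = 0.01, resid_sd = 0.01,
                    effect_size = 1, day63_missing_frac = 0, seed = 31L)
  study <- generate_study(cfg)
  mm <- collapse_to_metabolites(study$features, study$samples)
  fits <- fit_trend_models(mm, "C")
  # the planted shape is the z-scored scaled time, so the regression
  # slope per unit scaled time is effect_size / sd(scaled days)
  days <- cfg$days
  t1 <- days / max(days); t1 <- t1 - mean(t1)
  slope_expected <- cfg$effect_size / sd(t1)
  expect_true(all(abs(fits$beta_lin - slope_expected) <
                    0.05 * abs(slope_expected)))
  expect_true(all(fits$p_lin < 1e-6))
  expect_true(all(fits$converged))
})

test_that("concave quadratic data yields a negative quadratic coefficient", {
  study <- trend_study(n_per_class = 2L, seed = 33L)
  mm <- collapse_to_metabolites(study$features, study$samples)
  fits <- fit_trend_models(mm, "C")
  truth <- study$truth$metabolites
  truth <- truth[truth$group == "C", ]
  concave <- truth$metabolite[truth$archetype == 4]
  expect_true(all(fits$beta_quad[fits$metabolite %in% concave] < 0))
  convex <- truth$metabolite[truth$archetype == 3]
  expect_true(all(fits$beta_quad[fits$metabolite %in% convex] > 0))
})

test_that("the four-way classification rule follows the two-stage gates", {
  base <- data.frame(metabolite = "m", group = "C", beta_lin = 1,
                     beta_quad = -1, p_lin = 0.001, p_quad = 0.4,
                     sigma_subject = 0.3, sigma_resid = 0.3,
                     aic_m0 = 10, aic_m1 = 5, aic_m2 = 6, n_obs = 75L,
                     converged = TRUE)
  expect_equal(classify_trend(base)$label, "model1_up")
  quad <- base; quad$p_quad <- 0.01
  expect_equal(classify_trend(quad)$label, "model2_down")
  quad_up <- quad; quad_up$beta_quad <- 2
  expect_equal(classify_trend(quad_up)$label, "model2_up")
  none <- base; none$p_lin <- 0.2; none$p_quad <- 0.3
  expect_equal(classify_trend(none)$label, "none")
  bad <- base; bad$converged <- FALSE
  expect_equal(classify_trend(bad)$label, "none")
  expect_equal(classify_trend(base)$direction, "up")
})

test_that("reversing the time axis flips linear labels, keeps quadratic ones", {
  study <- trend_study(n_per_class = 3L, seed = 35L)
  mm <- collapse_to_metabolites(study$features, study$samples)
  cls <- classify_trend(fit_trend_models(mm, "C"))
  rev_samples <- mm$samples
  rev_samples$day <- max(rev_samples$day) - rev_samples$day
  mm_rev <- metabolite_matrix(mm$intensity, rev_samples)
  cls_rev <- classify_trend(fit_trend_models(mm_rev, "C"))
  flip <- c(model1_up = "model1_down", model1_down = "model1_up",
            model2_up = "model2_up", model2_down = "model2_down",
            none = "none")
  expect_equal(cls_rev$label, unname(flip[cls$label]))
})

test_that("planted four-class trends are recovered accurately", {
  study <- trend_study(n_per_class = 15L, n_subjects = 15L, seed = 37L)
  mm <- collapse_to_metabolites(study$features, study$samples)
  cls <- classify_trend(fit_trend_models(mm, "C"))
  truth <- study$truth$metabolites
  truth <- truth[truth$group == "C", ]
  expected <- trend_label_for(truth$archetype[match(cls$metabolite,
                                                    truth$metabolite)])
  expect_gte(mean(cls$label == expected), 0.9)
})

test_that("concordance selection implements the C=AE-opposite-A rule", {
  mk <- function(metabolite, group, label) {
    direction <- ifelse(endsWith(label, "_up"), "up",
                        ifelse(endsWith(label, "_down"), "down", "none"))
    data.frame(metabolite = metabolite, group = group, label = label,
               direction = direction)
  }
  classes <- rbind(
    mk("a", "C", "model1_up"), mk("a", "AE", "model2_up"),
    mk("a", "A", "model1_down"),                       # selected
    mk("b", "C", "model1_up"), mk("b", "AE", "model1_up"),
    mk("b", "A", "model1_up"),                         # same in A: no
    mk("c", "C", "model1_up"), mk("c", "AE", "none"),
    mk("c", "A", "model1_down"),                       # AE none: no
    mk("d", "C", "model2_down"), mk("d", "AE", "model1_down"),
    mk("d", "A", "model1_up"))                         # selected
  res <- concordance_select(classes)
  expect_setequal(res$metabolite[res$selected], c("a", "d"))
  # strict-label mode also requires the same four-way class in C and AE
  strict <- concordance_select(classes, mode = "class")
  expect_setequal(strict$metabolite[strict$selected], character(0))
  expect_error(concordance_select(classes[classes$group != "A", ]),
               "C, A and AE")
})

test_that("planted concordant metabolites are found with few false picks", {
  cfg <- sim_config(ion_modes = "POS",
                    n_metabolites_per_archetype =
                      setNames(integer(0), character(0)),
                    n_null_metabolites = 40L, n_concordant = 10L,
                    crossgroup_change_frac = 0,
                    n_features_per_metabolite = 1L, qc_n = 0L,
                    seed = 39L)
  study <- generate_study(cfg)
  mm <- collapse_to_metabolites(study$features, study$samples)
  res <- lmm_stage(mm)
  truth <- study$truth$metabolites
  planted <- unique(truth$metabolite[truth$kind == "concordant"])
  sel <- res$concordance$metabolite[res$concordance$selected]
  expect_gte(sum(planted %in% sel) / length(planted), 0.8)
  expect_lte(sum(!sel %in% planted), 2L)
})
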