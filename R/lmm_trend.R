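# Per-metabolite linear mixed models over the full time course, four-way
# trend classification (linear/quadratic x up/down) by likelihood-ratio
# tests, and the C/AE-concordant, A-opposed selection.

#' Fit nested mixed models per metabolite
#'
#' For each metabolite in one group, fits by maximum likelihood (so the
#' likelihood-ratio tests between fixed-effect nestings are valid):
#' M0 `log2(y) ~ 1 + (1|subject)`, M1 adds scaled centered time `t`,
#' M2 adds `t^2`. Time is `day / max(day)` centered at its observed
#' mean, for numeric stability of the quadratic term. Unbalanced data
#' (e.g. missing day-63 samples) is handled by the likelihood.
#' `p_lin` is the chi-squared(1) LRT of M1 vs M0, `p_quad` of M2 vs M1.
#'
#' @param matrix a `MetaboliteMatrix`.
#' @param group group to fit.
#' @return data.frame, one row per metabolite: `metabolite`, `group`,
#'   `beta_lin` (slope from M1, per unit scaled time), `beta_quad`
#'   (quadratic coefficient from M2), `p_lin`, `p_quad`,
#'   `sigma_subject`, `sigma_resid`, `aic_m0`, `aic_m1`, `aic_m2`,
#'   `n_obs`, `converged`.
#' @export
fit_trend_models <- function(matrix, group) {
  stopifnot(inherits(matrix, "MetaboliteMatrix"))
  s <- matrix$samples
  sel <- !s$is_qc & s$group == group
  if (!any(sel)) stop("group not present in metadata: ", group)
  ids <- s$sample_id[sel]
  day <- s$day[sel]
  subject <- factor(s$subject_id[sel])
  if (length(unique(day)) < 3) stop("need >= 3 timepoints")
  if (nlevels(subject) < 4) stop("need >= 4 subjects")
  tmax <- max(day)
  y_all <- log2(matrix$intensity[, ids, drop = FALSE])
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit_one <- function(yi) {
    ok <- !is.na(yi)
    empty <- list(beta_lin = NA_real_, beta_quad = NA_real_,
                  p_lin = NA_real_, p_quad = NA_real_,
                  sigma_subject = NA_real_, sigma_resid = NA_real_,
                  aic_m0 = NA_real_, aic_m1 = NA_real_, aic_m2 = NA_real_,
                  n_obs = sum(ok), converged = FALSE)
    if (length(unique(day[ok])) < 2) return(empty)
    t1 <- day[ok] / tmax
    t1 <- t1 - mean(t1)
    df <- data.frame(y = yi[ok], t1 = t1, t2 = t1^2, subject = subject[ok])
    fits <- tryCatch({
      m0 <- lme4::lmer(y ~ 1 + (1 | subject), data = df, REML = FALSE,
                       control = ctrl)
      m1 <- lme4::lmer(y ~ t1 + (1 | subject), data = df, REML = FALSE,
                       control = ctrl)
      m2 <- lme4::lmer(y ~ t1 + t2 + (1 | subject), data = df,
                       REML = FALSE, control = ctrl)
      list(m0 = m0, m1 = m1, m2 = m2)
    }, error = function(e) NULL)
    if (is.null(fits)) return(empty)
    ll <- vapply(fits, function(f) as.numeric(logLik(f)), numeric(1))
    p_lin <- pchisq(max(0, 2 * (ll[2] - ll[1])), df = 1,
                    lower.tail = FALSE)
    p_quad <- pchisq(max(0, 2 * (ll[3] - ll[2])), df = 1,
                     lower.tail = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fits$m2))
    conv <- all(vapply(fits, function(f) {
      isTRUE(f@optinfo$conv$opt == 0)
    }, logical(1)))
    list(beta_lin = unname(lme4::fixef(fits$m1)["t1"]),
         beta_quad = unname(lme4::fixef(fits$m2)["t2"]),
         p_lin = p_lin, p_quad = p_quad,
         sigma_subject = vc$sdcor[vc$grp == "subject"],
         sigma_resid = vc$sdcor[vc$grp == "Residual"],
         aic_m0 = 2 * 3 - 2 * ll[1],
         aic_m1 = 2 * 4 - 2 * ll[2],
         aic_m2 = 2 * 5 - 2 * ll[3],
         n_obs = sum(ok), converged = conv)
  }
  rows <- lapply(seq_len(nrow(y_all)), function(i) {
    res <- fit_one(y_all[i, ])
    data.frame(metabolite = rownames(y_all)[i], group = group,
               res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify fitted trends into four categories
#'
#' Two-stage rule: a significant quadratic term (`p_quad < alpha`) gives
#' `model2_up`/`model2_down` by the sign of the quadratic coefficient
#' (up = convex / late rise, down = concave / mid-course peak);
#' otherwise a significant linear term gives `model1_up`/`model1_down`
#' by the sign of the slope; otherwise `none`. With `select = "aic"`
#' the model order is instead chosen by smallest AIC (among models
#' whose added term is significant). Non-converged or skipped fits are
#' labeled `none`.
#'
#' @param fits output of [fit_trend_models()].
#' @param alpha significance level (default 0.05).
#' @param select `"lrt"` (default) or `"aic"`.
#' @return data.frame: `metabolite`, `group`, `label` in
#'   `{model1_up, model1_down, model2_up, model2_down, none}`,
#'   `direction` in `{up, down, none}`.
#' @export
classify_trend <- function(fits, alpha = 0.05, select = c("lrt", "aic")) {
  select <- match.arg(select)
  n <- nrow(fits)
  label <- rep("none", n)
  for (i in seq_len(n)) {
    f <- fits[i, ]
    if (!isTRUE(f$converged) || is.na(f$p_lin) || is.na(f$p_quad)) next
    use_quad <- if (select == "lrt") {
      f$p_quad < alpha
    } else {
      f$p_quad < alpha && f$aic_m2 < f$aic_m1
    }
    if (use_quad && !is.na(f$beta_quad) && f$beta_quad != 0) {
      label[i] <- if (f$beta_quad > 0) "model2_up" else "model2_down"
    } else if (f$p_lin < alpha && !is.na(f$beta_lin) && f$beta_lin != 0) {
      label[i] <- if (f$beta_lin > 0) "model1_up" else "model1_down"
    }
  }
  direction <- ifelse(endsWith(label, "_up"), "up",
                      ifelse(endsWith(label, "_down"), "down", "none"))
  data.frame(metabolite = fits$metabolite, group = fits$group,
             label = label, direction = direction,
             stringsAsFactors = FALSE)
}

#' Select metabolites concordant in C and AE and opposed in A
#'
#' A metabolite is selected iff its trend direction is the same in
#' groups C and AE (and not `none`) and opposite in group A. With
#' `mode = "class"` the full four-way label must match between C and AE
#' instead of the direction alone.
#'
#' @param classes stacked [classify_trend()] output covering groups
#'   C, A and AE.
#' @param mode `"direction"` (default) or `"class"`.
#' @return data.frame: `metabolite`, `class_C`, `class_A`, `class_AE`,
#'   `direction_C`, `direction_A`, `direction_AE`, `selected`.
#' @export
concordance_select <- function(classes, mode = c("direction", "class")) {
  mode <- match.arg(mode)
  need <- c("C", "A", "AE")
  if (!all(need %in% classes$group)) {
    stop("classes must cover groups C, A and AE")
  }
  mets <- unique(classes$metabolite)
  pick <- function(g, col) {
    sub <- classes[classes$group == g, ]
    sub[[col]][match(mets, sub$metabolite)]
  }
  out <- data.frame(
    metabolite = mets,
    class_C = pick("C", "label"),
    class_A = pick("A", "label"),
    class_AE = pick("AE", "label"),
    direction_C = pick("C", "direction"),
    direction_A = pick("A", "direction"),
    direction_AE = pick("AE", "direction"),
    stringsAsFactors = FALSE
  )
  out[is.na(out)] <- "none"
  opposite <- c(up = "down", down = "up")
  same_ca <- if (mode == "direction") {
    out$direction_C == out$direction_AE
  } else {
    out$class_C == out$class_AE
  }
  out$selected <- same_ca &
    out$direction_C %in% c("up", "down") &
    out$direction_A == opposite[out$direction_C]
  out$selected[is.na(out$selected)] <- FALSE
  rownames(out) <- NULL
  out
}

#' Run the LMM trend stage for all groups
#'
#' @param matrix a `MetaboliteMatrix` carrying groups C, A and AE.
#' @param config configuration list.
#' @return list: `fits` (stacked), `classes` (stacked), `concordance`.
#' @export
lmm_stage <- function(matrix, config = default_config()) {
  lc <- config$lmm
  groups <- intersect(c("C", "A", "AE"),
                      unique(matrix$samples$group[!matrix$samples$is_qc]))
  fits <- do.call(rbind, lapply(groups, function(g) {
    fit_trend_models(matrix, g)
  }))
  classes <- do.call(rbind, lapply(groups, function(g) {
    classify_trend(fits[fits$group == g, ], alpha = lc$alpha,
                   select = lc$select)
  }))
  conc <- NULL
  if (all(c("C", "A", "AE") %in% groups)) {
    conc <- concordance_select(classes, mode = lc$concordance)
  }
  list(fits = fits, classes = classes, concordance = conc)
}
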