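# Soft clustering of temporal profiles: per-timepoint medians, row
# standardization, fuzzy c-means (alternating membership/centroid
# updates), minimum-centroid-distance (Dmin) selection of the cluster
# number, and membership-threshold core sets.

#' Per-timepoint median profiles for one group
#'
#' Collapses a metabolite matrix to a metabolite x timepoint profile:
#' each cell is the log2 of the median intensity over the group's
#' non-QC samples at that day (missing samples ignored). The log2 of
#' the median equals the median of the log2 intensities (log2 is
#' monotone), so downstream standardization and clustering operate on
#' the same log2 scale as the rest of the pipeline.
#'
#' @param matrix a `MetaboliteMatrix`.
#' @param group group to profile.
#' @return A `TimeProfile`: list with `profile` (metabolite x day
#'   matrix), `timepoints` (ordered days), `standardized = FALSE`,
#'   `dropped_zero_variance` (empty).
#' @export
timepoint_medians <- function(matrix, group) {
  stopifnot(inherits(matrix, "MetaboliteMatrix"))
  s <- matrix$samples
  sel <- !s$is_qc & s$group == group
  if (!any(sel)) stop("group not present in metadata: ", group)
  days <- sort(unique(s$day[sel]))
  prof <- vapply(days, function(d) {
    ids <- s$sample_id[sel & s$day == d]
    apply(matrix$intensity[, ids, drop = FALSE], 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else median(v)
    })
  }, numeric(nrow(matrix$intensity)))
  if (nrow(matrix$intensity) == 1L) prof <- matrix(prof, nrow = 1L)
  dimnames(prof) <- list(rownames(matrix$intensity), as.character(days))
  if (anyNA(prof)) {
    bad <- which(is.na(prof), arr.ind = TRUE)[1L, ]
    stop(sprintf("no observed sample for metabolite '%s' at day %s",
                 rownames(prof)[bad[1L]], colnames(prof)[bad[2L]]))
  }
  structure(list(profile = log2(prof), timepoints = days,
                 standardized = FALSE,
                 dropped_zero_variance = character(0)),
            class = "TimeProfile")
}

#' @export
print.TimeProfile <- function(x, ...) {
  cat(sprintf("TimeProfile: %d metabolites x %d timepoints (%s)%s\n",
              nrow(x$profile), length(x$timepoints),
              paste(x$timepoints, collapse = ","),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Z-score each profile row across timepoints
#'
#' Each row is centered and scaled to unit sample standard deviation.
#' Zero-variance rows cannot be standardized; they are removed and their
#' names recorded in `dropped_zero_variance`.
#'
#' @param profile a non-standardized `TimeProfile`.
#' @return A standardized `TimeProfile`.
#' @export
standardize_profile <- function(profile) {
  stopifnot(inherits(profile, "TimeProfile"))
  if (profile$standardized) stop("profile is already standardized")
  m <- profile$profile
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  zero <- s == 0 | is.na(s)
  if (all(zero)) stop("all rows have zero variance")
  z <- (m[!zero, , drop = FALSE] - mu[!zero]) / s[!zero]
  structure(list(profile = z, timepoints = profile$timepoints,
                 standardized = TRUE,
                 dropped_zero_variance = rownames(m)[zero]),
            class = "TimeProfile")
}

# Squared Euclidean distances between rows of x and rows of v.
sqdist <- function(x, v) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * tcrossprod(x, v)
  d2[d2 < 0] <- 0
  d2
}

# Initial centroids: c distinct data rows drawn by the current RNG with
# D^2 weighting (each further row drawn with probability proportional to
# its squared distance from the rows already chosen), which spreads the
# starting centroids across the data and avoids the duplicate-centroid
# local optima of uniform draws.
fcm_init_rows <- function(x, c) {
  n <- nrow(x)
  idx <- sample.int(n, 1L)
  while (length(idx) < c) {
    d2 <- apply(sqdist(x, x[idx, , drop = FALSE]), 1L, min)
    d2[idx] <- 0
    cand <- if (sum(d2) > 0) {
      sample.int(n, 1L, prob = d2)
    } else {
      sample(setdiff(seq_len(n), idx), 1L)
    }
    idx <- c(idx, cand)
  }
  x[idx, , drop = FALSE]
}

# Membership update: u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1)).  Points
# coincident with one or more centroids split membership equally among
# the zero-distance centroids.
fcm_memberships <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  zero <- d2 < 1e-24
  u <- w / rowSums(w)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means clustering of a standardized profile
#'
#' Alternating-update fuzzy c-means minimizing
#' `J = sum_i sum_k u_ik^m ||x_i - v_k||^2` with the standard update
#' equations: memberships `u_ik = [sum_j (d_ik/d_ij)^(2/(m-1))]^-1` and
#' centroids `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`. Initial centroids
#' are `c` distinct profile rows drawn by a seeded RNG (or supplied via
#' `init`). Convergence when the maximum absolute membership change
#' drops below `tol`.
#'
#' @param profile a standardized `TimeProfile`.
#' @param c number of clusters, `1 <= c <= nrow`.
#' @param m fuzzifier, > 1 (default 2).
#' @param seed RNG seed for the initialization.
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @param init optional c x timepoint matrix of initial centroids,
#'   overriding the seeded draw.
#' @return A `ClusterResult`: `c`, `m`, `centroids`, `membership`
#'   (rows sum to 1), `objective`, `objective_trace` (non-increasing),
#'   `n_iter`, `converged`, `seed`.
#' @export
fuzzy_cmeans <- function(profile, c, m = 2, seed = 1L, tol = 1e-6,
                         max_iter = 300L, init = NULL) {
  stopifnot(inherits(profile, "TimeProfile"))
  if (!profile$standardized) stop("profile must be standardized first")
  x <- profile$profile
  n <- nrow(x)
  if (!is.numeric(c) || length(c) != 1 || c < 1 || c > n) {
    stop("c must satisfy 1 <= c <= number of rows (", n, ")")
  }
  c <- as.integer(c)
  if (!is.numeric(m) || m <= 1) stop("fuzzifier m must be > 1")
  if (is.null(init)) {
    v <- withr::with_seed(seed, fcm_init_rows(x, c))
  } else {
    stopifnot(is.matrix(init), nrow(init) == c, ncol(init) == ncol(x))
    v <- init
  }
  u <- fcm_memberships(sqdist(x, v), m)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    um <- u^m
    v <- crossprod(um, x) / colSums(um)
    d2 <- sqdist(x, v)
    u_new <- fcm_memberships(d2, m)
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  dimnames(u) <- list(rownames(x), paste0("cluster", seq_len(c)))
  dimnames(v) <- list(paste0("cluster", seq_len(c)), colnames(x))
  structure(list(c = c, m = m, centroids = v, membership = u,
                 objective = trace[length(trace)],
                 objective_trace = trace, n_iter = iter,
                 converged = converged, seed = seed,
                 timepoints = profile$timepoints),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: c = %d, m = %g, %d metabolites, objective %.4f (%d iterations%s)\n",
              x$c, x$m, nrow(x$membership), x$objective, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Fuzzifier value for a profile
#'
#' Returns the configured fuzzifier (default 2), or, when `m` is the
#' string `"estimate"`, a data-driven value from the dimension/size
#' heuristic of Schwaemmle and Jensen (2010):
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`
#' with `N` profiles and `D` timepoints.
#'
#' @param profile a standardized `TimeProfile`.
#' @param m numeric fuzzifier or `"estimate"`.
#' @return A single numeric > 1.
#' @export
estimate_fuzzifier <- function(profile, m = 2) {
  if (is.numeric(m)) {
    if (m <= 1) stop("fuzzifier m must be > 1")
    return(m)
  }
  if (!identical(m, "estimate")) stop("m must be numeric or \"estimate\"")
  n <- nrow(profile$profile)
  d <- ncol(profile$profile)
  1 + (1418 / n + 22.05) * d^-2 +
    (12.33 / n + 0.243) * d^(-0.0406 * log(n) - 0.1134)
}

#' Minimum-centroid-distance curve over candidate cluster numbers
#'
#' For each `c` in `c_min:c_max`, runs [fuzzy_cmeans()] with `repeats`
#' seeds derived from `seed` and records the median (over repeats) of
#' the minimum pairwise Euclidean distance between centroids.
#'
#' @param profile a standardized `TimeProfile`.
#' @param c_min,c_max candidate range (`c_max <= nrow - 1`).
#' @param m fuzzifier.
#' @param repeats runs per `c`.
#' @param seed base seed; run seeds are `seed + 1000*c + r`.
#' @param tol,max_iter passed to [fuzzy_cmeans()].
#' @return A `DminCurve`: data.frame `c`, `dmin`, plus attributes
#'   `repeats` and `seed`.
#' @export
dmin_curve <- function(profile, c_min = 2L, c_max, m = 2, repeats = 3L,
                       seed = 1L, tol = 1e-6, max_iter = 300L) {
  stopifnot(inherits(profile, "TimeProfile"))
  n <- nrow(profile$profile)
  if (missing(c_max)) c_max <- min(8L, n - 1L)
  if (c_max < c_min) stop("c_max must be >= c_min")
  if (c_max > n - 1L) stop("c_max must be <= nrow - 1")
  cs <- seq.int(c_min, c_max)
  dmin <- vapply(cs, function(ck) {
    vals <- vapply(seq_len(repeats), function(r) {
      fit <- fuzzy_cmeans(profile, ck, m = m,
                          seed = seed + 1000L * ck + r,
                          tol = tol, max_iter = max_iter)
      min(dist(fit$centroids))
    }, numeric(1))
    median(vals)
  }, numeric(1))
  out <- data.frame(c = cs, dmin = dmin)
  attr(out, "repeats") <- repeats
  attr(out, "seed") <- seed
  class(out) <- c("DminCurve", "data.frame")
  out
}

#' Select the cluster number from a Dmin curve
#'
#' Automated elbow rule standing in for visual inspection. The relative
#' drop at `c` is `r(c) = (Dmin(c) - Dmin(c+1)) / Dmin(c)`. A drop
#' qualifies when `r(c) >= delta` *and* it lands in the curve's floor —
#' `Dmin(c+1) <= 2 * min(Dmin)` — i.e. adding the (c+1)-th centroid
#' produced a near-duplicate, the signature of exceeding the true
#' cluster number. The selected `c` is the smallest qualifying drop,
#' i.e. the first entry into the floor. A curve with no qualifying drop
#' returns the
#' smallest candidate with attribute `flat_curve = TRUE` and a warning.
#' A non-NULL `force_c` short-circuits the rule.
#'
#' @param curve a `DminCurve` with at least 3 candidate values.
#' @param delta relative-drop threshold (default 0.2).
#' @param force_c manual override.
#' @return Integer cluster number (attribute `flat_curve` when the rule
#'   found no elbow).
#' @export
select_optimal_c <- function(curve, delta = 0.2, force_c = NULL) {
  if (!is.null(force_c)) return(as.integer(force_c))
  stopifnot(inherits(curve, "DminCurve"))
  if (nrow(curve) < 3) stop("curve needs at least 3 candidate values of c")
  d <- curve$dmin
  r <- (d[-length(d)] - d[-1]) / d[-length(d)]
  in_floor <- d[-1] <= 2 * min(d)
  ok <- which(r >= delta & in_floor)
  if (!length(ok)) {
    warning("no qualifying Dmin drop; returning c_min")
    return(structure(as.integer(curve$c[1L]), flat_curve = TRUE))
  }
  as.integer(curve$c[min(ok)])
}

#' Core members of each cluster
#'
#' Each metabolite is assigned to its argmax-membership cluster (ties to
#' the lowest cluster index) and kept as a core member iff that
#' membership strictly exceeds `threshold`.
#'
#' @param result a `ClusterResult`.
#' @param threshold membership cut (default 0.7).
#' @return A `CoreSet` data.frame: `metabolite`, `cluster`, `membership`,
#'   with attribute `threshold`.
#' @export
core_members <- function(result, threshold = 0.7) {
  stopifnot(inherits(result, "ClusterResult"))
  u <- result$membership
  best <- apply(u, 1L, which.max)   # ties -> lowest index
  best_u <- u[cbind(seq_len(nrow(u)), best)]
  keep <- best_u > threshold
  out <- data.frame(metabolite = rownames(u)[keep],
                    cluster = as.integer(best[keep]),
                    membership = best_u[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("CoreSet", "data.frame")
  out
}

#' Heatmap-ready matrix of core metabolites
#'
#' Rows are core metabolites grouped by cluster (ascending cluster
#' index) and ordered within cluster by descending membership; values
#' are the standardized profile.
#'
#' @param result a `ClusterResult`.
#' @param core a `CoreSet` from the same result.
#' @param profile the standardized `TimeProfile` that was clustered.
#' @return A numeric matrix with attributes `cluster` and `membership`
#'   giving the per-row annotation (zero rows when the core is empty).
#' @export
heatmap_matrix <- function(result, core, profile) {
  stopifnot(inherits(result, "ClusterResult"),
            inherits(profile, "TimeProfile"))
  if (nrow(core) == 0) {
    warning("empty core set; heatmap matrix has no rows")
    m <- profile$profile[integer(0), , drop = FALSE]
    attr(m, "cluster") <- integer(0)
    attr(m, "membership") <- numeric(0)
    return(m)
  }
  ord <- order(core$cluster, -core$membership)
  core <- core[ord, , drop = FALSE]
  m <- profile$profile[core$metabolite, , drop = FALSE]
  attr(m, "cluster") <- core$cluster
  attr(m, "membership") <- core$membership
  m
}

#' Run the clustering stage for one group
#'
#' Medians, standardization, Dmin-based selection of `c` (honoring
#' `cluster$force_c`), the final fuzzy c-means fit, and the core set.
#'
#' @param matrix a `MetaboliteMatrix`.
#' @param group group to cluster.
#' @param config configuration list.
#' @param seed RNG seed for initializations.
#' @return list: `profile` (standardized), `curve`, `c`, `fit`, `core`.
#' @export
cluster_stage <- function(matrix, group, config = default_config(),
                          seed = 1L) {
  cc <- config$cluster
  prof <- standardize_profile(timepoint_medians(matrix, group))
  m <- estimate_fuzzifier(prof, cc$m)
  c_max <- min(cc$c_max, nrow(prof$profile) - 1L)
  curve <- dmin_curve(prof, c_min = cc$c_min, c_max = c_max, m = m,
                      repeats = cc$repeats, seed = seed,
                      tol = cc$tol, max_iter = cc$max_iter)
  c_star <- suppressWarnings(
    select_optimal_c(curve, delta = cc$delta, force_c = cc$force_c))
  fit <- fuzzy_cmeans(prof, c_star, m = m, seed = seed,
                      tol = cc$tol, max_iter = cc$max_iter)
  core <- core_members(fit, threshold = cc$membership_threshold)
  list(profile = prof, curve = curve, c = c_star, fit = fit, core = core)
}
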