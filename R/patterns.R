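# Canonical temporal patterns: a small template library on the study's
# day grid, correlation-based assignment of cluster centroids to
# templates, and cross-group comparison of core-metabolite patterns.

#' Temporal pattern template library
#'
#' Builds standardized (mean 0, sd 1 across timepoints) template shapes
#' on the given day grid.
#'
#' `"default5"` mirrors the broad time-course categories seen in
#' longitudinal metabolomics: P1 rise-then-fall (peak at `peak_day`),
#' P2 fall-then-rise (its negative), P3 monotone up, P4 monotone down,
#' P5 late rise (flat through the intervention, rising in recovery,
#' i.e. after the second-to-last day).
#'
#' `"trend4"` holds polynomial trend shapes used by the study
#' generator: T1 linear up, T2 linear down, T3 convex quadratic
#' ("quad up"), T4 concave quadratic ("quad down"), on scaled centered
#' time.
#'
#' @param timepoints ordered integer days (>= 3).
#' @param library `"default5"` or `"trend4"`.
#' @param peak_day interior day carrying the P1 peak / P2 trough.
#' @return data.frame of class `PatternTemplates`: `pattern_id`, `name`,
#'   and one column per timepoint.
#' @export
archetype_templates <- function(timepoints, library = "default5",
                                peak_day = 28) {
  timepoints <- sort(as.numeric(timepoints))
  if (length(timepoints) < 3) stop("need at least 3 timepoints")
  zs <- function(v) (v - mean(v)) / sd(v)
  if (identical(library, "default5")) {
    if (!peak_day %in% timepoints) {
      stop("peak_day must be one of the timepoints")
    }
    p1 <- zs(-abs(timepoints - peak_day))
    p3 <- zs(timepoints)
    t_pen <- timepoints[length(timepoints) - 1L]
    p5raw <- pmax(0, timepoints - t_pen)
    p5 <- zs(p5raw)
    shapes <- rbind(p1, -p1, p3, -p3, p5)
    nms <- c("rise_then_fall", "fall_then_rise", "monotone_up",
             "monotone_down", "late_rise")
  } else if (identical(library, "trend4")) {
    tc <- timepoints / max(timepoints)
    tc <- tc - mean(tc)
    lin <- zs(tc)
    quad <- zs(tc^2)
    shapes <- rbind(lin, -lin, quad, -quad)
    nms <- c("linear_up", "linear_down", "quad_up", "quad_down")
  } else {
    stop("unknown template library: ", library)
  }
  out <- data.frame(pattern_id = seq_len(nrow(shapes)), name = nms,
                    stringsAsFactors = FALSE)
  shapes <- as.data.frame(shapes)
  names(shapes) <- as.character(timepoints)
  rownames(shapes) <- NULL
  out <- cbind(out, shapes)
  class(out) <- c("PatternTemplates", "data.frame")
  out
}

template_matrix <- function(templates) {
  m <- as.matrix(templates[, -(1:2), drop = FALSE])
  rownames(m) <- templates$name
  m
}

#' Assign a centroid to its best-matching pattern
#'
#' Pearson correlation of the centroid against every template; the
#' argmax wins, exact ties break to the lowest `pattern_id`.
#'
#' @param centroid numeric vector over the template timepoints.
#' @param templates a `PatternTemplates` table.
#' @return list: `pattern_id`, `name`, `correlation`.
#' @export
assign_pattern <- function(centroid, templates) {
  tm <- template_matrix(templates)
  if (length(centroid) != ncol(tm)) {
    stop("centroid length does not match template timepoints")
  }
  if (sd(centroid) == 0) stop("zero-variance centroid cannot be assigned")
  cors <- apply(tm, 1L, function(t) cor(centroid, t))
  best <- which.max(cors)   # which.max takes the first (lowest id) on ties
  list(pattern_id = templates$pattern_id[best],
       name = templates$name[best],
       correlation = unname(cors[best]))
}

#' Assign every cluster centroid of a fit to a pattern
#'
#' @param result a `ClusterResult`.
#' @param templates a `PatternTemplates` table on the same timepoints.
#' @return data.frame: `cluster`, `pattern_id`, `pattern_name`,
#'   `correlation`.
#' @export
assign_patterns <- function(result, templates) {
  stopifnot(inherits(result, "ClusterResult"))
  rows <- lapply(seq_len(result$c), function(k) {
    a <- assign_pattern(result$centroids[k, ], templates)
    data.frame(cluster = k, pattern_id = a$pattern_id,
               pattern_name = a$name, correlation = a$correlation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare core-metabolite patterns between two groups
#'
#' Intersects the core sets of two groups (same ion mode and day grid)
#' and flags, per shared metabolite, whether its assigned pattern
#' differs between the groups; membership scores in both groups and
#' their difference are reported alongside.
#'
#' @param core_x,core_y `CoreSet` tables.
#' @param assign_x,assign_y cluster-to-pattern tables from
#'   [assign_patterns()] for the same fits.
#' @param labels length-2 character, names of the two groups.
#' @return A `PatternChangeReport`: list with `table` (one row per
#'   shared metabolite), `n_shared`, `n_changed`.
#' @export
compare_core_patterns <- function(core_x, assign_x, core_y, assign_y,
                                  labels = c("X", "Y")) {
  shared <- intersect(core_x$metabolite, core_y$metabolite)
  if (!length(shared)) {
    warning("no shared core metabolites between ", labels[1], " and ",
            labels[2])
  }
  ix <- match(shared, core_x$metabolite)
  iy <- match(shared, core_y$metabolite)
  px <- assign_x$pattern_id[match(core_x$cluster[ix], assign_x$cluster)]
  py <- assign_y$pattern_id[match(core_y$cluster[iy], assign_y$cluster)]
  tab <- data.frame(
    metabolite = shared,
    cluster_x = core_x$cluster[ix],
    cluster_y = core_y$cluster[iy],
    pattern_x = px,
    pattern_y = py,
    membership_x = core_x$membership[ix],
    membership_y = core_y$membership[iy],
    membership_delta = core_y$membership[iy] - core_x$membership[ix],
    pattern_changed = px != py,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_shared = length(shared),
                 n_changed = sum(tab$pattern_changed),
                 groups = labels),
            class = "PatternChangeReport")
}

#' @export
print.PatternChangeReport <- function(x, ...) {
  cat(sprintf("PatternChangeReport %s vs %s: %d shared core metabolites, %d with changed pattern\n",
              x$groups[1], x$groups[2], x$n_shared, x$n_changed))
  invisible(x)
}
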