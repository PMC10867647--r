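# Paired differential statistics (day 63 vs day 0 by default), volcano
# classification at p < 0.05 and |log2FC| > 1, and exclusive set overlaps
# across groups.

#' Paired per-metabolite change between two days
#'
#' For one group, compares `day_cmp` against `day_ref` using only
#' subjects with both days observed for the metabolite. The log2 fold
#' change is the mean over those subjects of
#' `log2(x[day_cmp] / x[day_ref])`; the p-value comes from a two-sided
#' paired test on per-subject log2 intensities (`t` by default,
#' `wilcoxon` optional). Metabolites with fewer than 3 complete pairs, or
#' a degenerate zero-variance difference, get `p_value = NA`.
#'
#' @param matrix a `MetaboliteMatrix`.
#' @param group one of `"C"`, `"A"`, `"AE"`.
#' @param day_ref reference day (default 0).
#' @param day_cmp comparison day (default 63).
#' @param test `"t"` or `"wilcoxon"`.
#' @return data.frame: `metabolite`, `group`, `log2fc`, `p_value`,
#'   `q_value` (BH over the non-missing p), `n_pairs`.
#' @export
paired_change <- function(matrix, group, day_ref = 0L, day_cmp = 63L,
                          test = c("t", "wilcoxon")) {
  stopifnot(inherits(matrix, "MetaboliteMatrix"))
  test <- match.arg(test)
  s <- matrix$samples
  if (!group %in% s$group) stop("group not present in metadata: ", group)
  sel <- !s$is_qc & s$group == group
  if (!any(sel & s$day == day_ref) || !any(sel & s$day == day_cmp)) {
    stop(sprintf("group %s lacks samples on day %d or %d",
                 group, day_ref, day_cmp))
  }
  ref <- s[sel & s$day == day_ref, c("sample_id", "subject_id")]
  cmp <- s[sel & s$day == day_cmp, c("sample_id", "subject_id")]
  common <- intersect(ref$subject_id, cmp$subject_id)
  ref_ids <- ref$sample_id[match(common, ref$subject_id)]
  cmp_ids <- cmp$sample_id[match(common, cmp$subject_id)]
  lref <- log2(matrix$intensity[, ref_ids, drop = FALSE])
  lcmp <- log2(matrix$intensity[, cmp_ids, drop = FALSE])
  d <- lcmp - lref      # per-subject log2 ratios
  stats_one <- function(di) {
    di <- di[!is.na(di)]
    n <- length(di)
    lfc <- if (n) mean(di) else NA_real_
    p <- NA_real_
    if (n >= 3 && sd(di) > 0) {
      # t.test itself refuses near-constant differences; flag those NA
      p <- tryCatch({
        if (test == "t") {
          t.test(di)$p.value
        } else {
          suppressWarnings(wilcox.test(di, exact = FALSE)$p.value)
        }
      }, error = function(e) NA_real_)
    }
    c(lfc, p, n)
  }
  res <- t(apply(d, 1L, stats_one))
  out <- data.frame(
    metabolite = rownames(matrix$intensity),
    group = group,
    log2fc = res[, 1L],
    p_value = res[, 2L],
    n_pairs = as.integer(res[, 3L]),
    stringsAsFactors = FALSE
  )
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  rownames(out) <- NULL
  out[, c("metabolite", "group", "log2fc", "p_value", "q_value", "n_pairs")]
}

#' Two-stage volcano classification
#'
#' `changed` = metabolites with `p_value < p_thresh` (strict);
#' `strong` = changed metabolites with `|log2fc| > lfc_thresh` (strict).
#' Metabolites with missing p are never classified.
#'
#' @param stats output of [paired_change()].
#' @param p_thresh p-value cut (default 0.05).
#' @param lfc_thresh absolute log2-fold-change cut (default 1, i.e.
#'   2-fold).
#' @return list with character vectors `changed` and `strong`, and the
#'   stats table with a `class` column (`"strong"`, `"changed"`, `"ns"`).
#' @export
classify_significant <- function(stats, p_thresh = 0.05, lfc_thresh = 1) {
  ok <- !is.na(stats$p_value)
  changed <- ok & stats$p_value < p_thresh
  strong <- changed & !is.na(stats$log2fc) & abs(stats$log2fc) > lfc_thresh
  stats$class <- ifelse(strong, "strong", ifelse(changed, "changed", "ns"))
  list(changed = stats$metabolite[changed],
       strong = stats$metabolite[strong],
       table = stats)
}

#' Exclusive overlap regions of k sets
#'
#' Computes the cardinality of every exclusive region of the Venn diagram
#' of the given sets (all 2^k - 1 nonempty membership signatures).
#'
#' @param sets named list of >= 2 character vectors.
#' @return data.frame with `region` (set names joined by `&`), `count`,
#'   plus attribute `"intersection_all"` (size of the full intersection,
#'   which for 3 sets is the triple region).
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets))) {
    stop("sets must be a named list of at least 2 sets")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  k <- length(sets)
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(r) paste(which(r), collapse = ","))
  combos <- unlist(lapply(seq_len(k), function(size) {
    utils::combn(k, size, simplify = FALSE)
  }), recursive = FALSE)
  region <- vapply(combos, function(ix) {
    paste(names(sets)[ix], collapse = "&")
  }, character(1))
  count <- vapply(combos, function(ix) {
    sum(sig == paste(ix, collapse = ","))
  }, integer(1))
  out <- data.frame(region = region, count = count,
                    stringsAsFactors = FALSE)
  attr(out, "intersection_all") <-
    length(Reduce(intersect, sets))
  out
}

#' Run the differential stage for several groups
#'
#' @param matrix a `MetaboliteMatrix`.
#' @param groups groups to analyze (default all present).
#' @param config configuration list.
#' @return list with `stats` (stacked classified table) and `overlaps`
#'   (exclusive regions of the changed sets, when >= 2 groups).
#' @export
differential_stage <- function(matrix, groups = NULL,
                               config = default_config()) {
  dc <- config$differential
  s <- matrix$samples
  if (is.null(groups)) {
    groups <- intersect(c("C", "A", "AE"), unique(s$group[!s$is_qc]))
  }
  per_group <- lapply(groups, function(g) {
    st <- paired_change(matrix, g, day_ref = dc$day_ref,
                        day_cmp = dc$day_cmp, test = dc$test)
    classify_significant(st, p_thresh = dc$p_threshold,
                         lfc_thresh = dc$lfc_thresh)
  })
  names(per_group) <- groups
  stats <- do.call(rbind, lapply(per_group, `[[`, "table"))
  rownames(stats) <- NULL
  overlaps <- NULL
  if (length(groups) >= 2) {
    overlaps <- overlap_sets(lapply(per_group, `[[`, "changed"))
  }
  list(stats = stats, overlaps = overlaps,
       changed = lapply(per_group, `[[`, "changed"),
       strong = lapply(per_group, `[[`, "strong"))
}
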