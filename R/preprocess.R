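# Preprocessing: MS2-score filter, collapse of duplicate features to one
# metabolite, QC stability report (CV over QC injections, sample PCA).

#' Filter features by MS2 identification score
#'
#' Retains features whose `ms2_score` is strictly greater than
#' `threshold`; features with a missing score are treated as unidentified
#' and dropped. Row order is preserved.
#'
#' @param table a `FeatureTable`.
#' @param threshold score cut in \[0,1\]; default 0.5.
#' @return A filtered `FeatureTable` (possibly with zero rows).
#' @export
filter_ms2 <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "FeatureTable"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0,1]")
  }
  keep <- !is.na(table$features$ms2_score) &
    table$features$ms2_score > threshold
  feature_table(table$features[keep, , drop = FALSE],
                table$intensity[keep, , drop = FALSE])
}

#' Collapse duplicate features to one row per metabolite
#'
#' When several features map to the same metabolite name, the metabolite's
#' per-sample value is the elementwise maximum over those features
#' (missing cells ignored; a cell missing in every feature stays missing).
#' The alternative `"best_feature"` keeps the single feature with the
#' highest mean intensity. Metabolite order follows first appearance.
#'
#' @param table a non-empty `FeatureTable`.
#' @param samples sample metadata to attach to the result.
#' @param method `"elementwise_max"` (default) or `"best_feature"`.
#' @return A `MetaboliteMatrix`.
#' @export
collapse_to_metabolites <- function(table, samples,
                                    method = c("elementwise_max",
                                               "best_feature")) {
  stopifnot(inherits(table, "FeatureTable"))
  method <- match.arg(method)
  if (nrow(table$intensity) == 0) stop("cannot collapse an empty table")
  names_ord <- unique(table$features$metabolite_name)
  idx_by_name <- split(seq_len(nrow(table$intensity)),
                       factor(table$features$metabolite_name,
                              levels = names_ord))
  collapse_one <- function(idx) {
    block <- table$intensity[idx, , drop = FALSE]
    if (length(idx) == 1L) return(block[1L, ])
    if (method == "elementwise_max") {
      apply(block, 2L, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else max(v)
      })
    } else {
      means <- rowMeans(block, na.rm = TRUE)
      block[which.max(means), ]
    }
  }
  out <- t(vapply(idx_by_name, collapse_one,
                  numeric(ncol(table$intensity))))
  colnames(out) <- colnames(table$intensity)
  metabolite_matrix(out, samples)
}

#' QC stability report
#'
#' Computes, per metabolite, the coefficient of variation (sample
#' sd / mean) over the QC injections, and a PCA of all samples on log2
#' intensities (metabolites centered; metabolites with any missing value
#' are excluded from the PCA).
#'
#' @param matrix a `MetaboliteMatrix`.
#' @param n_components number of principal components to report.
#' @return A list of class `QCReport`: `cv` (named numeric, possibly
#'   empty), `n_qc`, `scores` (sample x component matrix), `explained`
#'   (variance fractions), `n_pca_metabolites`.
#' @export
qc_report <- function(matrix, n_components = 2L) {
  stopifnot(inherits(matrix, "MetaboliteMatrix"))
  qc_ids <- matrix$samples$sample_id[matrix$samples$is_qc]
  n_qc <- length(qc_ids)
  if (n_qc >= 2) {
    qc <- matrix$intensity[, qc_ids, drop = FALSE]
    cv <- apply(qc, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      sd(v) / mean(v)
    })
  } else {
    warning("fewer than 2 QC samples; CV section empty")
    cv <- setNames(numeric(0), character(0))
  }
  x <- log2(matrix$intensity)
  complete <- rowSums(is.na(x)) == 0
  scores <- NULL
  explained <- numeric(0)
  if (ncol(x) >= 3 && sum(complete) >= 2) {
    pc <- prcomp(t(x[complete, , drop = FALSE]), center = TRUE,
                 scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  } else {
    warning("not enough samples or complete metabolites for PCA")
  }
  structure(list(cv = cv, n_qc = n_qc, scores = scores,
                 explained = explained,
                 n_pca_metabolites = sum(complete)),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d QC samples; median CV %.3f; PCA on %d metabolites\n",
              x$n_qc,
              if (length(x$cv)) median(x$cv, na.rm = TRUE) else NA_real_,
              x$n_pca_metabolites))
  invisible(x)
}

#' Run the preprocessing stage
#'
#' MS2 filter, optional QC-CV filter, and collapse to a metabolite
#' matrix, driven by the `preprocess` section of the configuration.
#'
#' @param features a `FeatureTable`.
#' @param samples sample metadata.
#' @param config configuration list (see [default_config()]).
#' @return A list with `matrix` (`MetaboliteMatrix`) and `qc` (`QCReport`).
#' @export
preprocess_study <- function(features, samples, config = default_config()) {
  pc <- config$preprocess
  ft <- filter_ms2(features, pc$ms2_threshold)
  if (nrow(ft$intensity) == 0) stop("no features survive the MS2 filter")
  mm <- collapse_to_metabolites(ft, samples, method = pc$collapse)
  qc <- suppressWarnings(qc_report(mm))
  if (!is.null(pc$max_qc_cv) && length(qc$cv)) {
    keep <- is.na(qc$cv) | qc$cv <= pc$max_qc_cv
    mm <- metabolite_matrix(mm$intensity[keep, , drop = FALSE], samples)
  }
  list(matrix = mm, qc = qc)
}
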