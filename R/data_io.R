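#' @importFrom stats median sd setNames cor prcomp t.test wilcox.test
#'   phyper p.adjust pchisq logLik rnorm runif dist
#' @importFrom utils head modifyList
NULL

# ---------------------------------------------------------------------------
# Domain containers.  Lightweight S3: a FeatureTable couples a feature
# annotation data.frame with an intensity matrix (features x samples); a
# MetaboliteMatrix couples a metabolite x sample matrix with its sample
# metadata.  Intensities are strictly positive where present; missing cells
# are NA.

#' Construct a feature table
#'
#' @param features data.frame with columns `feature_id`, `metabolite_name`,
#'   `ms2_score` (numeric in \[0,1\] or `NA`).
#' @param intensity numeric matrix, rows = features (rownames =
#'   `feature_id`), columns = sample ids; strictly positive or `NA`.
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(features, intensity) {
  stopifnot(is.data.frame(features), is.matrix(intensity))
  req <- c("feature_id", "metabolite_name", "ms2_score")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("feature annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  features <- as.data.frame(features)[req]
  features$feature_id <- as.character(features$feature_id)
  features$metabolite_name <- as.character(features$metabolite_name)
  features$ms2_score <- as.numeric(features$ms2_score)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  }
  if (nrow(features) != nrow(intensity)) {
    stop("feature annotation and intensity matrix disagree on row count")
  }
  rownames(intensity) <- features$feature_id
  bad <- features$ms2_score[!is.na(features$ms2_score)]
  if (any(bad < 0 | bad > 1)) stop("ms2_score outside [0,1]")
  if (any(intensity[!is.na(intensity)] <= 0)) {
    stop("intensities must be strictly positive where present")
  }
  if (anyDuplicated(colnames(intensity))) stop("duplicate sample_id columns")
  structure(list(features = features, intensity = intensity),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features x %d samples (%d metabolite names)\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$features$metabolite_name))))
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$intensity)

#' Construct a metabolite matrix
#'
#' @param intensity metabolite x sample numeric matrix (rownames =
#'   metabolite names), strictly positive or `NA`.
#' @param samples validated sample metadata (see [validate_samples()])
#'   covering at least the matrix columns.
#' @return An object of class `MetaboliteMatrix`.
#' @export
metabolite_matrix <- function(intensity, samples) {
  stopifnot(is.matrix(intensity))
  if (is.null(rownames(intensity))) stop("intensity needs metabolite rownames")
  if (is.null(colnames(intensity))) stop("intensity needs sample_id colnames")
  if (anyDuplicated(rownames(intensity))) stop("duplicate metabolite names")
  if (anyDuplicated(colnames(intensity))) stop("duplicate sample columns")
  samples <- validate_samples(samples)
  unknown <- setdiff(colnames(intensity), samples$sample_id)
  if (length(unknown)) {
    stop("sample column(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  }
  if (any(intensity[!is.na(intensity)] <= 0)) {
    stop("intensities must be strictly positive where present")
  }
  samples <- samples[match(colnames(intensity), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(intensity = intensity, samples = samples),
            class = "MetaboliteMatrix")
}

#' @export
print.MetaboliteMatrix <- function(x, ...) {
  cat(sprintf("MetaboliteMatrix: %d metabolites x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  invisible(x)
}

#' @export
dim.MetaboliteMatrix <- function(x) dim(x$intensity)

#' Validate sample metadata
#'
#' Checks the sample-metadata contract: unique `sample_id`; QC samples
#' flagged `is_qc` need no subject/group/day; non-QC samples must carry
#' `subject_id`, `group` and `day`; each (subject_id, day, ion_mode)
#' occurs at most once.
#'
#' @param samples data.frame with columns `sample_id`, `subject_id`,
#'   `group`, `day`, `ion_mode`, `is_qc`.
#' @param day_set optional admissible set of days; `NULL` skips the check.
#' @return The metadata as a normalized data.frame.
#' @export
validate_samples <- function(samples, day_set = NULL) {
  req <- c("sample_id", "subject_id", "group", "day", "ion_mode", "is_qc")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  s <- as.data.frame(samples)[req]
  s$sample_id <- as.character(s$sample_id)
  s$subject_id <- as.character(s$subject_id)
  s$subject_id[!is.na(s$subject_id) & s$subject_id == ""] <- NA_character_
  s$group <- as.character(s$group)
  s$group[!is.na(s$group) & s$group == ""] <- NA_character_
  s$day <- suppressWarnings(as.integer(s$day))
  s$ion_mode <- as.character(s$ion_mode)
  s$is_qc <- as.logical(as.integer(s$is_qc))
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  }
  if (any(is.na(s$is_qc))) stop("is_qc must be 0/1 for every sample")
  if (any(!s$ion_mode %in% c("POS", "NEG"))) {
    stop("ion_mode must be POS or NEG")
  }
  nonqc <- s[!s$is_qc, , drop = FALSE]
  bad <- is.na(nonqc$subject_id) | is.na(nonqc$group) | is.na(nonqc$day)
  if (any(bad)) {
    stop("non-QC sample(s) lacking subject_id, group or day: ",
         paste(nonqc$sample_id[bad], collapse = ", "))
  }
  if (any(!nonqc$group %in% c("C", "A", "AE"))) {
    stop("group must be one of C, A, AE")
  }
  if (!is.null(day_set) && any(!nonqc$day %in% day_set)) {
    stop("day outside the configured day set: ",
         paste(unique(nonqc$day[!nonqc$day %in% day_set]), collapse = ", "))
  }
  key <- paste(nonqc$subject_id, nonqc$day, nonqc$ion_mode, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- nonqc$sample_id[duplicated(key)]
    stop("duplicate (subject_id, day, ion_mode): ",
         paste(dup, collapse = ", "))
  }
  s
}

# ---------------------------------------------------------------------------
# Readers / writers.  TSV or CSV on input (dialect by extension), always
# TSV on output, missing cells as empty fields, floats at a fixed number
# of significant digits for deterministic files.

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data.table::fread(path, sep = sep, na.strings = c("", "NA"),
                    colClasses = NULL, data.table = FALSE)
}

#' Read a study (feature table + sample metadata)
#'
#' @param feature_path features file: columns `feature_id`,
#'   `metabolite_name`, `ms2_score`, then one intensity column per sample.
#' @param meta_path sample metadata file (see [validate_samples()]).
#' @param day_set optional admissible day set for validation.
#' @return A list with elements `features` (a `FeatureTable`) and
#'   `samples` (validated metadata).
#' @export
read_study <- function(feature_path, meta_path, day_set = NULL) {
  if (!file.exists(feature_path)) stop("file not found: ", feature_path)
  if (!file.exists(meta_path)) stop("file not found: ", meta_path)
  meta <- validate_samples(read_delim_auto(meta_path), day_set = day_set)
  feat <- read_delim_auto(feature_path)
  ann_cols <- c("feature_id", "metabolite_name", "ms2_score")
  missing_cols <- setdiff(ann_cols, names(feat))
  if (length(missing_cols)) {
    stop("features file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(feat), ann_cols)
  unknown <- setdiff(sample_cols, meta$sample_id)
  if (length(unknown)) {
    stop("feature column(s) not in sample metadata: ",
         paste(unknown, collapse = ", "))
  }
  intensity <- as.matrix(feat[sample_cols])
  storage.mode(intensity) <- "double"
  ft <- feature_table(feat[ann_cols], intensity)
  list(features = ft, samples = meta)
}

#' Write a pipeline table to TSV
#'
#' Deterministic serialization: fixed column order as given, numeric
#' columns rounded to `digits` significant digits, missing cells written
#' as empty fields, tab separated.
#'
#' @param obj a data.frame, `FeatureTable` or `MetaboliteMatrix`.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, digits = 6L) UseMethod("write_table")

#' @export
write_table.data.frame <- function(obj, path, digits = 6L) {
  out <- obj
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- signif(out[[j]], digits)
    }
  }
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @export
write_table.matrix <- function(obj, path, digits = 6L) {
  df <- data.frame(row_id = rownames(obj), as.data.frame(obj),
                   check.names = FALSE)
  write_table.data.frame(df, path, digits = digits)
}

#' @export
write_table.MetaboliteMatrix <- function(obj, path, digits = 6L) {
  df <- data.frame(metabolite_name = rownames(obj$intensity),
                   as.data.frame(obj$intensity), check.names = FALSE)
  write_table.data.frame(df, path, digits = digits)
}

#' @export
write_table.FeatureTable <- function(obj, path, digits = 6L) {
  df <- cbind(obj$features,
              as.data.frame(obj$intensity, check.names = FALSE))
  write_table.data.frame(df, path, digits = digits)
}

#' Write a full study to disk
#'
#' Writes `features.tsv` and `samples.tsv` under `dir` in the layout
#' accepted by [read_study()].
#'
#' @param features a `FeatureTable`.
#' @param samples sample metadata.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(features, samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(features, file.path(dir, "features.tsv"))
  s <- samples
  s$is_qc <- as.integer(s$is_qc)
  write_table(s, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Read a metabolite matrix written by [write_table()]
#'
#' @param path a TSV whose first column is `metabolite_name`.
#' @param samples sample metadata for the matrix columns.
#' @return A `MetaboliteMatrix`.
#' @export
read_metabolite_matrix <- function(path, samples) {
  df <- read_delim_auto(path)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  metabolite_matrix(m, samples)
}

#' Subset a study to one ion mode
#'
#' Keeps the samples acquired in `ion_mode` and drops features with no
#' observed intensity in those samples.
#'
#' @param features a `FeatureTable`.
#' @param samples sample metadata.
#' @param ion_mode `"POS"` or `"NEG"`.
#' @return A list with the subset `features` and `samples`.
#' @export
subset_ion_mode <- function(features, samples, ion_mode = c("POS", "NEG")) {
  ion_mode <- match.arg(ion_mode)
  keep_samples <- samples$sample_id[samples$ion_mode == ion_mode]
  keep_samples <- intersect(colnames(features$intensity), keep_samples)
  if (!length(keep_samples)) stop("no samples in ion mode ", ion_mode)
  intensity <- features$intensity[, keep_samples, drop = FALSE]
  keep_rows <- rowSums(!is.na(intensity)) > 0
  ft <- feature_table(features$features[keep_rows, , drop = FALSE],
                      intensity[keep_rows, , drop = FALSE])
  list(features = ft,
       samples = samples[samples$sample_id %in% keep_samples, , drop = FALSE])
}
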