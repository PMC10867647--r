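# End-to-end pipeline: preprocessing -> differential -> clustering ->
# patterns -> LMM trends -> concordance -> enrichment, per ion mode,
# with every stage's table written to the output directory.

#' Run the full pipeline on a study
#'
#' Processes each ion mode present in the metadata: MS2 filter and
#' collapse, QC report, paired differential statistics with set
#' overlaps, per-group soft clustering with Dmin-based cluster-number
#' selection, pattern assignment and cross-group core comparisons
#' (C vs A and A vs AE), per-metabolite mixed-model trend
#' classification, C/AE-vs-A concordance selection, and pathway
#' enrichment plus class composition of the concordant set. All outputs
#' are written as TSV/JSON under `out_dir`.
#'
#' @param features a `FeatureTable` (both ion modes allowed).
#' @param samples sample metadata.
#' @param out_dir output directory.
#' @param config configuration list.
#' @param seed RNG seed for clustering initializations.
#' @param annotation optional `AnnotationMap`; defaults to the packaged
#'   toy annotation over the preprocessed universe.
#' @return A nested list of per-mode results, invisibly.
#' @export
run_pipeline <- function(features, samples, out_dir,
                         config = default_config(), seed = 1L,
                         annotation = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  modes <- intersect(c("POS", "NEG"), unique(samples$ion_mode))
  results <- list()
  for (mode in modes) {
    cm_log("info", "processing ion mode ", mode)
    sub <- subset_ion_mode(features, samples, mode)
    res <- run_pipeline_mode(sub$features, sub$samples, out_dir, mode,
                             config, seed, annotation)
    results[[mode]] <- res
  }
  invisible(results)
}

run_pipeline_mode <- function(features, samples, out_dir, mode, config,
                              seed, annotation) {
  tag <- function(name, ext = "tsv") {
    file.path(out_dir, sprintf("%s_%s.%s", name, mode, ext))
  }
  # ---- preprocess
  pre <- preprocess_study(features, samples, config)
  mm <- pre$matrix
  write_table(mm, tag("metabolites"))
  qc_df <- data.frame(metabolite_name = names(pre$qc$cv),
                      qc_cv = unname(pre$qc$cv),
                      stringsAsFactors = FALSE)
  write_table(qc_df, tag("qc_report"))
  if (!is.null(pre$qc$scores)) {
    write_table(data.frame(sample_id = rownames(pre$qc$scores),
                           pre$qc$scores, check.names = FALSE),
                tag("pca_scores"))
  }
  # ---- differential
  diff <- differential_stage(mm, config = config)
  write_table(diff$stats, tag("diff_stats"))
  if (!is.null(diff$overlaps)) {
    jsonlite::write_json(
      list(regions = diff$overlaps,
           intersection_all = attr(diff$overlaps, "intersection_all")),
      tag("overlaps", "json"), auto_unbox = TRUE, digits = NA)
  }
  # ---- clustering + patterns per group
  groups <- intersect(c("C", "A", "AE"),
                      unique(samples$group[!samples$is_qc]))
  templates <- archetype_templates(
    sort(unique(samples$day[!samples$is_qc])),
    library = config$patterns$library,
    peak_day = config$patterns$peak_day)
  cl <- list()
  for (g in groups) {
    st <- cluster_stage(mm, g, config = config, seed = seed)
    st$patterns <- assign_patterns(st$fit, templates)
    cl[[g]] <- st
    write_table(st$curve, tag(paste0("dmin_", g)))
    write_table(data.frame(metabolite = rownames(st$fit$membership),
                           st$fit$membership, check.names = FALSE),
                tag(paste0("clusters_", g)))
    write_table(data.frame(cluster = rownames(st$fit$centroids),
                           st$fit$centroids, check.names = FALSE),
                tag(paste0("centroids_", g)))
    write_table(as.data.frame(st$core), tag(paste0("core_", g)))
    hm <- heatmap_matrix(st$fit, st$core, st$profile)
    write_table(data.frame(metabolite = rownames(hm),
                           cluster = attr(hm, "cluster"),
                           membership = attr(hm, "membership"),
                           hm, check.names = FALSE),
                tag(paste0("heatmap_", g)))
    write_table(st$patterns, tag(paste0("patterns_", g)))
  }
  # ---- cross-group core-pattern comparisons
  comparisons <- list(c("C", "A"), c("A", "AE"))
  counts <- list()
  for (cmp in comparisons) {
    if (!all(cmp %in% groups)) next
    rep <- suppressWarnings(compare_core_patterns(
      cl[[cmp[1]]]$core, cl[[cmp[1]]]$patterns,
      cl[[cmp[2]]]$core, cl[[cmp[2]]]$patterns, labels = cmp))
    write_table(rep$table,
                tag(sprintf("pattern_changes_%s_vs_%s", cmp[1], cmp[2])))
    counts[[paste(cmp, collapse = "_vs_")]] <-
      list(n_shared = rep$n_shared, n_changed = rep$n_changed)
  }
  jsonlite::write_json(counts, tag("pattern_counts", "json"),
                       auto_unbox = TRUE, digits = NA)
  # ---- LMM trends + concordance
  lmm <- lmm_stage(mm, config = config)
  write_table(lmm$fits, tag("trend_fits"))
  write_table(lmm$classes, tag("trend_classes"))
  selected <- character(0)
  if (!is.null(lmm$concordance)) {
    write_table(lmm$concordance, tag("concordant"))
    selected <- lmm$concordance$metabolite[lmm$concordance$selected]
  }
  # ---- enrichment of the concordant set
  universe <- rownames(mm$intensity)
  ann <- if (is.null(annotation)) toy_annotation(universe) else annotation
  enr <- NULL
  if (length(selected)) {
    enr <- suppressWarnings(
      hypergeom_enrich(selected, ann, min_k = config$enrich$min_k))
    write_table(enr, tag("enrichment"))
    write_table(class_composition(intersect(selected, ann$universe), ann),
                tag("class_composition"))
  } else {
    cm_log("info", "no concordant metabolites in mode ", mode,
           "; enrichment skipped")
  }
  list(preprocess = pre, differential = diff, clusters = cl,
       pattern_counts = counts, lmm = lmm, enrichment = enr)
}
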