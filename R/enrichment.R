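# Pathway over-representation (one-sided hypergeometric) against a
# user-supplied annotation table, and compound-class composition of a
# selected metabolite set.

#' Build an annotation map
#'
#' @param pathways data.frame: `metabolite_name`, `pathway_id`,
#'   `pathway_name` (one row per membership).
#' @param universe character vector of background metabolite names;
#'   pathway members outside it are dropped.
#' @param classes optional data.frame `metabolite_name`,
#'   `compound_class`.
#' @return list of class `AnnotationMap`: `pathways`, `universe`,
#'   `class_map` (named character).
#' @export
annotation_map <- function(pathways, universe, classes = NULL) {
  req <- c("metabolite_name", "pathway_id", "pathway_name")
  if (!all(req %in% names(pathways))) {
    stop("pathways needs columns: ", paste(req, collapse = ", "))
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  p <- pathways[pathways$metabolite_name %in% universe, req, drop = FALSE]
  class_map <- character(0)
  if (!is.null(classes)) {
    class_map <- setNames(as.character(classes$compound_class),
                          as.character(classes$metabolite_name))
  }
  structure(list(pathways = p, universe = universe, class_map = class_map),
            class = "AnnotationMap")
}

#' Read annotation and class tables from disk
#'
#' @param annotation_path TSV/CSV with columns `metabolite_name`,
#'   `pathway_id`, `pathway_name`.
#' @param universe background metabolite names.
#' @param classes_path optional TSV/CSV with `metabolite_name`,
#'   `compound_class`.
#' @return An `AnnotationMap`.
#' @export
read_annotation <- function(annotation_path, universe,
                            classes_path = NULL) {
  pw <- read_delim_auto(annotation_path)
  cls <- if (!is.null(classes_path)) read_delim_auto(classes_path)
  annotation_map(pw, universe, cls)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway with `k = |selected ∩ pathway| >= min_k`, computes
#' the upper-tail probability `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the
#' pathway size and `n` the selected-set size, plus BH-adjusted
#' q-values across the reported pathways. Selected metabolites outside
#' the universe are dropped with a warning.
#'
#' @param selected character vector of metabolite names.
#' @param annotation an `AnnotationMap`.
#' @param min_k minimum overlap for a pathway to be reported.
#' @return data.frame sorted by ascending p: `pathway_id`,
#'   `pathway_name`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(selected, annotation, min_k = 1L) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  selected <- unique(as.character(selected))
  if (!length(selected)) stop("selected set is empty")
  outside <- setdiff(selected, annotation$universe)
  if (length(outside)) {
    warning(length(outside), " selected metabolite(s) outside the ",
            "universe dropped")
    selected <- setdiff(selected, outside)
  }
  if (!length(selected)) stop("no selected metabolites in the universe")
  N <- length(annotation$universe)
  n <- length(selected)
  by_path <- split(annotation$pathways$metabolite_name,
                   annotation$pathways$pathway_id)
  nm_by_path <- annotation$pathways$pathway_name[
    match(names(by_path), annotation$pathways$pathway_id)]
  rows <- mapply(function(members, pid, pname) {
    members <- unique(members)
    K <- length(members)
    k <- length(intersect(members, selected))
    if (k < min_k) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, pathway_name = pname, k = k, K = K,
               n = n, N = N, p_value = p, stringsAsFactors = FALSE)
  }, by_path, names(by_path), nm_by_path, SIMPLIFY = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(pathway_id = character(0),
                      pathway_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compound-class composition of a selected set
#'
#' Tallies the selected metabolites by compound class (metabolites not
#' covered by the class map count as `"unclassified"`); fractions sum
#' to 1.
#'
#' @param selected character vector of metabolite names.
#' @param annotation an `AnnotationMap`.
#' @return data.frame sorted by descending count: `compound_class`,
#'   `count`, `fraction`.
#' @export
class_composition <- function(selected, annotation) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  selected <- unique(as.character(selected))
  cls <- annotation$class_map[selected]
  cls[is.na(cls)] <- "unclassified"
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(compound_class = names(tab),
             count = as.integer(tab),
             fraction = as.numeric(tab) / length(selected),
             stringsAsFactors = FALSE)
}

#' Toy pathway annotation over a metabolite universe
#'
#' Builds a deterministic, self-contained annotation for testing and
#' simulated studies: metabolites are dealt round-robin into
#' `n_pathways` pathways named after common metabolic themes (with a
#' second membership for every third metabolite, so pathways overlap),
#' and assigned a compound class cyclically from a small class list.
#'
#' @param metabolites universe of metabolite names.
#' @param n_pathways number of pathways (default 12).
#' @return An `AnnotationMap`.
#' @export
toy_annotation <- function(metabolites, n_pathways = 12L) {
  metabolites <- unique(as.character(metabolites))
  themes <- c("glycine serine and threonine metabolism",
              "cysteine and methionine metabolism",
              "tryptophan metabolism",
              "vitamin B6 metabolism",
              "arginine biosynthesis",
              "histidine metabolism",
              "alanine aspartate and glutamate metabolism",
              "pantothenate and CoA biosynthesis",
              "sphingolipid metabolism",
              "pyrimidine metabolism",
              "TCA cycle",
              "D-amino acid metabolism")
  n_pathways <- min(n_pathways, length(themes))
  pid <- sprintf("path%02d", seq_len(n_pathways))
  primary <- data.frame(
    metabolite_name = metabolites,
    pathway_id = pid[(seq_along(metabolites) - 1L) %% n_pathways + 1L],
    stringsAsFactors = FALSE
  )
  second_idx <- seq_along(metabolites)[seq_along(metabolites) %% 3L == 0L]
  secondary <- data.frame(
    metabolite_name = metabolites[second_idx],
    pathway_id = pid[(second_idx + 4L) %% n_pathways + 1L],
    stringsAsFactors = FALSE
  )
  pathways <- rbind(primary, secondary)
  pathways$pathway_name <- themes[match(pathways$pathway_id, pid)]
  classes <- data.frame(
    metabolite_name = metabolites,
    compound_class = c("amino acids and peptides", "fatty acids and conjugates",
                       "pyridines", "TCA acids", "benzoic acids",
                       "nucleosides")[(seq_along(metabolites) - 1L) %% 6L + 1L],
    stringsAsFactors = FALSE
  )
  annotation_map(pathways, metabolites, classes)
}
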