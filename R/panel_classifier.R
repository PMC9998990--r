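# Count-threshold MT/WT classification and rule-based comparator biomarkers.

#' Panel model: gene set plus count threshold
#'
#' A panel model calls a sample MT (mutant-type) when at least `k` of its
#' panel genes carry a retained nonsynonymous mutation, WT otherwise.
#' `default_panel()` loads the bundled 18-gene NSCLC immunotherapy panel
#' with k = 2.
#'
#' @param genes Character vector of unique gene symbols.
#' @param k Count threshold (default 2, must be >= 1).
#' @return A list of class `"panel_model"`.
#' @export
panel_model <- function(genes, k = 2L) {
  genes <- normalize_gene(genes)
  if (anyDuplicated(genes)) stop("panel genes must be unique")
  if (length(genes) < 1L) stop("panel must contain at least one gene")
  stopifnot(k >= 1)
  structure(list(genes = genes, k = as.integer(k)), class = "panel_model")
}

#' @rdname panel_model
#' @export
default_panel <- function() {
  path <- system.file("extdata", "default_panel.json", package = "mutpanel",
                      mustWork = TRUE)
  read_panel_json(path)
}

#' Read / write a panel model as JSON
#'
#' @param path JSON file with fields `genes` (array) and `k` (integer);
#'   optional `prevalence` (named object) is carried through as an attribute.
#' @export
read_panel_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- panel_model(j$genes, k = j$k)
  if (!is.null(j$prevalence)) attr(p, "prevalence") <- unlist(j$prevalence)
  p
}

#' @rdname read_panel_json
#' @param panel A `"panel_model"`.
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "panel_model"))
  jsonlite::write_json(list(genes = panel$genes, k = panel$k), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Panel model: ", length(x$genes), " genes, MT when count >= ",
      x$k, "\n  ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Count mutated panel genes per sample
#'
#' Panel genes absent from the matrix's gene universe cannot be
#' distinguished from wild-type in binary mutation input and count as
#' unmutated; they are reported once per call via a warning.
#'
#' @param matrix Binary mutation matrix (samples x genes).
#' @param panel A [panel_model()].
#' @param samples Sample IDs to score (default: all rows). A sample absent
#'   from the matrix is an error.
#' @return Named integer vector of panel mutation counts.
#' @export
count_panel_mutations <- function(matrix, panel, samples = rownames(matrix)) {
  stopifnot(is.matrix(matrix), inherits(panel, "panel_model"))
  absent_s <- setdiff(samples, rownames(matrix))
  if (length(absent_s))
    stop("sample(s) absent from matrix: ",
         paste(utils::head(absent_s, 5), collapse = ", "))
  missing_g <- setdiff(panel$genes, colnames(matrix))
  if (length(missing_g))
    warning("panel gene(s) not in the cohort's gene universe ",
            "(treated as unmutated): ", paste(missing_g, collapse = ", "))
  present <- intersect(panel$genes, colnames(matrix))
  if (!length(present))
    return(stats::setNames(rep(0L, length(samples)), samples))
  counts <- as.integer(rowSums(matrix[samples, present, drop = FALSE]))
  stats::setNames(counts, samples)
}

#' MT/WT call from a panel mutation count
#'
#' @param count Nonnegative integer vector of panel mutation counts.
#' @param panel A [panel_model()] supplying the threshold `k`.
#' @return Factor with levels `WT`, `MT`; `MT` iff `count >= k`.
#' @export
classify_mt_wt <- function(count, panel) {
  stopifnot(inherits(panel, "panel_model"), all(count >= 0))
  factor(ifelse(count >= panel$k, "MT", "WT"), levels = c("WT", "MT"))
}

#' Stratify samples by panel mutation count
#'
#' @inheritParams count_panel_mutations
#' @return Named list mapping each count stratum `"0"`, `"1"`, ... (up to
#'   the maximum observed) to its sample IDs; the strata partition the
#'   samples.
#' @export
stratify_by_count <- function(matrix, panel) {
  counts <- count_panel_mutations(matrix, panel)
  strata <- split(names(counts), factor(counts, levels = 0:max(counts)))
  strata
}

#' Gene-set comparator rule
#'
#' A rule labels a sample positive when at least `min_mutated` of its genes
#' are mutated. `keap1_comutation_rule()` and `ddr_rule()` build the two
#' literature comparators: KEAP1-driven co-mutation (>= 2 mutated among
#' KEAP1, STK11, PBRM1, SMARCA4) and the five-gene DNA-damage-repair
#' signature (>= 1 mutated among MSH2, MSH6, PMS2, POLE, BRCA2).
#' `apobec_rule()` requires an explicit gene list: no canonical
#' APOBEC-related mutation gene set exists, so none is bundled.
#'
#' @param name Rule name used in reports.
#' @param genes Gene symbols making up the rule's set.
#' @param min_mutated Minimum mutated genes for a positive call.
#' @param positive_label,negative_label Labels emitted by the rule.
#' @return A list of class `"gene_set_rule"`.
#' @export
gene_set_rule <- function(name, genes, min_mutated = 1L,
                          positive_label = paste0(name, "+"),
                          negative_label = paste0(name, "-")) {
  genes <- normalize_gene(genes)
  if (anyDuplicated(genes)) stop("rule genes must be unique")
  if (min_mutated < 1 || min_mutated > length(genes))
    stop("min_mutated must be in [1, ", length(genes), "]")
  structure(list(name = name, genes = genes,
                 min_mutated = as.integer(min_mutated),
                 positive_label = positive_label,
                 negative_label = negative_label),
            class = "gene_set_rule")
}

#' @rdname gene_set_rule
#' @export
keap1_comutation_rule <- function() {
  gene_set_rule("CO", c("KEAP1", "STK11", "PBRM1", "SMARCA4"),
                min_mutated = 2L)
}

#' @rdname gene_set_rule
#' @export
ddr_rule <- function() {
  gene_set_rule("DDR", c("MSH2", "MSH6", "PMS2", "POLE", "BRCA2"),
                min_mutated = 1L)
}

#' @rdname gene_set_rule
#' @export
apobec_rule <- function(genes) {
  if (missing(genes) || !length(genes))
    stop("the APOBEC gene-status rule has no agreed gene list; ",
         "supply one explicitly")
  gene_set_rule("APOBEC", genes, min_mutated = 1L)
}

#' Evaluate a gene-set rule on a mutation matrix
#'
#' @inheritParams count_panel_mutations
#' @param rule A [gene_set_rule()].
#' @return Named character vector of rule labels per sample.
#' @export
evaluate_gene_set_rule <- function(matrix, rule, samples = rownames(matrix)) {
  stopifnot(inherits(rule, "gene_set_rule"))
  counts <- count_panel_mutations(matrix, panel_model(rule$genes, k = 1L),
                                  samples = samples)
  labels <- ifelse(counts >= rule$min_mutated,
                   rule$positive_label, rule$negative_label)
  stats::setNames(labels, samples)
}
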