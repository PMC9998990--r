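# Binary mutation matrix, gene-prevalence filter, tumor mutational burden.

#' Build the binary sample-by-gene mutation matrix
#'
#' Entry `(s, g)` is 1 iff sample `s` carries at least one retained variant
#' in gene `g`; multiplicity is collapsed. Every cohort sample appears as a
#' row, including samples with no retained mutations (all-zero rows).
#'
#' @param cohort A `"cohort"` whose mutations have already passed
#'   [apply_variant_filters()].
#' @return An integer matrix of 0/1 with samples as rownames and genes as
#'   colnames (genes in alphabetical order).
#' @export
build_binary_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cohort$sample_ids) == 0L) stop("cohort has no samples")
  samples <- cohort$sample_ids
  genes <- sort(unique(cohort$mutations$gene))
  m <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  if (length(genes)) {
    i <- match(cohort$mutations$sample_id, samples)
    j <- match(cohort$mutations$gene, genes)
    keep <- !is.na(i)
    m[cbind(i[keep], j[keep])] <- 1L
  }
  m
}

#' Drop genes mutated in too few samples
#'
#' Keeps exactly the genes mutated in at least `min_samples` samples (the
#' boundary is inclusive: a gene mutated in exactly `min_samples` samples is
#' retained). The sample set is unchanged.
#'
#' @param matrix Binary mutation matrix from [build_binary_matrix()].
#' @param min_samples Minimum number of mutated samples per gene (default 3).
#' @return The matrix restricted to retained gene columns.
#' @export
prevalence_filter <- function(matrix, min_samples = 3L) {
  stopifnot(is.matrix(matrix), min_samples >= 1)
  keep <- colSums(matrix) >= min_samples
  if (!any(keep))
    stop("prevalence filter removed every gene; lower min_samples (",
         min_samples, ")")
  matrix[, keep, drop = FALSE]
}

#' Tumor mutational burden per sample
#'
#' TMB is the number of retained nonsynonymous mutations (substitutions and
#' indels) per megabase of sequenced territory. Samples with TMB at or above
#' `cutoff` are labelled `TMB_H`, strictly below `TMB_L` (the boundary value
#' is high).
#'
#' @param cohort A filtered `"cohort"` (synonymous/intronic variants already
#'   removed upstream).
#' @param panel_size_mb Sequenced territory in megabases (e.g. about 1.14 for
#'   a large targeted panel, 30-38 for an exome). Required; must be positive.
#' @param cutoff TMB-high threshold in mutations/Mb (default 10).
#' @return A data frame with columns `sample_id`, `mutation_count`,
#'   `panel_size_mb`, `tmb`, `group`.
#' @export
compute_tmb <- function(cohort, panel_size_mb, cutoff = 10) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is.numeric(panel_size_mb) || length(panel_size_mb) != 1L ||
      is.na(panel_size_mb) || panel_size_mb <= 0)
    stop("panel_size_mb must be a single positive number of megabases")
  counts <- table(factor(cohort$mutations$sample_id,
                         levels = cohort$sample_ids))
  mutation_count <- as.integer(counts)
  tmb <- mutation_count / panel_size_mb
  data.frame(sample_id = cohort$sample_ids,
             mutation_count = mutation_count,
             panel_size_mb = panel_size_mb,
             tmb = tmb,
             group = ifelse(tmb >= cutoff, "TMB_H", "TMB_L"),
             stringsAsFactors = FALSE)
}
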