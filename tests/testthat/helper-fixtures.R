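# Shared fixtures: small record builders and random fixture generators.

# A canonical mutation-record data frame with overridable fields.
make_records <- function(n = 1, sample_id = "S1", gene = "TP53",
                         classification = "missense", type = "SNV",
                         supporting_reads = NA_integer_,
                         population_af = NA_real_, dbsnp_common = NA) {
  data.frame(sample_id = rep_len(sample_id, n),
             gene = rep_len(gene, n),
             variant_classification = rep_len(classification, n),
             variant_type = rep_len(type, n),
             supporting_reads = rep_len(as.integer(supporting_reads), n),
             population_af = rep_len(as.numeric(population_af), n),
             dbsnp_common = rep_len(dbsnp_common, n),
             stringsAsFactors = FALSE)
}

# Random variant fixture exercising every filter rule.
random_records <- function(n) {
  classes <- c("missense", "nonsense", "silent", "intron", "splice",
               "frameshift_indel", "other")
  types <- c("SNV", "insertion", "deletion", "other")
  data.frame(
    sample_id = sprintf("S%02d", sample.int(20, n, replace = TRUE)),
    gene = sprintf("G%03d", sample.int(50, n, replace = TRUE)),
    variant_classification = sample(classes, n, replace = TRUE),
    variant_type = sample(types, n, replace = TRUE),
    supporting_reads = ifelse(runif(n) < 0.2, NA_integer_,
                              sample.int(200, n, replace = TRUE)),
    population_af = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 0.05)),
    dbsnp_common = sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                          prob = c(0.1, 0.6, 0.3)),
    stringsAsFactors = FALSE
  )
}

# Minimal clinical table for a set of sample ids.
make_clinical <- function(sample_ids, time = 12, event = 1L) {
  data.frame(sample_id = sample_ids,
             time_months = rep_len(time, length(sample_ids)),
             event = rep_len(as.integer(event), length(sample_ids)),
             endpoint = "OS", stringsAsFactors = FALSE)
}

# Cohort from explicit per-sample mutated gene sets.
make_cohort <- function(gene_sets, time = 12, event = 1L) {
  ids <- names(gene_sets)
  recs <- do.call(rbind, lapply(ids, function(s) {
    genes <- gene_sets[[s]]
    if (!length(genes)) return(NULL)
    make_records(length(genes), sample_id = s, gene = genes)
  }))
  if (is.null(recs)) recs <- make_records(0)
  suppressMessages(assemble_cohort(recs, make_clinical(ids, time, event)))
}

# Small binary matrix from a named list of mutated genes per sample.
make_matrix <- function(gene_sets, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(unlist(gene_sets)))
  m <- matrix(0L, nrow = length(gene_sets), ncol = length(genes),
              dimnames = list(names(gene_sets), genes))
  for (s in names(gene_sets)) m[s, intersect(gene_sets[[s]], genes)] <- 1L
  m
}
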