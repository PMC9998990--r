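# Reading mutation / clinical tables and variant-level filtering.

# Canonical variant classifications used throughout the package.
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift_indel", "inframe_indel",
                     "splice", "silent", "intron", "other")
VARIANT_TYPES <- c("SNV", "insertion", "deletion", "other")

# Single built-in gene alias: "BRAC2" is an occasional literature typo for BRCA2.
GENE_ALIASES <- c(BRAC2 = "BRCA2")

#' Column dialect for MAF-style mutation tables
#'
#' A dialect maps the columns of a tab-separated mutation table onto the
#' canonical per-variant fields (`sample_id`, `gene`, `variant_classification`,
#' `variant_type`, and the optional `supporting_reads`, `population_af`,
#' `dbsnp_common`), and maps the table's variant-classification vocabulary
#' onto the canonical one. `maf_dialect()` ships the standard MAF header
#' names and classification terms; `tsv_dialect()` builds a dialect for an
#' arbitrary table.
#'
#' @param sample_id,gene,variant_classification,variant_type Column names in
#'   the input table. `variant_type` may be `NA` if absent.
#' @param supporting_reads,population_af,dbsnp_common Optional column names
#'   (`NA` = not present; the corresponding filter rule is then skipped).
#' @param classification_map Named character vector mapping input
#'   classification strings (upper-cased) to canonical classes; unmapped
#'   values become `"other"`.
#' @param type_map Named character vector mapping input variant-type strings
#'   (upper-cased) to canonical types.
#' @return A list of class `"mutation_dialect"`.
#' @export
tsv_dialect <- function(sample_id, gene, variant_classification,
                        variant_type = NA_character_,
                        supporting_reads = NA_character_,
                        population_af = NA_character_,
                        dbsnp_common = NA_character_,
                        classification_map = maf_classification_map(),
                        type_map = maf_type_map()) {
  structure(list(
    columns = c(sample_id = sample_id, gene = gene,
                variant_classification = variant_classification,
                variant_type = variant_type,
                supporting_reads = supporting_reads,
                population_af = population_af,
                dbsnp_common = dbsnp_common),
    classification_map = classification_map,
    type_map = type_map
  ), class = "mutation_dialect")
}

#' @rdname tsv_dialect
#' @export
maf_dialect <- function() {
  tsv_dialect(sample_id = "Tumor_Sample_Barcode",
              gene = "Hugo_Symbol",
              variant_classification = "Variant_Classification",
              variant_type = "Variant_Type",
              supporting_reads = "t_alt_count",
              population_af = "AF",
              dbsnp_common = NA_character_)
}

#' @rdname tsv_dialect
#' @export
maf_classification_map <- function() {
  c(MISSENSE_MUTATION = "missense",
    NONSENSE_MUTATION = "nonsense",
    NONSTOP_MUTATION = "nonsense",
    FRAME_SHIFT_DEL = "frameshift_indel",
    FRAME_SHIFT_INS = "frameshift_indel",
    IN_FRAME_DEL = "inframe_indel",
    IN_FRAME_INS = "inframe_indel",
    SPLICE_SITE = "splice",
    SPLICE_REGION = "splice",
    SILENT = "silent",
    SYNONYMOUS = "silent",
    INTRON = "intron",
    MISSENSE = "missense",
    NONSENSE = "nonsense",
    FRAMESHIFT_INDEL = "frameshift_indel",
    INFRAME_INDEL = "inframe_indel",
    SPLICE = "splice")
}

#' @rdname tsv_dialect
#' @export
maf_type_map <- function() {
  c(SNP = "SNV", SNV = "SNV", DNP = "SNV", TNP = "SNV", ONP = "SNV",
    INS = "insertion", INSERTION = "insertion",
    DEL = "deletion", DELETION = "deletion")
}

normalize_gene <- function(x) {
  g <- toupper(trimws(x))
  hit <- g %in% names(GENE_ALIASES)
  if (any(hit)) g[hit] <- GENE_ALIASES[g[hit]]
  g
}

#' Read an annotated somatic mutation table
#'
#' Reads a tab-separated mutation table (MAF-like) into the canonical
#' per-variant data frame. One row in equals one record out; gene symbols are
#' trimmed and upper-cased; classification and type vocabularies are mapped
#' through the dialect, with unmapped values becoming `"other"`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect A [tsv_dialect()] / [maf_dialect()] column mapping.
#' @return A data frame with columns `sample_id`, `gene`,
#'   `variant_classification`, `variant_type`, `supporting_reads`,
#'   `population_af`, `dbsnp_common` (the optional ones `NA` when the dialect
#'   does not map them).
#' @export
read_mutation_table <- function(path, dialect = maf_dialect()) {
  stopifnot(inherits(dialect, "mutation_dialect"))
  if (!file.exists(path)) stop("mutation table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", quote = "")
  if (nrow(raw) == 0L) {
    message("mutation table '", path, "' has no data rows")
    return(empty_mutation_records())
  }
  cols <- dialect$columns
  mandatory <- c("sample_id", "gene", "variant_classification")
  for (f in mandatory) {
    if (is.na(cols[[f]]) || !cols[[f]] %in% names(raw)) {
      stop("mutation table is missing mandatory column '", cols[[f]],
           "' (maps to ", f, ")")
    }
  }
  get_opt <- function(field, parse = identity, default) {
    col <- cols[[field]]
    if (is.na(col) || !col %in% names(raw)) rep(default, nrow(raw))
    else parse(raw[[col]])
  }
  cls_raw <- toupper(trimws(as.character(raw[[cols[["variant_classification"]]]])))
  cls <- unname(dialect$classification_map[cls_raw])
  cls[is.na(cls)] <- "other"
  typ_raw <- toupper(trimws(as.character(get_opt("variant_type", identity,
                                                 NA_character_))))
  typ <- unname(dialect$type_map[typ_raw])
  typ[is.na(typ) & !is.na(typ_raw)] <- "other"
  out <- data.frame(
    sample_id = trimws(as.character(raw[[cols[["sample_id"]]]])),
    gene = normalize_gene(raw[[cols[["gene"]]]]),
    variant_classification = cls,
    variant_type = typ,
    supporting_reads = get_opt("supporting_reads",
                               function(x) suppressWarnings(as.integer(x)),
                               NA_integer_),
    population_af = get_opt("population_af",
                            function(x) suppressWarnings(as.numeric(x)),
                            NA_real_),
    dbsnp_common = get_opt("dbsnp_common", parse_logical, NA),
    stringsAsFactors = FALSE
  )
  validate_mutation_records(out)
  out
}

empty_mutation_records <- function() {
  data.frame(sample_id = character(), gene = character(),
             variant_classification = character(), variant_type = character(),
             supporting_reads = integer(), population_af = numeric(),
             dbsnp_common = logical(), stringsAsFactors = FALSE)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "T", "YES", "Y")] <- TRUE
  out[v %in% c("0", "FALSE", "F", "NO", "N")] <- FALSE
  out
}

validate_mutation_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "gene", "variant_classification", "variant_type")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("mutation records lack columns: ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(trimws(records$sample_id))))
    stop("mutation records contain empty sample_id values")
  if (any(!nzchar(trimws(records$gene))))
    stop("mutation records contain empty gene symbols")
  af <- records$population_af
  bad <- !is.na(af) & (af < 0 | af > 1)
  if (any(bad)) stop("population_af outside [0,1] in rows: ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  invisible(records)
}

#' Variant-level filter configuration
#'
#' Defaults reproduce the standard somatic filtering applied to targeted-panel
#' NSCLC cohorts: intronic variants removed; variants at > 1% population
#' allele frequency removed; variants flagged as common dbSNP polymorphisms
#' removed; synonymous (silent) variants removed; variants with fewer than 50
#' supporting reads removed (a variant with exactly 50 reads is retained);
#' copy-number/fusion-like records (variant type other than substitution or
#' indel) removed. Rules whose underlying field is entirely missing are
#' skipped (fail-open), with one log message per skipped column.
#'
#' @param drop_silent,drop_intronic,drop_dbsnp_common,drop_cnv_fusion Logical
#'   switches for the corresponding rules.
#' @param max_population_af Population allele-frequency ceiling in `[0,1]`.
#' @param min_supporting_reads Minimum read support; strictly smaller values
#'   are removed.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(drop_silent = TRUE, drop_intronic = TRUE,
                          max_population_af = 0.01, drop_dbsnp_common = TRUE,
                          min_supporting_reads = 50L, drop_cnv_fusion = TRUE) {
  stopifnot(is.numeric(max_population_af), max_population_af >= 0,
            max_population_af <= 1, min_supporting_reads >= 0)
  structure(list(drop_silent = isTRUE(drop_silent),
                 drop_intronic = isTRUE(drop_intronic),
                 max_population_af = max_population_af,
                 drop_dbsnp_common = isTRUE(drop_dbsnp_common),
                 min_supporting_reads = as.integer(min_supporting_reads),
                 drop_cnv_fusion = isTRUE(drop_cnv_fusion)),
            class = "filter_config")
}

#' Apply variant-level filters
#'
#' Filters are applied in a fixed order — structural (CNV/fusion-like),
#' intronic, population frequency, common dbSNP flag, synonymous, low read
#' support — and each removed record is attributed to the first rule that
#' removed it, so the report counts are a deterministic partition:
#' `retained + sum(removals) == input`.
#'
#' @param records Canonical mutation-record data frame
#'   (see [read_mutation_table()]).
#' @param cfg A [filter_config()].
#' @return A list with `records` (the retained data frame) and `report`
#'   (class `"filter_report"`: named removal counts plus input/retained
#'   totals and the rules skipped for missing fields).
#' @export
apply_variant_filters <- function(records, cfg = filter_config()) {
  validate_mutation_records(records)
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(records)
  # 0 = retained; otherwise index of the first rule that removed the record
  rule_names <- c("cnv_fusion", "intron", "population_af", "dbsnp_common",
                  "silent", "low_support")
  removed_by <- integer(n)
  skipped <- character()
  mark <- function(idx, hit) {
    hit <- hit & removed_by == 0L
    removed_by[hit] <<- idx
    removed_by
  }
  if (cfg$drop_cnv_fusion)
    removed_by <- mark(1L, !is.na(records$variant_type) &
                           records$variant_type == "other")
  if (cfg$drop_intronic)
    removed_by <- mark(2L, records$variant_classification == "intron")
  af <- records$population_af
  if (all(is.na(af)) && n > 0L) {
    skipped <- c(skipped, "population_af")
    message("population_af absent from all records; frequency rule skipped")
  } else {
    removed_by <- mark(3L, !is.na(af) & af > cfg$max_population_af)
  }
  if (cfg$drop_dbsnp_common) {
    db <- records$dbsnp_common
    if (all(is.na(db)) && n > 0L) {
      skipped <- c(skipped, "dbsnp_common")
      message("dbsnp_common absent from all records; dbSNP rule skipped")
    } else {
      removed_by <- mark(4L, !is.na(db) & db)
    }
  }
  if (cfg$drop_silent)
    removed_by <- mark(5L, records$variant_classification == "silent")
  sr <- records$supporting_reads
  if (all(is.na(sr)) && n > 0L) {
    skipped <- c(skipped, "supporting_reads")
    message("supporting_reads absent from all records; read-support rule skipped")
  } else {
    removed_by <- mark(6L, !is.na(sr) & sr < cfg$min_supporting_reads)
  }
  removals <- vapply(seq_along(rule_names),
                     function(i) sum(removed_by == i), integer(1))
  names(removals) <- rule_names
  retained <- records[removed_by == 0L, , drop = FALSE]
  rownames(retained) <- NULL
  report <- structure(list(input = n, retained = nrow(retained),
                           removals = removals, skipped_rules = skipped),
                      class = "filter_report")
  list(records = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter report\n")
  cat("  input records: ", x$input, "\n", sep = "")
  for (r in names(x$removals))
    cat(sprintf("  removed (%s): %d\n", r, x$removals[[r]]))
  cat("  retained: ", x$retained, "\n", sep = "")
  if (length(x$skipped_rules))
    cat("  rules skipped (field missing): ",
        paste(x$skipped_rules, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a clinical survival table
#'
#' @param path Path to a tab- or comma-separated file with a header.
#' @param sample_id,time,event,endpoint Column names in the input; `endpoint`
#'   may be `NA` (then `default_endpoint` is used for all rows).
#' @param default_endpoint `"OS"` or `"PFS"`.
#' @param sep Field separator (`"\t"` or `","`); guessed from the file
#'   extension when `NULL`.
#' @return A data frame with columns `sample_id`, `time_months` (numeric,
#'   `>= 0`), `event` (integer 0/1), `endpoint`, plus any additional input
#'   columns carried through as covariates.
#' @export
read_clinical_table <- function(path, sample_id = "sample_id",
                                time = "time_months", event = "event",
                                endpoint = NA_character_,
                                default_endpoint = "OS", sep = NULL) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "")
  for (col in c(sample_id, time, event)) {
    if (!col %in% names(raw)) stop("clinical table is missing column '",
                                   col, "'")
  }
  tm <- suppressWarnings(as.numeric(raw[[time]]))
  bad_t <- is.na(tm) | tm < 0
  if (any(bad_t))
    stop("unparseable or negative survival time in rows: ",
         paste(utils::head(which(bad_t), 10), collapse = ", "))
  ev <- parse_event(raw[[event]])
  if (anyNA(ev))
    stop("unparseable event indicator in rows: ",
         paste(utils::head(which(is.na(ev)), 10), collapse = ", "))
  ep <- if (!is.na(endpoint) && endpoint %in% names(raw))
    toupper(trimws(raw[[endpoint]])) else rep(default_endpoint, nrow(raw))
  out <- data.frame(sample_id = trimws(as.character(raw[[sample_id]])),
                    time_months = tm, event = ev, endpoint = ep,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), c(sample_id, time, event, endpoint))
  for (col in extra) out[[col]] <- raw[[col]]
  out
}

parse_event <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!out %in% c(0L, 1L)] <- NA_integer_
    return(out)
  }
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA_integer_, length(v))
  out[v %in% c("1", "TRUE", "DEAD", "DECEASED", "PROGRESSED", "YES", "EVENT")] <- 1L
  out[v %in% c("0", "FALSE", "ALIVE", "LIVING", "CENSORED", "NO")] <- 0L
  out
}

#' Assemble a validated cohort
#'
#' Joins filtered mutation records with a clinical table into a `"cohort"`
#' object. The sample universe is the clinical table's sample set; mutation
#' records referencing unknown samples are dropped with a log message (or
#' rejected, per `unknown_samples`). Samples with no retained mutations stay
#' in the cohort.
#'
#' @param mutations Canonical mutation-record data frame.
#' @param clinical Clinical data frame (see [read_clinical_table()]).
#' @param unknown_samples `"drop"` (log and discard) or `"error"`.
#' @param provenance Optional free-text provenance note.
#' @return A list of class `"cohort"` with elements `mutations`, `clinical`,
#'   `sample_ids`, `provenance`.
#' @export
assemble_cohort <- function(mutations, clinical,
                            unknown_samples = c("drop", "error"),
                            provenance = "") {
  unknown_samples <- match.arg(unknown_samples)
  validate_mutation_records(mutations)
  stopifnot(all(c("sample_id", "time_months", "event") %in% names(clinical)))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample_id in clinical table")
  sample_ids <- clinical$sample_id
  unknown <- setdiff(unique(mutations$sample_id), sample_ids)
  if (length(unknown)) {
    if (unknown_samples == "error")
      stop("mutation records reference unknown samples: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    message(length(unknown), " mutation sample(s) absent from the clinical ",
            "table; their records were dropped")
    mutations <- mutations[mutations$sample_id %in% sample_ids, , drop = FALSE]
    rownames(mutations) <- NULL
  }
  structure(list(mutations = mutations, clinical = clinical,
                 sample_ids = sample_ids, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: ", length(x$sample_ids), " samples, ",
      nrow(x$mutations), " mutation records, ",
      length(unique(x$mutations$gene)), " genes\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to MAF-like and clinical TSV files
#'
#' Emits `mutations.tsv` (standard MAF column headers) and `clinical.tsv`
#' into `dir`; the pair round-trips through [read_cohort()].
#'
#' @param cohort A `"cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- cohort$mutations
  rev_class <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
                 frameshift_indel = "Frame_Shift_Del",
                 inframe_indel = "In_Frame_Del", splice = "Splice_Site",
                 silent = "Silent", intron = "Intron", other = "Targeted_Region")
  rev_type <- c(SNV = "SNP", insertion = "INS", deletion = "DEL", other = "OTHER")
  maf <- data.frame(Hugo_Symbol = m$gene,
                    Tumor_Sample_Barcode = m$sample_id,
                    Variant_Classification = rev_class[m$variant_classification],
                    Variant_Type = rev_type[ifelse(is.na(m$variant_type),
                                                   "SNV", m$variant_type)],
                    t_alt_count = m$supporting_reads,
                    AF = m$population_af,
                    stringsAsFactors = FALSE)
  utils::write.table(maf, file.path(dir, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mut <- read_mutation_table(file.path(dir, "mutations.tsv"), maf_dialect())
  cli <- read_clinical_table(file.path(dir, "clinical.tsv"))
  assemble_cohort(mut, cli, provenance = paste("read from", dir))
}
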