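# Readers and writers for the pipeline's tabular interchange formats:
# TSV matrices with a leading subject_id column, a BED-like gene annotation
# table, VCF 4.2 with a per-sample DS (dosage) FORMAT field, and the YAML
# truth ledger.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# subjects-as-rows matrix <-> TSV with first column subject_id
.write_matrix_tsv <- function(mat, path) {
  df <- data.frame(subject_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

.read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  m
}

#' Write a dosage matrix as VCF 4.2 with a DS FORMAT field
#'
#' One record per variant with `FORMAT=DS` carrying each subject's expected
#' minor-allele dosage; REF is the major allele and ALT the minor allele,
#' so DS counts ALT copies.
#'
#' @param dosages Subjects x variants matrix (subject ids as row names).
#' @param variant_map Data frame `variant_id`, `chrom`, `pos`, `major`,
#'   `minor`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dosage_vcf <- function(dosages, variant_map, path) {
  stopifnot(all(variant_map$variant_id %in% colnames(dosages)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=residcog",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Estimated alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")), con)
  for (i in seq_len(nrow(variant_map))) {
    v <- variant_map[i, ]
    ds <- sprintf("%.4g", dosages[, v$variant_id])
    writeLines(paste(c(v$chrom, v$pos, v$variant_id, v$major, v$minor,
                       ".", "PASS", ".", "DS", ds), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a DS-dosage VCF into a dosage matrix and variant map
#'
#' Uses `vcfR` when available, otherwise a minimal line parser for the
#' single-FORMAT `DS` layout written by [write_dosage_vcf()].
#'
#' @param path VCF path.
#' @return List with `dosages` (subjects x variants) and `variant_map`.
#' @export
read_dosage_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    dosages <- t(ds)
    colnames(dosages) <- fix$ID
    vm <- data.frame(variant_id = fix$ID, chrom = as.integer(fix$CHROM),
                     pos = as.integer(fix$POS), major = fix$REF,
                     minor = fix$ALT, stringsAsFactors = FALSE)
    return(list(dosages = dosages, variant_map = vm))
  }
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(header, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t")
  vm <- data.frame(
    variant_id = vapply(parts, `[`, "", 3),
    chrom = as.integer(vapply(parts, `[`, "", 1)),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    major = vapply(parts, `[`, "", 4),
    minor = vapply(parts, `[`, "", 5), stringsAsFactors = FALSE)
  dosages <- t(vapply(parts,
                      function(p) as.numeric(p[-(1:9)]),
                      numeric(length(samples))))
  dosages <- t(dosages)
  rownames(dosages) <- samples
  colnames(dosages) <- vm$variant_id
  list(dosages = dosages, variant_map = vm)
}

#' Write a synthetic cohort bundle to a directory
#'
#' Emits the interchange files downstream stages read: phenotype and
#' pathology TSVs, dosage VCF (plus a TSV dosage matrix), methylation and
#' expression matrices with their covariates, BED-like gene annotation, and
#' the YAML truth ledger.
#'
#' @param cohort A `residcog_cohort` bundle from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "residcog_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_tsv(cohort$subjects, p("subjects.tsv"))
  .write_tsv(cohort$pathologies, p("pathologies.tsv"))
  .write_matrix_tsv(cohort$genotypes$dosages, p("dosages.tsv"))
  write_dosage_vcf(cohort$genotypes$dosages, cohort$genotypes$variant_map,
                   p("dosages.vcf"))
  .write_tsv(cohort$genotypes$variant_map, p("variant_map.tsv"))
  .write_tsv(data.frame(subject_id = names(cohort$genotypes$platform),
                        platform = cohort$genotypes$platform,
                        stringsAsFactors = FALSE), p("platform.tsv"))
  .write_matrix_tsv(cohort$methylation$betas, p("methylation.tsv"))
  .write_tsv(data.frame(subject_id = names(cohort$methylation$batch),
                        batch = cohort$methylation$batch,
                        bisulfite = cohort$methylation$bisulfite,
                        stringsAsFactors = FALSE),
             p("methylation_covariates.tsv"))
  .write_tsv(cohort$methylation$cpg_map, p("cpg_map.tsv"))
  .write_matrix_tsv(cohort$expression$values, p("expression.tsv"))
  .write_tsv(cohort$expression$tech, p("expression_covariates.tsv"))
  .write_tsv(cohort$genes[, c("gene_id", "chrom", "start", "end", "strand")],
             p("genes.tsv"))
  yaml::write_yaml(cohort$truth, p("truth.yaml"))
  invisible(dir)
}
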