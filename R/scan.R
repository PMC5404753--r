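# Stage 1: additive association scan of residual cognition, per-platform
# analysis with fixed-effect meta-analysis, suggestive filtering, greedy LD
# clumping, candidate-gene annotation, expression triage, and cis-eQTL.

#' Single-variant association with residual cognition
#'
#' Additive linear model: trait ~ dosage + ancestry covariates (EV1--3).
#' The effect is the change in residual cognition (z-score units) per
#' additional minor allele; inference uses the t reference with
#' n - k - 1 degrees of freedom.
#'
#' @param dosage Per-subject minor-allele dosage in \[0, 2\].
#' @param trait Per-subject residual cognition.
#' @param covariates Data frame / matrix of nuisance covariates (typically
#'   EV1--3), or `NULL`.
#' @param predictor_id Variant identifier for the output row.
#' @param platform Analysis stratum label.
#' @return An [assoc_stat()] row.
#' @export
snp_association <- function(dosage, trait, covariates = NULL,
                            predictor_id = "variant", platform = "all") {
  .ols_single_term(dosage, trait, covariates, predictor_id, platform,
                   zero_var_msg = "zero variance predictor")
}

#' Association scan over a dosage matrix
#'
#' Vectorised equivalent of calling [snp_association()] per variant with a
#' shared covariate set (Frisch--Waugh residualization; identical estimates
#' and p-values to the per-variant OLS fits). Variants that are monomorphic
#' or collinear with the covariates are dropped with a warning.
#'
#' @param dosages Subjects x variants numeric matrix with variant column
#'   names.
#' @param trait Per-subject trait vector.
#' @param covariates Covariate table shared across variants, or `NULL`.
#' @param platform Analysis stratum label.
#' @return Data frame of [assoc_stat()] rows, one per retained variant.
#' @export
assoc_scan <- function(dosages, trait, covariates = NULL, platform = "all") {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(trait))
  Z <- .covariate_matrix(covariates, length(trait))
  keep <- complete.cases(trait, Z) & rowSums(is.na(dosages)) == 0
  dosages <- dosages[keep, , drop = FALSE]
  trait <- trait[keep]
  Zdf <- if (ncol(Z)) as.data.frame(Z[keep, , drop = FALSE]) else NULL
  n <- length(trait)
  if (n < 20L) stop("insufficient complete cases: ", n)
  mono <- apply(dosages, 2, var) == 0
  if (any(mono)) {
    warning("dropping ", sum(mono), " monomorphic variant(s)")
    dosages <- dosages[, !mono, drop = FALSE]
  }
  if (ncol(dosages) == 0L) {
    return(assoc_stat("none", 0, 1, 1, n, platform)[0, ])
  }
  rz <- .residualize_predictors(dosages, Zdf)
  pt_ <- .partial_t_pvalues(rz, trait)
  # recover beta and se on the dosage scale from the residualized fit
  Q <- rz$Q
  yr <- trait - Q %*% crossprod(Q, trait)
  Xr <- dosages - Q %*% crossprod(Q, dosages)
  xnorm2 <- colSums(Xr^2)
  beta <- as.numeric(crossprod(Xr, yr)) / xnorm2
  rss <- sum(yr^2) - beta^2 * xnorm2
  sigma2 <- rss / rz$df
  se <- sqrt(sigma2 / xnorm2)
  p <- pmax(as.numeric(pt_$p), .Machine$double.xmin)
  out <- data.frame(predictor_id = colnames(dosages), beta = beta, se = se,
                    p_value = p, n = n, platform = platform,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_stat", class(out))
  rownames(out) <- NULL
  out
}

#' Fixed-effect inverse-variance meta-analysis of two platform strata
#'
#' Combines per-platform association results:
#' beta = sum(b_i / se_i^2) / sum(1 / se_i^2), se = 1 / sqrt(sum(1 / se_i^2)),
#' with a normal (z) p-value. When one stratum is absent the other passes
#' through unchanged. Meta-analysing K identical studies shrinks the
#' standard error by exactly sqrt(K).
#'
#' @param stats_a,stats_b [assoc_stat()] rows for the same predictor (one may
#'   be `NULL`).
#' @param minor_a,minor_b Optional coded (minor) alleles; a mismatch is an
#'   error rather than a silent flip.
#' @return An [assoc_stat()] row with platform `"meta"`.
#' @export
meta_analyze <- function(stats_a, stats_b, minor_a = NULL, minor_b = NULL) {
  if (is.null(stats_a) && is.null(stats_b)) stop("both strata absent")
  if (is.null(stats_b)) return(stats_a)
  if (is.null(stats_a)) return(stats_b)
  if (stats_a$predictor_id != stats_b$predictor_id) {
    stop("predictor mismatch: ", stats_a$predictor_id, " vs ",
         stats_b$predictor_id)
  }
  if (!is.null(minor_a) && !is.null(minor_b) && minor_a != minor_b) {
    stop("coded allele mismatch for ", stats_a$predictor_id, ": ",
         minor_a, " vs ", minor_b)
  }
  w <- c(1 / stats_a$se^2, 1 / stats_b$se^2)
  beta <- sum(w * c(stats_a$beta, stats_b$beta)) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  p <- max(2 * pnorm(-abs(z)), .Machine$double.xmin)
  assoc_stat(stats_a$predictor_id, beta, se, p,
             stats_a$n + stats_b$n, "meta")
}

#' Filter association results at the suggestive threshold
#'
#' Retains variants with p strictly below the suggestive threshold
#' (default 1e-5, chosen for moderate sample sizes where genome-wide
#' significance is out of reach). The returned table carries an attribute
#' `n_genome_wide` counting variants below the genome-wide threshold
#' (default 5e-8).
#'
#' @param stats Data frame of association rows with a `p_value` column.
#' @param threshold Suggestive p-value threshold (strict `<`).
#' @param genome_wide Genome-wide significance threshold (strict `<`).
#' @return The retained rows, sorted by p ascending.
#' @export
suggestive_filter <- function(stats, threshold = 1e-5, genome_wide = 5e-8) {
  if (nrow(stats) == 0L) {
    attr(stats, "n_genome_wide") <- 0L
    return(stats)
  }
  out <- stats[stats$p_value < threshold, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genome_wide") <- sum(stats$p_value < genome_wide)
  out
}

#' Linkage disequilibrium as squared dosage correlation
#'
#' r-squared between two dosage vectors (squared Pearson correlation).
#' Computed on dosages rather than phased haplotypes, which is what an
#' imputed-dosage pipeline holds; invariant to allele flips.
#'
#' @param dosage_x,dosage_y Per-subject dosages.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_x, dosage_y) {
  keep <- complete.cases(dosage_x, dosage_y)
  x <- dosage_x[keep]; y <- dosage_y[keep]
  if (var(x) == 0 || var(y) == 0) stop("zero variance dosage")
  min(cor(x, y)^2, 1)
}

#' Greedy LD clumping of suggestive variants
#'
#' Sorts variants by ascending p-value (ties broken by chromosome then
#' position); the best unassigned variant seeds a clump and absorbs every
#' unassigned variant on the same chromosome with r-squared to it above the
#' threshold; repeats until all variants are assigned. The number of clumps
#' is the number of independent loci; each clump's lead SNP is its seed.
#'
#' @param stats Suggestive association rows with columns `predictor_id`,
#'   `p_value`, plus `chrom` and `pos` (merged from the variant map if
#'   absent).
#' @param dosages Subjects x variants dosage matrix covering the variants in
#'   `stats`.
#' @param variant_map Optional data frame with `variant_id`, `chrom`, `pos`
#'   used to attach coordinates.
#' @param r2_threshold Clumping threshold on r-squared (strict `>`).
#' @return List of clumps; each is a list with `lead` (association row),
#'   `members` (data frame of `variant_id`, `r2`), `region_chrom`, and
#'   `region_span` (min/max member position).
#' @export
ld_clump <- function(stats, dosages, variant_map = NULL, r2_threshold = 0.2) {
  if (nrow(stats) == 0L) return(list())
  stats <- as.data.frame(stats)
  if (!all(c("chrom", "pos") %in% names(stats))) {
    stopifnot(!is.null(variant_map))
    idx <- match(stats$predictor_id, variant_map$variant_id)
    stats$chrom <- variant_map$chrom[idx]
    stats$pos <- variant_map$pos[idx]
  }
  stopifnot(all(stats$predictor_id %in% colnames(dosages)))
  ord <- order(stats$p_value, stats$chrom, stats$pos)
  stats <- stats[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(stats))
  clumps <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1L]
    lead <- stats[i, , drop = FALSE]
    assigned[i] <- TRUE
    cand <- which(!assigned & stats$chrom == lead$chrom)
    r2 <- vapply(cand, function(j) {
      ld_r2(dosages[, lead$predictor_id], dosages[, stats$predictor_id[j]])
    }, numeric(1))
    take <- cand[r2 > r2_threshold]
    assigned[take] <- TRUE
    members <- data.frame(
      variant_id = c(lead$predictor_id, stats$predictor_id[take]),
      r2 = c(1, r2[r2 > r2_threshold]),
      p_value = c(lead$p_value, stats$p_value[take]),
      pos = c(lead$pos, stats$pos[take]),
      stringsAsFactors = FALSE)
    clumps[[length(clumps) + 1L]] <- list(
      lead = lead,
      members = members,
      region_chrom = lead$chrom,
      region_span = range(members$pos))
  }
  clumps
}

#' Candidate genes within a window of a lead SNP
#'
#' Retains genes whose nearest boundary lies within `window_kb` of the SNP
#' (1-based inclusive coordinates; `<=` comparison on base pairs). The
#' signed distance is 0 kb when the SNP falls inside the gene span, positive
#' when the SNP lies 5' of the gene's transcription start on the gene's
#' strand, and negative when it lies 3' of the gene's end (so a SNP
#' downstream of a + strand gene gets a negative distance).
#'
#' @param lead_chrom,lead_pos Lead SNP coordinates.
#' @param genes Gene annotation data frame: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param window_kb Window half-width in kb (default 100).
#' @return Data frame `gene_id`, `signed_distance_kb` for retained genes.
#' @export
annotate_genes <- function(lead_chrom, lead_pos, genes, window_kb = 100) {
  stopifnot(nrow(genes) > 0L, all(genes$start <= genes$end))
  g <- genes[genes$chrom == lead_chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(gene_id = character(0), signed_distance_kb = numeric(0),
                      stringsAsFactors = FALSE))
  }
  dist_bp <- ifelse(lead_pos < g$start, g$start - lead_pos,
                    ifelse(lead_pos > g$end, lead_pos - g$end, 0))
  keep <- dist_bp <= window_kb * 1000
  g <- g[keep, , drop = FALSE]
  dist_bp <- dist_bp[keep]
  # upstream (5') of the gene on its strand => positive
  upstream <- ifelse(g$strand == "+", lead_pos < g$start, lead_pos > g$end)
  signed <- ifelse(dist_bp == 0, 0, ifelse(upstream, dist_bp, -dist_bp)) / 1000
  out <- data.frame(gene_id = g$gene_id, signed_distance_kb = signed,
                    stringsAsFactors = FALSE)
  out[order(abs(out$signed_distance_kb)), , drop = FALSE]
}

#' Expression triage for a candidate gene
#'
#' A candidate is carried into the methylation and RNA stages only if it has
#' non-zero brain expression in a majority of subjects -- strictly more than
#' `min_fraction` (default 0.8).
#'
#' @param gene_id Gene to check.
#' @param expr Expression table: list with `values` (subjects x genes matrix,
#'   gene column names) or a matrix directly.
#' @param min_fraction Required fraction of subjects with value > 0
#'   (strict `>`).
#' @return List with `gene_id`, `fraction_nonzero`, `expressed_flag`.
#' @export
expression_triage <- function(gene_id, expr, min_fraction = 0.8) {
  values <- if (is.list(expr) && !is.data.frame(expr)) expr$values else expr
  if (!gene_id %in% colnames(values)) stop("gene absent: ", gene_id)
  v <- values[, gene_id]
  frac <- mean(v > 0, na.rm = TRUE)
  list(gene_id = gene_id, fraction_nonzero = frac,
       expressed_flag = frac > min_fraction)
}

#' cis-eQTL test of a lead SNP against nearby genes
#'
#' Regresses each candidate gene's expression on the lead SNP's dosage with
#' the RNA technical covariates; one association row per gene. Genes with
#' constant expression are flagged as degenerate rather than tested.
#'
#' @param dosage Lead-SNP dosage per subject.
#' @param expr_values Subjects x genes expression matrix (candidate genes).
#' @param tech_covariates Data frame of RNA technical covariates.
#' @param platform Label for the output rows.
#' @return Data frame of association rows; degenerate genes appear with
#'   `NA` statistics and are listed in attribute `degenerate`.
#' @export
cis_eqtl <- function(dosage, expr_values, tech_covariates = NULL,
                     platform = "eqtl") {
  expr_values <- as.matrix(expr_values)
  rows <- vector("list", ncol(expr_values))
  degenerate <- character(0)
  for (j in seq_len(ncol(expr_values))) {
    gene <- colnames(expr_values)[j]
    v <- expr_values[, j]
    if (var(v, na.rm = TRUE) == 0) {
      degenerate <- c(degenerate, gene)
      rows[[j]] <- data.frame(predictor_id = gene, beta = NA_real_,
                              se = NA_real_, p_value = NA_real_,
                              n = sum(complete.cases(v, dosage)),
                              platform = platform, stringsAsFactors = FALSE)
      next
    }
    st <- .ols_single_term(dosage, v, tech_covariates, gene, platform)
    rows[[j]] <- as.data.frame(st)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}
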