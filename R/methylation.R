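# Stage 2: region-level methylation omnibus test. Per-CpG regressions of
# residual cognition on methylation with technical covariates, Fisher
# combination of the per-CpG p-values, and an empirical null from permuting
# the trait. Also the kNN imputation used to complete the beta matrix.

#' k-nearest-neighbour imputation of methylation beta values
#'
#' Each missing entry is replaced by the mean of that CpG's value among the
#' k subjects nearest to the one with the gap. Subject distance is the root
#' mean squared difference over the CpGs both subjects have observed
#' (a Euclidean distance normalised for unequal overlap). Non-missing
#' entries are never touched; `k` is capped at the number of subjects with
#' an observed value at the CpG.
#'
#' @param betas Subjects x CpGs matrix of beta values in \[0, 1\], `NA` for
#'   missing.
#' @param k Neighbourhood size (default 100).
#' @return The completed matrix.
#' @export
knn_impute <- function(betas, k = 100) {
  betas <- as.matrix(betas)
  if (!any(is.na(betas))) return(betas)
  obs <- !is.na(betas)
  if (any(rowSums(obs) == 0L)) {
    stop("subject(s) with all CpGs missing: ",
         paste(rownames(betas)[rowSums(obs) == 0L], collapse = ", "))
  }
  M <- betas; M[!obs] <- 0
  W <- obs * 1
  # mean squared difference over shared observed CpGs, via the expansion
  # sum (x_i - x_j)^2 = sum x_i^2 + sum x_j^2 - 2 sum x_i x_j on the overlap
  S <- M^2
  shared <- tcrossprod(W)
  ss <- tcrossprod(S * W, W) + tcrossprod(W, S * W) - 2 * tcrossprod(M)
  D2 <- ss / pmax(shared, 1)
  D2[shared == 0] <- Inf
  diag(D2) <- Inf
  out <- betas
  for (j in which(colSums(!obs) > 0L)) {
    donors <- which(obs[, j])
    for (i in which(!obs[, j])) {
      kk <- min(k, length(donors))
      nn <- donors[order(D2[i, donors])[seq_len(kk)]]
      out[i, j] <- mean(betas[nn, j])
    }
  }
  out
}

#' CpGs within a flanking window of a gene
#'
#' Returns the CpG ids on the gene's chromosome with position in
#' `[start - flank, end + flank]` (1-based inclusive; default flank 100 kb
#' on either side of the transcribed span).
#'
#' @param gene One-row gene annotation (`chrom`, `start`, `end`).
#' @param cpg_map Data frame with `cpg_id`, `chrom`, `pos`.
#' @param flank_kb Flank width in kb.
#' @return Character vector of CpG ids.
#' @export
region_cpgs <- function(gene, cpg_map, flank_kb = 100) {
  flank <- flank_kb * 1000
  keep <- cpg_map$chrom == gene$chrom &
    cpg_map$pos >= gene$start - flank &
    cpg_map$pos <= gene$end + flank
  cpg_map$cpg_id[keep]
}

#' Single-CpG association with residual cognition
#'
#' Linear model: trait ~ beta value + technical covariates (batch and mean
#' bisulfite conversion).
#'
#' @param beta Per-subject methylation beta values at one CpG.
#' @param trait Per-subject residual cognition.
#' @param tech Data frame of technical covariates (e.g. `batch` factor and
#'   `bisulfite` numeric), or `NULL`.
#' @param predictor_id CpG id for the output row.
#' @return An [assoc_stat()] row.
#' @export
cpg_association <- function(beta, trait, tech = NULL,
                            predictor_id = "cpg") {
  .ols_single_term(beta, trait, tech, predictor_id, platform = "methylation",
                   zero_var_msg = "constant methylation beta")
}

#' Fisher's combined statistic
#'
#' T = -2 * sum(ln p_i). Under k independent uniform p-values T is
#' chi-squared with 2k degrees of freedom; here the correlation between
#' CpGs is handled by the permutation null instead, so T is used only as a
#' summary to be calibrated empirically. Zero p-values are an error: any
#' flooring must be explicit at the call site, never silent here.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Nonnegative combined statistic.
#' @export
fisher_statistic <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(is.na(p_values))) stop("missing p-values")
  if (any(p_values <= 0)) stop("p-value of 0 (or below) is not loggable")
  if (any(p_values > 1)) stop("p-values must lie in (0, 1]")
  -2 * sum(log(p_values))
}

#' Benjamini--Hochberg q-values
#'
#' Step-up false-discovery-rate q-values (wraps `stats::p.adjust`).
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# Shared core of the unadjusted and SNP-adjusted omnibus tests. `Z` is the
# nuisance covariate data frame used in every per-CpG model; permutations
# reuse one permutation of the trait across all the region's CpGs so the
# combined statistic is a valid joint draw.
.omnibus_core <- function(betas, trait, Z, B, seed, gene_id, adjusted,
                          scheme = c("raw", "freedman-lane"),
                          p_floor = 1e-300) {
  scheme <- match.arg(scheme)
  betas <- as.matrix(betas)
  if (ncol(betas) == 0L) stop("no CpGs in region")
  if (B <= 0) stop("B must be positive")
  if (B < 100) warning("B < 100 permutations gives a coarse empirical p")
  keep <- complete.cases(trait, if (!is.null(Z)) Z else trait) &
    rowSums(is.na(betas)) == 0
  betas <- betas[keep, , drop = FALSE]
  trait <- trait[keep]
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- length(trait)
  if (n < 20L) stop("insufficient complete cases: ", n)
  rz <- .residualize_predictors(betas, Z)

  floor_p <- function(P) {
    if (any(P < p_floor)) {
      warning("per-CpG p-value(s) below ", p_floor, " floored before logging")
      P[P < p_floor] <- p_floor
    }
    P
  }
  obs <- .partial_t_pvalues(rz, trait)
  p_obs <- floor_p(as.numeric(obs$p))
  T_obs <- fisher_statistic(p_obs)

  if (!is.null(seed)) set.seed(seed)
  if (scheme == "freedman-lane") {
    fit_part <- trait - as.numeric(rz$Q %*% crossprod(rz$Q, trait))
    base <- trait - fit_part   # fitted values under the nuisance model
    eps <- fit_part
  }
  exceed <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    Yp <- matrix(0, n, b)
    for (jj in seq_len(b)) {
      perm <- sample.int(n)
      Yp[, jj] <- if (scheme == "raw") trait[perm] else base + eps[perm]
    }
    Pm <- .partial_t_pvalues(rz, Yp)$p
    Pm[Pm < p_floor] <- p_floor
    T_perm <- -2 * colSums(log(Pm))
    exceed <- exceed + sum(T_perm >= T_obs)
    done <- done + b
  }
  empirical_p <- (1 + exceed) / (B + 1)
  top <- which.min(p_obs)
  structure(list(
    gene_id = gene_id,
    n_cpgs = ncol(betas),
    observed_T = T_obs,
    empirical_p = empirical_p,
    fdr_q = NA_real_,
    top_cpg = colnames(betas)[top],
    top_cpg_p = p_obs[top],
    cpg_p_values = setNames(p_obs, colnames(betas)),
    adjusted_for_snp = adjusted,
    n = n, B = B, scheme = scheme
  ), class = "omnibus_result")
}

#' Region-level methylation omnibus test
#'
#' Three steps: (1) each CpG in the region is tested against residual
#' cognition by linear regression with the technical covariates; (2) the
#' per-CpG p-values are combined into one observed statistic by Fisher's
#' method; (3) the trait vector is permuted across subjects B times
#' (methylation and covariates fixed, covariates refit within each
#' permutation), the statistic recomputed each time, and the empirical
#' p-value taken as `(1 + #\{T_perm >= T_obs\}) / (B + 1)` -- the add-one
#' convention that keeps the p-value valid and nonzero. One permutation is
#' shared across all the region's CpGs per draw.
#'
#' @param betas Subjects x CpGs matrix for the region (complete; run
#'   [knn_impute()] first if needed).
#' @param trait Residual cognition per subject.
#' @param tech Technical covariate data frame (batch, bisulfite), or `NULL`.
#' @param B Number of permutations (default 10000).
#' @param seed Seed for the permutation stream (`NULL` to use the current
#'   RNG state).
#' @param gene_id Region label.
#' @return An `omnibus_result` list: `gene_id`, `n_cpgs`, `observed_T`,
#'   `empirical_p`, `fdr_q` (filled across regions by the caller),
#'   `top_cpg`, `top_cpg_p`, per-CpG p-values, and bookkeeping fields.
#' @export
omnibus_test <- function(betas, trait, tech = NULL, B = 10000, seed = NULL,
                         gene_id = "region") {
  .omnibus_core(betas, trait, tech, B, seed, gene_id, adjusted = FALSE)
}

#' SNP-adjusted methylation omnibus test
#'
#' Identical machinery to [omnibus_test()] with the region's lead-SNP dosage
#' and the ancestry covariates (EV1--3) added to every per-CpG regression,
#' used to check whether the epigenetic association is independent of the
#' genetic one. By default the raw trait is permuted, matching the
#' unadjusted procedure; `scheme = "freedman-lane"` instead permutes
#' residuals from the nuisance model and is better calibrated when the
#' added covariates carry strong signal.
#'
#' @inheritParams omnibus_test
#' @param lead_dosage Lead-SNP dosage per subject.
#' @param ev_covariates Data frame of ancestry covariates (EV1--3), or
#'   `NULL`.
#' @param scheme Permutation scheme, `"raw"` (default) or
#'   `"freedman-lane"`.
#' @return An `omnibus_result` with `adjusted_for_snp = TRUE`.
#' @export
omnibus_adjusted <- function(betas, trait, tech = NULL, lead_dosage,
                             ev_covariates = NULL, B = 10000, seed = NULL,
                             gene_id = "region",
                             scheme = c("raw", "freedman-lane")) {
  Z <- data.frame(lead_dosage = lead_dosage)
  if (!is.null(ev_covariates)) Z <- cbind(Z, ev_covariates)
  if (!is.null(tech)) Z <- cbind(Z, tech)
  .omnibus_core(betas, trait, Z, B, seed, gene_id, adjusted = TRUE,
                scheme = match.arg(scheme))
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat(sprintf("Omnibus methylation test: %s%s\n", x$gene_id,
              if (x$adjusted_for_snp) " (SNP-adjusted)" else ""))
  cat(sprintf("  %d CpGs, n = %d, B = %d permutations\n",
              x$n_cpgs, x$n, x$B))
  cat(sprintf("  observed T = %.3f, empirical p = %.4g\n",
              x$observed_T, x$empirical_p))
  cat(sprintf("  top CpG: %s (p = %.3g)\n", x$top_cpg, x$top_cpg_p))
  invisible(x)
}
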