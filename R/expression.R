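# Stage 3: transcript-level association with residual cognition, and the
# conditional models used in secondary analyses (TDP-43 adjustment,
# two-SNP joint models).

#' Gene expression association with residual cognition
#'
#' Linear model: trait ~ batch-adjusted FPKM + RNA technical covariates
#' (RNA integrity score, log2 total aligned reads, postmortem interval,
#' ribosomal bases). The effect is per FPKM unit, so highly expressed genes
#' naturally show small per-unit coefficients.
#'
#' @param values Per-subject adjusted FPKM for one gene.
#' @param trait Per-subject residual cognition.
#' @param tech Data frame of technical covariates, or `NULL`.
#' @param predictor_id Gene id for the output row.
#' @return An [assoc_stat()] row.
#' @export
expression_association <- function(values, trait, tech = NULL,
                                   predictor_id = "gene") {
  .ols_single_term(values, trait, tech, predictor_id, platform = "rna",
                   zero_var_msg = "constant expression")
}

#' Marginal and conditional association of a predictor
#'
#' Fits the marginal model trait ~ dosage (+ covariates) and the conditional
#' model with one conditioning variable added (a TDP-43 stage or severity
#' score entered as a linear ordinal term, or a second SNP's dosage), and
#' reports the attenuation of the predictor's effect,
#' `1 - beta_conditional / beta_marginal`. Used to ask whether a genetic
#' effect on residual cognition survives adjustment for a putative mediator
#' or is fully captured by a partner variant on the same haplotype.
#'
#' @param dosage Predictor of interest (per-subject).
#' @param trait Residual cognition per subject.
#' @param conditioning Conditioning variable (non-constant; an r-squared
#'   with the predictor above `collinearity_r2` is an error).
#' @param covariates Shared covariate table for both models, or `NULL`.
#' @param predictor_id,conditioning_id Labels for reporting.
#' @param collinearity_r2 Guard threshold (default 0.99).
#' @return List with `marginal` and `conditional` [assoc_stat()] rows and
#'   `attenuation`.
#' @export
conditional_association <- function(dosage, trait, conditioning,
                                    covariates = NULL,
                                    predictor_id = "predictor",
                                    conditioning_id = "conditioning",
                                    collinearity_r2 = 0.99) {
  keep <- complete.cases(dosage, trait, conditioning)
  if (var(conditioning[keep]) == 0) stop("conditioning variable is constant")
  r2 <- cor(dosage[keep], conditioning[keep])^2
  if (r2 > collinearity_r2) {
    stop("conditioning variable collinear with predictor (r2 = ",
         signif(r2, 3), ")")
  }
  marg <- .ols_single_term(dosage, trait, covariates, predictor_id, "marginal")
  cond_cov <- data.frame(conditioning = conditioning)
  names(cond_cov) <- conditioning_id
  if (!is.null(covariates)) cond_cov <- cbind(cond_cov, covariates)
  cond <- .ols_single_term(dosage, trait, cond_cov, predictor_id,
                           "conditional")
  list(marginal = marg, conditional = cond,
       attenuation = 1 - cond$beta / marg$beta)
}
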