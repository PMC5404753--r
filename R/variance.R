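# Sequential adjusted R-squared ledger: how much variance in last global
# cognition is explained by demographics + pathology, and how much more by
# the candidate genetic / epigenetic / transcriptomic features.

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`, the usual penalty for predictor
#' count, so adding uninformative features can lower the adjusted value.
#'
#' @param r2 Unadjusted R-squared in \[0, 1\].
#' @param n Sample size.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  stopifnot(r2 >= 0, r2 <= 1 + 1e-12)
  if (n <= p + 1) stop("n must exceed p + 1 (n = ", n, ", p = ", p, ")")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# One OLS fit on an assembled design; returns r2, adjusted r2, n, p.
.ledger_fit <- function(X, y, label) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient ", label, " design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p <- ncol(X) - 1L
  list(r2 = r2, adj = adjusted_r2(r2, length(y), p), p = p)
}

#' Sequential adjusted R-squared variance ledger
#'
#' Two nested OLS models of raw last global cognition (not the residual):
#' the base model with demographics and the ten pathologies, and the full
#' model adding the candidate features (lead-SNP dosages, top-CpG beta
#' values, RNA levels). The ledger reports the base adjusted R-squared, the
#' increment gained by the features, and the unexplained remainder
#' `1 - full`; the three sum to 1 by construction. The increment can be
#' negative because adjusted R-squared penalises predictor count.
#'
#' @param subjects Subject table as for [compute_residual_cognition()].
#' @param pathologies Pathology table as for [compute_residual_cognition()].
#' @param features Data frame of candidate features with a `subject_id`
#'   column; only subjects complete across all tables enter.
#' @return A list of class `variance_ledger`: `n`, `base_adj_r2`,
#'   `full_adj_r2`, `increment`, `unexplained`, plus unadjusted
#'   `base_r2`/`full_r2` and predictor counts.
#' @export
sequential_ledger <- function(subjects, pathologies, features) {
  demog <- c("age_at_death", "sex", "education", "cohort")
  path <- c("tangles", "neuritic_plaques", "diffuse_plaques", "caa",
            "atherosclerosis", "arteriolosclerosis", "macroinfarcts",
            "microinfarcts", "lewy_bodies", "hippocampal_sclerosis")
  stopifnot("subject_id" %in% names(features), ncol(features) >= 2L)
  dat <- merge(subjects, pathologies[, c("subject_id", path)],
               by = "subject_id", sort = FALSE)
  dat <- merge(dat, features, by = "subject_id", sort = FALSE)
  feat_cols <- setdiff(names(features), "subject_id")
  need <- c(demog, path, feat_cols, "last_global_cognition")
  dat <- dat[complete.cases(dat[, need]), , drop = FALSE]
  if (nrow(dat) < 20L) stop("insufficient complete cases: ", nrow(dat))
  dat$cohort <- factor(dat$cohort)
  y <- dat$last_global_cognition
  X_base <- model.matrix(~ ., data = dat[, c(demog, path), drop = FALSE])
  X_full <- cbind(X_base, as.matrix(dat[, feat_cols, drop = FALSE]))
  base <- .ledger_fit(X_base, y, "base")
  full <- .ledger_fit(X_full, y, "full")
  structure(list(
    n = nrow(dat),
    base_adj_r2 = base$adj,
    full_adj_r2 = full$adj,
    increment = full$adj - base$adj,
    unexplained = 1 - full$adj,
    base_r2 = base$r2,
    full_r2 = full$r2,
    p_base = base$p,
    p_full = full$p,
    feature_names = feat_cols
  ), class = "variance_ledger")
}

#' @export
print.variance_ledger <- function(x, ...) {
  cat("Sequential adjusted R-squared ledger\n")
  cat(sprintf("  n = %d complete cases, %d -> %d predictors\n",
              x$n, x$p_base, x$p_full))
  cat(sprintf("  demographics + pathology: %.1f%%\n", 100 * x$base_adj_r2))
  cat(sprintf("  increment from features:  %.1f%%\n", 100 * x$increment))
  cat(sprintf("  unexplained:              %.1f%%\n", 100 * x$unexplained))
  invisible(x)
}
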