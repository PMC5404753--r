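# Shared OLS machinery for single-predictor association tests.
#
# Every stage of the pipeline fits the same shape of model: trait ~ predictor
# + nuisance covariates, with the inference on the predictor term. The
# helpers here centralise complete-case handling, degenerate-input checks,
# and the t-based inference so per-stage wrappers stay thin.

#' Construct a one-row association statistic
#'
#' Standard container for a single predictor--trait test: effect estimate,
#' standard error, two-sided p-value, sample size, and the analysis stratum
#' (genotyping platform or `"meta"`).
#'
#' @param predictor_id Identifier of the tested predictor.
#' @param beta Effect estimate per unit of the predictor.
#' @param se Standard error of `beta` (must be positive).
#' @param p_value Two-sided p-value in (0, 1].
#' @param n Number of complete cases used.
#' @param platform Label of the analysis stratum; `"meta"` for combined.
#' @return A one-row `data.frame` with class `assoc_stat`.
#' @export
assoc_stat <- function(predictor_id, beta, se, p_value, n, platform = "all") {
  stopifnot(is.finite(beta), is.finite(se), se > 0,
            p_value > 0, p_value <= 1, n >= 1)
  out <- data.frame(predictor_id = as.character(predictor_id),
                    beta = beta, se = se, p_value = p_value,
                    n = as.integer(n), platform = as.character(platform),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_stat", class(out))
  out
}

# Covariates arrive as NULL, a vector, a matrix, or a data.frame (possibly
# holding factors). Returns a numeric model matrix without intercept.
.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  if (is.vector(covariates) && !is.list(covariates)) {
    covariates <- data.frame(cov1 = covariates)
  }
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  mm <- model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]
}

# OLS of y on [1, x, Z]; returns inference for the x term. `min_n` guards
# against underpowered degenerate fits rather than statistical power per se.
.ols_single_term <- function(x, y, covariates = NULL, predictor_id = "x",
                             platform = "all", min_n = 20L,
                             zero_var_msg = "zero variance predictor") {
  stopifnot(length(x) == length(y))
  Z <- .covariate_matrix(covariates, length(y))
  keep <- complete.cases(x, y, Z)
  x <- x[keep]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  n <- length(y)
  if (n < min_n) {
    stop("insufficient complete cases: ", n, " < ", min_n)
  }
  if (var(x) == 0) stop(zero_var_msg)
  if (var(y) == 0) stop("zero variance response")
  X <- cbind(`(Intercept)` = 1, predictor = x, Z)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("rank-deficient design in association model")
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["predictor"])
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  p <- max(p, .Machine$double.xmin)   # keep within (0, 1]
  assoc_stat(predictor_id, beta, se, p, n, platform)
}

# Frisch-Waugh residualization: p-values for many predictors sharing one
# covariate set, identical to fitting each full OLS model. Used by the
# variant scan and the permutation omnibus where per-fit lm() would be slow.
#
# Returns a list with unit-normalised residualized predictors (n x m), the
# thin-Q basis of [1, Z], and the error degrees of freedom of the full model.
.residualize_predictors <- function(X, covariates = NULL) {
  n <- nrow(X)
  Z <- cbind(1, .covariate_matrix(covariates, n))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariate matrix")
  Q <- qr.Q(qz)
  Xr <- X - Q %*% crossprod(Q, X)
  norms <- sqrt(colSums(Xr^2))
  if (any(norms < 1e-12)) {
    stop("predictor collinear with covariates: ",
         paste(colnames(X)[norms < 1e-12], collapse = ", "))
  }
  list(Xu = sweep(Xr, 2, norms, "/"), Q = Q, df = n - ncol(Z) - 1L)
}

# Given the output of .residualize_predictors and a response vector (or
# matrix of responses in columns), return the matrix of two-sided t-test
# p-values (m predictors x k responses) and the t statistics.
.partial_t_pvalues <- function(rz, Y) {
  Y <- as.matrix(Y)
  Yr <- Y - rz$Q %*% crossprod(rz$Q, Y)
  ynorm <- sqrt(colSums(Yr^2))
  ynorm[ynorm < 1e-300] <- 1e-300
  Yu <- sweep(Yr, 2, ynorm, "/")
  R <- crossprod(rz$Xu, Yu)                 # partial correlations, m x k
  R <- pmin(pmax(R, -1 + 1e-15), 1 - 1e-15)
  Tm <- R * sqrt(rz$df / (1 - R^2))
  P <- 2 * pt(-abs(Tm), rz$df)
  list(t = Tm, p = P)
}
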