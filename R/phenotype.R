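# Phenotype construction: composite pathology scores, global cognition,
# and the residual-cognition trait that every downstream stage consumes.

#' Composite pathology score from regional scaled counts
#'
#' Neurofibrillary tangles, neuritic plaques, and diffuse plaques are counted
#' in five brain regions; each region's counts are scaled (divided by the
#' region's baseline standard deviation, so values stay nonnegative) and the
#' composite is the square root of the regional average, which tames the
#' strong positive skew of raw counts.
#'
#' @param regional_scaled_values Nonnegative scaled counts, one per region.
#' @return `sqrt(mean(regional_scaled_values))`, a nonnegative scalar.
#' @examples
#' composite_pathology_score(c(1, 1, 1, 1, 1))  # 1
#' composite_pathology_score(c(4, 0))           # sqrt(2)
#' @export
composite_pathology_score <- function(regional_scaled_values) {
  v <- regional_scaled_values[!is.na(regional_scaled_values)]
  if (length(v) == 0L) stop("no non-missing regional values")
  if (any(v < 0)) stop("regional scaled values must be nonnegative")
  sqrt(mean(v))
}

#' Scale regional counts by their baseline standard deviation
#'
#' Scaling without centering keeps values nonnegative so the square root in
#' [composite_pathology_score()] is defined. Constant regions scale to zero.
#'
#' @param counts Matrix of raw regional counts (subjects x regions).
#' @param baseline_sd Optional per-region SDs; defaults to the column SDs of
#'   `counts` (cohort-combined baseline).
#' @return Matrix of scaled counts with the same dimensions.
#' @export
scale_regional_counts <- function(counts, baseline_sd = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  if (is.null(baseline_sd)) baseline_sd <- apply(counts, 2, sd, na.rm = TRUE)
  stopifnot(length(baseline_sd) == ncol(counts))
  baseline_sd[baseline_sd == 0] <- 1
  sweep(counts, 2, baseline_sd, "/")
}

#' Cerebral amyloid angiopathy score
#'
#' CAA is graded on a five-level scale (0--4) in four neocortical regions;
#' the score is the arithmetic mean of the four grades.
#'
#' @param regional_grades Exactly four grades, each in \[0, 4\].
#' @return Mean grade in \[0, 4\].
#' @export
caa_score <- function(regional_grades) {
  if (length(regional_grades) != 4L) stop("exactly four regional grades required")
  if (any(is.na(regional_grades)) ||
      any(regional_grades < 0 | regional_grades > 4)) {
    stop("grades must lie in [0, 4]")
  }
  mean(regional_grades)
}

#' Global cognition from a 17-test battery
#'
#' Global cognitive performance is the mean of per-test z-scores, each score
#' standardised against the battery's baseline mean and SD. Tests may be
#' missing; by default at least half must be present.
#'
#' @param test_scores Numeric vector of raw test scores (17 in the standard
#'   battery), `NA` for missing tests.
#' @param baseline_means,baseline_sds Baseline mean and SD per test;
#'   `baseline_sds` must be positive.
#' @param min_fraction Minimum fraction of non-missing tests required;
#'   below it the summary is returned as `NA` with a warning.
#' @return Mean z-score, or `NA` when too few tests are present.
#' @export
global_cognition <- function(test_scores, baseline_means, baseline_sds,
                             min_fraction = 0.5) {
  stopifnot(length(test_scores) == length(baseline_means),
            length(test_scores) == length(baseline_sds))
  if (any(baseline_sds <= 0)) stop("baseline SDs must be positive")
  present <- !is.na(test_scores)
  if (!any(present)) stop("all tests missing")
  if (mean(present) < min_fraction) {
    warning("fewer than ", round(100 * min_fraction),
            "% of tests present; returning NA")
    return(NA_real_)
  }
  z <- (test_scores[present] - baseline_means[present]) / baseline_sds[present]
  mean(z)
}

#' Residual cognition: regress pathology and demographics out of cognition
#'
#' Fits the multivariate linear model of last global cognition on the four
#' demographic covariates (age at death, sex, education, study cohort) and
#' the ten neuropathology indices (tangles, neuritic plaques, diffuse
#' plaques, CAA, atherosclerosis, arteriolosclerosis, macroinfarcts,
#' microinfarcts, Lewy bodies, hippocampal sclerosis). TDP-43 measures are
#' deliberately not part of this model. The residual is the trait
#' ("residual cognition") carried into the association stages; it captures
#' performing better -- or worse -- than the pathological burden predicts.
#'
#' @param subjects Data frame with `subject_id`, `age_at_death`, `sex`,
#'   `education`, `cohort`, and `last_global_cognition`.
#' @param pathologies Data frame with `subject_id` and the ten pathology
#'   columns named in Details.
#' @return A list of class `residual_fit`: `coefficients`, per-subject
#'   `residuals` (named by `subject_id`), `fitted`, `r_squared`,
#'   `adjusted_r_squared`, `n`, and `subjects` -- the input table restricted
#'   to complete cases with a `residual_cognition` column filled in.
#' @export
compute_residual_cognition <- function(subjects, pathologies) {
  demog <- c("age_at_death", "sex", "education", "cohort")
  path <- c("tangles", "neuritic_plaques", "diffuse_plaques", "caa",
            "atherosclerosis", "arteriolosclerosis", "macroinfarcts",
            "microinfarcts", "lewy_bodies", "hippocampal_sclerosis")
  stopifnot(all(c("subject_id", demog, "last_global_cognition") %in%
                  names(subjects)),
            all(c("subject_id", path) %in% names(pathologies)))
  dat <- merge(subjects, pathologies[, c("subject_id", path)],
               by = "subject_id", sort = FALSE)
  covars <- c(demog, path)
  dat <- dat[complete.cases(dat[, c(covars, "last_global_cognition")]), ,
             drop = FALSE]
  if (nrow(dat) < 20L) stop("insufficient complete cases: ", nrow(dat))
  dat$cohort <- factor(dat$cohort)
  X <- model.matrix(~ ., data = dat[, covars, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  y <- dat$last_global_cognition
  fit <- lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- ncol(X) - 1L
  r2 <- 1 - rss / tss
  dat$residual_cognition <- res
  structure(list(
    coefficients = fit$coefficients,
    residuals = setNames(res, dat$subject_id),
    fitted = setNames(fit$fitted.values, dat$subject_id),
    r_squared = r2,
    adjusted_r_squared = adjusted_r2(r2, n, p),
    n = n,
    covariate_names = covars,
    subjects = dat
  ), class = "residual_fit")
}

#' @export
print.residual_fit <- function(x, ...) {
  cat("Residual-cognition model fit\n")
  cat(sprintf("  n = %d complete cases\n", x$n))
  cat(sprintf("  R-squared = %.4f (adjusted %.4f)\n",
              x$r_squared, x$adjusted_r_squared))
  cat(sprintf("  residual SD = %.4f\n", sd(x$residuals)))
  invisible(x)
}

#' Per-subject cognitive decline slope
#'
#' Least-squares slope of global cognition on time (years), one subject at a
#' time. Subjects with fewer than three visits get `NA` with a warning.
#'
#' @param visit_times Visit times in years (e.g. years before death, or
#'   years since enrollment -- only differences matter).
#' @param global_scores Global cognition at each visit.
#' @return Slope in cognition z-score units per year, or `NA`.
#' @export
decline_slope <- function(visit_times, global_scores) {
  keep <- complete.cases(visit_times, global_scores)
  x <- visit_times[keep]; y <- global_scores[keep]
  if (length(x) < 3L) {
    warning("fewer than 3 visits; slope set to NA")
    return(NA_real_)
  }
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}
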