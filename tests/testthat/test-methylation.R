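test_that("kNN imputation leaves complete input untouched and fills gaps", {
  set.seed(1)
  b <- matrix(runif(200, 0.2, 0.8), 20, 10,
              dimnames = list(sprintf("S%02d", 1:20), sprintf("cg%02d", 1:10)))
  expect_identical(knn_impute(b), b)
  # one gap among identical neighbours with value 0.7 imputes to 0.7
  b2 <- matrix(0.7, 20, 10, dimnames = dimnames(b))
  b2[3, 4] <- NA
  expect_equal(knn_impute(b2)[3, 4], 0.7)
  # observed entries are never modified
  b3 <- b
  b3[5, 2] <- NA
  out <- knn_impute(b3, k = 5)
  expect_equal(out[-5, ], b[-5, ])
  expect_false(is.na(out[5, 2]))
  # subject with no data at all is an error
  b4 <- b
  b4[1, ] <- NA
  expect_error(knn_impute(b4), "all CpGs missing")
})

test_that("kNN imputation beats column-mean imputation on masked data", {
  # mask-and-recover: subjects have correlated methylation profiles, so
  # neighbours carry signal a column mean ignores
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 60; m <- 30
    subj <- rnorm(n)
    truth <- plogis(outer(subj, rnorm(m, 0, 0.8), "+") +
                      matrix(rnorm(n * m, 0, 0.4), n))
    masked <- truth
    idx <- which(matrix(runif(n * m) < 0.05, n))
    masked[idx] <- NA
    imp <- knn_impute(masked, k = 10)
    rmse_knn <- sqrt(mean((imp[idx] - truth[idx])^2))
    cm <- matrix(colMeans(masked, na.rm = TRUE), n, m, byrow = TRUE)
    rmse_cm <- sqrt(mean((cm[idx] - truth[idx])^2))
    wins <- wins + (rmse_knn < rmse_cm)
  }
  expect_gte(wins, 18)
})

test_that("region CpG lookup applies the flanking window inclusively", {
  gene <- data.frame(chrom = 2, start = 500000, end = 550000)
  cpgs <- data.frame(
    cpg_id = c("at_start", "inside", "at_flank", "past_flank", "wrong_chrom"),
    chrom = c(2, 2, 2, 2, 3),
    pos = c(500000, 520000, 650000, 650001, 520000),
    stringsAsFactors = FALSE)
  got <- region_cpgs(gene, cpgs, flank_kb = 100)
  expect_setequal(got, c("at_start", "inside", "at_flank"))
  # constructed fixture with an exact in-window count
  set.seed(7)
  fix <- data.frame(cpg_id = sprintf("cg%03d", 1:60), chrom = 2,
                    pos = c(sample(400000:650000, 44),
                            sample(700000:900000, 16)))
  expect_length(region_cpgs(gene, fix, 100), 44)
})

test_that("per-CpG association matches lm and is well calibrated under the null", {
  set.seed(3)
  n <- 200
  beta <- runif(n, 0, 1)
  tech <- data.frame(batch = factor(sample(c("b1", "b2"), n, TRUE)),
                     bisulfite = rnorm(n, 98.5, 0.5))
  y <- 3 * beta + rnorm(n, 0, 0.5)
  st <- cpg_association(beta, y, tech)
  ref <- summary(lm(y ~ beta + batch + bisulfite, data = tech))
  expect_equal(st$p_value, ref$coefficients["beta", "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_lt(st$p_value, 1e-20)
  # null p-values uniform across replicates
  p <- replicate(1000, {
    cpg_association(runif(120, 0, 1), rnorm(120))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_error(cpg_association(rep(0.5, n), y, tech), "constant")
})

test_that("planted CpG effects are detected with good power at n = 648", {
  hits <- sapply(1:40, function(s) {
    set.seed(400 + s)
    n <- 648
    x <- runif(n, 0, 1)
    y <- 0.15 * scale(x) + rnorm(n)
    cpg_association(x, as.numeric(y))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("Fisher statistic is -2 sum log p with strict domain checks", {
  expect_equal(fisher_statistic(rep(1, 5)), 0)
  expect_equal(fisher_statistic(c(0.1, 0.01)), -2 * (log(0.1) + log(0.01)))
  expect_equal(fisher_statistic(c(0.1, 0.01)), 13.8155, tolerance = 1e-4)
  expect_error(fisher_statistic(c(0.5, 0)), "not loggable")
  expect_error(fisher_statistic(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(fisher_statistic(numeric(0)), "empty")
  # permutation-invariant and strictly decreasing in each argument
  p <- c(0.2, 0.05, 0.8)
  expect_equal(fisher_statistic(p), fisher_statistic(rev(p)))
  expect_gt(fisher_statistic(c(0.1, 0.05)), fisher_statistic(c(0.2, 0.05)))
})

test_that("Fisher statistic of k uniforms behaves as chi-squared(2k)", {
  set.seed(5)
  k <- 6
  draws <- replicate(10000, fisher_statistic(runif(k)))
  expect_lt(abs(mean(draws) - 2 * k), 0.05 * 2 * k)
  expect_lt(abs(var(draws) - 4 * k), 0.15 * 4 * k)
})

test_that("BH q-values match the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_fdr(0.07), 0.07)
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p[p <= 0] <- 1e-12
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("omnibus per-CpG p-values equal the single-CpG regression p-values", {
  set.seed(8)
  n <- 100
  B <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("cg", 1:5)))
  tech <- data.frame(batch = factor(sample(c("b1", "b2"), n, TRUE)),
                     bisulfite = rnorm(n))
  y <- rnorm(n) + 0.5 * B[, 2]
  om <- omnibus_test(B, y, tech, B = 100, seed = 1)
  for (j in 1:5) {
    expect_equal(unname(om$cpg_p_values[j]),
                 cpg_association(B[, j], y, tech)$p_value,
                 tolerance = 1e-10)
  }
  expect_equal(om$observed_T, fisher_statistic(om$cpg_p_values))
})

test_that("an extreme observed statistic gives empirical p = 1/(B+1)", {
  set.seed(9)
  n <- 150
  B <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("cg", 1:4)))
  y <- 5 * B[, 1] + rnorm(n, 0, 0.05)     # overwhelming signal
  om <- omnibus_test(B, y, B = 500, seed = 2)
  expect_equal(om$empirical_p, 1 / 501)
  expect_equal(om$top_cpg, "cg1")
})

test_that("empirical p is invariant to subject relabeling and trait shifts", {
  set.seed(10)
  n <- 80
  Bm <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("cg", 1:3)))
  y <- rnorm(n) + 0.4 * Bm[, 1]
  om1 <- omnibus_test(Bm, y, B = 300, seed = 11)
  om2 <- omnibus_test(Bm, y + 100, B = 300, seed = 11)
  expect_equal(om1$empirical_p, om2$empirical_p)   # same perms: exact
  perm <- sample(n)
  om3 <- omnibus_test(Bm[perm, ], y[perm], B = 1000, seed = 11)
  # relabeling changes which permutations are drawn, so agreement is up to
  # Monte-Carlo noise; the observed statistic itself is exactly invariant
  expect_equal(om1$observed_T, om3$observed_T, tolerance = 1e-10)
  expect_lt(abs(om1$empirical_p - om3$empirical_p),
            3 * sqrt(0.5 / 300) + 3 * sqrt(0.5 / 1000))
})

test_that("single-CpG omnibus approaches the exact permutation p at large B", {
  set.seed(12)
  n <- 60
  x <- matrix(runif(n), n, 1, dimnames = list(NULL, "cg1"))
  y <- 0.8 * x[, 1] + rnorm(n, 0, 0.9)
  om <- omnibus_test(x, y, B = 20000, seed = 13)
  # with one CpG the Fisher statistic is monotone in the per-CpG p, so the
  # omnibus p converges to the exact permutation p of the regression t-test
  obs_p <- cpg_association(x[, 1], y)$p_value
  set.seed(99)
  perm_p <- mean(replicate(20000, {
    cpg_association(x[, 1], sample(y))$p_value <= obs_p
  }))
  expect_equal(om$empirical_p, perm_p, tolerance = 0.01)
})

test_that("SNP-adjusted omnibus is unchanged by an orthogonalised dosage", {
  set.seed(14)
  n <- 120
  Bm <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("cg", 1:4)))
  y <- rnorm(n) + 0.3 * Bm[, 2]
  # orthogonalise a dosage in-sample against trait and all CpGs
  d_raw <- rbinom(n, 2, 0.3)
  Q <- qr.Q(qr(cbind(1, y, Bm)))
  d <- d_raw - Q %*% crossprod(Q, d_raw)
  om0 <- omnibus_test(Bm, y, B = 400, seed = 15)
  om1 <- omnibus_adjusted(Bm, y, lead_dosage = as.numeric(d), B = 400,
                          seed = 15)
  # the added covariate is exactly orthogonal, so only the 1-df change in
  # the t reference moves the statistic
  expect_equal(om1$observed_T, om0$observed_T, tolerance = 0.02)
  expect_lt(abs(om1$empirical_p - om0$empirical_p), 0.05)
  expect_true(om1$adjusted_for_snp)
})

test_that("a fully SNP-mediated CpG signal vanishes after adjustment", {
  set.seed(16)
  n <- 400
  d <- rbinom(n, 2, 0.4)
  Bm <- matrix(plogis(0.8 * d + rnorm(n * 3, 0, 0.3)), n, 3,
               dimnames = list(NULL, paste0("cg", 1:3)))
  y <- 0.4 * d + rnorm(n)                # trait depends on dosage only
  om0 <- omnibus_test(Bm, y, B = 400, seed = 17)
  om1 <- omnibus_adjusted(Bm, y, lead_dosage = d, B = 400, seed = 17)
  expect_lt(om0$empirical_p, 0.05)
  expect_gt(om1$empirical_p, 10 * om0$empirical_p)
})

test_that("omnibus input validation: empty regions, tiny B", {
  y <- rnorm(50)
  expect_error(omnibus_test(matrix(numeric(0), 50, 0), y), "no CpGs")
  x <- matrix(runif(50 * 25), 50)
  colnames(x) <- paste0("cg", 1:25)
  expect_error(omnibus_test(x, y, B = 0), "positive")
  expect_warning(omnibus_test(x[, 1:2], y, B = 50, seed = 1), "coarse")
})
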