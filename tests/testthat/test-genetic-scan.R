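test_that("snp association recovers an exact linear effect", {
  set.seed(1)
  d <- rbinom(200, 2, 0.3)
  st <- snp_association(d, 0.5 * d + 1, predictor_id = "v1")
  expect_equal(st$beta, 0.5, tolerance = 1e-10)
  expect_lt(st$p_value, 1e-100)
  expect_error(snp_association(rep(1, 50), rnorm(50)),
               "zero variance predictor")
})

test_that("snp association matches lm() with covariates", {
  set.seed(2)
  n <- 150
  d <- rbinom(n, 2, 0.25) + runif(n, 0, 0.05)
  ev <- data.frame(ev1 = rnorm(n), ev2 = rnorm(n), ev3 = rnorm(n))
  y <- 0.3 * d + 0.2 * ev$ev1 + rnorm(n)
  st <- snp_association(d, y, ev)
  ref <- summary(lm(y ~ d + ev1 + ev2 + ev3, data = ev))$coefficients["d", ]
  expect_equal(st$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(st$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(st$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("p-values are consistent with |beta/se| under the normal approximation", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(100:400, 1)
    d <- rbinom(n, 2, runif(1, 0.1, 0.4))
    y <- rnorm(1, 0, 0.3) * d + rnorm(n)
    st <- snp_association(d, y)
    p_norm <- 2 * pnorm(-abs(st$beta / st$se))
    expect_equal(st$p_value, p_norm, tolerance = 0.1)
  }
})

test_that("vectorised scan equals per-variant association fits", {
  set.seed(3)
  n <- 120
  D <- matrix(rbinom(n * 8, 2, 0.3), n, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  ev <- data.frame(ev1 = rnorm(n), ev2 = rnorm(n), ev3 = rnorm(n))
  y <- 0.25 * D[, 3] + rnorm(n)
  scan <- assoc_scan(D, y, ev)
  for (j in 1:8) {
    single <- snp_association(D[, j], y, ev, predictor_id = colnames(D)[j])
    k <- match(colnames(D)[j], scan$predictor_id)
    expect_equal(scan$beta[k], single$beta, tolerance = 1e-10)
    expect_equal(scan$se[k], single$se, tolerance = 1e-10)
    expect_equal(scan$p_value[k], single$p_value, tolerance = 1e-10)
  }
})

test_that("fixed-effect meta-analysis follows the inverse-variance formulas", {
  a <- assoc_stat("v", 1, 1, 0.32, 100, "A")
  b <- assoc_stat("v", 0, 1, 0.99, 100, "B")
  m <- meta_analyze(a, b)
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, 1 / sqrt(2))
  # identical strata: same beta, se shrinks by sqrt(2)
  m2 <- meta_analyze(a, a)
  expect_equal(m2$beta, a$beta)
  expect_equal(m2$se, a$se / sqrt(2))
  # single stratum passes through
  expect_identical(meta_analyze(a, NULL), a)
  expect_identical(meta_analyze(NULL, b), b)
  expect_error(meta_analyze(a, assoc_stat("w", 0, 1, 0.9, 10)), "mismatch")
  expect_error(meta_analyze(a, b, minor_a = "G", minor_b = "T"), "allele")
})

test_that("meta-analysis of K identical studies shrinks se by exactly sqrt(K)", {
  a <- assoc_stat("v", 0.4, 0.1, 6.3e-5, 500, "A")
  # repeated pooling of identical strata mirrors K independent studies
  st <- a
  for (k in 2:5) {
    st <- meta_analyze(st, a)
    expect_equal(st$se, a$se / sqrt(k), tolerance = 1e-12)
    expect_equal(st$beta, a$beta, tolerance = 1e-12)
  }
})

test_that("suggestive filter applies the strict 1e-5 threshold", {
  s <- data.frame(predictor_id = c("a", "b", "c"),
                  p_value = c(9.9e-6, 1e-5, 2e-9))
  out <- suggestive_filter(s)
  expect_setequal(out$predictor_id, c("a", "c"))
  expect_equal(attr(out, "n_genome_wide"), 1L)
  empty <- suggestive_filter(s[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("ld_r2 is the squared dosage correlation and allele-flip invariant", {
  set.seed(4)
  x <- rbinom(500, 2, 0.3) + runif(500, 0, 0.01)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)
  y <- rbinom(500, 2, 0.3)
  expect_lt(ld_r2(x, y), 0.05)
  expect_error(ld_r2(x, rep(1, 500)), "zero variance")
})

test_that("greedy clumping matches a brute-force oracle on random instances", {
  set.seed(9)
  for (rep in 1:100) {
    n <- 300
    m <- sample(5:50, 1)
    blocks <- sort(sample(1:6, m, replace = TRUE))
    base <- lapply(1:6, function(b) rbinom(n, 2, runif(1, 0.2, 0.4)))
    D <- sapply(seq_len(m), function(j) {
      b <- blocks[j]
      flip <- rbinom(n, 2, 0.12)          # partial correlation within block
      pmin(pmax(base[[b]] + flip - rbinom(n, 2, 0.12), 0), 2)
    })
    colnames(D) <- sprintf("v%02d", seq_len(m))
    stats <- data.frame(predictor_id = colnames(D),
                        p_value = runif(m, 1e-9, 1e-5),
                        chrom = blocks, pos = seq_len(m) * 1000,
                        stringsAsFactors = FALSE)
    clumps <- ld_clump(stats, D, r2_threshold = 0.2)
    got <- lapply(clumps, function(cl) sort(cl$members$variant_id))
    want <- clump_oracle(stats, D, 0.2)
    expect_equal(got, want)
    # lead has the smallest p in its clump
    for (cl in clumps) {
      expect_equal(cl$lead$p_value, min(cl$members$p_value))
    }
  }
})

test_that("clump partition is stable under input shuffling", {
  set.seed(10)
  n <- 250; m <- 20
  D <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, sprintf("v%02d", 1:m)))
  stats <- data.frame(predictor_id = colnames(D),
                      p_value = runif(m, 1e-8, 1e-5),
                      chrom = rep(1:2, each = 10), pos = 1:m * 500,
                      stringsAsFactors = FALSE)
  ref <- ld_clump(stats, D)
  for (i in 1:5) {
    shuf <- stats[sample(nrow(stats)), ]
    expect_equal(ld_clump(shuf, D), ref)
  }
})

test_that("one variant yields one clump; high-LD pair merges under the best lead", {
  set.seed(12)
  d1 <- rbinom(400, 2, 0.3)
  flip <- runif(400) < 0.05
  d2 <- ifelse(flip, 2 - d1, d1)           # r2 well above 0.2
  D <- cbind(a = d1, b = d2)
  s1 <- data.frame(predictor_id = "a", p_value = 1e-7, chrom = 1, pos = 100)
  expect_length(ld_clump(s1, D), 1)
  s2 <- rbind(s1, data.frame(predictor_id = "b", p_value = 1e-6,
                             chrom = 1, pos = 200))
  cl <- ld_clump(s2, D)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$lead$predictor_id, "a")
})

test_that("gene annotation applies the 100-kb window and sign convention", {
  genes <- data.frame(gene_id = c("g_plus", "g_minus", "g_far"),
                      chrom = c(1, 1, 1),
                      start = c(1000, 500000, 2000000),
                      end = c(2000, 501000, 2001000),
                      strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  # SNP inside the span: distance 0
  ann <- annotate_genes(1, 1500, genes)
  expect_equal(ann$signed_distance_kb[ann$gene_id == "g_plus"], 0)
  # + strand gene [1000, 2000], SNP at 500: 5' of the start, +0.5 kb
  ann <- annotate_genes(1, 500, genes)
  expect_equal(ann$signed_distance_kb[ann$gene_id == "g_plus"], 0.5)
  # SNP downstream of the 3' end of a + strand gene: negative
  ann <- annotate_genes(1, 77320, genes)
  expect_equal(ann$signed_distance_kb[ann$gene_id == "g_plus"], -75.32)
  # - strand gene: 5' lies at the higher coordinate
  ann <- annotate_genes(1, 501500, genes)
  expect_equal(ann$signed_distance_kb[ann$gene_id == "g_minus"], 0.5)
  ann <- annotate_genes(1, 499000, genes)
  expect_equal(ann$signed_distance_kb[ann$gene_id == "g_minus"], -1)
  # 150 kb away from every boundary: excluded
  ann <- annotate_genes(1, 152000, genes)
  expect_false("g_plus" %in% ann$gene_id)
  # boundary: exactly 100,000 bp is retained (<=), 100,001 is not
  expect_true("g_plus" %in% annotate_genes(1, 102000, genes)$gene_id)
  expect_false("g_plus" %in% annotate_genes(1, 102001, genes)$gene_id)
})

test_that("expression triage requires non-zero values in >80% of subjects", {
  vals <- matrix(0, 100, 2, dimnames = list(NULL, c("gA", "gB")))
  vals[1:85, 1] <- runif(85, 1, 5)
  vals[1:80, 2] <- runif(80, 1, 5)
  expect_true(expression_triage("gA", vals)$expressed_flag)
  expect_false(expression_triage("gB", vals)$expressed_flag)   # exactly 80%
  expect_false(expression_triage("gB", vals * 0)$expressed_flag)
  expect_error(expression_triage("gC", vals), "absent")
})

test_that("cis-eQTL recovers a planted regulatory effect within 3 se", {
  set.seed(15)
  n <- 500
  d <- rbinom(n, 2, 0.4)
  tech <- data.frame(rin = rnorm(n, 7, 1), reads = rnorm(n, 27, 1),
                     pmi = rgamma(n, 4, 1), ribo = rnorm(n, 22, 1))
  expr <- 3.5 - 0.22 * d + 0.1 * tech$rin + rnorm(n, 0, 0.6)
  res <- cis_eqtl(d, cbind(gene1 = expr), tech)
  expect_equal(res$beta[1], -0.22, tolerance = 3 * res$se[1])
  # constant expression flagged as degenerate, not silently tested
  res2 <- cis_eqtl(d, cbind(gene1 = expr, flat = rep(2, n)), tech)
  expect_equal(attr(res2, "degenerate"), "flat")
  expect_true(is.na(res2$p_value[res2$predictor_id == "flat"]))
})

test_that("null eQTL p-values are uniform (KS over replicates)", {
  set.seed(16)
  p <- replicate(500, {
    d <- rbinom(120, 2, 0.3)
    cis_eqtl(d, cbind(g = rnorm(120)))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("a planted suggestive locus is recovered across seeds", {
  hits <- sapply(1:5, function(s) {
    co <- simulate_cohort(sim_config(
      n_subjects = 2000, n_variants = 30, n_cpgs_per_region = 4,
      maf_range = c(0.2, 0.4),
      planted_effects = list(list(target_id = "var0001", effect_size = 0.3,
                                  channel = "snp")),
      seed = 100 + s))
    fit <- compute_residual_cognition(co$subjects, co$pathologies)
    trait <- fit$residuals
    scan <- assoc_scan(co$genotypes$dosages[names(trait), ], trait,
                       fit$subjects[, c("ev1", "ev2", "ev3")])
    scan <- merge(scan, co$genotypes$variant_map[, c("variant_id", "chrom", "pos")],
                  by.x = "predictor_id", by.y = "variant_id")
    sugg <- suggestive_filter(scan)
    if (nrow(sugg) == 0) return(FALSE)
    cl <- ld_clump(sugg, co$genotypes$dosages, co$genotypes$variant_map)
    any(sapply(cl, function(x) "var0001" %in% x$members$variant_id))
  })
  expect_gte(sum(hits), 4)
})
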