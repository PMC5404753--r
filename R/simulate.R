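# Seeded synthetic multi-omic cohort generator. Emulates the statistical
# structure the pipeline assumes -- ~1,000 deceased subjects on two
# genotyping platforms, block-LD dosages, ten neuropathology indices, a
# 17-test cognition battery with pathology-driven decline, CpG beta values
# with technical covariates, adjusted-FPKM expression -- with planted
# SNP/CpG/RNA effects on residual cognition recorded in a truth ledger.

#' Simulation configuration
#'
#' Validated parameter bundle for [simulate_cohort()]. Defaults emulate the
#' motivating cohort: 979 subjects split across two genotyping platforms
#' (~88% on platform A), pathology and demographics explaining ~41% of the
#' variance in last global cognition, dosages in blocks of correlated
#' variants with MAF well above the 0.01 analysis floor.
#'
#' @param n_subjects Number of subjects.
#' @param n_variants Number of variants.
#' @param n_cpgs_per_region CpGs simulated inside each gene's +/-100 kb
#'   window.
#' @param n_genes Number of genes (each on its own chromosome).
#' @param maf_range Minor-allele-frequency range, within (0.01, 0.5).
#' @param ld_block_size Variants per LD block.
#' @param ld_decay Latent adjacent-variant correlation in \[0, 1). Dosage
#'   correlations are attenuated relative to this latent value by the
#'   binary thresholding of the Gaussian copula.
#' @param platform_split Fraction of subjects on platform A.
#' @param planted_effects List of planted effects, each a list with
#'   `target_id`, `effect_size` (residual-cognition SD units; per minor
#'   allele for `snp`, per SD of the feature for `cpg`/`rna`), and
#'   `channel` in `snp`/`cpg`/`rna`.
#' @param pathology_effect_fraction Target fraction of cognition variance
#'   explained by pathology + demographics (default 0.41).
#' @param noise_sd SD of the subject-level cognition noise (the
#'   residual-cognition scale unit; default 1).
#' @param methylation_missing_rate Missing-completely-at-random rate for
#'   beta values (default 0.01).
#' @param fractional_dosage_fraction Fraction of variants given fractional
#'   (imputation-like) dosage noise, truncated N(0, 0.05) within \[0, 2\].
#' @param tdp43_snp Optional variant id whose dosage shifts the TDP-43
#'   stage/severity latent (a "TMEM106B-like" link).
#' @param tdp43_snp_effect Latent-scale effect of `tdp43_snp` (default
#'   -0.5, protective).
#' @param seed Integer seed; fully determines the generated bundle.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 979,
                       n_variants = 90,
                       n_cpgs_per_region = 40,
                       n_genes = 6,
                       maf_range = c(0.05, 0.45),
                       ld_block_size = 10,
                       ld_decay = 0.8,
                       platform_split = 859 / 979,
                       planted_effects = list(),
                       pathology_effect_fraction = 0.41,
                       noise_sd = 1,
                       methylation_missing_rate = 0.01,
                       fractional_dosage_fraction = 0.3,
                       tdp43_snp = NULL,
                       tdp43_snp_effect = -0.5,
                       seed = 1L) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid sim_config field '", field, "': ", why)
  }
  chk(n_subjects >= 20, "n_subjects", "must be >= 20")
  chk(n_variants >= 1, "n_variants", "must be >= 1")
  chk(n_cpgs_per_region >= 1, "n_cpgs_per_region", "must be >= 1")
  chk(n_genes >= 1 && n_genes <= 22, "n_genes", "must be in 1..22")
  chk(length(maf_range) == 2 && maf_range[1] <= maf_range[2] &&
        maf_range[1] > 0.01 && maf_range[2] < 0.5,
      "maf_range", "must be an increasing pair within (0.01, 0.5)")
  chk(ld_block_size >= 1, "ld_block_size", "must be >= 1")
  chk(ld_decay >= 0 && ld_decay < 1, "ld_decay", "must lie in [0, 1)")
  chk(platform_split >= 0 && platform_split <= 1, "platform_split",
      "must lie in [0, 1]")
  chk(pathology_effect_fraction >= 0 && pathology_effect_fraction <= 0.95,
      "pathology_effect_fraction", "must lie in [0, 0.95]")
  chk(noise_sd > 0, "noise_sd", "must be positive")
  chk(methylation_missing_rate >= 0 && methylation_missing_rate < 1,
      "methylation_missing_rate", "must lie in [0, 1)")
  chk(fractional_dosage_fraction >= 0 && fractional_dosage_fraction <= 1,
      "fractional_dosage_fraction", "must lie in [0, 1]")
  chk(n_subjects >= 2 * length(planted_effects), "planted_effects",
      "n_subjects must be at least twice the number of planted effects")
  for (pe in planted_effects) {
    chk(all(c("target_id", "effect_size", "channel") %in% names(pe)),
        "planted_effects", "each entry needs target_id, effect_size, channel")
    chk(pe$channel %in% c("snp", "cpg", "rna"), "planted_effects",
        paste0("unknown channel '", pe$channel, "'"))
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_variants = as.integer(n_variants),
    n_cpgs_per_region = as.integer(n_cpgs_per_region),
    n_genes = as.integer(n_genes),
    maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size),
    ld_decay = ld_decay,
    platform_split = platform_split,
    planted_effects = planted_effects,
    pathology_effect_fraction = pathology_effect_fraction,
    noise_sd = noise_sd,
    methylation_missing_rate = methylation_missing_rate,
    fractional_dosage_fraction = fractional_dosage_fraction,
    tdp43_snp = tdp43_snp,
    tdp43_snp_effect = tdp43_snp_effect,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Dosages for one LD block: two Bernoulli(MAF) haplotype indicators drawn
# through a Gaussian copula with latent AR(1) correlation `decay`, summed.
# `mafs` may be a vector (one frequency per variant in the block).
.ld_block_dosages <- function(n, mafs, decay) {
  m <- length(mafs)
  thr <- qnorm(mafs)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && decay > 0) {
      for (j in 2:m) z[, j] <- decay * z[, j - 1] + sqrt(1 - decay^2) * z[, j]
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  dos
}

#' Simulate one block of LD-correlated dosages
#'
#' Dosages are the sum of two haplotype indicators, each Bernoulli(MAF),
#' drawn through a Gaussian copula whose latent correlation decays
#' geometrically with distance in variants (AR(1) with parameter `decay`).
#' Realised dosage correlations are attenuated relative to `decay` by the
#' thresholding of the latent normals.
#'
#' @param n_subjects Number of subjects.
#' @param block Number of variants in the block.
#' @param maf Minor allele frequency (scalar, shared across the block).
#' @param decay Latent adjacent-variant correlation in \[0, 1).
#' @param seed Optional seed.
#' @return Integer dosage matrix (subjects x block) with values in 0..2.
#' @export
simulate_ld_block <- function(n_subjects, block, maf, decay, seed = NULL) {
  if (decay < 0 || decay >= 1) stop("decay must lie in [0, 1)")
  stopifnot(block >= 1, maf > 0, maf < 1)
  if (!is.null(seed)) set.seed(seed)
  .ld_block_dosages(n_subjects, rep(maf, block), decay)
}

# Ordinal draw from a latent score and cumulative probabilities.
.latent_ordinal <- function(latent, cum_probs) {
  cuts <- qnorm(cum_probs) * sd(latent) + mean(latent)
  findInterval(latent, cuts)
}

#' Generate a seeded synthetic multi-omic cohort
#'
#' Draws a full cohort bundle with known ground truth: demographics and
#' ancestry covariates, block-LD genotype dosages on two platforms, ten
#' neuropathology indices (three square-root count composites from
#' gamma-distributed regional counts, an averaged CAA grade, two four-level
#' ordinal vascular scores, four binary lesions, plus optional TDP-43 stage
#' and severity), a 17-test cognition battery whose latent trait carries
#' the pathology burden and every planted effect, CpG beta values with
#' batch/bisulfite structure and MCAR gaps, and adjusted-FPKM expression
#' with four technical covariates. Cognition proximate to death is a linear
#' combination of demographics, pathologies, the planted-channel features,
#' and Gaussian noise, calibrated so pathology + demographics explain the
#' configured fraction of its variance.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `residcog_cohort` with components `subjects`,
#'   `pathologies`, `genotypes`, `cognition`, `methylation`, `expression`,
#'   `genes`, and `truth` (the ledger of planted effects and realised
#'   variance fractions).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  subject_id <- sprintf("S%05d", seq_len(n))

  ## demographics and ancestry covariates
  age_at_death <- rnorm(n, 88.8, 6.4)
  sex <- rbinom(n, 1, 0.644)                  # 1 = female
  education <- pmax(6, round(rnorm(n, 16.4, 3.6)))
  cohort <- ifelse(runif(n) < 0.503, "ROS-like", "MAP-like")
  ev1 <- rnorm(n); ev2 <- rnorm(n); ev3 <- rnorm(n)
  platform <- rep("B", n)
  platform[sample.int(n, round(config$platform_split * n))] <- "A"

  ## gene annotation: one gene per chromosome, 50-kb span
  genes <- data.frame(
    gene_id = sprintf("GENE%02d", seq_len(config$n_genes)),
    chrom = seq_len(config$n_genes),
    start = 1000000L,
    end = 1050000L,
    strand = rep(c("+", "-"), length.out = config$n_genes),
    stringsAsFactors = FALSE)

  ## genotypes: LD blocks, the first n_genes blocks inside gene spans,
  ## later blocks on the same chromosomes but megabases away
  n_blocks <- ceiling(config$n_variants / config$ld_block_size)
  dosages <- matrix(0, n, 0)
  vm <- list()
  vidx <- 0L
  for (b in seq_len(n_blocks)) {
    m <- min(config$ld_block_size, config$n_variants - ncol(dosages))
    g <- ((b - 1L) %% config$n_genes) + 1L
    base_pos <- if (b <= config$n_genes) {
      genes$start[g] + 2000L
    } else {
      genes$start[g] + 8000000L + (b %/% config$n_genes) * 1000000L
    }
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
    blk <- .ld_block_dosages(n, mafs, config$ld_decay)
    # enforce the MAF >= 0.01 analysis floor on the empirical frequencies
    for (j in seq_len(m)) {
      tries <- 0L
      while ((mean(blk[, j]) / 2 < 0.01 || mean(blk[, j]) / 2 > 0.99) &&
             tries < 50L) {
        blk[, j] <- rbinom(n, 2, mafs[j])
        tries <- tries + 1L
      }
    }
    ids <- sprintf("var%04d", vidx + seq_len(m))
    vm[[b]] <- data.frame(
      variant_id = ids, chrom = genes$chrom[g],
      pos = base_pos + (seq_len(m) - 1L) * 1000L,
      major = "A", minor = "G",
      maf = colMeans(blk) / 2, block = b, stringsAsFactors = FALSE)
    colnames(blk) <- ids
    dosages <- cbind(dosages, blk)
    vidx <- vidx + m
  }
  variant_map <- do.call(rbind, vm)
  # fractional imputation-like dosages for a configurable variant subset
  n_frac <- round(config$fractional_dosage_fraction * ncol(dosages))
  if (n_frac > 0) {
    frac_cols <- sample.int(ncol(dosages), n_frac)
    noise <- matrix(rnorm(n * n_frac, 0, 0.05), n, n_frac)
    dosages[, frac_cols] <- pmin(pmax(dosages[, frac_cols] + noise, 0), 2)
  }
  rownames(dosages) <- subject_id
  variant_map$maf <- colMeans(dosages) / 2

  ## pathologies from one latent burden factor
  burden <- rnorm(n)
  count_composite <- function(w_burden, shape, scale) {
    type_latent <- w_burden * burden + sqrt(1 - w_burden^2) * rnorm(n)
    u <- pnorm(0.75 * matrix(type_latent, n, 5) +
                 0.66 * matrix(rnorm(n * 5), n, 5))
    counts <- qgamma(pmin(pmax(u, 1e-12), 1 - 1e-12), shape, scale = scale)
    scaled <- scale_regional_counts(counts)
    apply(scaled, 1, composite_pathology_score)
  }
  tangles <- count_composite(0.75, 1.2, 3)
  neuritic_plaques <- count_composite(0.70, 1.1, 2.5)
  diffuse_plaques <- count_composite(0.60, 1.0, 3)
  caa_latent <- 0.5 * burden + sqrt(0.75) * rnorm(n)
  caa_grades <- matrix(0L, n, 4)
  for (r in 1:4) {
    caa_grades[, r] <- .latent_ordinal(0.8 * caa_latent + 0.6 * rnorm(n),
                                       c(0.40, 0.62, 0.82, 0.93))
  }
  caa <- apply(caa_grades, 1, caa_score)
  athero_latent <- 0.45 * burden + sqrt(1 - 0.45^2) * rnorm(n)
  atherosclerosis <- .latent_ordinal(athero_latent, c(0.30, 0.62, 0.87))
  arterio_latent <- 0.40 * burden + sqrt(1 - 0.40^2) * rnorm(n)
  arteriolosclerosis <- .latent_ordinal(arterio_latent, c(0.32, 0.65, 0.88))
  macroinfarcts <- rbinom(n, 1, plogis(-0.75 + 0.7 * burden))
  microinfarcts <- rbinom(n, 1, plogis(-1.0 + 0.6 * burden))
  lewy_bodies <- rbinom(n, 1, plogis(-1.3 + 0.5 * burden))
  hippocampal_sclerosis <- rbinom(n, 1, plogis(-2.4 + 0.8 * burden))

  ## TDP-43 stage/severity, optionally linked to a designated variant
  tdp_latent <- 0.45 * burden + rnorm(n)
  if (!is.null(config$tdp43_snp)) {
    d <- dosages[, config$tdp43_snp]
    tdp_latent <- tdp_latent +
      config$tdp43_snp_effect * as.numeric(scale(d))
  }
  tdp43_stage <- .latent_ordinal(tdp_latent, c(0.47, 0.67, 0.84))
  tdp43_severity <- .latent_ordinal(tdp_latent + 0.3 * rnorm(n),
                                    c(0.45, 0.60, 0.72, 0.84, 0.94))
  tdp43_stage[runif(n) < 0.156] <- NA        # measured in a subset only
  tdp43_severity[runif(n) < 0.17] <- NA

  ## methylation: n_cpgs_per_region CpGs inside each gene's 100-kb window
  batch <- sample(c("b1", "b2"), n, replace = TRUE)
  bisulfite <- rnorm(n, 98.5, 0.5)
  cpg_rows <- list()
  meth_latent <- matrix(0, n, 0)
  for (g in seq_len(config$n_genes)) {
    m <- config$n_cpgs_per_region
    pos <- sort(sample(seq(genes$start[g] - 80000L, genes$end[g] + 80000L),
                       m))
    ids <- sprintf("cg%02d_%03d", g, seq_len(m))
    cpg_rows[[g]] <- data.frame(cpg_id = ids, chrom = genes$chrom[g],
                                pos = pos, gene_id = genes$gene_id[g],
                                stringsAsFactors = FALSE)
    region_factor <- rnorm(n)
    lat <- 0.35 * matrix(region_factor, n, m) +
      0.85 * matrix(rnorm(n * m), n, m) +
      0.25 * (batch == "b2") +
      0.15 * matrix(bisulfite - mean(bisulfite), n, m)
    colnames(lat) <- ids
    meth_latent <- cbind(meth_latent, lat)
  }
  cpg_map <- do.call(rbind, cpg_rows)
  cpg_mu <- rnorm(ncol(meth_latent), 0, 1.5)
  betas_complete <- plogis(sweep(meth_latent, 2, cpg_mu, "+"))
  rownames(betas_complete) <- subject_id

  ## expression: adjusted-FPKM-like values with four technical covariates
  rin <- rnorm(n, 7, 1)
  log2_aligned_reads <- rnorm(n, 27, 0.8)
  pmi_hours <- rgamma(n, shape = 4, scale = 1.8)
  ribosomal_bases <- rnorm(n, 22, 1)       # log2 scale
  gene_mu <- runif(config$n_genes, 0.5, 6.5)
  expr_noise <- matrix(rnorm(n * config$n_genes, 0, 0.7), n)
  log2_expr <- sweep(0.30 * (rin - 7) + 0.10 * (log2_aligned_reads - 27) -
                       0.02 * (pmi_hours - mean(pmi_hours)) +
                       0.05 * (ribosomal_bases - 22) + expr_noise,
                     2, gene_mu, "+")
  colnames(log2_expr) <- genes$gene_id
  expr_values <- 2^log2_expr
  rownames(expr_values) <- subject_id

  ## cognition: pathology + demographics + planted channels + noise
  pd <- -(0.45 * tangles + 0.25 * neuritic_plaques + 0.10 * diffuse_plaques +
            0.10 * caa + 0.10 * atherosclerosis + 0.10 * arteriolosclerosis +
            0.15 * macroinfarcts + 0.08 * microinfarcts +
            0.20 * lewy_bodies + 0.30 * hippocampal_sclerosis) -
    0.02 * (age_at_death - 88.8) + 0.012 * (education - 16.4) +
    0.05 * sex + 0.04 * (cohort == "ROS-like") +
    0.02 * (ev1 + ev2 + ev3)
  planted_part <- numeric(n)
  truth_effects <- list()
  for (pe in config$planted_effects) {
    x <- switch(pe$channel,
      snp = {
        if (!pe$target_id %in% colnames(dosages))
          stop("planted snp target not simulated: ", pe$target_id)
        dosages[, pe$target_id]
      },
      cpg = {
        if (!pe$target_id %in% colnames(meth_latent))
          stop("planted cpg target not simulated: ", pe$target_id)
        as.numeric(scale(meth_latent[, pe$target_id]))
      },
      rna = {
        if (!pe$target_id %in% colnames(log2_expr))
          stop("planted rna target not simulated: ", pe$target_id)
        as.numeric(scale(log2_expr[, pe$target_id]))
      })
    planted_part <- planted_part + pe$effect_size * x
    truth_effects[[length(truth_effects) + 1L]] <- list(
      target_id = pe$target_id, channel = pe$channel,
      effect_size = pe$effect_size)
  }
  eps <- rnorm(n, 0, config$noise_sd)
  resid_part <- planted_part + eps
  f <- config$pathology_effect_fraction
  path_component <- if (f > 0) {
    as.numeric(scale(pd)) * sqrt(f / (1 - f)) * sd(resid_part)
  } else {
    numeric(n)
  }
  y_latent <- path_component + resid_part

  ## 17-test battery; baseline z-scoring sets the trait scale
  n_tests <- 17L
  tau <- 0.5
  a_k <- runif(n_tests, 10, 30)
  b_k <- runif(n_tests, 2, 5)
  y0 <- rnorm(n, 0, sqrt(1 - tau^2))
  base_scores <- sweep(sweep(outer(y0, rep(1, n_tests)) +
                               matrix(rnorm(n * n_tests, 0, tau), n),
                             2, b_k, "*"), 2, a_k, "+")
  baseline_means <- colMeans(base_scores)
  baseline_sds <- apply(base_scores, 2, sd)
  shift <- -0.91 - mean(y_latent)
  last_scores <- sweep(sweep(outer(shift + y_latent, rep(1, n_tests)) +
                               matrix(rnorm(n * n_tests, 0, tau), n),
                             2, b_k, "*"), 2, a_k, "+")
  colnames(base_scores) <- colnames(last_scores) <-
    sprintf("test%02d", seq_len(n_tests))
  last_global <- vapply(seq_len(n), function(i) {
    global_cognition(last_scores[i, ], baseline_means, baseline_sds)
  }, numeric(1))
  baseline_global <- vapply(seq_len(n), function(i) {
    global_cognition(base_scores[i, ], baseline_means, baseline_sds)
  }, numeric(1))

  ## longitudinal visits: linear trajectory from baseline to death
  n_visits <- sample(4:18, n, replace = TRUE)
  visit_times <- lapply(n_visits, function(v) as.numeric((v - 1L):0L))
  visit_global <- lapply(seq_len(n), function(i) {
    tt <- visit_times[[i]]
    span <- max(tt)
    baseline_global[i] +
      (last_global[i] - baseline_global[i]) * (span - tt) / span +
      rnorm(length(tt), 0, 0.15)
  })

  subjects <- data.frame(
    subject_id = subject_id, age_at_death = age_at_death, sex = sex,
    education = education, cohort = cohort, ev1 = ev1, ev2 = ev2, ev3 = ev3,
    baseline_global_cognition = baseline_global,
    last_global_cognition = last_global,
    residual_cognition = NA_real_,
    stringsAsFactors = FALSE)
  pathologies <- data.frame(
    subject_id = subject_id, tangles = tangles,
    neuritic_plaques = neuritic_plaques, diffuse_plaques = diffuse_plaques,
    caa = caa, atherosclerosis = atherosclerosis,
    arteriolosclerosis = arteriolosclerosis, macroinfarcts = macroinfarcts,
    microinfarcts = microinfarcts, lewy_bodies = lewy_bodies,
    hippocampal_sclerosis = hippocampal_sclerosis,
    tdp43_stage = tdp43_stage, tdp43_severity = tdp43_severity,
    stringsAsFactors = FALSE)

  ## methylation missingness (MCAR)
  betas <- betas_complete
  if (config$methylation_missing_rate > 0) {
    mask <- matrix(runif(length(betas)) < config$methylation_missing_rate,
                   nrow(betas))
    betas[mask] <- NA
  }

  ## truth ledger: realised variance bookkeeping via the phenotype module
  fit <- compute_residual_cognition(subjects, pathologies)
  truth <- list(
    seed = config$seed,
    planted_effects = truth_effects,
    target_pathology_fraction = f,
    realized_pathology_fraction = fit$r_squared,
    realized_planted_variance = if (length(truth_effects)) {
      var(planted_part) / var(y_latent)
    } else 0,
    residual_sd = sd(resid_part),
    n_subjects = n)

  structure(list(
    subjects = subjects,
    pathologies = pathologies,
    genotypes = list(dosages = dosages, variant_map = variant_map,
                     platform = setNames(platform, subject_id)),
    cognition = list(test_scores = last_scores,
                     baseline_scores = base_scores,
                     baseline_means = baseline_means,
                     baseline_sds = baseline_sds,
                     global_cognition = last_global,
                     baseline_global = baseline_global,
                     visit_times = visit_times,
                     visit_global = visit_global),
    methylation = list(betas = betas, cpg_map = cpg_map,
                       batch = setNames(batch, subject_id),
                       bisulfite = setNames(bisulfite, subject_id)),
    expression = list(values = expr_values, gene_ids = genes$gene_id,
                      tech = data.frame(subject_id = subject_id, rin = rin,
                                        log2_aligned_reads = log2_aligned_reads,
                                        pmi_hours = pmi_hours,
                                        ribosomal_bases = ribosomal_bases,
                                        stringsAsFactors = FALSE)),
    genes = genes,
    truth = truth,
    config = config
  ), class = "residcog_cohort")
}

#' @export
print.residcog_cohort <- function(x, ...) {
  cat("Synthetic multi-omic cohort\n")
  cat(sprintf("  %d subjects, %d variants (%d LD blocks), %d genes\n",
              nrow(x$subjects), ncol(x$genotypes$dosages),
              max(x$genotypes$variant_map$block), nrow(x$genes)))
  cat(sprintf("  %d CpGs, %d planted effect(s), seed %d\n",
              ncol(x$methylation$betas), length(x$truth$planted_effects),
              x$truth$seed))
  cat(sprintf("  pathology+demographics variance fraction: target %.2f, realised %.3f\n",
              x$truth$target_pathology_fraction,
              x$truth$realized_pathology_fraction))
  invisible(x)
}
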