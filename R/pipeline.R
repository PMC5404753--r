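# Orchestrator: wires the stages into the full multistep procedure and
# emits a convergence report naming genes with coincident genetic,
# epigenetic, and transcriptomic evidence.

#' Default pipeline thresholds
#'
#' The predefined decision thresholds of the multistep procedure:
#' suggestive GWAS p < 1e-5 (with 5e-8 as the genome-wide reference),
#' clumping at r-squared > 0.2, candidate genes within 100 kb of the lead
#' SNP, expression triage at > 80% of subjects with non-zero values,
#' 10,000 permutations for the omnibus test, omnibus FDR < 0.05, and raw
#' p < 0.05 for the RNA stage (mirroring the asymmetry of FDR for the
#' methylation stage and raw p for expression).
#'
#' @return Named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(p_suggestive = 1e-5, p_genome_wide = 5e-8, r2_clump = 0.2,
       window_kb = 100, expr_fraction = 0.8, B = 10000, fdr = 0.05,
       expr_p = 0.05)
}

# Per-stage seeds derived from one root so stages are independently
# reproducible; kept within the 32-bit integer range.
.derive_seed <- function(root, offset) {
  as.integer((as.numeric(root) * 48271 + offset) %% 2147483629)
}

.check_alignment <- function(cohort) {
  ids <- cohort$subjects$subject_id
  check <- list(
    dosages = rownames(cohort$genotypes$dosages),
    methylation = rownames(cohort$methylation$betas),
    expression = rownames(cohort$expression$values))
  for (nm in names(check)) {
    bad <- union(setdiff(ids, check[[nm]]), setdiff(check[[nm]], ids))
    if (length(bad)) {
      stop("subject-id mismatch between subjects and ", nm, ": ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    }
  }
  invisible(TRUE)
}

#' Convergence verdicts from the three stage outputs
#'
#' Pure function of the per-gene stage statistics: a candidate is
#' `convergent` when its locus is suggestive in the GWAS (true for every
#' candidate by construction), its methylation omnibus FDR is below `fdr`,
#' and its expression association p is below `expr_p`; `partial` when
#' exactly one of the two follow-up stages is significant; `genetic-only`
#' when neither is.
#'
#' @param candidates Data frame with columns `gene_id`, `omnibus_q`,
#'   `expression_p` (NA allowed when a stage was not run).
#' @param fdr Omnibus FDR threshold.
#' @param expr_p Expression p threshold.
#' @return The input with a `verdict` column appended.
#' @export
convergence_verdicts <- function(candidates, fdr = 0.05, expr_p = 0.05) {
  meth_sig <- !is.na(candidates$omnibus_q) & candidates$omnibus_q < fdr
  expr_sig <- !is.na(candidates$expression_p) &
    candidates$expression_p < expr_p
  n_sig <- meth_sig + expr_sig
  candidates$verdict <- c("genetic-only", "partial", "convergent")[n_sig + 1L]
  candidates
}

#' Run the full multistep residual-cognition pipeline
#'
#' Executes, on one cohort bundle: (1) the residual-cognition model and the
#' per-platform additive association scan with fixed-effect meta-analysis,
#' suggestive filtering, greedy LD clumping, candidate-gene annotation
#' within the window, and expression triage; (2) the region-level
#' methylation omnibus test for each retained candidate, plus the
#' SNP-adjusted rerun; (3) the expression association and the lead SNP's
#' cis-eQTL tests; then the sequential adjusted R-squared ledger and the
#' per-gene convergence verdicts. All randomness flows from `seed` through
#' documented per-stage derivations, so a rerun is bit-identical.
#'
#' @param cohort A `residcog_cohort` bundle ([simulate_cohort()] output or
#'   an equivalently shaped list loaded from files).
#' @param thresholds Threshold list as from [pipeline_thresholds()];
#'   entries can be overridden individually.
#' @param seed Root seed for the permutation stages.
#' @param out_dir Optional directory; when given, every intermediate table
#'   and the final report are written as TSV/YAML.
#' @param adjusted_scheme Permutation scheme for the SNP-adjusted omnibus
#'   rerun (`"raw"` or `"freedman-lane"`).
#' @param verbose Emit structured progress messages (stage, n, seed,
#'   runtime) to stderr.
#' @return A list of class `residcog_report`: `residual_fit`, `scan`
#'   (meta-analysed association table), `suggestive`, `clumps`,
#'   `candidates` (per-gene stage statistics with verdicts), `omnibus`
#'   results, `eqtl`, `variance_ledger`, and `thresholds`.
#' @export
run_pipeline <- function(cohort, thresholds = list(), seed = 1L,
                         out_dir = NULL, adjusted_scheme = "raw",
                         verbose = TRUE) {
  th <- utils::modifyList(pipeline_thresholds(), thresholds)
  t0 <- Sys.time()
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[residcog] %-12s %s (%.1fs elapsed)",
                                 stage, paste0(...),
                                 as.numeric(Sys.time() - t0, units = "secs")))
  }
  .check_alignment(cohort)
  ids <- cohort$subjects$subject_id

  ## residual-cognition trait
  fit <- compute_residual_cognition(cohort$subjects, cohort$pathologies)
  trait <- fit$residuals[ids]                # NA for incomplete subjects
  names(trait) <- ids
  say("residual", sprintf("n=%d r2=%.3f", fit$n, fit$r_squared))

  ## stage 1: per-platform scan + meta-analysis
  dosages <- cohort$genotypes$dosages[ids, , drop = FALSE]
  platform <- cohort$genotypes$platform[ids]
  evs <- cohort$subjects[, c("ev1", "ev2", "ev3")]
  per_platform <- list()
  for (pl in sort(unique(platform))) {
    idx <- which(platform == pl & !is.na(trait))
    if (length(idx) < 20L) next
    per_platform[[pl]] <- assoc_scan(dosages[idx, , drop = FALSE],
                                     trait[idx], evs[idx, , drop = FALSE],
                                     platform = pl)
  }
  if (length(per_platform) == 0L) stop("no platform stratum with >= 20 subjects")
  if (length(per_platform) == 1L) {
    meta <- per_platform[[1L]]
    meta$platform <- rep("meta", nrow(meta))
  } else {
    a <- per_platform[[1L]]; b <- per_platform[[2L]]
    common <- intersect(a$predictor_id, b$predictor_id)
    a <- a[match(common, a$predictor_id), ]
    b <- b[match(common, b$predictor_id), ]
    wa <- 1 / a$se^2; wb <- 1 / b$se^2
    beta <- (wa * a$beta + wb * b$beta) / (wa + wb)
    se <- 1 / sqrt(wa + wb)
    p <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
    meta <- data.frame(predictor_id = common, beta = beta, se = se,
                       p_value = p, n = a$n + b$n,
                       platform = rep("meta", length(common)),
                       stringsAsFactors = FALSE)
  }
  vm <- cohort$genotypes$variant_map
  meta <- merge(meta, vm[, c("variant_id", "chrom", "pos", "maf")],
                by.x = "predictor_id", by.y = "variant_id", sort = FALSE)
  say("scan", sprintf("%d variants, %d strata", nrow(meta),
                      length(per_platform)))

  sugg <- suggestive_filter(meta, th$p_suggestive, th$p_genome_wide)
  say("suggestive", sprintf("%d variants below %g", nrow(sugg),
                            th$p_suggestive))

  clumps <- ld_clump(sugg, dosages, vm, th$r2_clump)
  say("clump", sprintf("%d independent loci", length(clumps)))

  ## candidate genes: annotation + expression triage
  candidates <- list()
  for (ci in seq_along(clumps)) {
    cl <- clumps[[ci]]
    ann <- annotate_genes(cl$region_chrom, cl$lead$pos, cohort$genes,
                          th$window_kb)
    for (gi in seq_len(nrow(ann))) {
      tri <- expression_triage(ann$gene_id[gi], cohort$expression,
                               th$expr_fraction)
      candidates[[length(candidates) + 1L]] <- data.frame(
        gene_id = ann$gene_id[gi],
        clump = ci,
        lead_variant = cl$lead$predictor_id,
        lead_p = cl$lead$p_value,
        lead_beta = cl$lead$beta,
        signed_distance_kb = ann$signed_distance_kb[gi],
        fraction_nonzero = tri$fraction_nonzero,
        expressed = tri$expressed_flag,
        stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(candidates)) do.call(rbind, candidates) else
    data.frame(gene_id = character(0), clump = integer(0),
               lead_variant = character(0), lead_p = numeric(0),
               lead_beta = numeric(0), signed_distance_kb = numeric(0),
               fraction_nonzero = numeric(0), expressed = logical(0),
               stringsAsFactors = FALSE)
  say("annotate", sprintf("%d candidate gene(s), %d expressed",
                          nrow(candidates), sum(candidates$expressed)))

  ## stage 2 + 3 for expressed candidates
  tested <- candidates[candidates$expressed, , drop = FALSE]
  omnibus <- list()
  eqtl <- list()
  nc <- nrow(candidates)
  candidates$omnibus_p <- rep(NA_real_, nc)
  candidates$omnibus_q <- rep(NA_real_, nc)
  candidates$omnibus_p_adjusted <- rep(NA_real_, nc)
  candidates$top_cpg <- rep(NA_character_, nc)
  candidates$top_cpg_p <- rep(NA_real_, nc)
  candidates$expression_beta <- rep(NA_real_, nc)
  candidates$expression_p <- rep(NA_real_, nc)
  if (nrow(tested)) {
    ok <- complete.cases(trait)
    betas <- knn_impute(cohort$methylation$betas[ids, , drop = FALSE][ok, ,
                                                                     drop = FALSE])
    tech_meth <- data.frame(batch = factor(cohort$methylation$batch[ids][ok]),
                            bisulfite = cohort$methylation$bisulfite[ids][ok])
    tech_rna <- cohort$expression$tech[match(ids, cohort$expression$tech$subject_id),
                                       c("rin", "log2_aligned_reads",
                                         "pmi_hours", "ribosomal_bases")]
    for (ti in seq_len(nrow(tested))) {
      g <- tested$gene_id[ti]
      row <- which(candidates$gene_id == g &
                     candidates$clump == tested$clump[ti])
      gene <- cohort$genes[cohort$genes$gene_id == g, ]
      cpgs <- region_cpgs(gene, cohort$methylation$cpg_map, th$window_kb)
      lead_d <- dosages[ok, tested$lead_variant[ti]]
      if (length(cpgs)) {
        om <- omnibus_test(betas[, cpgs, drop = FALSE], trait[ok],
                           tech_meth, B = th$B,
                           seed = .derive_seed(seed, 100 + 2 * ti),
                           gene_id = g)
        om_adj <- omnibus_adjusted(betas[, cpgs, drop = FALSE], trait[ok],
                                   tech_meth, lead_dosage = lead_d,
                                   ev_covariates = evs[ok, , drop = FALSE],
                                   B = th$B,
                                   seed = .derive_seed(seed, 101 + 2 * ti),
                                   gene_id = g, scheme = adjusted_scheme)
        omnibus[[g]] <- list(unadjusted = om, adjusted = om_adj)
        candidates$omnibus_p[row] <- om$empirical_p
        candidates$omnibus_p_adjusted[row] <- om_adj$empirical_p
        candidates$top_cpg[row] <- om$top_cpg
        candidates$top_cpg_p[row] <- om$top_cpg_p
      }
      ex <- expression_association(cohort$expression$values[ids, g][ok],
                                   trait[ok], tech_rna[ok, , drop = FALSE],
                                   predictor_id = g)
      candidates$expression_beta[row] <- ex$beta
      candidates$expression_p[row] <- ex$p_value
      ## cis-eQTL of the lead SNP against genes within the window
      win_genes <- annotate_genes(gene$chrom,
                                  sugg$pos[match(tested$lead_variant[ti],
                                                 sugg$predictor_id)],
                                  cohort$genes, th$window_kb)
      if (nrow(win_genes)) {
        eq <- cis_eqtl(lead_d,
                       cohort$expression$values[ids, win_genes$gene_id,
                                                drop = FALSE][ok, ,
                                                              drop = FALSE],
                       tech_rna[ok, , drop = FALSE])
        eq$lead_variant <- tested$lead_variant[ti]
        eqtl[[length(eqtl) + 1L]] <- eq
      }
    }
    ## omnibus FDR across the tested regions; per-CpG FDR across all
    ## CpGs tested in all candidate regions of this run
    has_om <- !is.na(candidates$omnibus_p)
    candidates$omnibus_q[has_om] <- bh_fdr(candidates$omnibus_p[has_om])
    all_cpg_p <- unlist(lapply(omnibus, function(o) o$unadjusted$cpg_p_values))
    if (length(all_cpg_p)) {
      cpg_fdr <- bh_fdr(all_cpg_p)
      names(cpg_fdr) <- names(all_cpg_p)
    } else cpg_fdr <- numeric(0)
    say("omnibus", sprintf("%d region(s) tested, B=%d", sum(has_om), th$B))
  } else {
    cpg_fdr <- numeric(0)
  }
  eqtl <- if (length(eqtl)) do.call(rbind, eqtl) else NULL

  candidates <- convergence_verdicts(candidates, th$fdr, th$expr_p)
  say("verdicts", paste(sprintf("%s=%s", candidates$gene_id,
                                candidates$verdict), collapse = " "))

  ## variance ledger over lead SNPs + top CpGs + RNA of tested genes
  ledger <- NULL
  if (nrow(tested)) {
    feat <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
    leads <- unique(candidates$lead_variant[candidates$expressed])
    for (v in leads) feat[[paste0("snp_", v)]] <- dosages[, v]
    betas_all <- cohort$methylation$betas[ids, , drop = FALSE]
    for (i in which(candidates$expressed)) {
      cg <- candidates$top_cpg[i]
      if (!is.na(cg)) feat[[paste0("cpg_", cg)]] <- betas_all[, cg]
      g <- candidates$gene_id[i]
      feat[[paste0("rna_", g)]] <- cohort$expression$values[ids, g]
    }
    ledger <- sequential_ledger(cohort$subjects, cohort$pathologies, feat)
    say("variance", sprintf("base=%.3f increment=%.3f",
                            ledger$base_adj_r2, ledger$increment))
  }

  report <- structure(list(
    residual_fit = fit,
    scan = meta,
    per_platform = per_platform,
    suggestive = sugg,
    clumps = clumps,
    candidates = candidates,
    omnibus = omnibus,
    cpg_fdr = cpg_fdr,
    eqtl = eqtl,
    variance_ledger = ledger,
    thresholds = th,
    seed = seed
  ), class = "residcog_report")

  if (!is.null(out_dir)) .write_report(report, out_dir)
  say("done", sprintf("%d convergent gene(s)",
                      sum(candidates$verdict == "convergent")))
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_tsv(report$scan, p("association_meta.tsv"))
  .write_tsv(report$suggestive, p("suggestive.tsv"))
  if (length(report$clumps)) {
    cl <- do.call(rbind, lapply(seq_along(report$clumps), function(i) {
      m <- report$clumps[[i]]$members
      m$clump <- i
      m$lead <- report$clumps[[i]]$lead$predictor_id
      m$chrom <- report$clumps[[i]]$region_chrom
      m
    }))
    .write_tsv(cl, p("clumps.tsv"))
  }
  .write_tsv(report$candidates, p("report.tsv"))
  if (!is.null(report$eqtl)) .write_tsv(report$eqtl, p("eqtl.tsv"))
  if (!is.null(report$variance_ledger)) {
    yaml::write_yaml(unclass(report$variance_ledger)[
      c("n", "base_adj_r2", "full_adj_r2", "increment", "unexplained")],
      p("variance_ledger.yaml"))
  }
  invisible(dir)
}

#' @export
print.residcog_report <- function(x, ...) {
  cat("Multistep residual-cognition convergence report\n")
  cat(sprintf("  residual model: n=%d, R2=%.3f\n",
              x$residual_fit$n, x$residual_fit$r_squared))
  cat(sprintf("  scan: %d variants, %d suggestive, %d independent loci\n",
              nrow(x$scan), nrow(x$suggestive), length(x$clumps)))
  if (nrow(x$candidates)) {
    cat("  candidates:\n")
    for (i in seq_len(nrow(x$candidates))) {
      cc <- x$candidates[i, ]
      cat(sprintf("    %s [lead %s, p=%.2g] omnibus q=%s expr p=%s -> %s\n",
                  cc$gene_id, cc$lead_variant, cc$lead_p,
                  format(signif(cc$omnibus_q, 3)),
                  format(signif(cc$expression_p, 3)), cc$verdict))
    }
  } else cat("  no candidate genes\n")
  if (!is.null(x$variance_ledger)) {
    cat(sprintf("  variance: base %.1f%%, increment %.1f%%, unexplained %.1f%%\n",
                100 * x$variance_ledger$base_adj_r2,
                100 * x$variance_ledger$increment,
                100 * x$variance_ledger$unexplained))
  }
  invisible(x)
}
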