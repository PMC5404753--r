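# Shared fixtures, built in code at test time.

# Minimal subject + pathology tables with a configurable cognition rule.
make_pheno_tables <- function(n = 200, seed = 1,
                              cognition = function(X) rnorm(nrow(X))) {
  set.seed(seed)
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age_at_death = rnorm(n, 88, 6),
    sex = rbinom(n, 1, 0.64),
    education = round(rnorm(n, 16, 3)),
    cohort = sample(c("ROS-like", "MAP-like"), n, replace = TRUE),
    ev1 = rnorm(n), ev2 = rnorm(n), ev3 = rnorm(n),
    stringsAsFactors = FALSE)
  pathologies <- data.frame(
    subject_id = subjects$subject_id,
    tangles = sqrt(rgamma(n, 2, 1)),
    neuritic_plaques = sqrt(rgamma(n, 2, 1)),
    diffuse_plaques = sqrt(rgamma(n, 2, 1)),
    caa = runif(n, 0, 4),
    atherosclerosis = sample(0:3, n, replace = TRUE),
    arteriolosclerosis = sample(0:3, n, replace = TRUE),
    macroinfarcts = rbinom(n, 1, 0.3),
    microinfarcts = rbinom(n, 1, 0.25),
    lewy_bodies = rbinom(n, 1, 0.2),
    hippocampal_sclerosis = rbinom(n, 1, 0.1),
    stringsAsFactors = FALSE)
  X <- cbind(subjects[, c("age_at_death", "sex", "education")],
             cohort_num = as.numeric(subjects$cohort == "ROS-like"),
             pathologies[, -1])
  subjects$last_global_cognition <- cognition(as.matrix(X))
  list(subjects = subjects, pathologies = pathologies, X = as.matrix(X))
}

# Independently coded greedy clumping oracle, written directly from the
# textual rule: sort by p (ties by chrom, pos); best unassigned variant
# seeds a clump and absorbs unassigned same-chromosome variants with
# squared dosage correlation above the threshold.
clump_oracle <- function(stats, dosages, r2 = 0.2) {
  ord <- order(stats$p_value, stats$chrom, stats$pos)
  s <- stats[ord, ]
  left <- seq_len(nrow(s))
  out <- list()
  while (length(left)) {
    lead <- left[1]
    left <- left[-1]
    take <- integer(0)
    for (j in left) {
      if (s$chrom[j] == s$chrom[lead] &&
          cor(dosages[, s$predictor_id[lead]],
              dosages[, s$predictor_id[j]])^2 > r2) {
        take <- c(take, j)
      }
    }
    out[[length(out) + 1L]] <- sort(c(s$predictor_id[lead],
                                      s$predictor_id[take]))
    left <- setdiff(left, take)
  }
  out
}

# Step-up BH oracle from the formula: q_i = min over j >= rank(i) of
# m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
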