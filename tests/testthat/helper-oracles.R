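# Independent oracles and small fixture builders shared across test files.

# AUC by exhaustive enumeration of positive-negative pairs:
# concordant pairs count 1, ties count 0.5.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided p-value of the Wilcoxon signed-rank statistic by
# exhaustive sign-flip enumeration (valid for tie-free, zero-free
# differences).
signrank_perm_p <- function(before, after) {
  d <- before - after
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Build a cohort data frame from per-timepoint vectors.
make_cohort <- function(sbp_b, dbp_b, meds_b, sbp_d, dbp_d, meds_d,
                        ids = sprintf("P%03d", seq_along(sbp_b))) {
  data.frame(patient_id = ids,
             sbp_baseline = sbp_b, dbp_baseline = dbp_b,
             meds_baseline = meds_b,
             sbp_discharge = sbp_d, dbp_discharge = dbp_d,
             meds_discharge = meds_d,
             stringsAsFactors = FALSE)
}

# Random valid cohort for property tests.
random_cohort <- function(n, seed) {
  set.seed(seed)
  sbp_b <- runif(n, 130, 220)
  sbp_d <- runif(n, 110, 200)
  make_cohort(sbp_b = sbp_b,
              dbp_b = sbp_b - runif(n, 30, 90),
              meds_b = sample(0:6, n, replace = TRUE),
              sbp_d = sbp_d,
              dbp_d = sbp_d - runif(n, 30, 80),
              meds_d = sample(0:6, n, replace = TRUE))
}

# The four published group-mean profiles, medication counts rounded to
# integers, as single-patient cohorts.
group_mean_profiles <- function() {
  make_cohort(
    sbp_b = c(199.1, 193.1, 160.1, 167.9),
    dbp_b = c(96.5, 95.8, 81.3, 81.5),
    meds_b = c(3L, 3L, 4L, 3L),
    sbp_d = c(133.7, 139.2, 155.6, 156.7),
    dbp_d = c(78.5, 73.5, 80.2, 76.3),
    meds_d = c(2L, 3L, 1L, 3L)
  )
}
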