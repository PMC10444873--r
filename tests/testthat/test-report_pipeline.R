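test_that("paired comparison gates on normality and reports which test fired", {
  set.seed(1)
  before <- rnorm(30, mean = 20, sd = 1)
  after <- rnorm(30, mean = 10, sd = 1)
  res <- paired_comparison(before, after)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$test_name, "paired t-test")
  # strongly skewed differences fall through to the rank branch
  set.seed(2)
  skewed <- exp(rnorm(40, sd = 1.5))
  res2 <- paired_comparison(skewed + skewed^2, skewed)
  expect_equal(res2$test_name, "Wilcoxon signed-rank test")
})

test_that("degenerate and undersized comparisons are refused", {
  x <- c(150, 160, 170)
  expect_error(paired_comparison(x, x), "zero variance")
  expect_error(paired_comparison(x, x - 5), "zero variance")
  expect_error(paired_comparison(c(1, 2), c(3, 4)), "insufficient")
  expect_error(paired_comparison(1:4, 1:3), "equal-length")
})

test_that("the rank branch matches an exhaustive sign-flip permutation oracle", {
  force_rank <- test_policy(normality_alpha = 0.999)
  set.seed(33)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    before <- round(rnorm(n, 10, 4), 3)
    after <- round(before - rnorm(n, 1, 2), 7)  # tie-free, zero-free diffs
    res <- paired_comparison(before, after, force_rank)
    if (res$test_name == "Wilcoxon signed-rank test") {
      expect_equal(res$p_value, signrank_perm_p(before, after))
    }
  }
})

test_that("the unpaired branch selects Welch or Mann-Whitney by normality", {
  set.seed(4)
  a <- rnorm(30, 10); b <- rnorm(25, 12)
  res <- paired_comparison(a, b, test_policy(paired = FALSE))
  expect_equal(res$test_name, "Welch two-sample t-test")
  res2 <- paired_comparison(exp(rnorm(30, sd = 2)), exp(rnorm(25, sd = 2)),
                            test_policy(paired = FALSE))
  expect_equal(res2$test_name, "Mann-Whitney U test")
})

test_that("the whole-cohort summary table reproduces the pooled contrasts", {
  coh <- generate_cohort(seed = 1)
  st <- summary_table(coh)
  expect_equal(st$variable, c("sbp", "dbp", "meds", "hti"))
  expect_lt(abs(st$baseline_center[st$variable == "sbp"] - 185.3), 5)
  expect_true(all(st$baseline_center > st$discharge_center))
  expect_true(all(st$p_value < 1e-4))
})

test_that("all four variables fall with p < 0.0001 in at least 95% of seeds", {
  ok <- vapply(1:40, function(s) {
    st <- summary_table(generate_cohort(seed = s))
    all(st$baseline_center > st$discharge_center) && all(st$p_value < 1e-4)
  }, NA)
  expect_gte(mean(ok), 0.95)
})

test_that("tiny or constant cohorts keep their centers but report no p-values", {
  one <- make_cohort(180, 95, 3, 150, 80, 2)
  st <- summary_table(one)
  expect_equal(st$baseline_center[st$variable == "sbp"], 180)
  expect_true(all(is.na(st$p_value)))
  expect_match(st$test_name[1], "insufficient")
  const <- make_cohort(rep(180, 5), rep(95, 5), rep(3, 5),
                       rep(150, 5), rep(80, 5), rep(2, 5))
  stc <- summary_table(const)
  expect_true(all(stc$baseline_dispersion == 0))
  expect_true(all(is.na(stc$p_value)))
})

test_that("per-group summaries use medians for the index and means for raw variables", {
  coh <- generate_cohort(seed = 1)
  gs <- group_summary(coh)
  expect_equal(nrow(gs), 16L)
  expect_true(all(gs$center_policy[gs$variable == "hti"] == "median"))
  expect_true(all(gs$center_policy[gs$variable != "hti"] == "mean"))
  # a cohort entirely of group-1 patients leaves three empty group blocks
  grp <- classify_group(coh)
  only1 <- coh[grp == 1, ]
  g1 <- group_summary(only1)
  expect_equal(unique(g1$n[g1$group != 1]), 0L)
  expect_true(all(is.na(g1$p_value[g1$group != 1])))
})

test_that("group 1-3 index changes are significant and group 4's is not, in most seeds", {
  p <- vapply(1:30, function(s) {
    gs <- group_summary(generate_cohort(seed = s))
    gs$p_value[gs$variable == "hti"]
  }, numeric(4))
  expect_gt(mean(p[1, ] < 0.001), 0.5)
  expect_gt(mean(p[2, ] < 0.001), 0.5)
  expect_gt(mean(p[3, ] < 0.001), 0.5)
  expect_gt(mean(p[4, ] > 0.05), 0.5)
})

test_that("baseline burden correlates positively with benefit", {
  # perfectly monotone pairs
  coh <- make_cohort(c(200, 190, 180, 170), c(100, 98, 96, 94), c(4, 3, 2, 1),
                     c(130, 135, 140, 145), c(80, 80, 80, 80), c(1, 1, 1, 1))
  expect_equal(baseline_vs_benefit(coh)$rho, 1)
  # reversing the benefit ordering flips the sign
  rev <- make_cohort(c(200, 190, 180, 170), c(100, 98, 96, 94), c(1, 1, 1, 1),
                     c(196, 170, 140, 110), c(90, 90, 85, 80), c(1, 1, 1, 1))
  expect_equal(baseline_vs_benefit(rev)$rho, -1)
  const <- make_cohort(rep(150, 4), rep(90, 4), rep(2, 4),
                       rep(140, 4), rep(85, 4), rep(2, 4))
  expect_error(baseline_vs_benefit(const), "constant")
  rho <- vapply(1:20, function(s) baseline_vs_benefit(generate_cohort(seed = s))$rho, 0)
  expect_true(all(rho > 0.5))
})

test_that("the one-call analysis object assembles all components", {
  fit <- hti_analysis(generate_cohort(seed = 1))
  expect_s3_class(fit, "hti_analysis")
  expect_equal(sum(fit$response$group_counts), 99L)
  expect_true(all(c("group", "success", "d_hti", "hti_baseline") %in%
                    names(fit$cohort)))
  expect_equal(fit$roc$summary$n_pos[1] + fit$roc$summary$n_neg[1], 99L)
  expect_output(print(fit), "99 patients")
  expect_output(summary(fit), "Spearman")
})
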