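small_design <- trial_design(n_trials = 2, n_subjects = 5, seed = 3)

test_that("virtual trials return one row per subject, reproducibly", {
  t1 <- run_virtual_trials(small_design, drug, sysdef, std_regimen,
                           options = fast_opts())
  expect_equal(nrow(t1), 10)
  expect_equal(sum(t1$sex == "female"), 4)  # fixed 2-of-5 composition per trial
  t2 <- run_virtual_trials(small_design, drug, sysdef, std_regimen,
                           options = fast_opts())
  expect_identical(t1, t2)
})

test_that("with nonlinearities off, doubling the dose doubles every subject's AUC", {
  opt <- fast_opts(mbi = FALSE, saturable_binding = FALSE)
  a <- run_virtual_trials(small_design, drug, sysdef,
                          dose_regimen(400, 24, 14), options = opt)
  b <- run_virtual_trials(small_design, drug, sysdef,
                          dose_regimen(800, 24, 14), options = opt)
  expect_true(all(abs(b$auc_0_24_ss / a$auc_0_24_ss - 2) < 1e-6))
})

test_that("geometric mean intervals match hand-computed cases", {
  expect_equal(geomean_ci(c(1, 100))$gm, 10)
  eq <- geomean_ci(rep(3.2, 5))
  expect_equal(eq$gm, 3.2)
  expect_equal(eq$lo, 3.2)
  expect_equal(eq$hi, 3.2)

  g <- geomean_ci(c(2, 4, 8), level = 0.95)
  # frozen from the t-interval on log-scale spacing: se = log(2)/sqrt(3),
  # t(0.975, 2 df) = 4.3027
  expect_equal(g$gm, 4)
  expect_equal(g$lo, exp(log(4) - qt(0.975, 2) * sd(log(c(2, 4, 8))) / sqrt(3)))
  expect_equal(g$lo, 0.7148, tolerance = 1e-3)
  expect_equal(g$hi, 22.386, tolerance = 1e-3)

  expect_error(geomean_ci(c(1, -2)), class = "imatpbpk_domain_error")
  expect_error(geomean_ci(5), class = "imatpbpk_domain_error")
})

test_that("group comparison reproduces the exact Kruskal-Wallis rank computation", {
  m <- tibble::tibble(auc_0_24_ss = c(1, 2, 3, 4, 10, 20, 30, 40))
  lab <- c(rep(FALSE, 4), rep(TRUE, 4))
  cc <- compare_groups(m, lab, metric_cols = "auc_0_24_ss")
  kw <- kruskal.test(m$auc_0_24_ss, factor(lab))
  expect_equal(kw$statistic[[1]], 16 / 3)  # H for fully separated ranks, n=4+4
  expect_equal(cc$p_kruskal_wallis, kw$p.value)
  expect_equal(cc$p_kruskal_wallis, 0.0209, tolerance = 1e-2)
  expect_equal(cc$gm_ratio, 10)

  # identical groups: ratio one, p ~ 1
  m2 <- tibble::tibble(auc_0_24_ss = rep(c(1, 2, 3, 4), 2))
  cc2 <- compare_groups(m2, lab, metric_cols = "auc_0_24_ss")
  expect_equal(cc2$gm_ratio, 1)
  expect_gt(cc2$p_kruskal_wallis, 0.9)

  expect_error(compare_groups(m, c(rep(FALSE, 7), TRUE),
                              metric_cols = "auc_0_24_ss"),
               class = "imatpbpk_statistics_error")
})

test_that("the Kruskal-Wallis statistic matches rank and permutation oracles", {
  # independent oracle for H: direct rank-sum formula with tie correction
  h_oracle <- function(x, g) {
    r <- rank(x); n <- length(x)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  withr::with_seed(13, {
    for (i in 1:6) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      x <- round(runif(n1 + n2, 0, 20), 1)
      g <- factor(c(rep("a", n1), rep("b", n2)))
      expect_equal(kruskal.test(x, g)$statistic[[1]], h_oracle(x, g),
                   tolerance = 1e-12)
    }
  })

  # exact permutation distribution of H: the chi-square p-value used for the
  # group comparisons agrees with the exact tail for small samples
  x <- c(3.1, 8.4, 1.2, 9.9, 12.5, 6.6, 14.2, 2.8, 7.7)
  g <- factor(c(rep("a", 4), rep("b", 5)))
  h0 <- kruskal.test(x, g)$statistic[[1]]
  perms <- combn(9, 4)
  p_exact <- mean(apply(perms, 2, function(idx) {
    kruskal.test(x, factor(seq_len(9) %in% idx))$statistic[[1]] >= h0 - 1e-12
  }))
  expect_lt(abs(kruskal.test(x, g)$p.value - p_exact), 0.1)
})

test_that("sensitivity sweeps are monotone for CYP2C8 and flat for gut CYP3A4", {
  des <- trial_design(n_trials = 2, n_subjects = 5, seed = 8)
  sw <- sensitivity_sweep("CYP2C8_hepatic", c(0, 22.4, 85), des, drug, sysdef,
                          std_regimen, options = fast_opts())
  expect_true(all(diff(sw$summary$auc_0_24_ss) < 0))
  expect_lt(sw$stats$p_kruskal_wallis[sw$stats$metric == "auc_0_24_ss"], 0.05)

  gut <- sensitivity_sweep("CYP3A4_gut", c(2, 250), des, drug, sysdef,
                           std_regimen, options = fast_opts())
  a <- gut$stats[gut$stats$metric == "auc_0_24_ss", ]
  expect_lt(abs(a$fold_change_extremes - 1), 0.1)
  expect_gt(a$p_wilcoxon_extremes, 0.05)

  one <- sensitivity_sweep("weight", 70, des, drug, sysdef, std_regimen,
                           options = fast_opts())
  expect_equal(one$stats$fold_change_extremes,
               rep(1, 4))

  expect_error(sensitivity_sweep("shoe_size", 1:2, des, drug, sysdef,
                                 std_regimen),
               class = "imatpbpk_config_error")
})

test_that("matched sweep subjects differ only in the target parameter", {
  des <- trial_design(n_trials = 1, n_subjects = 4, seed = 19)
  sw <- sensitivity_sweep("AAG", c(0.5, 2), des, drug, sysdef, std_regimen,
                          options = fast_opts())
  lo <- sw$per_subject[sw$per_subject$level == 0.5, ]
  hi <- sw$per_subject[sw$per_subject$level == 2, ]
  expect_equal(lo$age, hi$age)
  expect_equal(lo$weight, hi$weight)
  expect_true(all(hi$auc_0_24_ss > lo$auc_0_24_ss))
})

test_that("a perpetrator without interactions gives GMRs of exactly one", {
  des <- trial_design(n_trials = 1, n_subjects = 3, seed = 23)
  null_perp <- perp_with(perps$trimethoprim, interactions = list())
  d <- ddi_study(drug, sysdef, std_regimen, null_perp, des,
                 options = fast_opts())
  expect_true(all(abs(d$summary$gmr - 1) < 1e-12))
  expect_false(any(d$summary$clinically_significant))

  zero_dose <- perp_with(perps$trimethoprim,
                         regimen = modifyList(perps$trimethoprim$regimen,
                                              list(dose_mg = 0)))
  d0 <- ddi_study(drug, sysdef, std_regimen, zero_dose, des,
                  options = fast_opts())
  expect_true(all(abs(d0$summary$gmr - 1) < 1e-12))
})

test_that("competitive inhibition vanishes monotonically as Ki grows", {
  des <- trial_design(n_trials = 1, n_subjects = 3, seed = 29)
  gmr_at <- function(ki) {
    p <- perps$trimethoprim
    p$interactions[[1]]$Ki_uM <- ki
    d <- ddi_study(drug, sysdef, std_regimen, p, des, options = fast_opts())
    d$summary$gmr[d$summary$metric == "auc_0_24_ss"]
  }
  g <- vapply(c(4.2, 40, 4000), gmr_at, 1)
  expect_true(all(diff(g) < 0))
  expect_lt(abs(g[3] - 1), 0.002)
})

test_that("autoinhibition shrinks the CYP3A4-inhibitor interaction at steady state", {
  # the accumulated autoinhibition of hepatic CYP3A4 leaves less activity for
  # a diltiazem-type inhibitor to remove: the steady-state AUC GMR with
  # imatinib autoinhibition active must be smaller than the GMR the same
  # perpetrator produces when the victim's CYP3A4 is not self-inactivated
  gmr_one <- function(mbi) {
    vapply(1:3, function(s) {
      ind <- ref_individual(seed = 600 + s, age = 35 + 10 * s)
      opt <- fast_opts(mbi = mbi)
      base <- simulate_pbpk(ind, drug, std_regimen, sysdef, options = opt)
      with <- simulate_pbpk(ind, drug, std_regimen, sysdef,
                            perpetrator = perps$diltiazem, options = opt)
      with$metrics$auc_0_24_ss / base$metrics$auc_0_24_ss
    }, 1)
  }
  expect_true(all(gmr_one(mbi = TRUE) < gmr_one(mbi = FALSE)))
})
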