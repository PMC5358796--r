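test_that("ICC(3,1) equals the ANOVA-decomposition oracle and its limits", {
  identical_raters <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(icc_consistency(identical_raters)$icc, 1)

  toy <- cbind(c(1, 2, 3, 2), c(2, 2, 4, 1))
  expect_equal(icc_consistency(toy)$icc, oracle_icc31(toy),
               tolerance = 1e-10)
  withr::with_seed(11, {
    for (i in 1:5) {
      m <- matrix(stats::rnorm(24, rep(1:8, 3), 0.5), 8, 3)
      expect_equal(icc_consistency(m)$icc, oracle_icc31(m),
                   tolerance = 1e-10)
    }
  })
  # undefined when samples do not differ
  flat <- matrix(2, 4, 3) + cbind(0, c(0.1, -0.1, 0.1, -0.1), 0)
  expect_warning(res <- icc_consistency(matrix(2, 4, 3)), "undefined")
  expect_true(is.na(res$icc))
  expect_error(icc_consistency(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("ICC is invariant to shifting and positive rescaling of all ratings", {
  withr::with_seed(12, m <- matrix(stats::rnorm(30, rep(1:10, 3), 0.4), 10, 3))
  base <- icc_consistency(m)$icc
  expect_equal(icc_consistency(m + 7)$icc, base, tolerance = 1e-10)
  expect_equal(icc_consistency(m * 3.5)$icc, base, tolerance = 1e-10)
})

test_that("one-way ANOVA matches explicit sums of squares and its identities", {
  identical_groups <- rep(c(1, 2, 3), 3)
  g <- rep(letters[1:3], each = 3)
  a0 <- one_way_anova(identical_groups, g)
  expect_equal(a0$f_statistic, 0)
  expect_equal(a0$p_value, 1)

  a <- c(3.1, 2.8, 4.0, 3.3)
  b <- c(5.2, 4.9, 6.1, 5.5)
  av <- one_way_anova(c(a, b), rep(c("a", "b"), each = 4))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(av$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)

  vals <- c(2.1, 3.4, 2.9, 3.8, 2.2, 5.0, 4.1, 4.4, 5.2, 4.8,
            6.3, 7.0, 6.1, 6.8, 7.2)
  grp <- rep(c("x", "y", "z"), each = 5)
  got <- one_way_anova(vals, grp)
  oracle <- oracle_anova(vals, grp)
  expect_equal(got$f_statistic, oracle$f, tolerance = 1e-10)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  expect_error(one_way_anova(vals, rep("x", 15)), "2 groups")
})

test_that("Tukey HSD collapses to the pooled t-test for two groups", {
  a <- c(1.2, 2.3, 1.8, 2.9, 1.1)
  b <- c(2.0, 3.1, 2.7, 3.5)
  tk <- tukey_hsd(c(a, b), rep(c("a", "b"), c(5, 4)))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-10)
  expect_equal(tk$difference, mean(b) - mean(a), tolerance = 1e-12)

  same <- rep(c(1, 2, 3), 3)
  tk0 <- tukey_hsd(same, rep(letters[1:3], each = 3))
  expect_true(all(tk0$p_adjusted > 1 - 1e-8))
})

test_that("Tukey agrees with a permutation cross-check on calls and ranking", {
  vals <- c(2.5, 3.1, 2.8, 3.4, 2.7,   # x
            4.0, 4.6, 4.3, 4.9, 4.2,   # y = x + 1.5
            7.8, 8.4, 8.0, 8.6, 7.7)   # z, far from both
  grp <- rep(c("x", "y", "z"), each = 5)
  tk <- tukey_hsd(vals, grp)
  perm_p <- purrr::map_dbl(seq_len(nrow(tk)), function(i) {
    ga <- tk$group_1[i]
    gb <- tk$group_2[i]
    x <- vals[grp %in% c(ga, gb)]
    lab <- grp[grp %in% c(ga, gb)]
    obs <- abs(mean(x[lab == gb]) - mean(x[lab == ga]))
    withr::with_seed(40 + i, {
      sims <- replicate(400, {
        p <- sample(lab)
        abs(mean(x[p == gb]) - mean(x[p == ga]))
      })
    })
    mean(sims >= obs - 1e-12)
  })
  # every honest difference is called by both routes, and the closest
  # pair of groups is the least significant under both
  expect_true(all(tk$p_adjusted < 0.05))
  expect_true(all(perm_p < 0.05))
  expect_equal(which.max(tk$p_adjusted), which.max(perm_p))
})

test_that("independent t-tests match the closed form and degenerate gracefully", {
  a <- c(1.5, 2, 2.5)
  expect_equal(independent_t(a, a)$t_statistic, 0)
  expect_equal(independent_t(a, a)$p_value, 1)

  x <- c(3.2, 2.9, 3.8, 3.1, 3.5, 2.7)
  y <- c(4.4, 4.9, 4.1, 5.2, 4.6, 4.8)
  got <- independent_t(x, y)
  oracle <- oracle_welch_t(x, y)
  expect_equal(got$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-10)

  # |t| grows without bound as the jitter shrinks around shifted constants
  t_for <- function(eps) {
    abs(independent_t(c(1, 1 + eps, 1 - eps), c(2, 2 + eps, 2 - eps))$t_statistic)
  }
  expect_gt(t_for(1e-3), t_for(1e-1))
  expect_gt(t_for(1e-5), t_for(1e-3))
  expect_warning(res <- independent_t(c(1, 1), c(2, 2)), "zero variance")
  expect_true(is.na(res$t_statistic))
})

test_that("regression recovers exact lines and matches the normal equations", {
  x <- 1:6
  exact <- linear_regression(x, 2 * x + 1)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  y <- c(2.3, 2.8, 4.1, 4.0, 5.6, 5.9)
  fit <- linear_regression(x, y)
  oracle <- oracle_lm(x, y)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate, c(oracle$intercept, oracle$slope),
               tolerance = 1e-10)
  expect_equal(glance(fit)$r_squared, oracle$r_squared, tolerance = 1e-10)

  withr::with_seed(13, noise <- stats::rnorm(2000))
  flat <- linear_regression(seq_len(2000), 5 + noise)
  expect_lt(flat$r_squared, 0.01)
  expect_error(linear_regression(rep(1, 5), 1:5), "degenerate")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("the study report reproduces cohort arithmetic and generator structure", {
  cohort <- cohort_patients()
  cs <- summarize_cohort(cohort)
  expect_equal(cs$mean_age, 74.5)
  expect_equal(cs$age_min, 57)
  expect_equal(cs$age_max, 88)
  expect_equal(cs$mean_oarsi, 4.07, tolerance = 1e-12)

  tab <- generate_study_table(n_patients = 60, seed = 14)
  rep <- reproduce_study(tab, cohort = cohort)
  expect_s3_class(rep, "study_report")
  expect_equal(rep$cohort_summary$mean_age, 74.5)
  # monotone descriptor coupling fixes the regression slope signs
  expect_gt(rep$regressions$entropy_bits$slope, 0)
  expect_lt(rep$regressions$homogeneity$slope, 0)
  # grade 3 is excluded from the descriptor group comparison
  expect_false(3 %in% rep$lbp_group_sizes$bone_grade)
  expect_equal(rep$counts$n_samples, 180)
  expect_equal(rep$counts$n_with_descriptors +
                 rep$counts$n_excluded_no_cartilage, 180)
  tidied <- tidy(rep)
  expect_true(all(c("cohort_mean_age", "icc", "r_squared_entropy_bits") %in%
                    tidied$statistic))
  expect_error(reproduce_study(tab[, -5]), "missing columns")
})
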