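# Subject-level statistics: normalization, normality, group comparisons,
# Spearman matrix, regression.

test_that("NMF normalization is a guarded ratio", {
  expect_equal(as.numeric(normalize_nmf(2.0, 4.0)), 0.5)
  expect_equal(as.numeric(normalize_nmf(0, 3)), 0)
  expect_equal(as.numeric(normalize_nmf(3.6, 1.2)), 3.0)
  expect_identical(attr(normalize_nmf(1, 1), "units"), "mmol/g protein")
  expect_error(normalize_nmf(1, 0), class = "cm_domain_error")
  expect_error(normalize_nmf(1, -2), class = "cm_domain_error")
})

test_that("normality check has correct size and power", {
  expect_error(normality_check(c(1, 2)), class = "cm_domain_error")
  expect_error(normality_check(rep(3, 10)), class = "cm_degenerate")
  set.seed(101)
  # type I: null normal data rejected at about alpha
  p_null <- replicate(1000, normality_check(rnorm(50)))
  expect_equal(mean(p_null < 0.05), 0.05, tolerance = 0.4)
  expect_gt(mean(p_null < 0.05), 0.02)
  # power: strong lognormality detected essentially always
  p_lnorm <- replicate(200, normality_check(rlnorm(200, sdlog = 1)))
  expect_gt(mean(p_lnorm < 0.05), 0.95)
})

test_that("group comparison matches the pooled-t hand computation", {
  gc <- compare_groups(c(1, 2, 3, 4), c(11, 12, 13, 14))
  # mean diff -10, pooled SD 1.291, SE 0.9129 -> t = -10.95
  expect_identical(gc$test_used, "student")
  expect_equal(gc$statistic, -10.95, tolerance = 5e-3)
  expect_equal(gc$df, 6)
  expect_equal(unname(gc$group_means), c(2.5, 12.5))
  # identical groups: t = 0, p = 1
  gc0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gc0$statistic, 0)
  expect_equal(gc0$p_two_sided, 1)
  expect_error(compare_groups(1, c(1, 2)), class = "cm_domain_error")
})

test_that("the variance gate selects Welch under variance inflation", {
  set.seed(7)
  picks <- replicate(500, {
    x <- rnorm(20); y <- rnorm(20, sd = 10)
    compare_groups(x, y)$test_used
  })
  expect_gte(mean(picks == "welch"), 0.99)
  # and the Levene alternative gates the same way on gross inflation
  set.seed(8)
  gcl <- compare_groups(rnorm(20), rnorm(20, sd = 10),
                        variance_gate = "levene")
  expect_identical(gcl$test_used, "welch")
})

test_that("genotype-stratified comparisons cover both strata or warn", {
  co <- generate_cohort(cohort_sim_config(seed = 3))
  res <- compare_groups_by_genotype(co)
  expect_length(res, 4L)  # 2 variables x 2 strata
  expect_setequal(names(res),
                  c("ea:AD_FLG_wt", "ea:AD_FLG_carrier",
                    "nmf:AD_FLG_wt", "nmf:AD_FLG_carrier"))
  # without wild-type controls everything is skipped with warnings
  no_ad_wt <- co[!(co$group == "AD" & co$flg == "WT"), ]
  expect_warning(compare_groups_by_genotype(no_ad_wt, variables = "ea"),
                 class = "corneomech_warning")
  no_wt <- co[!(co$group == "control" & co$flg == "WT"), ]
  res2 <- suppressWarnings(compare_groups_by_genotype(no_wt))
  expect_length(res2, 0L)
  expect_length(attr(res2, "skipped"), 4L)
  # BH adjustment is available but off by default
  expect_null(attr(res, "p_adjusted"))
  res3 <- compare_groups_by_genotype(co, p_adjust = "BH")
  expect_length(attr(res3, "p_adjusted"), 4L)
})

test_that("group NMF deficit depresses Ea in carriers and non-carriers", {
  co <- generate_cohort(cohort_sim_config(scale = 50, seed = 4))
  res <- compare_groups_by_genotype(co)
  for (nm in names(res)) {
    expect_lt(res[[nm]]$group_means[1], res[[nm]]$group_means[2])
    expect_lt(res[[nm]]$p_two_sided, 0.001)
  }
})

test_that("Spearman rho matches the rank formula and is monotone-invariant", {
  sm <- spearman_matrix(data.frame(nmf = 1:5, ea = c(3, 1, 2, 5, 4)),
                        variables = c("nmf", "ea"))
  # 1 - 6 * 8 / (5 * 24) = 0.6
  expect_equal(sm$rho["nmf", "ea"], 0.6)
  expect_identical(sm$n["nmf", "ea"], 5L)
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    base <- spearman_matrix(data.frame(nmf = x, ea = y),
                            variables = c("nmf", "ea"))$rho[1, 2]
    trans <- spearman_matrix(data.frame(nmf = exp(3 * x), ea = y^3 + y),
                             variables = c("nmf", "ea"))$rho[1, 2]
    expect_equal(trans, base, tolerance = 1e-12)
  }
  # perfect monotone relations
  x <- c(0.3, 1.2, 2.5, 7, 9)
  expect_equal(spearman_matrix(data.frame(nmf = x, ea = exp(x)),
                               variables = c("nmf", "ea"))$rho[1, 2], 1)
  expect_equal(spearman_matrix(data.frame(nmf = x, ea = -x),
                               variables = c("nmf", "ea"))$rho[1, 2], -1)
})

test_that("exact permutation p-values agree with the reference algorithm", {
  set.seed(21)
  for (n in c(5, 7, 9)) {
    x <- rnorm(n); y <- rnorm(n)  # continuous: no ties
    ours <- corneomech:::spearman_exact_p(x, y)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
    expect_equal(ours, min(ref, 1), tolerance = 1e-10)
  }
  # with ties the DP still yields a valid two-sided permutation p
  p_tied <- corneomech:::spearman_exact_p(c(1, 1, 2, 3, 4), c(2, 1, 1, 3, 4))
  expect_true(p_tied > 0 && p_tied <= 1)
})

test_that("the correlation matrix honours missing-data contracts", {
  co <- generate_cohort(cohort_sim_config(seed = 5))
  co$tewl[1:3] <- NA
  sm <- spearman_matrix(co)
  expect_identical(sm$n["ea", "tewl"], sum(complete.cases(co$ea, co$tewl)))
  # SCORAD pairs restricted to patients
  expect_identical(sm$n["ea", "scorad"], 20L)
  expect_true(isSymmetric(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 4))
  expect_true(all(abs(sm$rho) <= 1, na.rm = TRUE))
  # under 4 complete pairs: flagged missing, never fabricated
  co$scorad[co$group == "AD"][4:20] <- NA
  sm2 <- spearman_matrix(co)
  expect_identical(sm2$n["ea", "scorad"], 3L)
  expect_true(is.na(sm2$rho["ea", "scorad"]))
})

test_that("regression R^2 matches the OLS oracle", {
  x <- c(1, 5, 9, 12)
  r <- regression_r2(x, 2 * x + 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  # hand-computed small case: R^2 = 27/28
  expect_equal(regression_r2(c(1, 2, 3), c(2, 4, 5))$r_squared, 27 / 28)
  # independence: R^2 near zero at large n
  set.seed(31)
  r0 <- regression_r2(rnorm(2000), rnorm(2000))
  expect_lt(r0$r_squared, 0.01)
  expect_error(regression_r2(rep(2, 5), rnorm(5)), class = "cm_degenerate")
})

test_that("demographic summaries report strata counts and group means", {
  co <- generate_cohort(cohort_sim_config(seed = 6))
  d <- summarize_demographics(co)
  expect_identical(d$AD$n, 20L)
  expect_identical(d$control$n, 7L)
  expect_identical(unname(c(d$AD$flg_counts)), c(5L, 10L, 5L))
  expect_identical(unname(c(d$control$flg_counts)), c(5L, 2L, 0L))
  expect_true(is.na(d$control$scorad["mean"]))
  expect_equal(d$AD$tewl[["mean"]], mean(co$tewl[co$group == "AD"]))
})
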