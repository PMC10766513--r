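test_that("Levene statistic agrees with the car implementation", {
  set.seed(61)
  for (center in c("median", "mean")) {
    a <- rnorm(24); b <- rnorm(30, sd = 1.7)
    mine <- levene_test(a, b, center = center)
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(24, 30))),
                           center = if (center == "median") median else mean)
    expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("identical groups give statistic 0 and p 1", {
  x <- c(1, 2, 3, 4, 5)
  lt <- levene_test(x, x)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p.value, 1)
})

test_that("a constant group is reported as undefined", {
  expect_warning(lt <- levene_test(rep(1, 5), rep(2, 6)), "constant")
  expect_true(is.na(lt$statistic))
})

test_that("Levene statistic is shift- and scale-invariant", {
  set.seed(62)
  a <- rexp(20); b <- rexp(25) * 2
  s0 <- levene_test(a, b)$statistic
  expect_equal(levene_test(a + 100, b + 100)$statistic, s0,
               tolerance = 1e-10)
  expect_equal(levene_test(a * 7, b * 7)$statistic, s0, tolerance = 1e-10)
})

test_that("null rejection rate is near alpha at the study group sizes", {
  set.seed(63)
  rej <- mean(replicate(4000, {
    levene_test(rnorm(30), rnorm(24))$p.value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("a 3x SD difference is detected most of the time at n = 30", {
  set.seed(64)
  hits <- mean(replicate(200, {
    x <- rnorm(30)
    levene_test(3 * rnorm(30), x)$p.value < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("the default design yields 84 contrasts with the study alphas", {
  d <- quick_dataset(seed = 65, missing = study_missingness(seed = 65))
  ca <- contrast_all(d, alpha = 0.05)
  s <- ca$summary
  expect_equal(s$m, 84L)
  expect_equal(s$expected_false_positives, 4.2)
  expect_equal(s$alpha_bonferroni, 0.05 / 84)
  expect_equal(floor(1e5 * s$alpha_bonferroni) / 1e5, 5.9e-4)
  expect_equal(s$n_ratio_larger + s$n_ratio_smaller + s$n_ratio_tied, 84L)
  # Bonferroni-significant contrasts are a subset of raw-significant ones
  expect_true(all(ca$contrasts$significant_raw[
    ca$contrasts$significant_bonferroni]))
})

test_that("SD ratios are reciprocal between arm orderings", {
  d <- quick_dataset(seed = 66)
  ca <- contrast_all(d)
  one <- ca$contrasts[1, ]
  expect_equal(one$ratio * (one$sd_sta / one$sd_het), 1, tolerance = 1e-12)
})

test_that("arms from one profile split ratio directions about evenly", {
  # exchangeable null: no breeder or interaction variance, otherwise the
  # HET arm genuinely gains between-breeder variance within each cohort
  null_prof <- variance_profile(frac_lab = 0.15, frac_cage = 0.10,
                                frac_residual = 0.75)
  counts <- vapply(1:12, function(i) {
    d <- quick_dataset(seed = 400 + i, profile = null_prof)
    contrast_all(d)$summary$n_ratio_larger
  }, numeric(1))
  expect_lt(abs(mean(counts) - 42), 2 * sd(counts) / sqrt(12) + 2)
})

test_that("heterogenized cohorts gain variance when breeders differ", {
  # with real breeder and interaction variance the HET arm is genuinely
  # more variable, so ratios above 1 dominate
  counts <- vapply(1:6, function(i) {
    d <- quick_dataset(seed = 500 + i)
    contrast_all(d)$summary$n_ratio_larger
  }, numeric(1))
  expect_gt(mean(counts), 42)
})

test_that("Fisher's method matches its closed forms", {
  # k = 1 reduces to the input p
  expect_equal(fisher_combine(0.2)$combined_p, 0.2, tolerance = 1e-12)
  # all p = 0.5, k = 6: chi2 = -2 * 6 * log(0.5)
  fc <- fisher_combine(rep(0.5, 6))
  expect_equal(fc$chi2, -2 * 6 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 12L)
  expect_equal(fc$combined_p,
               pchisq(-12 * log(0.5), 12, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(fc$chi2, 4), 8.3178)
  expect_equal(round(fc$combined_p, 3), 0.760)
})

test_that("combined p-values are uniform under the null", {
  set.seed(68)
  ps <- replicate(4000, fisher_combine(runif(6))$combined_p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero p-values are rejected with clipping guidance", {
  expect_error(fisher_combine(c(0.5, 0)), "clip")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
})

test_that("per-outcome Fisher combination uses the six lab p-values", {
  d <- quick_dataset(seed = 69, missing = study_missingness(seed = 69))
  ca <- contrast_all(d)
  cc <- contrast_combined(ca)
  expect_equal(nrow(cc), 14L)
  expect_true(all(cc$k == 6L))
  expect_true(all(cc$df == 12L))
  one <- ca$contrasts[ca$contrasts$outcome == "glucose", "p"]
  expect_equal(cc$chi2[cc$outcome == "glucose"], -2 * sum(log(one)),
               tolerance = 1e-12)
})
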