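test_that("Pillai V with one outcome and two groups equals univariate R2", {
  set.seed(31)
  d <- data.frame(lab = rep(c("L1", "L2"), each = 15),
                  breeder = "B1",
                  y = rnorm(30) + rep(c(0, 1), each = 15))
  mp <- manova_pillai(d, outcomes = "y")
  a <- anova(lm(y ~ lab, data = d))
  r2 <- a["lab", "Sum Sq"] / sum(a[, "Sum Sq"])
  expect_equal(mp$V, r2, tolerance = 1e-12)
  expect_equal(mp$eta2, r2, tolerance = 1e-12)
})

test_that("Pillai V with p = 1 equals the partial R2 of the model drop", {
  d <- quick_dataset(seed = 32)
  mp <- manova_pillai(d, outcomes = "glucose")
  r_full <- sum(residuals(lm(glucose ~ lab * breeder, data = d))^2)
  r_add <- sum(residuals(lm(glucose ~ lab + breeder, data = d))^2)
  r_b <- sum(residuals(lm(glucose ~ breeder, data = d))^2)
  v_lab <- (r_b - r_add) / (r_b - r_add + r_full)
  expect_equal(mp$V[mp$effect == "lab"], v_lab, tolerance = 1e-12)
})

test_that("Type II Pillai statistics agree with the car implementation", {
  d <- quick_dataset(seed = 33, missing = study_missingness(seed = 33))
  mp <- manova_pillai(d)
  cc <- d[complete.cases(d[default_outcomes()]), ]
  fit <- lm(as.matrix(cc[default_outcomes()]) ~ lab * breeder, data = cc)
  cm <- car::Manova(fit, type = 2)
  ref <- summary(cm)$multivariate.tests
  pillai <- function(t) sum(diag(t$SSPH %*% solve(t$SSPH + t$SSPE)))
  expect_equal(mp$V[mp$effect == "lab"], pillai(ref$lab),
               tolerance = 1e-8)
  expect_equal(mp$V[mp$effect == "breeder"], pillai(ref$breeder),
               tolerance = 1e-8)
  expect_equal(mp$V[mp$effect == "lab:breeder"],
               pillai(ref$`lab:breeder`), tolerance = 1e-8)
})

test_that("permuted labels bring eta2 down to the null band", {
  d <- quick_dataset(seed = 34)
  obs <- manova_pillai(d)
  set.seed(34)
  perm <- replicate(10, {
    dp <- d
    idx <- sample(nrow(d))
    dp$lab <- d$lab[idx]; dp$breeder <- d$breeder[idx]
    dp$cage_id <- d$cage_id[idx]; dp$design <- d$design[idx]
    manova_pillai(dp)$eta2
  })
  # under the null E[V] is about p * df_h / (n - 1)
  expect_lt(mean(perm[1, ]), obs$eta2[obs$effect == "lab"] / 2)
  null_scale <- 14 * 5 / (324 - 1) / 5
  expect_lt(abs(mean(perm[1, ]) - null_scale), 3 * null_scale)
})

test_that("REML equals closed-form EMS estimators on balanced designs", {
  for (s2c in c(0.5, 2)) {
    toy <- balanced_cage_toy(k = 12, m = 4, s2_cage = s2c, seed = s2c * 10)
    f <- fit_lmm(toy, "y", fixed = ~1)
    a <- anova(lm(y ~ cage_id, data = toy))
    msb <- a["cage_id", "Mean Sq"]; msw <- a["Residuals", "Mean Sq"]
    expect_equal(f$sigma2_cage, (msb - msw) / 4, tolerance = 1e-8)
    expect_equal(f$sigma2_resid, msw, tolerance = 1e-8)
  }
})

test_that("zero cage variance and one-animal cages give boundary fits", {
  d <- quick_dataset(seed = 35,
                     profile = variance_profile(frac_lab = 0.2,
                                                frac_residual = 0.8))
  f <- fit_lmm(d, "body_weight", fixed = ~lab)
  expect_true(f$singular)
  expect_lt(f$sigma2_cage, 1e-8)

  solo <- d
  solo$cage_id <- solo$animal_id   # one animal per cage
  f2 <- fit_lmm(solo, "body_weight", fixed = ~lab)
  expect_true(f2$singular)
})

test_that("Satterthwaite df matches classical balanced closed forms", {
  toy <- balanced_cage_toy(k = 10, m = 4, s2_cage = 4, s2_res = 1,
                           seed = 41)
  f <- fit_lmm(toy, "y", fixed = ~1)
  expect_equal(satterthwaite_df(f, contrast = 1), 10 - 1, tolerance = 1e-2)

  # zero cage variance: df collapses to the OLS residual df
  toy0 <- balanced_cage_toy(k = 10, m = 4, s2_cage = 0, s2_res = 1,
                            seed = 42)
  f0 <- fit_lmm(toy0, "y", fixed = ~1)
  if (f0$singular)
    expect_equal(satterthwaite_df(f0, contrast = 1), 40 - 1,
                 tolerance = 0.05)
})

test_that("Satterthwaite df decreases as the cage variance share grows", {
  # one fixed noise realization, cage effects scaled up deterministically
  set.seed(43)
  k <- 20; m <- 6
  cage <- factor(rep(seq_len(k), each = m))
  cage_eff <- rnorm(k)
  noise <- rnorm(k * m)
  dfs <- vapply(c(0.1, 1, 3), function(sc) {
    toy <- data.frame(y = sc * cage_eff[as.integer(cage)] + noise,
                      cage_id = cage)
    satterthwaite_df(fit_lmm(toy, "y", fixed = ~1), contrast = 1)
  }, numeric(1))
  expect_true(all(diff(dfs) <= 1e-6))   # nonincreasing; saturates at k - 1
  expect_lt(dfs[2], dfs[1])
  expect_true(all(dfs > 0 & dfs <= k * m - 1 + 1e-6))
})

test_that("explained variance shares sum to one and recover a lab share", {
  d <- quick_dataset(seed = 36)
  f <- fit_lmm(d, "albumin")
  ev <- explained_variance(f)
  expect_equal(ev$total_check, 1, tolerance = 1e-12)
  expect_true(all(unlist(ev[c("per_term", "combined", "cage",
                              "residual")]) >= 0))

  # many labs so the realized lab variance concentrates at 0.25
  spec <- design_spec(n_labs = 40, n_breeders = 40, sta_n = 24,
                      het_per_breeder = 0)
  prof <- variance_profile(spec$outcome_names, frac_lab = 0.25,
                           frac_residual = 0.75)
  d2 <- simulate_outcomes(allocate_design(spec), prof, seed = 36)
  f2 <- fit_lmm(d2, "body_weight", fixed = ~lab)
  ev2 <- explained_variance(f2)
  expect_lt(abs(ev2$per_term[["lab"]] - 0.25), 0.05)
})

test_that("pure-noise data give a near-zero combined share", {
  shares <- vapply(1:8, function(i) {
    d <- quick_dataset(seed = 100 + i,
                       profile = variance_profile(frac_residual = 1))
    explained_variance(fit_lmm(d, "body_weight"))$combined
  }, numeric(1))
  expect_gte(mean(shares < 0.05), 0.75)
})

test_that("between-lab R2 is near zero without lab effects and recovers 0.15", {
  d0 <- quick_dataset(seed = 37,
                      profile = variance_profile(frac_cage = 0.1,
                                                 frac_residual = 0.9))
  bl0 <- between_lab_variance(d0, "STA", outcomes = c("glucose", "alt"))
  expect_lt(bl0$mean, 0.06)

  r2 <- vapply(1:10, function(i) {
    d <- quick_dataset(seed = 200 + i)
    between_lab_variance(d, "HET", outcomes = "body_weight")$mean
  }, numeric(1))
  expect_gt(mean(r2), 0.10)
  expect_lt(mean(r2), 0.20)
})

test_that("STA and HET arms from one profile give symmetric lab R2", {
  diffs <- vapply(1:10, function(i) {
    d <- quick_dataset(seed = 300 + i)
    between_lab_variance(d, "HET", outcomes = "creatinine")$mean -
      between_lab_variance(d, "STA", outcomes = "creatinine")$mean
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2.5 * sd(diffs) / sqrt(length(diffs)) + 0.02)
})
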