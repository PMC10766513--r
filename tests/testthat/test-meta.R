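# independent brute-force check of the DerSimonian-Laird estimator:
# compute Q and the moment equation from first principles, solving for
# tau2 on a fine grid rather than with the closed form
dl_oracle <- function(y, se) {
  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  # E[Q] = (k - 1) + tau2 * (sum w - sum w^2 / sum w); match Q by grid
  grid <- seq(0, 10, by = 1e-6)
  expQ <- (length(y) - 1) + grid * (sum(w) - sum(w^2) / sum(w))
  tau2 <- grid[which.min(abs(expQ - Q))]
  wstar <- 1 / (se^2 + tau2)
  list(tau2 = tau2, pooled = sum(wstar * y) / sum(wstar))
}

fake_studies <- function(y, se, outcome = "y", arm = "STA") {
  structure(data.frame(lab = paste0("LAB", seq_along(y)), outcome = outcome,
                       arm = arm, estimate = y, se = se,
                       n_animals = 10L, n_cages = 5L,
                       stringsAsFactors = FALSE),
            class = c("study_estimates", "data.frame"))
}

test_that("DL tau2 matches the hand-worked two-study example", {
  # k = 2, estimates 0 and 1, both se 0.5:
  # Q = 2, c = 8 - 32/8 = 4, tau2 = (2 - 1)/4 = 0.25, pooled = 0.5
  st <- fake_studies(c(0, 1), c(0.5, 0.5))
  m <- random_effects_meta(st, method = "DL")
  expect_equal(m$tau2, 0.25, tolerance = 1e-12)
  expect_equal(m$pooled_mean, 0.5, tolerance = 1e-12)
  orc <- dl_oracle(c(0, 1), c(0.5, 0.5))
  expect_equal(m$tau2, orc$tau2, tolerance = 1e-5)
  expect_equal(m$pooled_mean, orc$pooled, tolerance = 1e-5)
})

test_that("DL estimates agree with metafor on random inputs", {
  set.seed(71)
  for (i in 1:5) {
    k <- sample(4:10, 1)
    y <- rnorm(k); se <- runif(k, 0.2, 1)
    m <- random_effects_meta(fake_studies(y, se), method = "DL")
    ref <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(m$tau2, as.numeric(ref$tau2), tolerance = 1e-8)
    expect_equal(m$pooled_mean, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(m$ci_low, as.numeric(ref$ci.lb), tolerance = 1e-6)
  }
})

test_that("identical studies collapse to tau2 = 0 and full coverage", {
  st <- fake_studies(rep(2.5, 5), rep(0.4, 5))
  m <- random_effects_meta(st)
  expect_equal(m$tau2, 0)
  expect_equal(m$pooled_mean, 2.5)
  expect_equal(coverage_probability(m), 1)
})

test_that("with tau2 = 0 the pooled mean is the fixed-effect mean", {
  set.seed(72)
  y <- rnorm(6, sd = 0.01); se <- runif(6, 1, 2)  # Q far below k - 1
  m <- random_effects_meta(fake_studies(y, se))
  expect_equal(m$tau2, 0)
  w <- 1 / se^2
  expect_equal(m$pooled_mean, sum(w * y) / sum(w), tolerance = 1e-12)
})

test_that("a single study is rejected", {
  expect_error(random_effects_meta(fake_studies(1, 0.5)), "2 studies")
})

test_that("DL is calibrated and agrees with REML at k = 50", {
  set.seed(73)
  tau2 <- 0.3; se <- 0.4
  est <- t(replicate(150, {
    y <- rnorm(50, sd = sqrt(tau2 + se^2))
    st <- fake_studies(y, rep(se, 50))
    c(dl = random_effects_meta(st, "DL")$tau2,
      reml = random_effects_meta(st, "REML")$tau2)
  }))
  expect_lt(abs(mean(est[, "dl"]) - tau2),
            2 * sd(est[, "dl"]) / sqrt(nrow(est)) + 0.01)
  expect_lt(abs(mean(est[, "dl"]) / mean(est[, "reml"]) - 1), 0.10)
})

test_that("study summaries use the cage as the independent unit", {
  prof <- variance_profile(frac_cage = 0.4, frac_residual = 0.6)
  d <- quick_dataset(seed = 74, profile = prof)
  st <- study_summaries(d, "body_weight", "STA")
  expect_equal(nrow(st), 6L)
  expect_true(all(st$n_cages == 12L))
  # naive animal-based SE understates the uncertainty under cage clustering
  naive <- vapply(split(d[d$design == "STA", ], droplevels(
    d$lab[d$design == "STA"])), function(dl)
      sd(dl$body_weight) / sqrt(nrow(dl)), numeric(1))
  expect_gt(mean(st$se / naive), 1.05)
})

test_that("degenerate labs are excluded with a warning", {
  d <- quick_dataset(seed = 75)
  d$body_weight[d$lab == "LAB1" & d$design == "STA"] <- 7  # constant lab
  expect_warning(st <- study_summaries(d, "body_weight", "STA"),
                 "zero variance")
  expect_equal(nrow(st), 5L)
})

test_that("coverage counts studies inside the pooled interval", {
  st <- fake_studies(c(0, 0.1, -0.1, 0.05, -0.05, 50), rep(0.5, 6))
  m <- random_effects_meta(st)
  expect_equal(coverage_probability(m), 5 / 6)
})

test_that("the pooled CI covers the true grand mean at the nominal rate", {
  set.seed(76)
  mu <- 1.7; tau2 <- 0.2; se <- 0.35; k <- 6
  hits <- mean(replicate(800, {
    y <- rnorm(k, mu, sqrt(tau2 + se^2))
    m <- random_effects_meta(fake_studies(y, rep(se, k)))
    m$ci_low <= mu && mu <= m$ci_high
  }))
  expect_gt(hits, 0.90)
  expect_lt(hits, 0.99)
})

test_that("forest export has one study row per lab plus a pooled row", {
  d <- quick_dataset(seed = 77, missing = study_missingness(seed = 77))
  ms <- meta_all(d)
  fx <- forest_export(ms)
  expect_equal(nrow(fx), 14L * 2L * 7L)
  expect_equal(sum(fx$pooled), 28L)
  # pooled CI narrower than every study CI when tau2 = 0 and ses are equal
  st <- fake_studies(rep(1, 5) + c(-.01, .01, 0, -.005, .005), rep(0.5, 5))
  m <- random_effects_meta(st)
  fx2 <- forest_export(list(m))
  pooled_w <- diff(unlist(fx2[fx2$pooled, c("ci_low", "ci_high")]))
  study_w <- fx2$ci_high[!fx2$pooled] - fx2$ci_low[!fx2$pooled]
  expect_true(all(pooled_w < study_w))
})

test_that("forest tables round-trip through TSV at 1e-12", {
  d <- quick_dataset(seed = 78)
  fx <- forest_export(meta_all(d, outcomes = c("glucose", "albumin")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(fx, path, sep = "\t", row.names = FALSE, quote = FALSE)
  fx2 <- read.delim(path)
  expect_equal(fx2$estimate, fx$estimate, tolerance = 1e-12)
  expect_equal(fx2$ci_low, fx$ci_low, tolerance = 1e-12)
})

test_that("the design-arm share of the deviation scatter behaves", {
  d <- quick_dataset(seed = 79, missing = study_missingness(seed = 79))
  ms <- meta_all(d)
  dev <- deviation_table(ms)
  dm <- design_effect_model(dev)
  expect_gte(dm$r2_arm, 0)
  expect_lt(dm$r2_arm, 0.15)   # arms share one generating profile

  # permuted arm labels stay in the null band near zero
  set.seed(79)
  dev_p <- dev
  dev_p$arm <- sample(dev_p$arm)
  expect_lt(design_effect_model(dev_p)$r2_arm, 0.1)

  # constant response carries no design signal
  dev0 <- dev
  dev0$deviation <- 1
  expect_equal(design_effect_model(dev0)$r2_arm, 0)

  # an injected arm shift is recovered at roughly its generating share
  set.seed(80)
  dev2 <- dev
  base_var <- var(dev2$deviation)
  shift <- sqrt(base_var)            # 1 SD shift between arms
  dev2$deviation <- dev2$deviation + (dev2$arm == "HET") * shift
  r2 <- design_effect_model(dev2)$r2_arm
  expect_gt(r2, 0.05)
})

test_that("degenerate deviation tables are rejected", {
  d <- quick_dataset(seed = 81)
  dev <- deviation_table(meta_all(d, outcomes = "glucose"))
  expect_error(design_effect_model(dev), "two outcomes")
})
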