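#' Critical value of the F distribution
#'
#' Upper-`alpha` quantile of `F(df1, df2)`; with the design-level referral
#' `(1, 5)` at `alpha = 0.05` this is 6.61, the threshold used by the
#' simulated-sampling power analysis.
#'
#' @param alpha Tail probability.
#' @param df1,df2 Degrees of freedom.
#' @return The critical value.
#' @export
critical_f <- function(alpha = 0.05, df1 = 1, df2 = 5) {
  stopifnot(alpha > 0, alpha < 1, df1 > 0, df2 > 0)
  stats::qf(1 - alpha, df1, df2)
}

#' First principal component of a standardized outcome matrix
#'
#' Principal component analysis on the correlation matrix (so per-column
#' affine rescaling is irrelevant); returns the scores along the leading
#' eigenvector, with the sign fixed so the largest-magnitude loading is
#' positive. An optional varimax rotation of the first two axes is
#' available since orthogonal rotation of principal axes can be read
#' either way.
#'
#' @param X Numeric matrix, `n x p` with `p >= 2`.
#' @param rotation `"none"` (default) or `"varimax"` (rotates the first
#'   two components and returns the first rotated one).
#' @return A list with `scores` (length-`n` vector), `loadings`,
#'   `prop_var` (share of total variance carried by the component).
#' @export
pca_first_component <- function(X, rotation = c("none", "varimax")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0],
                                       collapse = ", "))
  Z <- scale(X)
  ee <- eigen(stats::cor(X), symmetric = TRUE)
  if (rotation == "varimax" && ncol(X) >= 2L) {
    L <- ee$vectors[, 1:2] %*% diag(sqrt(ee$values[1:2]))
    rot <- stats::varimax(L)
    lo <- rot$loadings[, 1]
    v <- lo / sqrt(sum(lo^2))
    prop <- sum(lo^2) / ncol(X)
  } else {
    v <- ee$vectors[, 1]
    prop <- ee$values[1] / ncol(X)
  }
  v <- v * sign(v[which.max(abs(v))])
  list(scores = drop(Z %*% v), loadings = v, prop_var = prop)
}

#' Configuration for the simulated-sampling power analysis
#'
#' Emulates the design-stage sample-size procedure: per replicate, draw a
#' mean shift for each of the 12 continuous variables from the effect-size
#' distribution, simulate a standardized (STA, `n_sta`) and a heterogenized
#' (HET, `n_het`) cohort, run a correlation-matrix PCA over the variables,
#' feed the first principal component into a one-way ANOVA of cohort, and
#' call the replicate significant when the F ratio exceeds the design-level
#' critical value `F(alpha; df1, df2)` (default 6.6 for `(1, 5)`).
#'
#' @param n_sta,n_het Cohort sizes.
#' @param n_variables Number of continuous outcome variables.
#' @param effect_mean,effect_sd Normal effect-size distribution for the
#'   per-variable HET-vs-STA mean shift, in within-cohort SD units. These
#'   defaults are a documented placeholder for the unpublished design
#'   assumptions, not a calibrated reproduction of them.
#' @param n_reps Monte-Carlo replicates (>= 100 for a reported power).
#' @param alpha Significance level for the threshold.
#' @param df1,df2 Degrees of freedom of the threshold referral.
#' @param rotation PCA rotation, see [pca_first_component()].
#' @param seed Integer seed.
#' @return An object of class `power_config`.
#' @export
power_config <- function(n_sta = 24L, n_het = 30L, n_variables = 12L,
                         effect_mean = 0.5, effect_sd = 0.25,
                         n_reps = 2000L, alpha = 0.05,
                         df1 = 1, df2 = 5, rotation = "none",
                         seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_reps >= 1, n_variables >= 2,
            n_sta >= 2, n_het >= 2)
  structure(list(n_sta = as.integer(n_sta), n_het = as.integer(n_het),
                 n_variables = as.integer(n_variables),
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 n_reps = as.integer(n_reps), alpha = alpha,
                 df1 = df1, df2 = df2, rotation = rotation,
                 seed = as.integer(seed)), class = "power_config")
}

#' Monte-Carlo power of the PCA-ANOVA design test
#'
#' @param config A [power_config()].
#' @param trace Return the per-replicate trace (F ratio, PC1 variance
#'   share, exceedance flag)?
#' @return A list of class `power_result`: `power`, `mc_se`
#'   (`sqrt(p(1-p)/n_reps)`), `f_crit`, `config`, and (with `trace`)
#'   `replicates`.
#' @export
simulate_power <- function(config = power_config(), trace = FALSE) {
  stopifnot(inherits(config, "power_config"))
  fcrit <- critical_f(config$alpha, config$df1, config$df2)
  set.seed(child_seed(config$seed, "power"))
  p <- config$n_variables
  arm <- factor(rep(c("STA", "HET"), c(config$n_sta, config$n_het)))
  n <- length(arm)
  fstats <- numeric(config$n_reps)
  prop1 <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    shifts <- stats::rnorm(p, config$effect_mean, config$effect_sd)
    X <- matrix(stats::rnorm(n * p), n, p)
    X[arm == "HET", ] <- sweep(X[arm == "HET", , drop = FALSE], 2, shifts,
                               "+")
    pc <- pca_first_component(X, rotation = config$rotation)
    a <- stats::anova(stats::lm(pc$scores ~ arm))
    fstats[r] <- a$`F value`[1]
    prop1[r] <- pc$prop_var
  }
  exceed <- fstats >= fcrit
  pw <- mean(exceed)
  out <- list(power = pw,
              mc_se = sqrt(pw * (1 - pw) / config$n_reps),
              f_crit = fcrit, n_reps = config$n_reps, config = config)
  if (trace)
    out$replicates <- data.frame(rep = seq_len(config$n_reps),
                                 f_stat = fstats, pc1_prop_var = prop1,
                                 exceeds = exceed)
  class(out) <- "power_result"
  out
}

#' @exportS3Method base::print
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Simulated-sampling power: %.3f (MC se %.3f, %d reps, F threshold %.2f)\n",
    x$power, x$mc_se, x$n_reps, x$f_crit))
  invisible(x)
}
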