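#' Per-laboratory study summaries for one outcome and arm
#'
#' Treats each laboratory's cohort as one replicate study. Because animals
#' are pair-housed and cagemates are correlated, the cage is the
#' independent unit: the study estimate is the mean of cage means and its
#' standard error is the SD of cage means over the square root of the
#' number of cages.
#'
#' @param dataset A phenotype dataset.
#' @param outcome Outcome column name.
#' @param arm `"STA"` or `"HET"`.
#' @return A data frame of class `study_estimates`, one row per retained
#'   laboratory: `lab`, `outcome`, `arm`, `estimate`, `se`, `n_animals`,
#'   `n_cages`. Laboratories with fewer than two cages, or with a zero SD
#'   of cage means, are excluded with a warning.
#' @export
study_summaries <- function(dataset, outcome, arm = c("STA", "HET")) {
  arm <- match.arg(arm)
  d <- dataset[dataset$design == arm & !is.na(dataset[[outcome]]), ,
               drop = FALSE]
  labs <- levels(droplevels(factor(d$lab)))
  rows <- lapply(labs, function(l) {
    dl <- d[d$lab == l, , drop = FALSE]
    cm <- tapply(dl[[outcome]], dl$cage_id, mean)
    cm <- cm[!is.na(cm)]
    if (length(cm) < 2L) {
      warning("lab ", l, ", outcome ", outcome, ", arm ", arm,
              ": fewer than 2 cages; excluded")
      return(NULL)
    }
    se <- stats::sd(cm) / sqrt(length(cm))
    if (se == 0) {
      warning("lab ", l, ", outcome ", outcome, ", arm ", arm,
              ": zero variance across cages, se undefined; excluded")
      return(NULL)
    }
    data.frame(lab = l, outcome = outcome, arm = arm,
               estimate = mean(cm), se = se,
               n_animals = nrow(dl), n_cages = length(cm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no laboratory provided two cages for ", outcome,
                         " (", arm, ")")
  rownames(out) <- NULL
  class(out) <- c("study_estimates", "data.frame")
  out
}

#' Random-effects meta-analysis across laboratories
#'
#' Pools the per-laboratory study estimates under a random-effects model.
#' `method = "DL"` uses the DerSimonian-Laird moment estimator
#' \eqn{\hat\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))}
#' with fixed-effect weights \eqn{w = 1/se^2}; `method = "REML"` maximizes
#' the restricted likelihood (via [metafor::rma()]). The pooled mean uses
#' weights \eqn{w^* = 1/(se^2 + \tau^2)} and a normal-quantile 95%
#' confidence interval; `knapp_hartung = TRUE` substitutes the
#' Knapp-Hartung t-based interval.
#'
#' @param studies A [study_summaries()] data frame (>= 2 studies).
#' @param method Between-study variance estimator.
#' @param level Confidence level.
#' @param knapp_hartung Use the Knapp-Hartung adjustment for the CI.
#' @return An object of class `meta_result`: `tau2`, `pooled_mean`,
#'   `ci_low`, `ci_high`, `weights`, `k`, `Q`, per-study `inside_ci`
#'   flags and `coverage` (their mean), plus the input studies.
#' @export
random_effects_meta <- function(studies, method = c("DL", "REML"),
                                level = 0.95, knapp_hartung = FALSE) {
  method <- match.arg(method)
  y <- studies$estimate; se <- studies$se
  k <- length(y)
  if (k < 2L)
    stop("random-effects meta-analysis needs at least 2 studies ",
         "(tau2 is undefined for a single study)")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  ybar_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar_fe)^2)
  if (method == "DL") {
    cval <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / cval)
  } else {
    rm <- metafor::rma(yi = y, sei = se, method = "REML")
    tau2 <- as.numeric(rm$tau2)
  }
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se_pooled <- sqrt(1 / sum(wstar))
  if (knapp_hartung) {
    q <- sum(wstar * (y - pooled)^2) / (k - 1)
    se_pooled <- sqrt(max(q, .Machine$double.eps) / sum(wstar))
    crit <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  } else {
    crit <- stats::qnorm(1 - (1 - level) / 2)
  }
  ci <- pooled + c(-1, 1) * crit * se_pooled
  inside <- y >= ci[1] & y <= ci[2]
  out <- list(outcome = studies$outcome[1], arm = studies$arm[1],
              k = k, method = method, tau2 = tau2, Q = Q,
              pooled_mean = pooled, se_pooled = se_pooled,
              ci_low = ci[1], ci_high = ci[2], level = level,
              weights = wstar, inside_ci = inside,
              coverage = mean(inside), studies = studies,
              knapp_hartung = knapp_hartung)
  class(out) <- "meta_result"
  out
}

#' @exportS3Method base::print
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s), %s / %s: k = %d\n",
              x$method, x$outcome, x$arm, x$k))
  cat(sprintf("  pooled %.4g [%.4g, %.4g], tau2 = %.4g, coverage %d/%d\n",
              x$pooled_mean, x$ci_low, x$ci_high, x$tau2,
              sum(x$inside_ci), x$k))
  invisible(x)
}

#' Coverage probability of study estimates
#'
#' Fraction of per-laboratory study estimates lying inside the pooled 95%
#' confidence interval of the meta-analytic mean — the replicability
#' statistic compared between design arms.
#'
#' @param meta A [random_effects_meta()] result.
#' @return Scalar in `[0, 1]`.
#' @export
coverage_probability <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  mean(meta$inside_ci)
}

#' Meta-analyses for every outcome and arm
#'
#' @param dataset A phenotype dataset.
#' @param outcomes Outcome columns.
#' @param method Passed to [random_effects_meta()].
#' @return A list of class `meta_set`: `metas` (list of `meta_result`),
#'   and `coverage_summary` (per-arm mean and SD of coverage across
#'   outcomes).
#' @export
meta_all <- function(dataset, outcomes = default_outcomes(),
                     method = "DL") {
  outcomes <- intersect(outcomes, names(dataset))
  metas <- list()
  for (arm in c("STA", "HET")) for (v in outcomes) {
    st <- study_summaries(dataset, v, arm)
    metas[[paste(v, arm, sep = ".")]] <-
      random_effects_meta(st, method = method)
  }
  cov <- data.frame(
    outcome = vapply(metas, `[[`, "", "outcome"),
    arm = vapply(metas, `[[`, "", "arm"),
    coverage = vapply(metas, coverage_probability, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(cov) <- NULL
  summ <- do.call(rbind, lapply(split(cov, cov$arm), function(d)
    data.frame(arm = d$arm[1], mean_coverage = mean(d$coverage),
               sd_coverage = stats::sd(d$coverage),
               n_outcomes = nrow(d), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(metas = metas, coverage = cov, coverage_summary = summ),
            class = "meta_set")
}

#' Standardized deviations of study estimates from the pooled mean
#'
#' The "dance around the means" response: for each outcome, laboratory and
#' arm, the absolute standardized deviation
#' `|estimate - pooled| / se` of the study estimate from its meta-analytic
#' pooled mean.
#'
#' @param meta_set A [meta_all()] result.
#' @return Data frame with columns `outcome`, `lab`, `arm`, `deviation`.
#' @export
deviation_table <- function(meta_set) {
  stopifnot(inherits(meta_set, "meta_set"))
  do.call(rbind, lapply(meta_set$metas, function(m) {
    data.frame(outcome = m$outcome, lab = m$studies$lab, arm = m$arm,
               deviation = abs(m$studies$estimate - m$pooled_mean) /
                 m$studies$se,
               stringsAsFactors = FALSE)
  }))
}

#' Share of the "dance around the means" explained by the design arm
#'
#' Mixed model of the standardized deviations with design arm as fixed
#' effect and crossed random intercepts for outcome and laboratory; the
#' reported quantity is the arm's marginal R-squared — how much of the
#' study-to-study scatter the choice of STA vs HET design explains.
#'
#' @param deviations A [deviation_table()] data frame.
#' @return A list with `r2_arm`, variance components
#'   (`var_arm`, `var_outcome`, `var_lab`, `var_resid`) and the fitted
#'   model.
#' @export
design_effect_model <- function(deviations) {
  need <- c("outcome", "lab", "arm", "deviation")
  stopifnot(all(need %in% names(deviations)))
  d <- deviations
  if (length(unique(d$outcome)) < 2L || length(unique(d$lab)) < 2L)
    stop("need at least two outcomes and two laboratories for the crossed ",
         "random effects")
  d$arm <- factor(d$arm, levels = c("STA", "HET"))
  if (stats::var(d$deviation) == 0)
    return(list(r2_arm = 0, var_arm = 0, var_outcome = 0, var_lab = 0,
                var_resid = 0, model = NULL))
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    check.conv.grad = lme4::.makeCC(action = "ignore", tol = 2e-3),
    check.conv.hess = lme4::.makeCC(action = "ignore", tol = 1e-6))
  fit <- suppressMessages(
    lmerTest::lmer(deviation ~ arm + (1 | outcome) + (1 | lab),
                   data = d, REML = TRUE, control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_out <- vc$vcov[vc$grp == "outcome"]
  v_lab <- vc$vcov[vc$grp == "lab"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  var_arm <- mean((drop(X %*% lme4::fixef(fit)) -
                   mean(drop(X %*% lme4::fixef(fit))))^2)
  total <- var_arm + v_out + v_lab + v_res
  list(r2_arm = var_arm / total, var_arm = var_arm,
       var_outcome = v_out, var_lab = v_lab, var_resid = v_res,
       model = fit)
}

#' Tidy forest-plot table
#'
#' One row per study plus one pooled row per outcome and arm, with
#' estimates and 95% confidence limits, ready for forest plotting.
#'
#' @param meta_set A [meta_all()] result (or a list of `meta_result`s).
#' @return Data frame with columns `outcome`, `arm`, `study`, `estimate`,
#'   `ci_low`, `ci_high`, `weight`, `n_animals`, `pooled` (logical).
#' @export
forest_export <- function(meta_set) {
  metas <- if (inherits(meta_set, "meta_set")) meta_set$metas else meta_set
  out <- do.call(rbind, lapply(metas, function(m) {
    crit <- stats::qnorm(1 - (1 - m$level) / 2)
    st <- data.frame(
      outcome = m$outcome, arm = m$arm, study = m$studies$lab,
      estimate = m$studies$estimate,
      ci_low = m$studies$estimate - crit * m$studies$se,
      ci_high = m$studies$estimate + crit * m$studies$se,
      weight = m$weights / sum(m$weights),
      n_animals = m$studies$n_animals, pooled = FALSE,
      stringsAsFactors = FALSE)
    rbind(st, data.frame(
      outcome = m$outcome, arm = m$arm, study = "pooled",
      estimate = m$pooled_mean, ci_low = m$ci_low, ci_high = m$ci_high,
      weight = 1, n_animals = sum(m$studies$n_animals), pooled = TRUE,
      stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
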