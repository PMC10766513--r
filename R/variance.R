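#' MANOVA with Pillai-trace effect sizes
#'
#' Multivariate analysis of variance of the outcome battery on test
#' laboratory, breeding site and their interaction, using Type II sums of
#' products (each main effect adjusted for the other, the interaction
#' adjusted for both). The multivariate effect size is
#' \eqn{\eta^2 = V/s} where \eqn{V} is the Pillai trace and
#' \eqn{s = \min(p, \mathrm{df}_h)}.
#'
#' Rows with any missing outcome are dropped (listwise deletion).
#'
#' @param dataset A phenotype dataset.
#' @param outcomes Outcome columns to include.
#' @param lab,breeder Names of the two factor columns.
#' @return A data frame of class `pillai_result` with one row per effect:
#'   Pillai `V`, approximate `F`, `df1`, `df2`, `p.value`, `eta2`, `s`,
#'   plus attributes `n` (complete cases) and `p` (outcomes).
#' @examples
#' d <- simulate_outcomes(allocate_design(design_spec()), default_profile())
#' manova_pillai(d)
#' @export
manova_pillai <- function(dataset, outcomes = default_outcomes(),
                          lab = "lab", breeder = "breeder") {
  outcomes <- intersect(outcomes, names(dataset))
  keep <- stats::complete.cases(dataset[outcomes])
  d <- dataset[keep, , drop = FALSE]
  Y <- as.matrix(d[outcomes])
  p <- ncol(Y); n <- nrow(Y)
  fl <- droplevels(factor(d[[lab]])); fb <- droplevels(factor(d[[breeder]]))
  if (nlevels(fl) < 2L && nlevels(fb) < 2L)
    stop("need at least two levels of laboratory or breeding site")
  rss <- function(form, data) {
    fit <- stats::lm(form, data = data)
    list(ssp = crossprod(stats::residuals(fit)),
         df = n - fit$rank, rank = fit$rank)
  }
  dd <- data.frame(fl = fl, fb = fb)
  dd$Y <- Y
  if (nlevels(fl) < 2L || nlevels(fb) < 2L) {
    # single-factor reduction: one effect, H = SS(factor), E = residual SSP
    fac <- if (nlevels(fl) >= 2L) "fl" else "fb"
    nm <- if (fac == "fl") lab else breeder
    m_0 <- rss(Y ~ 1, dd)
    m_f <- rss(stats::as.formula(paste("Y ~", fac)), dd)
    effects <- list(list(H = m_0$ssp - m_f$ssp, df = m_f$rank - m_0$rank))
    names(effects) <- nm
    m_ful <- m_f
    E <- m_ful$ssp
  } else {
  m_l   <- rss(Y ~ fl, dd)
  m_b   <- rss(Y ~ fb, dd)
  m_lb  <- rss(Y ~ fl + fb, dd)
  m_ful <- rss(Y ~ fl * fb, dd)
  E <- m_ful$ssp
  effects <- list(
    lab = list(H = m_b$ssp - m_lb$ssp, df = m_lb$rank - m_b$rank),
    breeder = list(H = m_l$ssp - m_lb$ssp, df = m_lb$rank - m_l$rank),
    `lab:breeder` = list(H = m_lb$ssp - m_ful$ssp,
                         df = m_ful$rank - m_lb$rank))
  }
  if (m_ful$df <= 0) stop("no residual degrees of freedom")
  qE <- qr(E)
  if (qE$rank < p) {
    bad <- outcomes[qE$pivot[(qE$rank + 1):p]]
    stop("rank-deficient error matrix; offending outcome(s): ",
         paste(bad, collapse = ", "))
  }
  res <- do.call(rbind, lapply(names(effects), function(nm) {
    H <- effects[[nm]]$H; dfh <- effects[[nm]]$df
    V <- sum(diag(H %*% solve(H + E)))
    s <- min(p, dfh)
    mm <- (abs(dfh - p) - 1) / 2
    nn <- (m_ful$df - p - 1) / 2
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * nn + s + 1)
    Fstat <- (df2 / df1) * V / (s - V)
    data.frame(effect = nm, V = V, F = Fstat, df1 = df1, df2 = df2,
               p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
               s = s, eta2 = V / s, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "n") <- n; attr(res, "p") <- p
  attr(res, "df_error") <- m_ful$df
  class(res) <- c("pillai_result", "data.frame")
  res
}

#' Fit a mixed model with a cage random intercept
#'
#' REML fit of `outcome ~ fixed + (1 | cage)` via [lmerTest::lmer()]. The
#' variance components are then refined by solving the restricted-likelihood
#' score equation in the cage-to-residual variance ratio exactly, so that
#' balanced designs reproduce the closed-form expected-mean-squares
#' estimators to near machine precision. A fit is flagged singular when the
#' cage variance is estimated at the zero boundary.
#'
#' @param dataset A phenotype dataset.
#' @param outcome Name of the response column.
#' @param fixed One-sided formula for the fixed effects
#'   (default `~ breeder * lab`).
#' @param cage Name of the cage grouping column.
#' @return An object of class `lmm_fit`: the `merMod` model plus
#'   `sigma2_cage`, `sigma2_resid`, `loglik` (REML), `singular`,
#'   `coefficients`, `n`, `n_cages`.
#' @export
fit_lmm <- function(dataset, outcome, fixed = ~ breeder * lab,
                    cage = "cage_id") {
  keep <- !is.na(dataset[[outcome]])
  d <- droplevels(dataset[keep, , drop = FALSE])
  fixed_terms <- attr(stats::terms(fixed), "term.labels")
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  form <- stats::as.formula(
    paste(outcome, "~", rhs, "+ (1 |", cage, ")"))
  # sum-to-zero contrasts so per-factor fitted components are centered and
  # the semi-partial variance decomposition reflects the factors themselves
  fvars <- all.vars(fixed)
  for (v in fvars) {
    if (!is.numeric(d[[v]])) {
      d[[v]] <- droplevels(factor(d[[v]]))
      stats::contrasts(d[[v]]) <- stats::contr.sum(nlevels(d[[v]]))
    }
  }
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = d, REML = TRUE, control = ctrl)))
  n <- nrow(d)
  rank_x <- length(lme4::fixef(fit))
  if (n <= rank_x) stop("fewer observations than fixed-effect parameters")
  # refine the variance ratio by solving the REML score equation exactly:
  # root finding is not limited by the flatness of the profiled criterion
  sol <- reml_ratio_root(lme4::getME(fit, "y"), lme4::getME(fit, "X"),
                         factor(d[[cage]]))
  sigma2_resid <- sol$sigma2_resid
  if (sigma2_resid <= 0) stop("zero residual variance; model is degenerate")
  sigma2_cage <- sol$lambda * sigma2_resid
  theta <- sqrt(sol$lambda)
  singular <- sigma2_cage < 1e-10 * sigma2_resid
  cages_per_animal <- table(d[[cage]])
  structure(list(
    model = fit, formula = form, outcome = outcome,
    sigma2_cage = sigma2_cage, sigma2_resid = sigma2_resid,
    theta = theta, loglik = as.numeric(stats::logLik(fit)),
    singular = singular,
    coefficients = lme4::fixef(fit), n = n,
    n_cages = length(cages_per_animal),
    data = d, cage = cage), class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat("Cage random-intercept model:",
      deparse(x$formula), "\n")
  cat(sprintf("  sigma2_cage = %.5g, sigma2_resid = %.5g%s\n",
              x$sigma2_cage, x$sigma2_resid,
              if (x$singular) "  [singular/boundary fit]" else ""))
  cat(sprintf("  n = %d animals in %d cages, REML logLik = %.3f\n",
              x$n, x$n_cages, x$loglik))
  invisible(x)
}

#' Satterthwaite effective degrees of freedom
#'
#' Effective degrees of freedom for a fixed-effect contrast in a cage
#' random-intercept model, `df = 2 Var(c'b)^2 / Var(Var(c'b))`, with the
#' denominator from the delta method over the REML variance-component
#' estimates. With a zero cage variance the model reduces to ordinary least
#' squares and the residual degrees of freedom are returned.
#'
#' @param fit An [fit_lmm()] object.
#' @param contrast Numeric contrast vector over the fixed coefficients;
#'   default tests the first non-intercept coefficient (or the intercept in
#'   an intercept-only model).
#' @return Effective degrees of freedom (positive scalar).
#' @export
satterthwaite_df <- function(fit, contrast = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  k <- length(fit$coefficients)
  if (is.null(contrast)) {
    contrast <- numeric(k)
    contrast[if (k > 1L) 2L else 1L] <- 1
  }
  if (length(contrast) != k)
    stop("contrast length must match the ", k, " fixed coefficients")
  ct <- lmerTest::contest1D(fit$model, contrast, ddf = "Satterthwaite")
  df <- ct$df
  if (!is.finite(df) || df <= 0) {
    warning("non-positive Satterthwaite curvature; using residual df")
    df <- fit$n - k
  }
  df
}

#' Per-factor explained-variance proportions
#'
#' Decomposes the total variance implied by a cage random-intercept model
#' into shares for each fixed factor (semi-partial: variance of that
#' factor's fitted component over the observed cells), the cage and
#' residual components, and the combined fixed-effects share, which equals
#' the marginal R-squared in the sense of Nakagawa.
#'
#' Because the variance of a fitted component overestimates the variance of
#' the true component by the sampling noise of the coefficients, each
#' component variance is bias-corrected by the trace of the coefficient
#' covariance against the centered design cross-product
#' (`adjust = FALSE` gives the plain plug-in shares).
#'
#' @param fit An [fit_lmm()] object.
#' @param adjust Apply the finite-sample bias correction (default).
#' @return A list with `per_term` (named shares), `combined`
#'   (marginal R-squared), `cage`, `residual`, and `total_check`
#'   (combined + cage + residual, equal to 1 by construction).
#' @export
explained_variance <- function(fit, adjust = TRUE) {
  stopifnot(inherits(fit, "lmm_fit"))
  X <- stats::model.matrix(fit$model)
  beta <- fit$coefficients
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit$model), "term.labels")
  n <- nrow(X)
  vc <- as.matrix(stats::vcov(fit$model))
  comp_var <- function(cols) {
    Xc <- sweep(X[, cols, drop = FALSE], 2,
                colMeans(X[, cols, drop = FALSE]))
    v <- mean((drop(Xc %*% beta[cols]))^2)
    if (adjust) v <- max(0, v - sum(vc[cols, cols] * crossprod(Xc)) / n)
    v
  }
  var_fixed <- comp_var(seq_along(beta))
  total <- var_fixed + fit$sigma2_cage + fit$sigma2_resid
  per_term <- vapply(seq_along(labels), function(t)
    comp_var(which(asgn == t)) / total, numeric(1))
  names(per_term) <- labels
  combined <- var_fixed / total
  list(per_term = per_term, combined = combined,
       cage = fit$sigma2_cage / total,
       residual = fit$sigma2_resid / total,
       total_check = combined + fit$sigma2_cage / total +
         fit$sigma2_resid / total)
}

#' Between-laboratory variance share per design arm
#'
#' For one design arm, fits for each outcome a mixed model with laboratory
#' as the only fixed factor and cage as random intercept, and reports the
#' laboratory marginal R-squared — the share of variance attributable to
#' the test laboratory.
#'
#' @param dataset A phenotype dataset.
#' @param design_arm `"STA"` or `"HET"`.
#' @param outcomes Outcome columns.
#' @return A list with `per_outcome` (data frame of outcome and `r2_lab`),
#'   `mean`, and `range`.
#' @export
between_lab_variance <- function(dataset, design_arm = c("STA", "HET"),
                                 outcomes = default_outcomes()) {
  design_arm <- match.arg(design_arm)
  d <- dataset[dataset$design == design_arm, , drop = FALSE]
  if (length(unique(d$lab)) < 2L) stop("need at least two laboratories")
  outcomes <- intersect(outcomes, names(d))
  r2 <- vapply(outcomes, function(v) {
    f <- fit_lmm(d, v, fixed = ~ lab)
    explained_variance(f)$combined
  }, numeric(1))
  list(per_outcome = data.frame(outcome = outcomes, r2_lab = unname(r2),
                                stringsAsFactors = FALSE),
       mean = mean(r2), range = range(r2), arm = design_arm)
}

# REML score root for the single-random-intercept model y = Xb + Zu + e.
# lambda = sigma2_group / sigma2_resid; V = I + lambda ZZ'. Uses the
# Woodbury identity through group sums, so no n x n matrix is formed.
# The restricted-likelihood derivative in lambda is
#   0.5 * (y'P ZZ' P y / s2 - tr(P ZZ')),  s2 = y'Py / (n - p),
# which is monotone decreasing through its root; the boundary lambda = 0 is
# returned when the score is already nonpositive there.
reml_ratio_root <- function(y, X, group) {
  n <- length(y); p <- ncol(X)
  nj <- as.vector(table(group))
  Zty <- rowsum(y, group)
  ZtX <- rowsum(X, group)
  eval_at <- function(lambda) {
    cj <- lambda / (1 + lambda * nj)
    # Vi M = M - Z diag(cj) Z'M for any M
    u <- y - (cj * Zty)[as.integer(group)]
    A <- X - (cj * ZtX)[as.integer(group), , drop = FALSE]
    G <- crossprod(X, A)
    beta <- solve(G, crossprod(A, y))
    w <- u - A %*% beta                       # w = P y
    s2 <- sum(y * w) / (n - p)
    Ztw <- rowsum(as.vector(w), group)
    quad <- sum(Ztw^2)
    B <- (1 - cj * nj) * ZtX                  # Z' Vi X
    tr <- sum(nj * (1 - cj * nj)) - sum((B %*% solve(G)) * B)
    list(score = quad / s2 - tr, s2 = s2, beta = beta)
  }
  e0 <- eval_at(0)
  if (!is.finite(e0$score) || e0$score <= 1e-8 * n)
    return(list(lambda = 0, sigma2_resid = e0$s2, beta = e0$beta))
  hi <- 1
  while (eval_at(hi)$score > 0 && hi < 1e8) hi <- hi * 4
  if (hi >= 1e8)
    return(list(lambda = hi, sigma2_resid = eval_at(hi)$s2,
                beta = eval_at(hi)$beta))
  root <- stats::uniroot(function(l) eval_at(l)$score, c(0, hi),
                         tol = 1e-14)$root
  er <- eval_at(root)
  list(lambda = root, sigma2_resid = er$s2, beta = er$beta)
}
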