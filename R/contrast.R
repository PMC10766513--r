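#' Two-group Levene / Brown-Forsythe test for equal variances
#'
#' One-way ANOVA F test on absolute deviations from the group center;
#' median centering (the Brown-Forsythe variant, default) is robust to
#' skewed outcomes such as blood chemistry. The statistic is referred to
#' `F(1, n - 2)`.
#'
#' @param group_a,group_b Numeric vectors; missing values dropped.
#' @param center `"median"` (default) or `"mean"`.
#' @return A list with `statistic`, `df`, `p.value`, `center`. When either
#'   group is constant the variance comparison is undefined and `statistic`
#'   and `p.value` are `NA` (with a warning), except that two identical
#'   constant groups give statistic 0 and p 1.
#' @export
levene_test <- function(group_a, group_b, center = c("median", "mean")) {
  center <- match.arg(center)
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 non-missing values per group")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("constant group: Levene statistic undefined")
    return(list(statistic = NA_real_, df = c(1L, n - 2L),
                p.value = NA_real_, center = center))
  }
  cfun <- if (center == "median") stats::median else mean
  za <- abs(a - cfun(a)); zb <- abs(b - cfun(b))
  zbar <- (sum(za) + sum(zb)) / n
  ssb <- n1 * (mean(za) - zbar)^2 + n2 * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw == 0)   # all deviations equal within each group
    return(list(statistic = if (ssb == 0) 0 else Inf,
                df = c(1L, n - 2L),
                p.value = if (ssb == 0) 1 else 0, center = center))
  stat <- (ssb / 1) / (ssw / (n - 2))
  list(statistic = stat, df = c(1L, n - 2L),
       p.value = stats::pf(stat, 1, n - 2, lower.tail = FALSE),
       center = center)
}

#' All within-laboratory HET-vs-STA variance contrasts
#'
#' For every laboratory and outcome, compares the within-cohort standard
#' deviation of the heterogenized (HET) and standardized (STA) arms:
#' SD ratio (HET over STA), Levene test, raw and Bonferroni-adjusted
#' significance at level `alpha`.
#'
#' @param dataset A phenotype dataset with both arms in every laboratory.
#' @param alpha Significance threshold (per contrast).
#' @param center Levene centering, see [levene_test()].
#' @param outcomes Outcome columns.
#' @return A list of class `contrast_result` with `contrasts` (one row per
#'   lab x outcome) and `summary`: `m` contrasts, counts of ratios above /
#'   below / equal to 1 (ties counted as "not larger" and flagged),
#'   significant counts raw and Bonferroni, `alpha`,
#'   `alpha_bonferroni = alpha/m`, and `expected_false_positives = m * alpha`.
#' @export
contrast_all <- function(dataset, alpha = 0.05, center = "median",
                         outcomes = default_outcomes()) {
  outcomes <- intersect(outcomes, names(dataset))
  labs <- levels(droplevels(factor(dataset$lab)))
  rows <- list()
  for (l in labs) {
    dl <- dataset[dataset$lab == l, , drop = FALSE]
    for (v in outcomes) {
      het <- dl[[v]][dl$design == "HET"]; het <- het[!is.na(het)]
      sta <- dl[[v]][dl$design == "STA"]; sta <- sta[!is.na(sta)]
      if (length(het) < 3L || length(sta) < 3L) {
        warning("lab ", l, ", outcome ", v,
                ": an arm has fewer than 3 values; contrast skipped")
        next
      }
      lt <- levene_test(het, sta, center = center)
      rows[[length(rows) + 1L]] <- data.frame(
        lab = l, outcome = v,
        sd_het = stats::sd(het), sd_sta = stats::sd(sta),
        ratio = stats::sd(het) / stats::sd(sta),
        n_het = length(het), n_sta = length(sta),
        levene_stat = lt$statistic, p = lt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  m <- nrow(contrasts)
  alpha_b <- alpha / m
  contrasts$significant_raw <- !is.na(contrasts$p) & contrasts$p < alpha
  contrasts$significant_bonferroni <- !is.na(contrasts$p) &
    contrasts$p < alpha_b
  out <- list(
    contrasts = contrasts,
    summary = list(
      m = m,
      n_ratio_larger = sum(contrasts$ratio > 1),
      n_ratio_smaller = sum(contrasts$ratio < 1),
      n_ratio_tied = sum(contrasts$ratio == 1),
      n_significant_raw = sum(contrasts$significant_raw),
      n_significant_bonferroni = sum(contrasts$significant_bonferroni),
      alpha = alpha, alpha_bonferroni = alpha_b,
      expected_false_positives = m * alpha,
      center = center))
  class(out) <- "contrast_result"
  out
}

#' @exportS3Method base::print
print.contrast_result <- function(x, ...) {
  s <- x$summary
  cat(s$m, "HET-vs-STA variance contrasts (", s$center, "centering )\n")
  cat("  SD ratio > 1 in", s$n_ratio_larger, "cases, < 1 in",
      s$n_ratio_smaller,
      if (s$n_ratio_tied > 0) paste0("(", s$n_ratio_tied, " tied)") else "",
      "\n")
  cat(sprintf("  significant: %d raw (alpha = %g, expected false positives %.1f), %d after Bonferroni (alpha' = %.2g)\n",
              s$n_significant_raw, s$alpha, s$expected_false_positives,
              s$n_significant_bonferroni, s$alpha_bonferroni))
  invisible(x)
}

#' Fisher's method for combining independent p-values
#'
#' \eqn{\chi^2 = -2 \sum \ln p_i} on \eqn{2k} degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return A list with `chi2`, `df`, `combined_p`, `k`.
#' @export
fisher_combine <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values to combine")
  if (any(p <= 0))
    stop("p-values must be in (0, 1]; clip zero p-values ",
         "(e.g. to .Machine$double.xmin) before combining")
  if (any(p > 1)) stop("p-values must be in (0, 1]")
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df,
       combined_p = stats::pchisq(chi2, df, lower.tail = FALSE),
       k = length(p))
}

#' Combine per-laboratory variance contrasts per outcome
#'
#' Applies [fisher_combine()] to the Levene p-values of each outcome across
#' the laboratories, yielding one combined variance-equality measure per
#' outcome.
#'
#' @param contrast_result A [contrast_all()] result.
#' @return Data frame with one row per outcome: `k`, `chi2`, `df`,
#'   `combined_p`.
#' @export
contrast_combined <- function(contrast_result) {
  stopifnot(inherits(contrast_result, "contrast_result"))
  ct <- contrast_result$contrasts
  out <- do.call(rbind, lapply(split(ct, ct$outcome), function(d) {
    fc <- fisher_combine(d$p)
    data.frame(outcome = d$outcome[1], k = fc$k, chi2 = fc$chi2,
               df = fc$df, combined_p = fc$combined_p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[match(unique(ct$outcome), out$outcome), , drop = FALSE]
}
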