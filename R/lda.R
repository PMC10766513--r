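#' Fisher linear discriminant analysis of the outcome battery
#'
#' Fits an LDA with breeding site (or test laboratory) as the class label
#' and the outcomes as predictors, via [MASS::lda()] with equal class
#' priors. Rows with any missing outcome are dropped. Eigenvalues of the
#' between- over within-class scatter give the proportion of trace per
#' discriminant; because the discriminants standardize to unit within-class
#' variance, results are invariant to affine rescaling of any input column.
#'
#' @param dataset A phenotype dataset.
#' @param label Name of the class column (`"breeder"` or `"lab"`).
#' @param outcomes Predictor columns.
#' @return An object of class `lda_fit`: the `MASS::lda` model,
#'   `eigenvalues`, `proportion_of_trace`, `n`, `classes`, and the
#'   complete-case training data.
#' @export
fit_lda <- function(dataset, label = "breeder",
                    outcomes = default_outcomes()) {
  outcomes <- intersect(outcomes, names(dataset))
  keep <- stats::complete.cases(dataset[outcomes]) & !is.na(dataset[[label]])
  d <- dataset[keep, , drop = FALSE]
  g <- droplevels(factor(d[[label]]))
  if (nlevels(g) < 2L) stop("need at least two classes")
  X <- as.matrix(d[outcomes])
  # reject predictors that are constant within every class or collinear
  within_sd <- vapply(outcomes, function(v)
    max(tapply(d[[v]], g, stats::sd)), numeric(1))
  if (any(within_sd == 0))
    stop("singular within-class scatter; constant outcome(s): ",
         paste(outcomes[within_sd == 0], collapse = ", "))
  Xc <- X - rowsum(X, g)[g, ] / as.vector(table(g))[g]
  qrW <- qr(Xc)
  if (qrW$rank < ncol(X))
    stop("singular within-class scatter; collinear outcome(s): ",
         paste(outcomes[qrW$pivot[(qrW$rank + 1):ncol(X)]], collapse = ", "))
  k <- nlevels(g)
  model <- MASS::lda(X, grouping = g, prior = rep(1 / k, k))
  ev <- model$svd^2
  structure(list(model = model, label = label, outcomes = outcomes,
                 classes = levels(g), n = nrow(d),
                 eigenvalues = ev,
                 proportion_of_trace = ev / sum(ev),
                 training = d), class = "lda_fit")
}

#' @exportS3Method base::print
print.lda_fit <- function(x, ...) {
  cat("LDA by", x$label, "(", length(x$classes), "classes,", x$n, "cases )\n")
  cat("  proportion of trace:",
      paste(sprintf("%.3f", x$proportion_of_trace), collapse = " "), "\n")
  invisible(x)
}

#' Classify cases and report the correct-classification rate
#'
#' Assigns each case to the class with the nearest centroid in
#' Mahalanobis distance under the pooled within-class covariance and equal
#' priors. `method = "resubstitution"` scores the training data;
#' `method = "loo"` uses leave-one-out cross-validation.
#'
#' @param fit An [fit_lda()] object.
#' @param newdata Optional dataset to classify (must contain the training
#'   outcome columns); ignored for `method = "loo"`.
#' @param method Validation mode.
#' @return A list with `predicted`, `actual`, `rate`, `chance_rate`
#'   (`1/k`), `confusion` (true class x predicted), `method` and `scores`
#'   (discriminant coordinates plus a match flag; `NULL` for `"loo"`).
#' @export
classify_lda <- function(fit, newdata = NULL,
                         method = c("resubstitution", "loo")) {
  stopifnot(inherits(fit, "lda_fit"))
  method <- match.arg(method)
  if (method == "loo") {
    d <- fit$training
    g <- droplevels(factor(d[[fit$label]]))
    k <- nlevels(g)
    cv <- MASS::lda(as.matrix(d[fit$outcomes]), grouping = g,
                    prior = rep(1 / k, k), CV = TRUE)
    pred <- cv$class
    actual <- g
    scores <- NULL
  } else {
    d <- if (is.null(newdata)) fit$training else newdata
    miss <- setdiff(fit$outcomes, names(d))
    if (length(miss))
      stop("newdata lacks outcome column(s): ", paste(miss, collapse = ", "))
    keep <- stats::complete.cases(d[fit$outcomes]) & !is.na(d[[fit$label]])
    d <- d[keep, , drop = FALSE]
    pr <- stats::predict(fit$model, as.matrix(d[fit$outcomes]))
    pred <- pr$class
    actual <- factor(d[[fit$label]], levels = fit$classes)
    scores <- as.data.frame(pr$x)
    scores$actual <- actual
    scores$predicted <- pred
    scores$match <- pred == actual
  }
  confusion <- table(actual = actual, predicted = pred)
  list(predicted = pred, actual = actual,
       rate = mean(pred == actual),
       chance_rate = 1 / length(fit$classes),
       confusion = confusion, method = method, scores = scores)
}
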