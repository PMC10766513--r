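#' Per-outcome generative variance profile
#'
#' Specifies, for each outcome, a grand mean, a total standard deviation and
#' the fractions of total variance contributed by test laboratory, breeding
#' site, their interaction, cage and residual (animal-level) noise. The
#' fractions must be nonnegative and sum to one for each outcome.
#'
#' @param outcomes Character vector of outcome names.
#' @param grand_mean,total_sd Numeric, recycled over outcomes.
#' @param frac_lab,frac_breeder,frac_interaction,frac_cage,frac_residual
#'   Variance fractions, recycled over outcomes.
#' @return A data frame of class `variance_profile`, one row per outcome.
#' @seealso [default_profile()] for study-like defaults.
#' @export
variance_profile <- function(outcomes = default_outcomes(),
                             grand_mean = 0, total_sd = 1,
                             frac_lab = 0, frac_breeder = 0,
                             frac_interaction = 0, frac_cage = 0,
                             frac_residual = 1) {
  n <- length(outcomes)
  prof <- data.frame(
    outcome = as.character(outcomes),
    grand_mean = rep_len(grand_mean, n),
    total_sd = rep_len(total_sd, n),
    frac_lab = rep_len(frac_lab, n),
    frac_breeder = rep_len(frac_breeder, n),
    frac_interaction = rep_len(frac_interaction, n),
    frac_cage = rep_len(frac_cage, n),
    frac_residual = rep_len(frac_residual, n),
    stringsAsFactors = FALSE)
  fr <- as.matrix(prof[, c("frac_lab", "frac_breeder", "frac_interaction",
                           "frac_cage", "frac_residual")])
  if (any(fr < 0)) stop("variance fractions must be nonnegative")
  if (any(abs(rowSums(fr) - 1) > 1e-9))
    stop("variance fractions must sum to 1 (tolerance 1e-9) for every outcome")
  if (any(prof$total_sd < 0)) stop("total_sd must be nonnegative")
  class(prof) <- c("variance_profile", "data.frame")
  prof
}

#' Study-like default variance profile
#'
#' Variance fractions of the magnitude seen in multi-laboratory mouse
#' phenotyping: laboratory 0.15, breeding site 0.04, lab-by-breeder
#' interaction 0.11, cage 0.10, residual 0.60, identical across the 14
#' outcomes, on a standardized scale (grand mean 0, total SD 1).
#'
#' @param outcomes Outcome names.
#' @return A [variance_profile()].
#' @export
default_profile <- function(outcomes = default_outcomes()) {
  variance_profile(outcomes,
                   frac_lab = 0.15, frac_breeder = 0.04,
                   frac_interaction = 0.11, frac_cage = 0.10,
                   frac_residual = 0.60)
}

# deterministic child seeds per pipeline stage, kept within 32-bit range
child_seed <- function(seed, stage) {
  offsets <- c(allocate = 101L, outcomes = 211L, missing = 307L,
               power = 401L, pipeline = 503L)
  (as.integer(seed) %% 2000000011L) + offsets[[stage]]
}

#' Simulate outcomes under a crossed random-effects model
#'
#' Fills the outcome columns of a roster with draws from
#' \deqn{y = \mu + a_{lab} + b_{breeder} + c_{lab \times breeder} + d_{cage} + e,}
#' where each effect is a zero-mean Gaussian with variance equal to the
#' outcome's variance fraction times its total variance, shared by all
#' animals at the same factor level. Outcomes are generated independently
#' unless `latent_cor > 0`, in which case a per-animal latent factor induces
#' a common residual correlation across outcomes (relevant for
#' discriminant-analysis structure).
#'
#' @param roster An [allocate_design()] roster.
#' @param profile A [variance_profile()] covering the roster's outcomes.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param latent_cor Residual correlation shared by all outcome pairs,
#'   in `[0, 1)`.
#' @return The roster with outcome columns filled; attributes
#'   `variance_profile` and `sim_seed` record the generating conditions.
#' @export
simulate_outcomes <- function(roster, profile, seed = 1L, latent_cor = 0) {
  stopifnot(inherits(roster, "animal_roster"),
            inherits(profile, "variance_profile"))
  if (latent_cor < 0 || latent_cor >= 1)
    stop("latent_cor must be in [0, 1)")
  spec <- attr(roster, "design_spec")
  vars <- spec$outcome_names
  missing_prof <- setdiff(vars, profile$outcome)
  if (length(missing_prof))
    stop("profile lacks outcomes: ", paste(missing_prof, collapse = ", "))
  n <- nrow(roster)
  lab_i <- as.integer(roster$lab)
  brd_i <- as.integer(roster$breeder)
  int_i <- (lab_i - 1L) * spec$n_breeders + brd_i
  cage_i <- match(roster$cage_id, unique(roster$cage_id))
  n_cage <- max(cage_i)

  set.seed(child_seed(seed, "outcomes"))
  latent <- if (latent_cor > 0) stats::rnorm(n) else NULL
  for (v in vars) {
    p <- profile[profile$outcome == v, ][1, ]
    s2 <- p$total_sd^2
    a <- stats::rnorm(spec$n_labs,    sd = sqrt(p$frac_lab * s2))
    b <- stats::rnorm(spec$n_breeders, sd = sqrt(p$frac_breeder * s2))
    cc <- stats::rnorm(spec$n_labs * spec$n_breeders,
                       sd = sqrt(p$frac_interaction * s2))
    d <- stats::rnorm(n_cage, sd = sqrt(p$frac_cage * s2))
    res_sd <- sqrt(p$frac_residual * s2)
    e <- if (is.null(latent)) stats::rnorm(n, sd = res_sd) else
      res_sd * (sqrt(latent_cor) * latent +
                sqrt(1 - latent_cor) * stats::rnorm(n))
    roster[[v]] <- p$grand_mean + a[lab_i] + b[brd_i] + cc[int_i] +
      d[cage_i] + e
  }
  attr(roster, "variance_profile") <- profile
  attr(roster, "sim_seed") <- as.integer(seed)
  roster
}

#' Missingness scheme for a simulated dataset
#'
#' Mirrors the three loss mechanisms of a multi-laboratory animal study:
#' whole animals lost (death or euthanasia), animals whose three EPM
#' outcomes are all lost (video-transfer failures among survivors), and
#' isolated single blood-chemistry values excluded for measurement error.
#'
#' @param n_animals_lost Animals removed entirely.
#' @param n_behavior_lost Surviving animals losing all three EPM outcomes.
#' @param n_assay_lost Isolated blood-chemistry values set missing.
#' @param per_lab_losses Optional integer vector: animals lost per lab
#'   (overrides uniform selection; must sum to `n_animals_lost`).
#' @param seed Integer seed for the random selection.
#' @return An object of class `missingness_spec`.
#' @seealso [study_missingness()] for the study preset.
#' @export
missingness_spec <- function(n_animals_lost = 0L, n_behavior_lost = 0L,
                             n_assay_lost = 0L, per_lab_losses = NULL,
                             seed = 1L) {
  n_animals_lost <- as.integer(n_animals_lost)
  n_behavior_lost <- as.integer(n_behavior_lost)
  n_assay_lost <- as.integer(n_assay_lost)
  if (n_animals_lost < 0L || n_behavior_lost < 0L || n_assay_lost < 0L)
    stop("missingness counts must be nonnegative")
  if (!is.null(per_lab_losses)) {
    per_lab_losses <- as.integer(per_lab_losses)
    if (sum(per_lab_losses) != n_animals_lost)
      stop("per_lab_losses must sum to n_animals_lost")
  }
  structure(list(n_animals_lost = n_animals_lost,
                 n_behavior_lost = n_behavior_lost,
                 n_assay_lost = n_assay_lost,
                 per_lab_losses = per_lab_losses,
                 seed = as.integer(seed)),
            class = "missingness_spec")
}

#' Study missingness preset
#'
#' Sixteen animals lost overall with the laboratory-specific loss pattern
#' 1/0/3/4/5/3, nine survivors losing their three EPM outcomes, and two
#' isolated blood-chemistry exclusions. On the default 324-animal design
#' this leaves 308 animals, 299 of them behaviorally complete, and
#' 4,283 non-missing outcome measures.
#'
#' @param seed Integer seed for the random selection.
#' @return A [missingness_spec()].
#' @export
study_missingness <- function(seed = 1L) {
  missingness_spec(n_animals_lost = 16L, n_behavior_lost = 9L,
                   n_assay_lost = 2L,
                   per_lab_losses = c(1L, 0L, 3L, 4L, 5L, 3L),
                   seed = seed)
}

#' Inject missingness into a simulated dataset
#'
#' Removes whole animals, blanks the EPM block for some survivors, and
#' blanks isolated blood-chemistry values, all selected uniformly at random
#' under the scheme's seed (or per lab when `per_lab_losses` is given).
#'
#' @param dataset A dataset from [simulate_outcomes()].
#' @param mspec A [missingness_spec()].
#' @return The reduced dataset; [dataset_accounting()] summarizes the result.
#' @export
inject_missingness <- function(dataset, mspec) {
  stopifnot(inherits(mspec, "missingness_spec"))
  n <- nrow(dataset)
  if (mspec$n_animals_lost + mspec$n_behavior_lost > n)
    stop("infeasible missingness: n_animals_lost + n_behavior_lost exceeds ",
         n, " animals")
  set.seed(child_seed(mspec$seed, "missing"))
  if (!is.null(mspec$per_lab_losses)) {
    labs <- levels(droplevels(factor(dataset$lab)))
    if (length(mspec$per_lab_losses) != length(labs))
      stop("per_lab_losses length (", length(mspec$per_lab_losses),
           ") does not match number of labs (", length(labs), ")")
    drop_idx <- unlist(lapply(seq_along(labs), function(l) {
      idx <- which(dataset$lab == labs[l])
      k <- mspec$per_lab_losses[l]
      if (k > length(idx)) stop("infeasible per-lab losses for ", labs[l])
      sample(idx, k)
    }))
  } else {
    drop_idx <- if (mspec$n_animals_lost > 0L)
      sample.int(n, mspec$n_animals_lost) else integer(0)
  }
  if (length(drop_idx)) dataset <- dataset[-drop_idx, , drop = FALSE]

  epm <- intersect(epm_outcomes(), names(dataset))
  if (mspec$n_behavior_lost > 0L) {
    if (length(epm) != 3L)
      stop("dataset lacks the three EPM outcome columns")
    beh <- sample.int(nrow(dataset), mspec$n_behavior_lost)
    dataset[beh, epm] <- NA_real_
  }
  if (mspec$n_assay_lost > 0L) {
    blood <- intersect(blood_outcomes(), names(dataset))
    cells <- expand.grid(row = seq_len(nrow(dataset)), col = blood,
                         stringsAsFactors = FALSE)
    ok <- !mapply(function(r, v) is.na(dataset[r, v]), cells$row, cells$col)
    cells <- cells[ok, , drop = FALSE]
    if (mspec$n_assay_lost > nrow(cells))
      stop("infeasible n_assay_lost: not enough non-missing blood values")
    pick <- cells[sample.int(nrow(cells), mspec$n_assay_lost), , drop = FALSE]
    for (i in seq_len(nrow(pick)))
      dataset[pick$row[i], pick$col[i]] <- NA_real_
  }
  rownames(dataset) <- NULL
  dataset
}

#' Dataset accounting summary
#'
#' Counts retained animals, cages, non-missing measures per outcome and in
#' total, behaviorally complete animals (all three EPM outcomes present),
#' and the allocation table of animals per laboratory, arm and breeder.
#'
#' @param dataset A phenotype dataset (simulated or read from CSV).
#' @param outcomes Outcome column names; defaults to the canonical 14 when
#'   present, otherwise every numeric column beyond the design columns.
#' @return A list of class `dataset_accounting`.
#' @export
dataset_accounting <- function(dataset, outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- intersect(default_outcomes(), names(dataset))
    if (!length(outcomes))
      outcomes <- setdiff(names(dataset)[vapply(dataset, is.numeric, TRUE)],
                          c("animal_id", "lab", "breeder", "design", "cage_id"))
  }
  nm <- vapply(outcomes, function(v) sum(!is.na(dataset[[v]])), integer(1))
  epm <- intersect(epm_outcomes(), outcomes)
  behav_complete <- if (length(epm))
    sum(stats::complete.cases(dataset[epm])) else NA_integer_
  out <- list(
    animals_retained = nrow(dataset),
    n_cages = length(unique(dataset$cage_id)),
    nonmissing_per_outcome = nm,
    total_nonmissing = sum(nm),
    behaviorally_complete = behav_complete,
    allocation = table(lab = dataset$lab, design = dataset$design))
  class(out) <- "dataset_accounting"
  out
}

#' @exportS3Method base::print
print.dataset_accounting <- function(x, ...) {
  cat("Animals retained:", x$animals_retained,
      " (behaviorally complete:", x$behaviorally_complete, ")\n")
  cat("Cages:", x$n_cages, "\n")
  cat("Non-missing measures:", x$total_nonmissing, "\n")
  print(x$allocation)
  invisible(x)
}

#' Estimate a generative variance profile from data
#'
#' Recovers the variance components of the crossed generative model for one
#' outcome by REML, treating laboratory, breeding site, their interaction
#' and cage all as random intercepts. This is the parameter-recovery
#' counterpart of [simulate_outcomes()]: on data simulated from a
#' [variance_profile()] the estimated fractions converge to the generating
#' ones. (The fixed-effect decomposition of [explained_variance()] answers
#' a different question and attributes interaction means partly to the main
#' effects.)
#'
#' @param dataset A phenotype dataset.
#' @param outcome Outcome column name.
#' @return A list with `components` (named variances for lab, breeder,
#'   interaction, cage, residual), `fractions` (components over their sum),
#'   and `total_var`.
#' @export
estimate_profile <- function(dataset, outcome) {
  d <- dataset[!is.na(dataset[[outcome]]), , drop = FALSE]
  d$.y <- d[[outcome]]
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    check.conv.grad = lme4::.makeCC(action = "ignore", tol = 2e-3),
    check.conv.hess = lme4::.makeCC(action = "ignore", tol = 1e-6))
  fit <- suppressMessages(lme4::lmer(
    .y ~ 1 + (1 | lab) + (1 | breeder) + (1 | lab:breeder) + (1 | cage_id),
    data = d, REML = TRUE, control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) vc$vcov[match(g, vc$grp)]
  comp <- c(lab = pick("lab"), breeder = pick("breeder"),
            interaction = pick("lab:breeder"), cage = pick("cage_id"),
            residual = pick("Residual"))
  list(components = comp, fractions = comp / sum(comp),
       total_var = sum(comp))
}
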