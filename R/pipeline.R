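pipeline_stages <- function() {
  c("simulate", "validate", "variance", "lda", "contrasts", "meta", "power")
}

#' Configuration for a full pipeline run
#'
#' @param input Path to a canonical-schema CSV, or `NULL` to simulate a
#'   dataset from `design`, `profile` and `missingness`.
#' @param stages Stages to run, a subset of
#'   `simulate, validate, variance, lda, contrasts, meta, power`.
#' @param design,profile,missingness Simulation conditions, used when
#'   `input` is `NULL`.
#' @param alpha Significance level for the variance contrasts.
#' @param levene_center Levene centering (`"median"` or `"mean"`).
#' @param tau2_method Between-study variance estimator (`"DL"` or
#'   `"REML"`).
#' @param lda_method LDA validation mode (`"resubstitution"` or `"loo"`).
#' @param power Optional [power_config()] for the power stage.
#' @param seed Root seed; per-stage child seeds are derived from it.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       stages = c("simulate", "validate", "variance", "lda",
                                  "contrasts", "meta"),
                       design = design_spec(), profile = default_profile(),
                       missingness = study_missingness(),
                       alpha = 0.05, levene_center = "median",
                       tau2_method = "DL", lda_method = "resubstitution",
                       power = NULL, seed = 1L, out_dir = tempfile("hetrep_")) {
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(pipeline_stages(), collapse = ", "), ")")
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input)
  structure(list(input = input, stages = stages, design = design,
                 profile = profile, missingness = missingness,
                 alpha = alpha, levene_center = levene_center,
                 tau2_method = tau2_method, lda_method = lda_method,
                 power = power, seed = as.integer(seed),
                 out_dir = out_dir), class = "run_config")
}

write_stage_table <- function(df, path, config_hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# hetrep %s config=%s",
                     as.character(utils::packageVersion("hetrep")),
                     config_hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

#' Run the full replicability pipeline
#'
#' Executes the configured stages in order — simulate (optional), validate,
#' variance decomposition, LDA classification, variance contrasts,
#' meta-analysis, power (optional) — writing each stage's tables as
#' tab-separated files under `out_dir` and a manifest with MD5 checksums.
#' Re-running with the same configuration and seed is bit-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: `manifest` (file, md5), per-stage
#'   `warnings`, dataset `accounting`, `seconds` per stage, `config`, and
#'   the in-memory stage `results`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(tools::md5sum(
    textConnection_write(config)), 1, 8)
  manifest <- character(0)
  warns <- list()
  secs <- numeric(0)
  results <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_stage_table(df, path, cfg_hash)
    manifest <<- c(manifest, path)
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    w <- character(0)
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        writeLines(paste("FAILED at stage", stage, ":", conditionMessage(e)),
                   file.path(config$out_dir, "FAILED"))
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
      }),
      warning = function(cnd) {
        w <<- c(w, conditionMessage(cnd))
        invokeRestart("muffleWarning")
      })
    warns[[stage]] <<- w
    secs[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  dataset <- NULL
  if ("simulate" %in% config$stages && is.null(config$input)) {
    dataset <- run_stage("simulate", function() {
      roster <- allocate_design(config$design, seed = config$seed)
      sim <- simulate_outcomes(roster, config$profile, seed = config$seed)
      ms <- config$missingness
      ms$seed <- config$seed
      d <- inject_missingness(sim, ms)
      write_phenotypes(d, file.path(config$out_dir, "dataset.csv"))
      manifest <<- c(manifest, file.path(config$out_dir, "dataset.csv"))
      d
    })
  } else if (!is.null(config$input)) {
    dataset <- read_phenotypes(config$input)
  }
  if (is.null(dataset))
    stop("no dataset: provide `input` or include the 'simulate' stage")
  outcomes <- intersect(default_outcomes(), names(dataset))

  acct <- NULL
  if ("validate" %in% config$stages) {
    acct <- run_stage("validate", function() {
      v <- validate_dataset(dataset, outcomes)
      if (length(v$problems))
        stop(paste(v$problems, collapse = "; "))
      a <- v$accounting
      emit(data.frame(metric = c("animals_retained", "n_cages",
                                 "total_nonmissing",
                                 "behaviorally_complete"),
                      value = c(a$animals_retained, a$n_cages,
                                a$total_nonmissing,
                                a$behaviorally_complete)),
           "accounting.tsv")
      a
    })
  }

  if ("variance" %in% config$stages) {
    results$variance <- run_stage("variance", function() {
      mp <- manova_pillai(dataset, outcomes)
      emit(as.data.frame(mp), "manova.tsv")
      uni <- do.call(rbind, lapply(outcomes, function(v) {
        f <- fit_lmm(dataset, v)
        ev <- explained_variance(f)
        at <- stats::anova(f$model, ddf = "Satterthwaite")
        data.frame(outcome = v,
                   share_breeder = ev$per_term[["breeder"]],
                   share_lab = ev$per_term[["lab"]],
                   share_interaction = ev$per_term[["breeder:lab"]],
                   share_cage = ev$cage, share_residual = ev$residual,
                   combined_r2 = ev$combined, singular = f$singular,
                   p_breeder = at["breeder", "Pr(>F)"],
                   p_lab = at["lab", "Pr(>F)"],
                   p_interaction = at["breeder:lab", "Pr(>F)"],
                   stringsAsFactors = FALSE)
      }))
      emit(uni, "univariate.tsv")
      bl <- do.call(rbind, lapply(c("STA", "HET"), function(a) {
        b <- between_lab_variance(dataset, a, outcomes)
        cbind(arm = a, b$per_outcome)
      }))
      emit(bl, "between_lab.tsv")
      list(manova = mp, univariate = uni, between_lab = bl)
    })
  }

  if ("lda" %in% config$stages) {
    results$lda <- run_stage("lda", function() {
      out <- list()
      for (lab in c("breeder", "lab")) {
        f <- fit_lda(dataset, lab, outcomes)
        cl <- classify_lda(f, method = config$lda_method)
        nd <- length(f$proportion_of_trace)
        emit(data.frame(ld = seq_len(nd),
                        proportion_of_trace = f$proportion_of_trace,
                        rate = cl$rate, chance_rate = cl$chance_rate,
                        method = cl$method),
             paste0("lda_", lab, ".tsv"))
        if (!is.null(cl$scores))
          emit(cl$scores, paste0("lda_", lab, "_scores.tsv"))
        out[[lab]] <- list(fit = f, classification = cl)
      }
      out
    })
  }

  if ("contrasts" %in% config$stages) {
    results$contrasts <- run_stage("contrasts", function() {
      ca <- contrast_all(dataset, alpha = config$alpha,
                         center = config$levene_center, outcomes = outcomes)
      emit(ca$contrasts, "contrasts.tsv")
      emit(contrast_combined(ca), "contrasts_combined.tsv")
      sdm <- stats::reshape(
        ca$contrasts[c("lab", "outcome", "ratio")],
        idvar = "outcome", timevar = "lab", direction = "wide")
      emit(sdm, "sd_ratio_matrix.tsv")
      ca
    })
  }

  if ("meta" %in% config$stages) {
    results$meta <- run_stage("meta", function() {
      ms <- meta_all(dataset, outcomes, method = config$tau2_method)
      meta_tab <- do.call(rbind, lapply(ms$metas, function(m)
        data.frame(outcome = m$outcome, arm = m$arm, k = m$k,
                   tau2 = m$tau2, pooled_mean = m$pooled_mean,
                   ci_low = m$ci_low, ci_high = m$ci_high,
                   coverage = m$coverage, stringsAsFactors = FALSE)))
      rownames(meta_tab) <- NULL
      emit(meta_tab, "meta.tsv")
      emit(ms$coverage_summary, "coverage.tsv")
      emit(forest_export(ms), "forest.tsv")
      dm <- design_effect_model(deviation_table(ms))
      emit(data.frame(r2_arm = dm$r2_arm, var_arm = dm$var_arm,
                      var_outcome = dm$var_outcome, var_lab = dm$var_lab,
                      var_resid = dm$var_resid), "design_effect.tsv")
      list(meta_set = ms, design_effect = dm)
    })
  }

  if ("power" %in% config$stages) {
    results$power <- run_stage("power", function() {
      pc <- if (is.null(config$power)) power_config(seed = config$seed)
            else config$power
      pr <- simulate_power(pc)
      emit(data.frame(power = pr$power, mc_se = pr$mc_se,
                      f_crit = pr$f_crit, n_reps = pr$n_reps,
                      n_sta = pc$n_sta, n_het = pc$n_het,
                      effect_mean = pc$effect_mean,
                      effect_sd = pc$effect_sd, alpha = pc$alpha,
                      seed = pc$seed), "power.tsv")
      pr
    })
  }

  man <- data.frame(file = basename(manifest),
                    md5 = unname(tools::md5sum(manifest)),
                    stringsAsFactors = FALSE)
  man_path <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  structure(list(manifest = man, warnings = warns, accounting = acct,
                 seconds = secs, seed = config$seed, config = config,
                 version = as.character(utils::packageVersion("hetrep")),
                 results = results),
            class = "run_report")
}

# hash the configuration by serializing its printable fields to text
textConnection_write <- function(config) {
  tf <- tempfile(fileext = ".txt")
  flat <- utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")]))
  writeLines(flat, tf)
  tf
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("hetrep pipeline run (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$accounting))
    cat("  animals:", x$accounting$animals_retained,
        "| non-missing measures:", x$accounting$total_nonmissing, "\n")
  for (s in names(x$seconds))
    cat(sprintf("  %-10s %6.2fs  %s\n", s, x$seconds[[s]],
                if (length(x$warnings[[s]]))
                  paste0("[", length(x$warnings[[s]]), " warning(s)]")
                else ""))
  cat("  files:", nrow(x$manifest), "written\n")
  invisible(x)
}

#' Recompute the headline study statistics from a deposited data file
#'
#' Runs the variance-decomposition, LDA, contrast and meta-analysis stages
#' on a phenotype CSV in the canonical schema and returns the headline
#' quantities (multivariate eta-squared per effect, LDA rates, per-arm
#' between-laboratory variance shares and coverage probabilities). Intended
#' for benchmarking against a deposited raw data file; it works equally on
#' synthetic datasets.
#'
#' @param path CSV path in the canonical schema.
#' @return A list with `eta2`, `lda_rates`, `between_lab`,
#'   `coverage_summary`, `contrast_summary`.
#' @export
study_benchmarks <- function(path) {
  if (!file.exists(path))
    stop("deposited data file not found: ", path,
         " (supply the raw study data in the canonical CSV schema)")
  d <- read_phenotypes(path)
  outcomes <- intersect(default_outcomes(), names(d))
  mp <- manova_pillai(d, outcomes)
  lda_rates <- vapply(c("breeder", "lab"), function(l)
    classify_lda(fit_lda(d, l, outcomes))$rate, numeric(1))
  bl <- vapply(c("STA", "HET"), function(a)
    between_lab_variance(d, a, outcomes)$mean, numeric(1))
  ms <- meta_all(d, outcomes)
  ca <- contrast_all(d, outcomes = outcomes)
  list(eta2 = stats::setNames(mp$eta2, mp$effect),
       lda_rates = lda_rates,
       between_lab = bl,
       coverage_summary = ms$coverage_summary,
       contrast_summary = ca$summary)
}
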