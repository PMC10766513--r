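#' Default outcome battery
#'
#' The 14 outcome variables measured on every animal: body weight, relative
#' adrenal weight, three elevated-plus-maze (EPM) measures, and nine blood
#' clinical-chemistry measures.
#'
#' @return Character vector of 14 outcome column names, in canonical order.
#' @export
default_outcomes <- function() {
  c("body_weight", "adrenal_weight_rel",
    "epm_distance", "epm_open_time", "epm_open_entries",
    "protein_total", "albumin", "globulin", "creatinine",
    "alt", "ast", "bilirubin", "glucose", "triglycerides")
}

#' Names of the elevated-plus-maze outcomes
#'
#' These three behavioral outcomes are lost together when a video recording
#' is lost, so missingness treats them as a block.
#'
#' @return Character vector of length 3.
#' @export
epm_outcomes <- function() {
  c("epm_distance", "epm_open_time", "epm_open_entries")
}

#' Names of the blood clinical-chemistry outcomes
#'
#' @return Character vector of length 9.
#' @export
blood_outcomes <- function() {
  c("protein_total", "albumin", "globulin", "creatinine",
    "alt", "ast", "bilirubin", "glucose", "triglycerides")
}

#' Multi-laboratory allocation scheme
#'
#' Describes how animals are allocated to test laboratories, breeding sites,
#' design arms and cages. In the standardized (STA) arm each laboratory's
#' whole cohort comes from a single, laboratory-specific breeding site; in
#' the heterogenized (HET) arm each laboratory receives equal numbers from
#' every other breeding site. Cagemates always share laboratory, breeding
#' site and design arm.
#'
#' @param n_labs Number of test laboratories.
#' @param n_breeders Number of breeding sites.
#' @param sta_n Animals per laboratory in the STA arm.
#' @param het_per_breeder Animals per non-home breeding site in the HET arm.
#' @param cage_size Animals per cage.
#' @param sta_breeder_map Integer vector of length `n_labs` mapping each lab
#'   to its STA breeding site; must be a bijection. Defaults to the identity
#'   pairing (lab i orders its STA cohort from breeder i).
#' @param outcome_names Ordered outcome labels.
#'
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' spec$total_animals  # 324
#' @export
design_spec <- function(n_labs = 6L, n_breeders = 6L, sta_n = 24L,
                        het_per_breeder = 6L, cage_size = 2L,
                        sta_breeder_map = NULL,
                        outcome_names = default_outcomes()) {
  n_labs <- as.integer(n_labs); n_breeders <- as.integer(n_breeders)
  sta_n <- as.integer(sta_n); het_per_breeder <- as.integer(het_per_breeder)
  cage_size <- as.integer(cage_size)
  if (n_labs < 2L || n_breeders < 2L)
    stop("need at least two laboratories and two breeding sites")
  if (n_breeders < n_labs)
    stop("sta_breeder_map cannot be a bijection: fewer breeders than labs")
  if (is.null(sta_breeder_map)) sta_breeder_map <- seq_len(n_labs)
  sta_breeder_map <- as.integer(sta_breeder_map)
  if (length(sta_breeder_map) != n_labs ||
      anyDuplicated(sta_breeder_map) ||
      any(sta_breeder_map < 1L | sta_breeder_map > n_breeders))
    stop("sta_breeder_map must be a bijection from labs into distinct breeding sites")
  if (sta_n %% cage_size != 0L)
    stop("STA arm size per lab (", sta_n, ") is not divisible by cage_size (",
         cage_size, ")")
  if (het_per_breeder %% cage_size != 0L)
    stop("HET animals per breeder (", het_per_breeder,
         ") is not divisible by cage_size (", cage_size, ")")
  het_n <- het_per_breeder * (n_breeders - 1L)
  out <- list(
    n_labs = n_labs, n_breeders = n_breeders, sta_n = sta_n,
    het_per_breeder = het_per_breeder, het_n = het_n,
    cage_size = cage_size, sta_breeder_map = sta_breeder_map,
    outcome_names = as.character(outcome_names),
    per_lab = sta_n + het_n,
    total_animals = n_labs * (sta_n + het_n)
  )
  class(out) <- "design_spec"
  out
}

#' @exportS3Method base::print
print.design_spec <- function(x, ...) {
  cat("Multi-laboratory design:",
      x$n_labs, "labs x", x$n_breeders, "breeding sites\n")
  cat("  STA: ", x$sta_n, " animals/lab from the mapped breeder\n", sep = "")
  cat("  HET: ", x$het_per_breeder, " animals from each of the ",
      x$n_breeders - 1L, " other breeders (", x$het_n, "/lab)\n", sep = "")
  cat("  cage size ", x$cage_size, "; total animals ", x$total_animals,
      " (", x$per_lab, "/lab)\n", sep = "")
  invisible(x)
}

lab_levels <- function(spec) sprintf("LAB%d", seq_len(spec$n_labs))
breeder_levels <- function(spec) sprintf("B%d", seq_len(spec$n_breeders))

#' Allocate animals to laboratories, breeders, arms and cages
#'
#' Builds the full animal roster for a [design_spec()]: each laboratory gets
#' `sta_n` STA animals from its mapped breeding site and `het_per_breeder`
#' HET animals from each other site, pair-housed (or `cage_size`-housed) in
#' cages that never mix laboratory, breeding site or design arm. Outcome
#' columns are created but left empty; fill them with [simulate_outcomes()].
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed (reserved for randomized cage-order variants;
#'   the allocation itself is deterministic).
#' @return A data frame of class `animal_roster` with columns `animal_id`,
#'   `lab`, `breeder`, `design`, `cage_id` and one `NA` column per outcome.
#' @examples
#' roster <- allocate_design(design_spec())
#' nrow(roster)  # 324
#' @export
allocate_design <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  labs <- lab_levels(spec); breeders <- breeder_levels(spec)
  rows <- vector("list", spec$n_labs)
  for (l in seq_len(spec$n_labs)) {
    home <- spec$sta_breeder_map[l]
    sta <- data.frame(
      lab = labs[l], breeder = breeders[home], design = "STA",
      within = seq_len(spec$sta_n), stringsAsFactors = FALSE)
    others <- setdiff(seq_len(spec$n_breeders), home)
    het <- if (spec$het_per_breeder > 0L)
      do.call(rbind, lapply(others, function(b) data.frame(
        lab = labs[l], breeder = breeders[b], design = "HET",
        within = seq_len(spec$het_per_breeder), stringsAsFactors = FALSE)))
    rows[[l]] <- rbind(sta, het)
  }
  roster <- do.call(rbind, rows)
  cage_no <- (roster$within - 1L) %/% spec$cage_size + 1L
  roster$cage_id <- sprintf("%s_%s_%s_c%02d",
                            roster$lab, roster$design, roster$breeder, cage_no)
  roster$animal_id <- sprintf("M%03d", seq_len(nrow(roster)))
  roster$lab <- factor(roster$lab, levels = labs)
  roster$breeder <- factor(roster$breeder, levels = breeders)
  roster$design <- factor(roster$design, levels = c("STA", "HET"))
  roster$within <- NULL
  roster <- roster[c("animal_id", "lab", "breeder", "design", "cage_id")]
  for (v in spec$outcome_names) roster[[v]] <- NA_real_
  rownames(roster) <- NULL
  attr(roster, "design_spec") <- spec
  class(roster) <- c("animal_roster", "data.frame")
  roster
}
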