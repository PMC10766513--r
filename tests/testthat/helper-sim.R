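# shared fixtures: all generated in code, no files

quick_dataset <- function(seed = 1, profile = default_profile(),
                          spec = design_spec(), missing = NULL,
                          latent_cor = 0) {
  d <- simulate_outcomes(allocate_design(spec), profile, seed = seed,
                         latent_cor = latent_cor)
  if (!is.null(missing)) d <- inject_missingness(d, missing)
  d
}

# tiny 2-lab/2-breeder design for fast exact checks
tiny_spec <- function() design_spec(n_labs = 2, n_breeders = 2, sta_n = 4,
                                    het_per_breeder = 4, cage_size = 2)

# balanced one-way cage toy: k cages of m animals, known variances
balanced_cage_toy <- function(k = 10, m = 4, s2_cage = 1, s2_res = 1,
                              seed = 1) {
  set.seed(seed)
  cage <- factor(rep(seq_len(k), each = m))
  y <- rnorm(k, sd = sqrt(s2_cage))[as.integer(cage)] +
    rnorm(k * m, sd = sqrt(s2_res))
  data.frame(y = y, cage_id = cage)
}
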