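# Shared builders for small in-code fixtures.

# A tiny fully-valid stack with deterministic values.
toy_stack <- function(nr = 10, nc = 10, vars = c("a", "b"), period = "T1",
                      seed = 1) {
  set.seed(seed)
  layers <- lapply(seq_along(vars), function(i)
    matrix(rnorm(nr * nc, mean = i), nr, nc))
  names(layers) <- vars
  env_stack(layers, period)
}

# Standard small synthetic world for pipeline tests (frozen study defaults
# scaled down where a test only needs structure, not statistical power).
toy_world <- function(nrow = 40, ncol = 40, n = 60, shift = 0, noise_sd = 0,
                      seed = 7, sigma = 0.5) {
  cfg <- synthetic_climate_config(nrow, ncol, 3, shift = shift,
                                  noise_sd = noise_sd, seed = seed)
  pair <- generate_climate_pair(cfg)
  sp <- virtual_species(mu = rep(0, 3), sigma = rep(sigma, 3))
  list(pair = pair, species = sp,
       occ_T1 = sample_virtual_occurrences(sp, pair$T1, n, seed = seed + 100),
       occ_T2 = sample_virtual_occurrences(sp, pair$T2, n, seed = seed + 200),
       area = full_area(pair$T1))
}

# Occurrence set at explicit cells on a stack.
occ_at_cells <- function(stack, cells, species = "sp", period = "T1") {
  retroniche:::occ_from_cells(species, period, stack, cells)
}
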