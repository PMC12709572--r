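# shared fixtures built in code; everything is deterministic given the seed

default_library <- function(seed = 1) gen_component_library(seed = seed)

# small noiseless cube with known scores
toy_cube <- function(n_samples, n_active = 6, seed = 10, noise_sd = 0,
                     scatter = NULL, lib = default_library(2)) {
  set.seed(seed)
  scores <- matrix(runif(n_samples * 6, 0.2, 2), n_samples, 6)
  if (n_active < 6) scores[, (n_active + 1):6] <- 0
  eems <- lapply(seq_len(n_samples), function(i) {
    gen_eem(scores[i, ], lib, noise_sd = noise_sd, seed = seed + i,
            scatter = scatter)
  })
  names(eems) <- paste0("S", seq_len(n_samples))
  list(cube = eem_cube(eems), scores = scores, lib = lib)
}

# exact exponential decay series
exp_series <- function(k = 1e-4, c0 = 1e-5, times = seq(0, 18000, 3600),
                       replicate = 1L) {
  tibble::tibble(time_s = times, concentration_M = c0 * exp(-k * times),
                 replicate = replicate)
}

flat_flux <- function(lo = 300, hi = 400, level = 1e-9) {
  flux_spectrum(seq(lo, hi, by = 1), rep(level, hi - lo + 1))
}

flat_abs <- function(a = 0.05, lo = 250, hi = 450) {
  abs_spectrum(seq(lo, hi, by = 1), rep(a, hi - lo + 1))
}
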