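# Shared fixtures: simulated oils are cached per (scenario, seed, sigma) so
# expensive FID synthesis and FFTs run once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached_oil <- function(scenario, seed = 1, noise_sigma = 0.05, ...) {
  key <- paste(scenario, seed, noise_sigma, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_oil(scenario, seed = seed, noise_sigma = noise_sigma, ...)
    spec <- process_fid(sim$fid)
    .sim_cache[[key]] <- list(sim = sim, spec = spec,
                              truth = sim$truth$compounds)
  }
  .sim_cache[[key]]
}

# Fast mixture for property tests: 1 s acquisition keeps every
# quantification window above the 8-point digital-resolution floor.
quick_mix <- function(conc, noise_sigma = 0, seed = 1, ...) {
  mixture_spec(
    tibble::tibble(abbrev = if (length(conc)) names(conc) else character(0),
                   conc_mg_ml = unname(conc)),
    noise_sigma = noise_sigma, seed = seed, aq_s = 1, ...
  )
}

quick_spec <- function(conc, noise_sigma = 0, seed = 1, ...) {
  sim <- simulate_fid(quick_mix(conc, noise_sigma, seed, ...))
  list(spec = process_fid(sim$fid), truth = sim$truth)
}

# True wt% yields under the default sample prep (25 x mg/mL in the tube).
true_yield_table <- function(truth_compounds) {
  tibble::tibble(compound = truth_compounds$abbrev,
                 true_yield = truth_compounds$conc_mg_ml * 25)
}
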