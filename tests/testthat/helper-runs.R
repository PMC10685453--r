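# Shared simulation fixtures, built once per test session and cached.
# Sizes are chosen so the whole suite stays fast while every estimator has
# enough statistics for its stated tolerance.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

thermo310 <- thermo_state(310)

# 1D double-well with a 10 kJ/mol central barrier between minima at +-6 A
double_well_1d <- function() {
  make_membrane_potential(model_potential(
    1, interfacial_min_depth = 10, core_barrier_height = 10,
    interfacial_min_position = 6, widths = c(well = 3, core = 3.5),
    z_max = 12))
}

# converged-ish WTMetaD run on the double well (about 1.5 s)
wtmetad_run_1d <- function() {
  cached("wt1d", run_wtmetad(
    double_well_1d(), diffusion_model("constant", 0.5), thermo310,
    dt = 0.01, n_steps = 4e6, seed = 11, stride = 10,
    w0 = 1.2, sigma = 0.5, pace = 1, bias_factor = 20,
    grid_spacing = 0.05, init = 6))
}

# long unbiased run in a harmonic well (equipartition / D estimator checks)
ou_run <- function(k = 10, D = 0.5, n_steps = 1e6, seed = 7, center = 0) {
  cached(sprintf("ou_%g_%g_%g_%g_%d", k, D, center, n_steps, seed), {
    sf <- harmonic_surface(k, center, z_max = center + 20)
    simulate_overdamped(sf, diffusion_model("constant", D), thermo310,
                        dt = 0.01, n_steps = n_steps, seed = seed,
                        stride = 1, init = center)
  })
}

random_ledger <- function(n, d = 1, seed = 42, zr = 5) {
  set.seed(seed)
  hills_ledger(
    time = seq_len(n) * 2,
    center = matrix(runif(n * d, -zr, zr), n, d),
    sigma = matrix(runif(n * d, 0.3, 0.8), n, d),
    height = runif(n, 0.1, 1.2),
    bias_factor = 20, thermo = thermo310, pace = 2)
}
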