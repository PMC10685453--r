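# Overdamped Langevin sampling of CV space (the desk-scale stand-in for the
# atomistic sampler). Euler-Maruyama in the Ito convention:
#   dz = (-beta D(z) dF/dz + dD/dz) dt + sqrt(2 D(z) dt) dW
# with reflective boundaries at |z| = z_max. With position-dependent D the
# explicit dD/dz spurious-drift term is required for the stationary density
# to be Boltzmann.

.cv_names <- function(d) if (d == 1L) "cv_cq" else c("cv_ring", "cv_tail")

.new_cv_trajectory <- function(times, values, thermo, stride, seed) {
  values <- as.matrix(values)
  colnames(values) <- .cv_names(ncol(values))
  structure(
    list(times = times, values = values, d = ncol(values),
         thermo = thermo, stride = stride, seed = seed),
    class = "cv_trajectory"
  )
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("<cv_trajectory> %d frames, %dD (%s), stride %g ps, %g ps total\n",
              nrow(x$values), x$d, paste(colnames(x$values), collapse = ", "),
              x$stride, max(x$times)))
  invisible(x)
}

.min_feature_width <- function(surface) {
  if (length(surface$s)) min(surface$s) else surface$z_max / 4
}

.check_dt <- function(surface, diffusion, thermo, dt) {
  # sample the gradient over the domain to estimate the stiffest drift
  d <- surface$d
  zs <- seq(-surface$z_max, surface$z_max, length.out = 201)
  pts <- if (d == 1L) matrix(zs, ncol = 1) else
    as.matrix(expand.grid(seq(-surface$z_max, surface$z_max, length.out = 61),
                          seq(-surface$z_max, surface$z_max, length.out = 61)))
  gmax <- max(abs(surface$grad(pts)))
  Dmax <- max(diffusion$D_bulk, diffusion$D_core)
  wmin <- .min_feature_width(surface)
  drift <- dt * Dmax * gmax * thermo$beta
  if (is.finite(drift) && drift > 0.2 * wmin) {
    warning(sprintf(paste0(
      "time step looks large: dt * D * max|grad F| * beta = %.3g A vs ",
      "feature width %.3g A; consider reducing dt"), drift, wmin))
  }
  invisible(drift)
}

.default_init <- function(surface) {
  if (!is.null(surface$params)) {
    rep(surface$params$interfacial_min_position, surface$d)
  } else {
    rep(0, surface$d)
  }
}

#' Well-tempered metadynamics bias settings
#'
#' Bias hook for [simulate_overdamped()]: Gaussian kernels of initial height
#' `w0` and width `sigma` are deposited every `pace` ps with heights tempered
#' by `bias_factor` (gamma), and the deposited bias is accumulated on a grid
#' of the given spacing. Defaults follow common permeation practice: 1.2
#' kJ/mol initial height, 0.5 Angstrom sigma, one kernel every 2 ps, gamma 20
#' for a neutral permeant (25 for a charged one, where the barrier is
#' higher), bias grid spacing 0.01 Angstrom.
#'
#' @param w0 Initial kernel height, kJ/mol.
#' @param sigma Kernel width(s), Angstrom (recycled across CV dimensions).
#' @param pace Deposition period, ps.
#' @param bias_factor Well-tempering factor gamma > 1.
#' @param grid_spacing Bias grid spacing, Angstrom.
#' @param truncation Kernel truncation radius in sigmas for grid
#'   accumulation (default 6; `Inf` disables truncation).
#' @return A `wtmetad_bias` settings object.
#' @export
wtmetad_bias <- function(w0 = 1.2, sigma = 0.5, pace = 2, bias_factor = 20,
                         grid_spacing = 0.01, truncation = 6) {
  if (w0 <= 0) stop("w0 must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (pace <= 0) stop("pace must be positive")
  if (bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  structure(list(w0 = w0, sigma = sigma, pace = pace,
                 bias_factor = bias_factor, grid_spacing = grid_spacing,
                 truncation = truncation),
            class = "wtmetad_bias")
}

#' Simulate overdamped Langevin dynamics on a model landscape
#'
#' Euler-Maruyama integration of overdamped (Brownian) dynamics on a
#' `cv_surface`, with constant or position-dependent diffusivity (Ito
#' convention, explicit spurious-drift term) and reflective boundaries at
#' `|z| = z_max`. With `bias` set, well-tempered metadynamics kernels are
#' deposited during the run and the reweighting factor c(t) is updated after
#' every deposition.
#'
#' @param surface A `cv_surface`.
#' @param diffusion A [diffusion_model()].
#' @param thermo A [thermo_state()] (or temperature in K).
#' @param dt Time step, ps.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param stride Output stride in steps (one frame every `stride` steps).
#' @param init Initial CV point; defaults to the interfacial minimum of a
#'   membrane landscape, else the origin.
#' @param bias Optional [wtmetad_bias()] settings.
#' @return With `bias = NULL`, a `cv_trajectory`. With a bias, a list with
#'   elements `trajectory`, `ledger` (a [hills_ledger()]), `reweight`
#'   (a `reweight_state` holding c(t)) and `bias_grid` (final bias).
#' @export
simulate_overdamped <- function(surface, diffusion, thermo, dt, n_steps,
                                seed = 1L, stride = 10L, init = NULL,
                                bias = NULL) {
  stopifnot(inherits(surface, "cv_surface"),
            inherits(diffusion, "diffusion_model"))
  thermo <- .as_thermo(thermo)
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1) stop("n_steps must be >= 1")
  .check_dt(surface, diffusion, thermo, dt)
  d <- surface$d
  if (is.null(init)) init <- .default_init(surface)
  init <- rep_len(as.numeric(init), d)
  metad <- !is.null(bias)
  if (metad) stopifnot(inherits(bias, "wtmetad_bias"))

  pace_steps <- if (metad) max(1L, as.integer(round(bias$pace / dt))) else 1L
  nbins <- if (metad) {
    as.integer(round(2 * surface$z_max / bias$grid_spacing)) + 1L
  } else 2L
  grid_lo <- rep(-surface$z_max, d)
  grid_hi <- rep(surface$z_max, d)

  set.seed(seed)
  res <- cpp_run_langevin(
    d, surface$h, surface$u, surface$c, surface$s,
    surface$tilt, surface$harm_k, surface$harm_c,
    if (diffusion$form == "smooth") 1L else 0L,
    diffusion$D_bulk, diffusion$D_core, diffusion$transition_width,
    thermo$beta, dt, as.numeric(n_steps), as.integer(stride), init,
    surface$z_max, 10 * .min_feature_width(surface),
    metad,
    if (metad) bias$w0 else 0, rep_len(if (metad) bias$sigma else 1, d),
    pace_steps, if (metad) bias$bias_factor else 2,
    grid_lo, grid_hi, rep(nbins, d),
    if (metad) bias$truncation else 6
  )

  traj <- .new_cv_trajectory(res$times, res$values, thermo,
                             stride = stride * dt, seed = seed)
  traj$frame_bias <- res$frame_bias
  if (!metad) return(traj)

  sig <- rep_len(bias$sigma, d)
  ledger <- hills_ledger(
    time = res$hill_times,
    center = res$hill_centers,
    sigma = matrix(sig, nrow = length(res$hill_times), ncol = d, byrow = TRUE),
    height = res$hill_heights,
    bias_factor = bias$bias_factor, thermo = thermo,
    pace = pace_steps * dt
  )
  grid <- .make_grid_spec(grid_lo, grid_hi, rep(nbins, d))
  rw <- structure(
    list(times = res$hill_times, c_of_t = res$c_of_t, thermo = thermo,
         bias_factor = bias$bias_factor, grid = grid,
         truncation = bias$truncation),
    class = "reweight_state"
  )
  bg <- bias_grid(grid_lo, grid_hi, rep(nbins, d))
  bg$values <- array(res$bias_values, dim = rep(nbins, d))
  list(trajectory = traj, ledger = ledger, reweight = rw, bias_grid = bg)
}

#' Run a full well-tempered metadynamics simulation
#'
#' Couples [simulate_overdamped()] with well-tempered bias deposition and the
#' on-the-fly reweighting factor. Thin convenience wrapper over
#' `simulate_overdamped(..., bias = wtmetad_bias(...))`.
#'
#' @inheritParams simulate_overdamped
#' @param w0,sigma,pace,bias_factor,grid_spacing,truncation See
#'   [wtmetad_bias()].
#' @return A list with `trajectory`, `ledger`, `reweight`, `bias_grid`.
#' @export
run_wtmetad <- function(surface, diffusion, thermo, dt, n_steps,
                        seed = 1L, stride = 10L, init = NULL,
                        w0 = 1.2, sigma = 0.5, pace = 2, bias_factor = 20,
                        grid_spacing = 0.01, truncation = 6) {
  simulate_overdamped(
    surface, diffusion, thermo, dt, n_steps, seed = seed, stride = stride,
    init = init,
    bias = wtmetad_bias(w0 = w0, sigma = sigma, pace = pace,
                        bias_factor = bias_factor,
                        grid_spacing = grid_spacing, truncation = truncation)
  )
}

#' @export
print.reweight_state <- function(x, ...) {
  cat(sprintf("<reweight_state> %d depositions, c(t_end) = %.4g kJ/mol (gamma = %g)\n",
              length(x$c_of_t), utils::tail(x$c_of_t, 1), x$bias_factor))
  invisible(x)
}
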