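# Position-dependent diffusion from restrained trajectories and the
# inhomogeneous solubility-diffusion (ISD) permeability:
#   1/P = integral of exp(beta F(z)) / D(z) dz over the membrane,
# F referenced to bulk water. D(z0) from a harmonically restrained window:
#   D = var(z)^2 / integral_0^inf <dz(0) dz(t)> dt
# (the positional-autocorrelation estimator; for an exponential ACF this is
# exactly var/tau).

# 1 A/ps = 1e4 cm/s
.APS_TO_CMS <- 1e4

.acf_fft <- function(x, lag_max) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(lag_max + 1)] / m
  ac / (n - seq_len(lag_max + 1) + 1) * 1  # unbiased-ish normalisation
}

.integrate_acf <- function(ac, dt_frame) {
  # trapezoid to the first zero-crossing sustained for 5 lags,
  # else to 10 * tau_guess (initial e-folding time)
  neg <- ac < 0
  run <- which(neg & c(rep(FALSE, 4), vapply(
    5:length(neg), function(i) all(neg[(i - 4):i]), TRUE)))
  cut <- if (length(run)) run[1] - 4L else {
    below <- which(ac < ac[1] / exp(1))
    tau_guess <- if (length(below)) (below[1] - 1) * dt_frame else
      (length(ac) - 1) * dt_frame
    min(length(ac), max(2L, as.integer(round(10 * tau_guess / dt_frame))))
  }
  idx <- seq_len(cut)
  sum((ac[idx[-length(idx)]] + ac[idx[-1]]) / 2) * dt_frame
}

.estimate_D_once <- function(z, dt_frame, lag_max) {
  v <- stats::var(z)
  I <- .integrate_acf(.acf_fft(z, lag_max), dt_frame)
  if (I <= 0) return(NA_real_)
  v^2 / I
}

#' Local diffusion coefficient from a restrained trajectory
#'
#' Positional-autocorrelation estimator for a window harmonically restrained
#' about `z0`: `D(z0) = var(z)^2 / int <dz(0) dz(t)> dt`, the autocorrelation
#' integrated to its first sustained zero-crossing (5 lags) or to 10 times
#' the initial decay time. The error is the standard error over contiguous
#' sub-blocks; non-stationary input (split-half variance ratio outside
#' [0.5, 2]) is rejected.
#'
#' @param traj A 1D `cv_trajectory` from a restrained run.
#' @param z0 Window centre (diagnostic only; default: trajectory mean).
#' @param n_blocks Blocks for the error estimate (default 5).
#' @param lag_max Maximum ACF lag in frames (default: capped at n/10).
#' @return List with `D` (A^2/ps), `error`, `tau` (implied correlation time
#'   var/D, ps), `z0`, and `var`.
#' @export
estimate_D_at <- function(traj, z0 = NULL, n_blocks = 5L, lag_max = NULL) {
  stopifnot(inherits(traj, "cv_trajectory"), traj$d == 1L)
  z <- as.numeric(traj$values[, 1])
  n <- length(z)
  if (n < 100) stop("restrained trajectory too short to estimate D")
  half <- stats::var(z[1:(n %/% 2)]) / stats::var(z[(n %/% 2 + 1):n])
  if (!is.finite(half) || half < 0.5 || half > 2) {
    stop(sprintf(
      "trajectory looks non-stationary (split-half variance ratio %.2f)",
      half))
  }
  dt_frame <- traj$stride
  if (is.null(lag_max)) lag_max <- min(n %/% 10, 5000L)
  D <- .estimate_D_once(z, dt_frame, lag_max)
  if (!is.finite(D)) stop("autocorrelation integral is not positive")
  cuts <- floor(seq(0, n, length.out = n_blocks + 1))
  Db <- vapply(seq_len(n_blocks), function(b) {
    .estimate_D_once(z[(cuts[b] + 1):cuts[b + 1]], dt_frame,
                     min(lag_max, (cuts[b + 1] - cuts[b]) %/% 5))
  }, 1)
  Db <- Db[is.finite(Db)]
  err <- if (length(Db) > 1) stats::sd(Db) / sqrt(length(Db)) else NA_real_
  list(D = D, error = err, tau = stats::var(z) / D,
       z0 = if (is.null(z0)) mean(z) else z0, var = stats::var(z))
}

#' Position-dependent diffusion profile from a window ladder
#'
#' Runs the window estimator at each restraint centre and assembles a
#' symmetric D(z) profile (windows at +-z are averaged by default, and the
#' profile is mirrored). Linear interpolation between nodes is used by the
#' permeability integral.
#'
#' @param trajs List of restrained 1D `cv_trajectory` objects.
#' @param centers Restraint centres, Angstrom (same length as `trajs`).
#' @param symmetrized Average D(z) with D(-z) and mirror the grid.
#' @return A `diffusion_profile` with `z`, `D`, `error`.
#' @export
build_D_profile <- function(trajs, centers, symmetrized = TRUE) {
  stopifnot(length(trajs) == length(centers))
  if (length(centers) < 5L) {
    warning("fewer than 5 window centres; D(z) coverage is thin")
  }
  est <- lapply(seq_along(trajs), function(i) {
    estimate_D_at(trajs[[i]], z0 = centers[i])
  })
  D <- vapply(est, `[[`, 1, "D")
  err <- vapply(est, `[[`, 1, "error")
  o <- order(centers)
  z <- centers[o]; D <- D[o]; err <- err[o]
  gaps <- diff(z)
  if (length(gaps) > 1 && max(gaps) > 2 * stats::median(gaps)) {
    warning("window ladder has a gap larger than twice the typical spacing")
  }
  if (symmetrized) {
    za <- sort(unique(round(abs(z), 6)))
    Ds <- vapply(za, function(a) mean(D[abs(abs(z) - a) < 1e-6]), 1)
    Es <- vapply(za, function(a) {
      e <- err[abs(abs(z) - a) < 1e-6]
      sqrt(mean(e^2)) / sqrt(length(e))
    }, 1)
    if (za[1] == 0) {
      z <- c(-rev(za[-1]), za)
      D <- c(rev(Ds[-1]), Ds)
      err <- c(rev(Es[-1]), Es)
    } else {
      z <- c(-rev(za), za)
      D <- c(rev(Ds), Ds)
      err <- c(rev(Es), Es)
    }
  }
  if (any(D <= 0)) stop("estimated diffusivities must be positive")
  structure(list(z = z, D = D, error = err), class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf("<diffusion_profile> %d nodes, z in [%g, %g] A, D in [%.3g, %.3g] A^2/ps\n",
              length(x$z), min(x$z), max(x$z), min(x$D), max(x$D)))
  invisible(x)
}

.D_at <- function(D_profile, z) {
  if (inherits(D_profile, "diffusion_profile")) {
    stats::approx(D_profile$z, D_profile$D, z, rule = 2)$y
  } else if (inherits(D_profile, "diffusion_model")) {
    D_profile$D(z)
  } else if (is.numeric(D_profile) && length(D_profile) == 1L) {
    rep(D_profile, length(z))
  } else stop("unsupported diffusion specification")
}

.Derr_at <- function(D_profile, z) {
  if (inherits(D_profile, "diffusion_profile") &&
      any(is.finite(D_profile$error))) {
    e <- D_profile$error
    e[!is.finite(e)] <- 0
    stats::approx(D_profile$z, e, z, rule = 2)$y
  } else rep(0, length(z))
}

#' Permeability from the inhomogeneous solubility-diffusion model
#'
#' `1/P = int_{z1}^{z2} exp(beta F(z)) / D(z) dz` with F referenced to bulk
#' water (the integrand is the local resistance). Trapezoidal quadrature on
#' the F grid with a half-resolution Richardson check; the error combines
#' per-bin F errors (first-order, `beta exp(beta F)` sensitivity) and D
#' errors. Result in cm/s (1 A/ps = 1e4 cm/s).
#'
#' @param F_profile A 1D `fes` in z, bulk-referenced: `|F|` at the bounds
#'   must be below 1 kJ/mol.
#' @param D_profile A `diffusion_profile`, [diffusion_model()], or a single
#'   constant diffusivity (A^2/ps).
#' @param bounds Integration bounds `c(z1, z2)`, Angstrom (default: the F
#'   grid range). Bounds need not be grid nodes; the integrand is linearly
#'   extended to them, so segment resistances add exactly at any split.
#' @param check_reference Require `|F| <= 1` kJ/mol at the bounds (disable
#'   when integrating a sub-segment for resistance decomposition).
#' @return A `permeability_result`: `P` and `error` (cm/s), `P_A_ps`,
#'   `integration_bounds`, and the `resistance` profile (s cm^-1 A^-1 per
#'   node).
#' @export
isd_permeability <- function(F_profile, D_profile, bounds = NULL,
                             check_reference = TRUE) {
  stopifnot(inherits(F_profile, "fes"), F_profile$d == 1L)
  zg <- F_profile$axes[[1]]
  if (is.null(bounds)) bounds <- range(zg)
  sel <- zg >= bounds[1] & zg <= bounds[2]
  if (sum(sel) < 3) stop("fewer than 3 F bins inside the bounds")
  msk <- as.logical(F_profile$mask)[sel]
  if (any(!msk)) stop("masked bins inside the integration bounds")
  # integration nodes: the bounds themselves plus interior grid nodes.
  # The resistance integrand is computed on the grid nodes and linearly
  # interpolated/extended to the bounds, so splitting the domain at any
  # interior point and summing segment resistances is exact.
  z <- unique(sort(c(bounds[1], zg[sel], bounds[2])))
  Fall <- as.numeric(F_profile$F)
  F <- stats::approx(zg, Fall, z, rule = 2)$y
  edgeF <- abs(F[c(1, length(F))])
  if (check_reference && any(edgeF > 1)) {
    stop(sprintf(
      "F is not bulk-referenced at the bounds (|F| = %.2f kJ/mol > 1)",
      max(edgeF)))
  }
  beta <- F_profile$thermo$beta
  Dg <- .D_at(D_profile, zg)
  if (any(Dg[sel] <= 0)) stop("D must be positive over the bounds")
  rg <- exp(beta * Fall) / Dg               # ps/A per unit length in A
  r <- stats::approx(zg, rg, z, rule = 2)$y
  D <- .D_at(D_profile, z)
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  R <- trapz(z, r)                          # ps/A... -> 1/P in (A/ps)^-1
  # Richardson check on half resolution
  half <- seq(1, length(z), by = 2)
  if (length(half) >= 3) {
    R2 <- trapz(z[half], r[half])
    if (abs(R2 - R) > 0.05 * R) {
      warning("quadrature changes by >5% at half resolution; refine the F grid")
    }
  }
  P_aps <- 1 / R
  # first-order error propagation: d(1/P)/dF_i = beta r_i w_i, plus D term
  w <- c(diff(z)[1] / 2, (diff(z)[-1] + diff(z)[-length(diff(z))]) / 2,
         diff(z)[length(z) - 1] / 2)
  Eall <- as.numeric(F_profile$error)
  Eall[!is.finite(Eall)] <- 0
  Ferr <- stats::approx(zg, Eall, z, rule = 2)$y
  Derr <- .Derr_at(D_profile, z)
  varR <- sum((beta * r * w * Ferr)^2) + sum((r / D * w * Derr)^2)
  P_err_aps <- P_aps^2 * sqrt(varR)
  structure(
    list(P = P_aps * .APS_TO_CMS, error = P_err_aps * .APS_TO_CMS,
         P_A_ps = P_aps, integration_bounds = bounds,
         resistance = data.frame(z = z, r = r / .APS_TO_CMS)),
    class = "permeability_result"
  )
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> P = %.4g +/- %.2g cm/s over [%g, %g] A\n",
              x$P, x$error, x$integration_bounds[1], x$integration_bounds[2]))
  invisible(x)
}

#' External-field specification
#'
#' A static field `E` along the membrane normal coupling to the permeant's
#' dipole `mu`. The first-order energy scale of the perturbation
#' across the membrane is `2 E mu`.
#'
#' @param E Field strength, mV/Angstrom, >= 0 (default 10).
#' @param mu Molecular dipole moment, debye, >= 0 (default 5.8).
#' @param direction +1 or -1, the field direction along +z.
#' @return A `field_spec`.
#' @export
field_spec <- function(E = 10, mu = 5.8, direction = 1) {
  if (E < 0 || mu < 0) stop("E and mu must be non-negative")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(list(E = E, mu = mu, direction = direction),
            class = "field_spec")
}

#' First-order field-coupling energy scale
#'
#' `2 E mu` converted to kJ/mol: E in mV/Angstrom to V/m (1e7), mu in debye
#' to C m (3.33564e-30), times Avogadro's number. For 10 mV/A and 5.8 D this
#' is about 2.33 kJ/mol, i.e. small compared with a 40 kJ/mol interfacial
#' well — a transmembrane potential barely perturbs permeation energetics.
#'
#' @param field A [field_spec()].
#' @return Energy scale in kJ/mol.
#' @export
field_energy_scale <- function(field = field_spec()) {
  stopifnot(inherits(field, "field_spec"))
  2 * (field$E * 1e7) * (field$mu * .DEBYE) * .AVOGADRO / 1000
}

#' Apply a dipole-field tilt to a surface
#'
#' Perturbs a gridded surface by `-E mu c(z)` where `c(z)` in [-1, 1] is the
#' orientation-averaged fraction of the dipole coupling active at z (first
#' axis). An antisymmetric coupling of constant magnitude c0 splits the two
#' interfacial minima by exactly `2 E mu c0`.
#'
#' @param fes An `fes`.
#' @param field A [field_spec()].
#' @param coupling_profile Function of z returning values in [-1, 1].
#' @return The perturbed `fes` (reference `"none"`).
#' @export
apply_field_tilt <- function(fes, field, coupling_profile) {
  stopifnot(inherits(fes, "fes"), inherits(field, "field_spec"))
  cz <- coupling_profile(fes$axes[[1]])
  if (any(abs(cz) > 1 + 1e-12)) {
    stop("coupling_profile must stay within [-1, 1]")
  }
  emu <- field$direction * field_energy_scale(field) / 2
  pert <- emu * cz
  out <- fes
  if (fes$d == 1L) out$F <- fes$F - pert
  else out$F <- sweep(fes$F, 1L, pert, "-")
  out$reference <- "none"
  out
}
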