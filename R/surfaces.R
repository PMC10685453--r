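# Analytic model landscapes.
#
# Every surface is a sum of one-dimensional Gaussian ridges/wells along unit
# directions in CV space, plus an optional linear tilt and per-dimension
# harmonic restraints:
#   F(z) = const + tilt.z + sum_k h_k exp(-(u_k.z - c_k)^2 / (2 s_k^2))
#          + sum_j k_j/2 (z_j - r_j)^2
# This family is closed under the operations the pipeline needs (protomer
# penalties, field tilts, restraints), has exact analytic gradients, and is
# evaluated identically by the R closures and the compiled integrator.

.as_points <- function(z, d) {
  if (is.matrix(z)) {
    if (ncol(z) != d) stop("points have ", ncol(z), " columns, surface is ", d, "D")
    return(z)
  }
  if (d == 1L) return(matrix(as.numeric(z), ncol = 1L))
  if (length(z) == d) return(matrix(as.numeric(z), ncol = d))
  stop("cannot interpret points for a ", d, "D surface")
}

.build_surface <- function(d, h, u, c, s, tilt, const, harm_k, harm_c, z_max,
                           extra = list()) {
  h <- as.numeric(h); c <- as.numeric(c); s <- as.numeric(s)
  u <- matrix(as.numeric(u), ncol = d)
  stopifnot(length(h) == nrow(u), length(c) == length(h), length(s) == length(h))
  if (any(s <= 0)) stop("Gaussian term widths must be positive")
  tilt <- rep_len(as.numeric(tilt), d)
  harm_k <- rep_len(as.numeric(harm_k), d)
  harm_c <- rep_len(as.numeric(harm_c), d)

  f <- function(z) {
    z <- .as_points(z, d)
    out <- rep(const, nrow(z)) + drop(z %*% tilt)
    if (length(h)) {
      q <- z %*% t(u)
      q <- sweep(q, 2L, c)
      e <- exp(-sweep(q^2, 2L, 2 * s^2, "/"))
      out <- out + drop(e %*% h)
    }
    for (j in seq_len(d)) {
      if (harm_k[j] != 0) out <- out + 0.5 * harm_k[j] * (z[, j] - harm_c[j])^2
    }
    out
  }
  grad <- function(z) {
    z <- .as_points(z, d)
    g <- matrix(rep(tilt, each = nrow(z)), ncol = d)
    if (length(h)) {
      q <- sweep(z %*% t(u), 2L, c)
      e <- exp(-sweep(q^2, 2L, 2 * s^2, "/"))
      pref <- e * sweep(q, 2L, -s^2, "/")     # d/dq of each term / h
      for (j in seq_len(d)) g[, j] <- g[, j] + drop(pref %*% (h * u[, j]))
    }
    for (j in seq_len(d)) {
      if (harm_k[j] != 0) g[, j] <- g[, j] + harm_k[j] * (z[, j] - harm_c[j])
    }
    g
  }

  structure(
    c(list(d = d, h = h, u = u, c = c, s = s, tilt = tilt, const = const,
           harm_k = harm_k, harm_c = harm_c, z_max = z_max,
           f = f, grad = grad), extra),
    class = "cv_surface"
  )
}

#' @export
print.cv_surface <- function(x, ...) {
  cat(sprintf("<cv_surface> %dD, %d Gaussian term(s), z_max = %g Angstrom\n",
              x$d, length(x$h), x$z_max))
  invisible(x)
}

#' Model membrane landscape parameters
#'
#' Parameter set for an analytic permeation landscape: symmetric interfacial
#' minima at `+-interfacial_min_position`, a central core barrier, and bulk
#' plateaus at `bulk_level`. In 2D the two axes are the membrane-normal
#' distances of the ring and tail moieties of the permeant, and a bounded
#' coupling term penalises ring-tail separation (the moieties belong to one
#' molecule).
#'
#' @param dimensionality 1 or 2 collective variables.
#' @param interfacial_min_depth Depth of the interfacial minima below bulk,
#'   kJ/mol, >= 0. Default 40, echoing a neutral drug bound at the
#'   headgroup/water interface.
#' @param core_barrier_height Rise from the interfacial minimum to the
#'   membrane centre, kJ/mol. Default 11.
#' @param interfacial_min_position Distance of the minima from the membrane
#'   centre, Angstrom. Default 12.
#' @param widths Named numeric: `well`, `core` (and `coupling` for 2D)
#'   Gaussian widths in Angstrom.
#' @param coupling_strength 2D only: bounded ring-tail separation penalty,
#'   kJ/mol. Default 20.
#' @param bulk_level Reference free energy of the bulk plateaus, kJ/mol.
#' @param tilt Linear perturbation, kJ/mol/Angstrom (external-field-like).
#' @param z_max Half-width of the modelled CV range (reflective boundary for
#'   the sampler), Angstrom. Default 45.
#' @return A `model_potential` parameter object.
#' @export
model_potential <- function(dimensionality = 1L,
                            interfacial_min_depth = 40,
                            core_barrier_height = 11,
                            interfacial_min_position = 12,
                            widths = c(well = 3, core = 5, coupling = 8),
                            coupling_strength = 20,
                            bulk_level = 0,
                            tilt = 0,
                            z_max = 45) {
  d <- as.integer(dimensionality)
  if (!d %in% c(1L, 2L)) stop("dimensionality must be 1 or 2")
  w <- c(well = 3, core = 5, coupling = 8)
  w[names(widths)] <- widths
  if (any(w <= 0)) stop("widths must be positive")
  if (interfacial_min_depth < 0) stop("interfacial_min_depth must be >= 0")
  if (interfacial_min_position <= 0 || interfacial_min_position >= z_max) {
    stop("interfacial_min_position must lie in (0, z_max)")
  }
  structure(
    list(dimensionality = d,
         interfacial_min_depth = interfacial_min_depth,
         core_barrier_height = core_barrier_height,
         interfacial_min_position = interfacial_min_position,
         widths = w, coupling_strength = coupling_strength,
         bulk_level = bulk_level, tilt = tilt, z_max = z_max),
    class = "model_potential"
  )
}

#' Build the analytic membrane free-energy surface
#'
#' Converts a [model_potential()] parameter set into an evaluable surface
#' (value and exact analytic gradient at any CV point). The Gaussian
#' amplitudes are solved from a small linear system so that, by construction,
#' `F(interfacial_min_position) - bulk_level == -interfacial_min_depth` and
#' `F(0) - F(interfacial_min_position) == core_barrier_height` (evaluated on
#' the diagonal for 2D), despite overlap between the features.
#'
#' @param params A `model_potential` object.
#' @return A `cv_surface` with elements `f(z)` and `grad(z)`, both vectorised
#'   over rows of a points matrix.
#' @examples
#' sf <- make_membrane_potential(model_potential())
#' sf$f(12) - sf$f(45)   # -40 at the nominal minimum
#' @export
make_membrane_potential <- function(params) {
  stopifnot(inherits(params, "model_potential"))
  p <- params
  z0 <- p$interfacial_min_position
  ww <- p$widths[["well"]]; wc <- p$widths[["core"]]
  gw <- function(x) exp(-x^2 / (2 * ww^2))
  gc_ <- function(x) exp(-x^2 / (2 * wc^2))
  # amplitudes A_well, A_core from the two construction constraints
  A <- rbind(c(1 + gw(2 * z0), gc_(z0)),
             c(2 * gw(z0), 1))
  b <- c(-p$interfacial_min_depth,
         -p$interfacial_min_depth + p$core_barrier_height)
  amp <- solve(A, b)

  if (p$dimensionality == 1L) {
    h <- c(amp[1], amp[1], amp[2])
    u <- matrix(1, 3, 1)
    cen <- c(z0, -z0, 0)
    s <- c(ww, ww, wc)
    const <- p$bulk_level
  } else {
    # separable half-amplitude copy on each axis keeps the diagonal exact
    h <- c(rep(amp[1] / 2, 4L), rep(amp[2] / 2, 2L))
    u <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(1, 0), c(0, 1))
    cen <- c(z0, -z0, z0, -z0, 0, 0)
    s <- c(ww, ww, ww, ww, wc, wc)
    # bounded ring-tail separation penalty: cs * (1 - exp(-(a-b)^2/2w^2))
    wcpl <- p$widths[["coupling"]]
    h <- c(h, -p$coupling_strength)
    u <- rbind(u, c(1, -1) / sqrt(2))
    cen <- c(cen, 0)
    s <- c(s, wcpl / sqrt(2))
    const <- p$bulk_level + p$coupling_strength
  }
  .build_surface(p$dimensionality, h, u, cen, s,
                 tilt = p$tilt, const = const,
                 harm_k = 0, harm_c = 0, z_max = p$z_max,
                 extra = list(params = p))
}

#' Harmonic restraint surface
#'
#' Quadratic well `k/2 (z - center)^2` per dimension, used for the restrained
#' windows of the diffusion estimator and for closed-form sampler checks.
#'
#' @param k Spring constant(s), kJ/mol/Angstrom^2.
#' @param center Restraint centre(s), Angstrom.
#' @param d Dimensionality (default length of `center`).
#' @param z_max Reflective boundary, Angstrom.
#' @return A `cv_surface`.
#' @export
harmonic_surface <- function(k, center = 0, d = length(center), z_max = 45) {
  if (any(k < 0)) stop("spring constant must be >= 0")
  .build_surface(as.integer(d), numeric(0), matrix(0, 0, d), numeric(0),
                 numeric(0), tilt = 0, const = 0,
                 harm_k = k, harm_c = center, z_max = z_max)
}

#' Flat surface
#' @param d Dimensionality.
#' @param z_max Reflective boundary, Angstrom.
#' @return A `cv_surface` with F identically 0.
#' @export
flat_surface <- function(d = 1L, z_max = 45) {
  harmonic_surface(k = rep(0, d), center = rep(0, d), d = d, z_max = z_max)
}

#' Add a harmonic restraint to an existing surface
#' @param surface A `cv_surface`.
#' @param k,center Spring constant(s) and centre(s).
#' @return A new `cv_surface`.
#' @export
restrain_surface <- function(surface, k, center) {
  stopifnot(inherits(surface, "cv_surface"))
  .build_surface(surface$d, surface$h, surface$u, surface$c, surface$s,
                 surface$tilt, surface$const,
                 surface$harm_k + rep_len(k, surface$d),
                 # combine two quadratic terms exactly only when one is zero;
                 # restraints are only ever added to unrestrained surfaces
                 ifelse(rep_len(k, surface$d) != 0, rep_len(center, surface$d),
                        surface$harm_c),
                 surface$z_max)
}

#' Neutral/charged protomer surface pair
#'
#' The charged-species landscape is the neutral one plus a smooth
#' core-localised destabilisation: a Gaussian ridge of height `core_penalty`
#' centred at the membrane core. In 2D the penalty acts along the tail axis
#' (the charged amine sits on the tail moiety), so the difference map crosses
#' zero at a band of constant `|CV_tail|`. The penalty vanishes in bulk, so
#' the two surfaces coincide in water by construction.
#'
#' @param base A `cv_surface` (the neutral landscape).
#' @param core_penalty Charged-minus-neutral free energy at the membrane
#'   centre, kJ/mol, >= 0. Default 64, chosen so the charged landscape's core
#'   maximum sits ~35 kJ/mol above bulk when paired with the default neutral
#'   landscape (-40 minimum, +11 rise).
#' @param core_width Gaussian width of the penalty, Angstrom. Default 7.4.
#' @return `list(neutral = , charged = )` of `cv_surface` objects.
#' @export
make_protomer_pair <- function(base, core_penalty = 64, core_width = 7.4) {
  stopifnot(inherits(base, "cv_surface"))
  if (core_penalty < 0) stop("core_penalty must be >= 0")
  if (core_width <= 0) stop("core_width must be positive")
  if (core_penalty == 0) return(list(neutral = base, charged = base))
  u_pen <- if (base$d == 1L) matrix(1, 1, 1) else matrix(c(0, 1), 1, 2)
  charged <- .build_surface(
    base$d,
    c(base$h, core_penalty),
    rbind(base$u, u_pen),
    c(base$c, 0),
    c(base$s, core_width),
    base$tilt, base$const, base$harm_k, base$harm_c, base$z_max
  )
  list(neutral = base, charged = charged)
}

#' Position-dependent diffusion model
#'
#' Either a constant diffusivity or a smooth symmetric profile
#' `D(z) = D_bulk + (D_core - D_bulk) * exp(-z^2 / (2 w^2))` that drops (or
#' rises) towards the membrane core over `transition_width`. Applied
#' per-coordinate in 2D.
#'
#' @param form `"constant"` or `"smooth"`.
#' @param D_bulk Bulk diffusivity, Angstrom^2/ps, > 0. Default 0.5.
#' @param D_core Core diffusivity, Angstrom^2/ps, > 0 (smooth form only).
#' @param transition_width Width of the core feature, Angstrom.
#' @return A `diffusion_model` with evaluators `D(z)` and `dD(z)`.
#' @export
diffusion_model <- function(form = c("constant", "smooth"),
                            D_bulk = 0.5, D_core = 0.2,
                            transition_width = 8) {
  form <- match.arg(form)
  if (D_bulk <= 0 || D_core <= 0) stop("diffusivities must be positive")
  if (transition_width <= 0) stop("transition_width must be positive")
  if (form == "constant") {
    D <- function(z) rep(D_bulk, length(z))
    dD <- function(z) rep(0, length(z))
  } else {
    w2 <- 2 * transition_width^2
    D <- function(z) D_bulk + (D_core - D_bulk) * exp(-z^2 / w2)
    dD <- function(z) (D_core - D_bulk) * exp(-z^2 / w2) * (-2 * z / w2)
  }
  structure(list(form = form, D_bulk = D_bulk, D_core = D_core,
                 transition_width = transition_width, D = D, dD = dD),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("<diffusion_model> %s, D_bulk = %g, D_core = %g A^2/ps\n",
              x$form, x$D_bulk, x$D_core))
  invisible(x)
}
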