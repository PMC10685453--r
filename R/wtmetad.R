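# Well-tempered metadynamics bookkeeping: the kernel ledger, grid-based bias
# evaluation, the tempering rule for the next kernel height, and the
# Tiwary-Parrinello reweighting factor c(t) computed from the gridded bias.

#' Gaussian kernel ledger
#'
#' Ordered record of deposited metadynamics kernels together with the bias
#' factor and thermodynamic state; defines the bias potential
#' `V(s, t) = sum over kernels with time <= t of height * prod_d
#' exp(-(s_d - center_d)^2 / (2 sigma_d^2))`.
#'
#' @param time Deposition times, ps, strictly increasing.
#' @param center Kernel centres: vector (1D) or matrix with one column per CV.
#' @param sigma Kernel widths, same shape as `center`.
#' @param height Kernel heights, kJ/mol, positive.
#' @param bias_factor Well-tempering factor gamma > 1.
#' @param thermo A [thermo_state()].
#' @param pace Deposition period, ps.
#' @return A `hills_ledger`.
#' @export
hills_ledger <- function(time, center, sigma, height, bias_factor,
                         thermo, pace) {
  thermo <- .as_thermo(thermo)
  center <- as.matrix(center)
  sigma <- as.matrix(sigma)
  time <- as.numeric(time)
  height <- as.numeric(height)
  d <- ncol(center)
  stopifnot(nrow(center) == length(time), all(dim(sigma) == dim(center)),
            length(height) == length(time))
  if (length(time) && any(diff(time) <= 0)) {
    stop("kernel times must be strictly increasing")
  }
  if (any(sigma <= 0)) stop("kernel sigmas must be positive")
  if (any(height <= 0)) stop("kernel heights must be positive")
  if (bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  structure(
    list(time = time, center = center, sigma = sigma, height = height,
         d = d, bias_factor = bias_factor, thermo = thermo, pace = pace),
    class = "hills_ledger"
  )
}

#' Empty kernel ledger
#' @inheritParams hills_ledger
#' @param d CV dimensionality.
#' @return A `hills_ledger` with no kernels.
#' @export
empty_ledger <- function(d = 1L, bias_factor = 20, thermo = thermo_state(),
                         pace = 2) {
  hills_ledger(numeric(0), matrix(numeric(0), 0, d),
               matrix(numeric(0), 0, d), numeric(0),
               bias_factor, thermo, pace)
}

#' @export
print.hills_ledger <- function(x, ...) {
  cat(sprintf("<hills_ledger> %d kernel(s), %dD, gamma = %g, pace = %g ps\n",
              length(x$time), x$d, x$bias_factor, x$pace))
  invisible(x)
}

#' @export
length.hills_ledger <- function(x) length(x$time)

# direct kernel summation at arbitrary points (vectorised over points);
# exact (untruncated), used for point queries and as the small-ledger route
.kernel_sum <- function(ledger, pts, t = Inf) {
  pts <- .as_points(pts, ledger$d)
  keep <- ledger$time <= t
  if (!any(keep)) return(rep(0, nrow(pts)))
  cen <- ledger$center[keep, , drop = FALSE]
  sig <- ledger$sigma[keep, , drop = FALSE]
  h <- ledger$height[keep]
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    q <- sweep(cen, 2L, pts[i, ], "-")
    out[i] <- sum(h * exp(-rowSums(q^2 / (2 * sig^2))))
  }
  out
}

#' Height of the next well-tempered kernel
#'
#' Tempering rule `w = w0 * exp(-V(s, t) / ((gamma - 1) kT))`: the next
#' kernel shrinks geometrically with the bias already accumulated at the
#' deposition point. An empty ledger returns `w0` exactly.
#'
#' @param ledger A [hills_ledger()].
#' @param s CV point (length-d numeric).
#' @param w0 Initial height, kJ/mol (default 1.2).
#' @return Height in kJ/mol.
#' @export
next_height <- function(ledger, s, w0 = 1.2) {
  stopifnot(inherits(ledger, "hills_ledger"))
  if (ledger$bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  V <- .kernel_sum(ledger, s)
  w0 * exp(-V / ((ledger$bias_factor - 1) * ledger$thermo$kT))
}

.make_grid_spec <- function(lo, hi, n) {
  list(lo = as.numeric(lo), hi = as.numeric(hi), n = as.integer(n),
       spacing = (as.numeric(hi) - as.numeric(lo)) / (as.integer(n) - 1L))
}

#' Uniform bias grid
#'
#' @param lo,hi Per-axis bounds, Angstrom.
#' @param n Nodes per axis (>= 2).
#' @return A `bias_grid` with zeroed values and per-axis node coordinates.
#' @export
bias_grid <- function(lo, hi, n) {
  lo <- as.numeric(lo); hi <- as.numeric(hi); n <- as.integer(n)
  d <- length(lo)
  stopifnot(length(hi) == d, length(n) == d, all(n >= 2L), all(hi > lo))
  axes <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = n[j]))
  structure(
    list(axes = axes, lo = lo, hi = hi, n = n,
         spacing = (hi - lo) / (n - 1L),
         values = array(0, dim = n), d = d),
    class = "bias_grid"
  )
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("<bias_grid> %s nodes, spacing %s A, max V = %.4g kJ/mol\n",
              paste(x$n, collapse = " x "),
              paste(signif(x$spacing, 4), collapse = ", "),
              max(x$values)))
  invisible(x)
}

#' Evaluate the metadynamics bias on a grid
#'
#' Accumulates `V(s, t)` for all kernels deposited up to time `t` on the
#' nodes of `grid`. By default the summation is exact (untruncated); passing
#' a finite `truncation` (radius in sigmas) reproduces the fast path used by
#' the live engine.
#'
#' @param ledger A [hills_ledger()].
#' @param grid A [bias_grid()].
#' @param t Include kernels with deposition time <= `t` (default all).
#' @param truncation Kernel truncation radius in sigmas (default `Inf`).
#' @return The grid with `values` filled.
#' @export
evaluate_bias <- function(ledger, grid, t = Inf, truncation = Inf) {
  stopifnot(inherits(ledger, "hills_ledger"), inherits(grid, "bias_grid"))
  if (ledger$d != grid$d) stop("ledger and grid dimensionality differ")
  keep <- ledger$time <= t
  out <- grid
  if (!any(keep)) {
    out$values <- array(0, dim = grid$n)
    return(out)
  }
  v <- cpp_kernels_on_grid(
    ledger$center[keep, , drop = FALSE],
    ledger$sigma[keep, , drop = FALSE],
    ledger$height[keep],
    grid$lo, grid$hi, grid$n, truncation
  )
  out$values <- array(v, dim = grid$n)
  out
}

#' Reweighting factor c(t) from a gridded bias
#'
#' Tiwary-Parrinello estimator evaluated by the grid's own quadrature:
#' `c(t) = (1/beta) ln[ sum e^{(gamma/(gamma-1)) beta V} /
#' sum e^{(1/(gamma-1)) beta V} ]` (the uniform node measure cancels).
#' Computed with a max-shift, so the result is finite whenever V is.
#'
#' @param grid A [bias_grid()] holding `V(s, t)` (or a numeric vector/array
#'   of bias values).
#' @param bias_factor Gamma > 1.
#' @param thermo A [thermo_state()].
#' @return c(t) in kJ/mol.
#' @export
update_c_of_t <- function(grid, bias_factor, thermo) {
  thermo <- .as_thermo(thermo)
  if (bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  if (inherits(grid, "bias_grid")) {
    V <- as.numeric(grid$values)
    dims <- grid$n
  } else {
    V <- as.numeric(grid)
    dims <- if (is.null(dim(grid))) length(V) else dim(grid)
  }
  if (!all(is.finite(V))) stop("bias values must be finite")
  # trapezoid quadrature: half weight on edge nodes of every axis
  w <- 1
  for (j in seq_along(dims)) {
    wj <- rep(1, dims[j])
    wj[c(1L, dims[j])] <- 0.5
    w <- outer(w, wj)
  }
  w <- as.numeric(w)
  beta <- thermo$beta
  a <- bias_factor / (bias_factor - 1) * beta
  b <- 1 / (bias_factor - 1) * beta
  vmax <- max(V, 0)
  (log(sum(w * exp(a * (V - vmax)))) -
      log(sum(w * exp(b * (V - vmax))))) / beta +
    (a - b) * vmax / beta
}

# c(t_i) for arbitrary frame times: the step function holding the value set
# by the last deposition at or before t (0 before the first kernel)
.c_at_times <- function(rwstate, times) {
  if (is.null(rwstate) || length(rwstate$c_of_t) == 0L) {
    return(rep(0, length(times)))
  }
  idx <- findInterval(times, rwstate$times)
  c(0, rwstate$c_of_t)[idx + 1L]
}
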