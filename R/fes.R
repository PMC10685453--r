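# Free-energy surface reconstruction from biased trajectories.
# F = -kT ln of the reweighted histogram, frame weights exp(beta (V(s,t) -
# c(t))), with burn-in removal, contiguous-block standard errors,
# probability-space symmetrization and an asymmetry diagnostic.

.new_fes <- function(axes, F, error, mask, reference, thermo,
                     signed = FALSE, bulk_cut = NULL) {
  structure(
    list(axes = axes, F = F, error = error, mask = mask,
         reference = reference, thermo = thermo, d = length(axes),
         signed = signed, bulk_cut = bulk_cut),
    class = "fes"
  )
}

#' @export
print.fes <- function(x, ...) {
  rng <- range(x$F[x$mask])
  cat(sprintf("<fes> %dD, %s bins (%d visited), F in [%.3g, %.3g] kJ/mol, reference %s\n",
              x$d, paste(lengths(x$axes), collapse = " x "), sum(x$mask),
              rng[1], rng[2], x$reference))
  invisible(x)
}

# symmetric-about-zero breaks covering [-z_max, z_max]
.fes_breaks <- function(z_max, bin_width) {
  m <- ceiling(z_max / bin_width - 1e-9)
  seq(-m * bin_width, m * bin_width, by = bin_width)
}

.bin_centers <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2

# weighted d-dimensional histogram on shared per-axis breaks
.weighted_hist <- function(values, weights, breaks) {
  d <- ncol(values)
  nb <- vapply(breaks, function(b) length(b) - 1L, 1L)
  idx <- rep(1L, nrow(values))
  keep <- rep(TRUE, nrow(values))
  mult <- 1L
  for (j in seq_len(d)) {
    ij <- findInterval(values[, j], breaks[[j]], rightmost.closed = TRUE)
    keep <- keep & ij >= 1L & ij <= nb[j]
    ij[!keep] <- 1L
    idx <- idx + (ij - 1L) * mult
    mult <- mult * nb[j]
  }
  h <- numeric(prod(nb))
  if (any(keep)) {
    tmp <- rowsum(weights[keep], idx[keep])
    h[as.integer(rownames(tmp))] <- tmp
  }
  array(h, dim = nb)
}

# frame weights exp(beta (V - c)), normalised by max for stability
.frame_weights <- function(traj, ledger, rwstate, truncation = 6) {
  n <- nrow(traj$values)
  if (is.null(ledger) || length(ledger) == 0L) return(rep(1, n))
  grid <- if (!is.null(rwstate$grid)) rwstate$grid else {
    zm <- max(abs(traj$values), abs(ledger$center)) + 3 * max(ledger$sigma)
    nb <- as.integer(round(2 * zm / 0.05)) + 1L
    .make_grid_spec(rep(-zm, ledger$d), rep(zm, ledger$d), rep(nb, ledger$d))
  }
  V <- cpp_bias_at_frames(traj$values, traj$times,
                          ledger$time, ledger$center, ledger$sigma,
                          ledger$height,
                          grid$lo, grid$hi, grid$n,
                          if (is.null(rwstate$truncation)) truncation else
                            rwstate$truncation)
  cc <- .c_at_times(rwstate, traj$times)
  arg <- traj$thermo$beta * (V - cc)
  exp(arg - max(arg))
}

.apply_burn_in <- function(traj, burn_in) {
  stopifnot(burn_in >= 0, burn_in < 1)
  keep <- traj$times >= burn_in * max(traj$times)
  traj$values <- traj$values[keep, , drop = FALSE]
  traj$times <- traj$times[keep]
  if (!is.null(traj$frame_bias)) traj$frame_bias <- traj$frame_bias[keep]
  traj
}

.resolve_breaks <- function(traj, breaks, bin_width) {
  if (!is.null(breaks)) {
    if (!is.list(breaks)) breaks <- rep(list(breaks), traj$d)
    return(breaks)
  }
  zm <- max(abs(traj$values))
  rep(list(.fes_breaks(zm + bin_width, bin_width)), traj$d)
}

#' Reweight a biased trajectory to a free-energy surface
#'
#' Histogram estimator with well-tempered metadynamics frame weights
#' `w_i = exp(beta (V(s_i, t_i) - c(t_i)))`; `V` is evaluated on the engine's
#' bias grid at the frame's own time and `c(t)` is the on-the-fly
#' reweighting factor. With an empty ledger all weights are equal and the
#' result reduces to `-kT ln` of the plain histogram. The first `burn_in`
#' fraction of the run is discarded (default 1/9, mirroring dropping the
#' first 500 ns of a 4.5 us production run).
#'
#' @param traj A `cv_trajectory`.
#' @param ledger A [hills_ledger()] (or `NULL` for an unbiased run).
#' @param rwstate The matching `reweight_state` (or `NULL`).
#' @param burn_in Fraction of the run discarded from the front.
#' @param bin_width Histogram bin width, Angstrom (default 0.5, the kernel
#'   sigma scale; the much finer bias grid is not a histogram grid).
#' @param breaks Optional explicit break vector(s) (list per axis),
#'   symmetric about zero.
#' @param reference `"min-zero"` or `"bulk-zero"`.
#' @param bulk_cut For `"bulk-zero"`: bins with `|center| >= bulk_cut` on
#'   every axis form the bulk region.
#' @return An `fes`; unvisited bins are masked, never imputed.
#' @export
reweight_to_fes <- function(traj, ledger = NULL, rwstate = NULL,
                            burn_in = 1 / 9, bin_width = 0.5, breaks = NULL,
                            reference = c("min-zero", "bulk-zero"),
                            bulk_cut = NULL) {
  stopifnot(inherits(traj, "cv_trajectory"))
  reference <- match.arg(reference)
  traj <- .apply_burn_in(traj, burn_in)
  breaks <- .resolve_breaks(traj, breaks, bin_width)
  w <- .frame_weights(traj, ledger, rwstate)
  h <- .weighted_hist(traj$values, w, breaks)
  if (nrow(traj$values) < 10 * sum(h > 0)) {
    warning("fewer than 10 frames per visited bin after burn-in; ",
            "the surface will be noisy")
  }
  mask <- h > 0
  if (!any(mask)) stop("no visited bins; run longer or coarsen the binning")
  F <- array(NA_real_, dim = dim(h))
  F[mask] <- -traj$thermo$kT * log(h[mask])
  fes <- .new_fes(lapply(breaks, .bin_centers), F,
                  array(NA_real_, dim = dim(h)), mask,
                  reference = "none", thermo = traj$thermo)
  reference_fes(fes, reference, bulk_cut)
}

#' Re-reference a free-energy surface
#'
#' @param fes An `fes`.
#' @param reference `"min-zero"` (minimum over visited bins becomes 0) or
#'   `"bulk-zero"` (mean over the bulk region becomes 0).
#' @param bulk_cut Bulk region: bins with `|center| >= bulk_cut` on every
#'   axis. Required for `"bulk-zero"`.
#' @return The re-referenced `fes`.
#' @export
reference_fes <- function(fes, reference = c("min-zero", "bulk-zero"),
                          bulk_cut = NULL) {
  stopifnot(inherits(fes, "fes"))
  reference <- match.arg(reference)
  if (reference == "min-zero") {
    fes$F <- fes$F - min(fes$F[fes$mask])
  } else {
    if (is.null(bulk_cut)) stop("bulk-zero referencing needs `bulk_cut`")
    bulk <- .bulk_mask(fes, bulk_cut)
    if (!any(bulk & fes$mask)) stop("no visited bins in the bulk region")
    fes$F <- fes$F - mean(fes$F[bulk & fes$mask])
    fes$bulk_cut <- bulk_cut
  }
  fes$reference <- reference
  fes
}

# Bulk = permeant fully in water. In 2D (ring/tail distances) that means
# both CVs beyond the cut AND on the same side of the membrane: the
# opposite-sign corners are stretched, non-physical configurations.
.bulk_mask <- function(fes, bulk_cut) {
  ks <- lapply(fes$axes, function(ax) abs(ax) >= bulk_cut)
  if (fes$d == 1L) return(array(ks[[1]], length(ks[[1]])))
  outer(ks[[1]], ks[[2]], "&") &
    outer(fes$axes[[1]], fes$axes[[2]], "*") > 0
}

#' Block-averaged error estimate for a reweighted surface
#'
#' Splits the post-burn-in trajectory into `n_blocks` contiguous equal time
#' slices (default three), reconstructs the surface from each, re-references
#' every block estimate, and fills the per-bin error with the standard error
#' across blocks. Bins missing from any block keep a masked (NA) error.
#'
#' @inheritParams reweight_to_fes
#' @param n_blocks Number of contiguous blocks, >= 2.
#' @return The full-data `fes` with the `error` field filled.
#' @export
block_error <- function(traj, ledger = NULL, rwstate = NULL, n_blocks = 3L,
                        burn_in = 1 / 9, bin_width = 0.5, breaks = NULL,
                        reference = c("min-zero", "bulk-zero"),
                        bulk_cut = NULL) {
  stopifnot(inherits(traj, "cv_trajectory"))
  reference <- match.arg(reference)
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  post <- .apply_burn_in(traj, burn_in)
  if (nrow(post$values) < n_blocks) {
    stop("fewer post-burn-in frames than blocks")
  }
  breaks <- .resolve_breaks(post, breaks, bin_width)
  full <- reweight_to_fes(traj, ledger, rwstate, burn_in = burn_in,
                          breaks = breaks, reference = reference,
                          bulk_cut = bulk_cut)
  cut_idx <- floor(seq(0, nrow(post$values), length.out = n_blocks + 1L))
  blockF <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    sel <- (cut_idx[b] + 1L):cut_idx[b + 1L]
    sub <- post
    sub$values <- post$values[sel, , drop = FALSE]
    sub$times <- post$times[sel]
    bf <- suppressWarnings(
      reweight_to_fes(sub, ledger, rwstate, burn_in = 0, breaks = breaks,
                      reference = reference, bulk_cut = bulk_cut)
    )
    blockF[[b]] <- ifelse(bf$mask, bf$F, NA_real_)
  }
  stacked <- simplify2array(blockF)
  nbf <- length(blockF[[1]])
  sdv <- apply(array(stacked, dim = c(nbf, n_blocks)), 1L, stats::sd)
  err <- array(sdv / sqrt(n_blocks), dim = dim(full$F))
  err[!full$mask] <- NA_real_
  full$error <- err
  full
}

.mirror <- function(a) {
  d <- length(dim(a))
  if (d == 1L || is.null(dim(a))) return(rev(a))
  if (d == 2L) return(a[nrow(a):1, ncol(a):1, drop = FALSE])
  stop("only 1D/2D surfaces supported")
}

.check_symmetric_axes <- function(fes) {
  for (ax in fes$axes) {
    if (max(abs(ax + rev(ax))) > 1e-9) {
      stop("axis bins are not symmetric about zero; rebin symmetrically")
    }
  }
  invisible(TRUE)
}

#' Symmetrize a free-energy surface
#'
#' Enforces the bilayer mirror symmetry by averaging in probability space:
#' `F_sym(s) = -kT ln[(e^{-beta F(s)} + e^{-beta F(-s)})/2]` (for 2D the
#' mirror flips both axes). Exact for populations and idempotent. Where only
#' one of a mirror pair is visited, its value is copied to both; pairs with
#' neither visited stay masked.
#'
#' @param fes An `fes` with axes symmetric about zero.
#' @return The symmetrized `fes`.
#' @export
symmetrize <- function(fes) {
  stopifnot(inherits(fes, "fes"))
  .check_symmetric_axes(fes)
  beta <- fes$thermo$beta; kT <- fes$thermo$kT
  Fm <- .mirror(fes$F); Mm <- .mirror(fes$mask)
  both <- fes$mask & Mm
  onlyA <- fes$mask & !Mm
  onlyB <- !fes$mask & Mm
  out <- fes
  if (any(both)) {
    a <- fes$F[both]; b <- Fm[both]
    lo <- pmin(a, b)
    out$F[both] <- -kT * (log1p(exp(-beta * (pmax(a, b) - lo))) - log(2)) +
      lo
  }
  out$F[onlyA] <- fes$F[onlyA]
  out$F[onlyB] <- Fm[onlyB]
  out$mask <- fes$mask | Mm
  if (!all(is.na(fes$error))) {
    Em <- .mirror(fes$error)
    e <- out$error
    e[both] <- 0.5 * sqrt(fes$error[both]^2 + Em[both]^2)
    e[onlyA] <- fes$error[onlyA]
    e[onlyB] <- Em[onlyB]
    out$error <- e
  }
  out
}

#' Maximum mirror asymmetry of a surface
#'
#' `max |F(s) - F(-s)|` over mirror pairs where both bins are visited; the
#' convergence diagnostic reported alongside the mean block error.
#'
#' @param fes An `fes` with axes symmetric about zero.
#' @return Asymmetry in kJ/mol (0 if no complete mirror pair exists).
#' @export
asymmetry <- function(fes) {
  stopifnot(inherits(fes, "fes"))
  .check_symmetric_axes(fes)
  Fm <- .mirror(fes$F)
  both <- fes$mask & .mirror(fes$mask)
  if (!any(both)) return(0)
  max(abs(fes$F[both] - Fm[both]))
}

#' Cross-check surface from the final bias
#'
#' Well-tempered estimator `F = -(gamma/(gamma-1)) V(s, t_end)` up to a
#' constant, evaluated on a grid; an independent cross-check for the
#' reweighting route (not the production estimator).
#'
#' @param ledger A [hills_ledger()].
#' @param grid A [bias_grid()] (nodes become the surface axes).
#' @param truncation Kernel truncation radius in sigmas.
#' @return A min-zero referenced `fes` on the grid nodes.
#' @export
bias_based_fes <- function(ledger, grid, truncation = Inf) {
  g <- evaluate_bias(ledger, grid, truncation = truncation)
  gam <- ledger$bias_factor
  F <- -gam / (gam - 1) * g$values
  fes <- .new_fes(g$axes, F, array(NA_real_, dim = dim(F)),
                  array(TRUE, dim = dim(F)),
                  reference = "none", thermo = ledger$thermo)
  reference_fes(fes, "min-zero")
}

#' Evaluate an analytic surface on a grid as an `fes`
#'
#' @param surface A `cv_surface`.
#' @param bin_width Bin width, Angstrom; or give `breaks`.
#' @param breaks Optional explicit break vector(s).
#' @param thermo A [thermo_state()].
#' @param reference Reference convention to apply.
#' @param bulk_cut Passed to [reference_fes()] for `"bulk-zero"`.
#' @return An `fes` with zero errors and all bins visited.
#' @export
fes_from_surface <- function(surface, bin_width = 0.5, breaks = NULL,
                             thermo = thermo_state(),
                             reference = c("min-zero", "bulk-zero"),
                             bulk_cut = NULL) {
  stopifnot(inherits(surface, "cv_surface"))
  reference <- match.arg(reference)
  thermo <- .as_thermo(thermo)
  if (is.null(breaks)) {
    breaks <- rep(list(.fes_breaks(surface$z_max, bin_width)), surface$d)
  } else if (!is.list(breaks)) breaks <- rep(list(breaks), surface$d)
  axes <- lapply(breaks, .bin_centers)
  pts <- as.matrix(do.call(expand.grid, axes))
  F <- array(surface$f(pts), dim = lengths(axes))
  fes <- .new_fes(axes, F, array(0, dim = dim(F)),
                  array(TRUE, dim = dim(F)), reference = "none",
                  thermo = thermo)
  reference_fes(fes, reference, bulk_cut)
}

#' Marginalize a 2D surface onto one axis
#'
#' Boltzmann marginal `F_j(z) = -kT ln sum_other e^{-beta F}` over visited
#' bins, e.g. to project a ring/tail surface onto the membrane normal for
#' the solubility-diffusion integral.
#'
#' @param fes A 2D `fes`.
#' @param axis Axis to keep (1 or 2).
#' @return A 1D `fes` (min-zero referenced).
#' @export
fes_marginal <- function(fes, axis = 1L) {
  stopifnot(inherits(fes, "fes"), fes$d == 2L)
  beta <- fes$thermo$beta; kT <- fes$thermo$kT
  W <- ifelse(fes$mask, exp(-beta * (fes$F - min(fes$F[fes$mask]))), 0)
  s <- if (axis == 1L) rowSums(W) else colSums(W)
  mask <- s > 0
  F <- rep(NA_real_, length(s))
  F[mask] <- -kT * log(s[mask])
  E <- if (all(is.na(fes$error))) rep(NA_real_, length(s)) else {
    We <- ifelse(fes$mask & !is.na(fes$error), W * fes$error, 0)
    es <- if (axis == 1L) rowSums(We) else colSums(We)
    ifelse(mask, es / s, NA_real_)
  }
  out <- .new_fes(fes$axes[axis], array(F, length(F)), array(E, length(E)),
                  array(mask, length(mask)),
                  reference = "none", thermo = fes$thermo)
  reference_fes(out, "min-zero")
}

#' Shift a surface by a constant
#' @param fes An `fes`.
#' @param dF Constant added to F, kJ/mol.
#' @return The shifted `fes` (reference set to `"none"`).
#' @export
shift_fes <- function(fes, dF) {
  stopifnot(inherits(fes, "fes"))
  fes$F <- fes$F + dF
  fes$reference <- "none"
  fes
}
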