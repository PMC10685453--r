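# Minimum free energy path on a gridded surface by the (zero-temperature)
# string method: steepest-descent motion of interior images along the
# gradient component perpendicular to the path, followed by equal-arc-length
# reparameterization each iteration. The surface is interpolated by
# separable Catmull-Rom bicubic convolution with analytic derivatives;
# masked (unvisited) bins are treated as high barriers so paths cannot cross
# unsampled regions.

# Catmull-Rom weights and derivatives at fraction t in [0, 1]
.cr_w <- function(t) {
  cbind(-0.5 * t + t^2 - 0.5 * t^3,
        1 - 2.5 * t^2 + 1.5 * t^3,
        0.5 * t + 2 * t^2 - 1.5 * t^3,
        -0.5 * t^2 + 0.5 * t^3)
}
.cr_dw <- function(t) {
  cbind(-0.5 + 2 * t - 1.5 * t^2,
        -5 * t + 4.5 * t^2,
        0.5 + 4 * t - 4.5 * t^2,
        -t + 1.5 * t^2)
}

#' Smooth interpolator for a gridded surface
#'
#' Bicubic (Catmull-Rom) convolution on the FES grid with analytic
#' gradients. Masked bins are replaced by `mask_value` (default: max visited
#' F + 100 kJ/mol) so the interpolant repels paths from unsampled regions;
#' coordinates outside the grid are clamped to the edge.
#'
#' @param fes An `fes`.
#' @param mask_value Value standing in for unvisited bins, kJ/mol.
#' @return A list with vectorised functions `f(p)` and `grad(p)` over rows
#'   of a points matrix, plus the `mask_value` used.
#' @export
fes_interpolator <- function(fes, mask_value = NULL) {
  stopifnot(inherits(fes, "fes"))
  d <- fes$d
  if (is.null(mask_value)) mask_value <- max(fes$F[fes$mask]) + 100
  F <- fes$F
  F[!fes$mask] <- mask_value
  axes <- fes$axes
  n <- lengths(axes)
  h <- vapply(axes, function(a) a[2] - a[1], 1)
  lo <- vapply(axes, function(a) a[1], 1)

  stencil <- function(x, j) {
    u <- (x - lo[j]) / h[j]
    u <- pmin(pmax(u, 0), n[j] - 1)
    i0 <- pmin(floor(u), n[j] - 2)
    idx <- outer(i0, c(-1, 0, 1, 2), "+") + 1   # may exceed bounds
    idx <- pmin(pmax(idx, 1L), n[j])
    list(idx = idx, t = u - i0)
  }

  if (d == 1L) {
    Fv <- as.numeric(F)
    eval1 <- function(p, deriv) {
      st <- stencil(p[, 1], 1L)
      W <- if (deriv) .cr_dw(st$t) / h[1] else .cr_w(st$t)
      rowSums(W * matrix(Fv[st$idx], nrow = nrow(st$idx)))
    }
    f <- function(p) eval1(.as_points(p, 1L), FALSE)
    grad <- function(p) matrix(eval1(.as_points(p, 1L), TRUE), ncol = 1)
  } else {
    evals <- function(p, dx, dy) {
      sx <- stencil(p[, 1], 1L)
      sy <- stencil(p[, 2], 2L)
      Wx <- if (dx) .cr_dw(sx$t) / h[1] else .cr_w(sx$t)
      Wy <- if (dy) .cr_dw(sy$t) / h[2] else .cr_w(sy$t)
      out <- numeric(nrow(p))
      for (a in 1:4) for (b in 1:4) {
        out <- out + Wx[, a] * Wy[, b] * F[cbind(sx$idx[, a], sy$idx[, b])]
      }
      out
    }
    f <- function(p) evals(.as_points(p, 2L), FALSE, FALSE)
    grad <- function(p) {
      p <- .as_points(p, 2L)
      cbind(evals(p, TRUE, FALSE), evals(p, FALSE, TRUE))
    }
  }
  list(f = f, grad = grad, mask_value = mask_value)
}

#' Locate free-energy minima on a surface
#'
#' Finds grid-local minima among visited bins inside a CV box and refines
#' each by per-axis parabolic interpolation of the surrounding bins.
#'
#' @param fes An `fes`.
#' @param region Optional box: numeric `c(lo, hi)` in 1D or a 2 x d matrix
#'   `rbind(lo, hi)`. Default: the whole grid.
#' @return A matrix of minima (one row each, d columns) with attribute
#'   `"F"`, sorted by increasing free energy.
#' @export
find_minima <- function(fes, region = NULL) {
  stopifnot(inherits(fes, "fes"))
  d <- fes$d
  n <- lengths(fes$axes)
  if (is.null(region)) {
    region <- rbind(vapply(fes$axes, min, 1), vapply(fes$axes, max, 1))
  } else if (!is.matrix(region)) region <- matrix(region, nrow = 2)
  inbox <- lapply(seq_len(d), function(j) {
    fes$axes[[j]] >= region[1, j] & fes$axes[[j]] <= region[2, j]
  })
  Fbig <- fes$F
  Fbig[!fes$mask] <- Inf
  cand <- list()
  if (d == 1L) {
    Fv <- as.numeric(Fbig)
    for (i in which(inbox[[1]] & is.finite(Fv))) {
      nb <- c(if (i > 1) Fv[i - 1], if (i < n[1]) Fv[i + 1])
      if (all(Fv[i] <= nb)) cand[[length(cand) + 1L]] <- i
    }
  } else {
    for (i in which(inbox[[1]])) for (j in which(inbox[[2]])) {
      if (!is.finite(Fbig[i, j])) next
      ii <- max(1, i - 1):min(n[1], i + 1)
      jj <- max(1, j - 1):min(n[2], j + 1)
      if (Fbig[i, j] <= min(Fbig[ii, jj])) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(cand)) stop("no visited local minimum inside the region")
  refine <- function(idx) {
    p <- Fval <- NULL
    p <- numeric(d)
    for (jd in seq_len(d)) {
      i <- idx[jd]
      ax <- fes$axes[[jd]]
      p[jd] <- ax[i]
      if (i > 1 && i < n[jd]) {
        sl <- function(k) { ix <- idx; ix[jd] <- k; Fbig[matrix(ix, 1)] }
        fm <- sl(i - 1); f0 <- sl(i); fp <- sl(i + 1)
        den <- fm - 2 * f0 + fp
        if (is.finite(den) && den > 0) {
          p[jd] <- ax[i] + 0.5 * (fm - fp) / den * (ax[2] - ax[1])
        }
      }
    }
    p
  }
  pts <- t(vapply(cand, function(ix) refine(as.integer(ix)), numeric(d)))
  Fv <- vapply(cand, function(ix) Fbig[matrix(as.integer(ix), 1)], 1)
  o <- order(Fv)
  # drop near-duplicates after refinement
  pts <- pts[o, , drop = FALSE]
  Fv <- Fv[o]
  keep <- !duplicated(round(pts / (fes$axes[[1]][2] - fes$axes[[1]][1])))
  structure(pts[keep, , drop = FALSE], F = Fv[keep])
}

#' Minimum free energy path by the string method
#'
#' Iterates (i) steepest-descent displacement of interior images along the
#' gradient component perpendicular to the path and (ii) reparameterization
#' to equal arc length, with fixed endpoints, until the maximum
#' perpendicular gradient drops below `tol` (or image displacement
#' stagnates) or `max_iter` is reached.
#'
#' @param fes A 2D `fes`.
#' @param start,end Endpoint CV points (typically from [find_minima()]).
#' @param n_images Number of images including endpoints (default 48).
#' @param tol Convergence threshold on the perpendicular gradient,
#'   kJ/mol/Angstrom (default 0.5).
#' @param max_iter Iteration cap (default 5000).
#' @param step_factor Maximum image displacement per iteration, as a
#'   fraction of the inter-image spacing.
#' @param waypoints Optional matrix of intermediate points for the initial
#'   path (default: straight line).
#' @return A `string_path`: `images`, `arc_length`, `F_along`, `converged`,
#'   `iterations`, `max_perp_grad`.
#' @export
string_mfep <- function(fes, start, end, n_images = 48L, tol = 0.5,
                        max_iter = 5000L, step_factor = 0.2,
                        waypoints = NULL) {
  stopifnot(inherits(fes, "fes"))
  d <- fes$d
  start <- rep_len(as.numeric(start), d)
  end <- rep_len(as.numeric(end), d)
  interp <- fes_interpolator(fes)
  if (max(interp$f(matrix(c(start, end), 2, d, byrow = TRUE))) >=
      interp$mask_value - 50) {
    stop("start/end lie outside the visited region of the surface")
  }
  if (sum((start - end)^2) == 0) {
    return(structure(list(images = matrix(start, 1, d),
                          arc_length = 0, F_along = interp$f(matrix(start, 1)),
                          converged = TRUE, iterations = 0L,
                          max_perp_grad = 0),
                     class = "string_path"))
  }
  lo <- vapply(fes$axes, min, 1); hi <- vapply(fes$axes, max, 1)
  anchors <- rbind(start, waypoints, end)
  seg <- sqrt(rowSums(diff(anchors)^2))
  tt <- c(0, cumsum(seg)) / sum(seg)
  ts <- seq(0, 1, length.out = n_images)
  path <- sapply(seq_len(d), function(j) stats::approx(tt, anchors[, j], ts)$y)
  path <- matrix(path, n_images, d)

  reparam <- function(p) {
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    if (s[length(s)] == 0) return(p)
    se <- seq(0, s[length(s)], length.out = nrow(p))
    matrix(sapply(seq_len(d), function(j) stats::approx(s, p[, j], se)$y),
           nrow(p), d)
  }

  inner <- 2:(n_images - 1)
  converged <- FALSE
  it <- 0L
  maxperp <- Inf
  for (it in seq_len(max_iter)) {
    g <- interp$grad(path)
    tan <- rbind(path[2, ] - path[1, ],
                 path[3:n_images, , drop = FALSE] -
                   path[1:(n_images - 2), , drop = FALSE],
                 path[n_images, ] - path[n_images - 1, ])
    tan <- tan / pmax(sqrt(rowSums(tan^2)), 1e-12)
    perp <- g - tan * rowSums(g * tan)
    maxperp <- max(sqrt(rowSums(perp[inner, , drop = FALSE]^2)))
    if (maxperp < tol) { converged <- TRUE; break }
    hspace <- sum(sqrt(rowSums(diff(path)^2))) / (n_images - 1)
    stepsz <- step_factor * hspace / max(maxperp, 1e-12)
    old <- path
    path[inner, ] <- path[inner, ] - stepsz * perp[inner, , drop = FALSE]
    path[, 1] <- pmin(pmax(path[, 1], lo[1]), hi[1])
    if (d == 2L) path[, 2] <- pmin(pmax(path[, 2], lo[2]), hi[2])
    path <- reparam(path)
    if (max(abs(path - old)) < 1e-6 * hspace) { converged <- maxperp < tol; break }
  }
  Fp <- interp$f(path)
  bad <- which(Fp >= interp$mask_value - 50)
  if (length(bad)) {
    stop("path exits the visited region at image ", bad[1])
  }
  structure(
    list(images = path,
         arc_length = c(0, cumsum(sqrt(rowSums(diff(path)^2)))),
         F_along = Fp, converged = converged, iterations = it,
         max_perp_grad = maxperp),
    class = "string_path"
  )
}

#' @export
print.string_path <- function(x, ...) {
  cat(sprintf(
    "<string_path> %d images, length %.3g A, %s after %d iteration(s), max perp grad %.3g kJ/mol/A\n",
    nrow(x$images), max(x$arc_length),
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$max_perp_grad))
  invisible(x)
}

#' One-dimensional profile along a path
#'
#' Free energy at each image against arc length, re-referenced so the bulk
#' endpoint (by default the endpoint farther from the CV origin, i.e. the
#' aqueous end of a permeation path) is zero.
#'
#' @param fes The `fes` the path was computed on.
#' @param path A `string_path`.
#' @param reference `"auto"` (farther endpoint from origin), `"start"`,
#'   `"end"`, or `"none"`.
#' @return A data.frame with columns `arc_length` and `F`.
#' @export
profile_along_path <- function(fes, path,
                               reference = c("auto", "start", "end", "none")) {
  stopifnot(inherits(path, "string_path"))
  reference <- match.arg(reference)
  interp <- fes_interpolator(fes)
  F <- interp$f(path$images)
  n <- nrow(path$images)
  ref <- switch(reference,
    none = 0,
    start = F[1],
    end = F[n],
    auto = if (sqrt(sum(path$images[1, ]^2)) >=
               sqrt(sum(path$images[n, ]^2))) F[1] else F[n])
  data.frame(arc_length = path$arc_length, F = F - ref)
}
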