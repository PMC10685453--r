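# FES estimation: reweighting reduction and recovery, block errors,
# symmetrization closed forms, asymmetry, bias-based cross-estimator.

make_fes_obj <- function(F, z = NULL, mask = NULL, err = NULL,
                         thermo = thermo310) {
  n <- length(F)
  if (is.null(z)) z <- seq(-n / 2 + 0.5, n / 2 - 0.5, length.out = n)
  sf <- flat_surface(1, z_max = max(abs(z)) + 0.5)
  fes <- fes_from_surface(sf, breaks = c(z - (z[2] - z[1]) / 2,
                                         max(z) + (z[2] - z[1]) / 2),
                          thermo = thermo)
  fes$F <- array(F, n)
  if (!is.null(mask)) fes$mask <- array(mask, n)
  fes$error <- if (is.null(err)) array(0, n) else array(err, n)
  fes$reference <- "none"
  fes
}

test_that("unbiased reweighting reduces to the plain histogram", {
  tr <- ou_run(k = 10, D = 0.5)
  breaks <- seq(-2, 2, by = 0.2)
  fes <- reweight_to_fes(tr, burn_in = 0, breaks = breaks)
  h <- table(cut(tr$values[, 1], breaks = breaks, right = FALSE))
  Fh <- -thermo310$kT * log(as.numeric(h))
  keep <- is.finite(Fh)
  expect_equal(as.numeric(fes$F)[keep] - min(as.numeric(fes$F)[keep]),
               Fh[keep] - min(Fh[keep]), tolerance = 1e-10)
  expect_identical(as.logical(fes$mask)[keep], rep(TRUE, sum(keep)))
})

test_that("reweighted FES recovers the double-well barrier", {
  res <- wtmetad_run_1d()
  fes <- reweight_to_fes(res$trajectory, res$ledger, res$reweight,
                         bin_width = 0.5)
  z <- fes$axes[[1]]
  barrier <- max(fes$F[abs(z) < 2]) - min(fes$F[fes$mask & abs(z) < 9])
  expect_equal(barrier, 10, tolerance = 0.1)

  # burn-in insensitivity on a converged run
  fes0 <- reweight_to_fes(res$trajectory, res$ledger, res$reweight,
                          burn_in = 0, bin_width = 0.5)
  b0 <- max(fes0$F[abs(z) < 2]) - min(fes0$F[fes0$mask & abs(z) < 9])
  err <- block_error(res$trajectory, res$ledger, res$reweight,
                     bin_width = 0.5)
  comb <- sqrt(sum(err$error[abs(z) < 2 | abs(z) < 9]^2, na.rm = TRUE))
  expect_lt(abs(b0 - barrier), max(comb, 0.5))
})

test_that("block errors: zero variance for identical blocks, sane scaling", {
  res <- wtmetad_run_1d()
  e3 <- block_error(res$trajectory, res$ledger, res$reweight, n_blocks = 3,
                    bin_width = 0.5)
  e6 <- block_error(res$trajectory, res$ledger, res$reweight, n_blocks = 6,
                    bin_width = 0.5)
  both <- e3$mask & !is.na(e3$error) & !is.na(e6$error) & e6$error > 0
  ratio <- e3$error[both] / e6$error[both]
  expect_true(stats::median(ratio) > 0.3 && stats::median(ratio) < 3)
  expect_error(block_error(res$trajectory, n_blocks = 1), ">= 2")

  # three identical copies of one block -> zero error
  tr <- ou_run(k = 10, D = 0.5)
  n <- nrow(tr$values)
  n3 <- floor(n / 3)
  rep3 <- tr
  rep3$values <- rbind(tr$values[1:n3, , drop = FALSE],
                       tr$values[1:n3, , drop = FALSE],
                       tr$values[1:n3, , drop = FALSE])
  rep3$times <- seq(0, by = tr$stride, length.out = 3 * n3)
  ez <- suppressWarnings(block_error(rep3, n_blocks = 3, burn_in = 0,
                                     bin_width = 0.2))
  expect_lt(max(ez$error[!is.na(ez$error)]), 1e-12)
})

test_that("symmetrization: fixed point, closed form, idempotence", {
  kT <- thermo310$kT; beta <- thermo310$beta
  sym0 <- make_fes_obj(c(3, 1, 4, 4, 1, 3))
  expect_equal(symmetrize(sym0)$F, sym0$F, tolerance = 1e-13)

  X <- 5
  step <- make_fes_obj(c(0, 0, 0, X, X, X))
  expect_equal(as.numeric(symmetrize(step)$F),
               rep(-kT * log((1 + exp(-beta * X)) / 2), 6), tolerance = 1e-12)

  set.seed(2)
  noisy <- make_fes_obj(runif(10, 0, 5))
  once <- symmetrize(noisy)
  expect_equal(symmetrize(once)$F, once$F, tolerance = 1e-10)

  # one-sided coverage is mirrored, double-masked bins stay masked
  half <- make_fes_obj(c(1, 2, NA, NA, NA, NA),
                       mask = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  sh <- symmetrize(half)
  expect_equal(as.numeric(sh$F[5:6]), c(2, 1))
  expect_false(any(sh$mask[3:4]))

  asym_ax <- make_fes_obj(1:5, z = c(-2, -1, 0, 1, 3))
  expect_error(symmetrize(asym_ax), "symmetric")
})

test_that("asymmetry measures the worst mirror mismatch", {
  expect_equal(asymmetry(make_fes_obj(c(1, 2, 2, 1))), 0)
  bump <- make_fes_obj(c(1, 2, 2 + 2, 1))
  expect_equal(asymmetry(bump), 2)
  res <- wtmetad_run_1d()
  err <- block_error(res$trajectory, res$ledger, res$reweight,
                     bin_width = 0.5)
  expect_lt(asymmetry(err), 3 * mean(err$error[err$mask], na.rm = TRUE) + 0.5)
})

test_that("bias-based estimator agrees with reweighting", {
  res <- wtmetad_run_1d()
  bb <- bias_based_fes(res$ledger, bias_grid(-12, 12, 481))
  expect_equal(max(bb$F) / max(-res$ledger$bias_factor /
                                 (res$ledger$bias_factor - 1) *
                                 evaluate_bias(res$ledger,
                                               bias_grid(-12, 12, 481))$values +
                                 max(res$ledger$bias_factor /
                                       (res$ledger$bias_factor - 1) *
                                       evaluate_bias(res$ledger,
                                                     bias_grid(-12, 12, 481))$values)),
               1, tolerance = 1e-9)   # prefactor gamma/(gamma-1) exactly
  z <- bb$axes[[1]]
  bar_bb <- max(bb$F[abs(z) < 2]) - min(bb$F[abs(z) < 9])
  fes <- reweight_to_fes(res$trajectory, res$ledger, res$reweight,
                         bin_width = 0.5)
  zf <- fes$axes[[1]]
  bar_rw <- max(fes$F[abs(zf) < 2]) - min(fes$F[fes$mask & abs(zf) < 9])
  expect_lt(abs(bar_bb - bar_rw), 1.5)
  flat <- bias_based_fes(empty_ledger(), bias_grid(-5, 5, 51))
  expect_true(all(flat$F == 0))
})

test_that("adding a constant to the bias only shifts the surface", {
  res <- wtmetad_run_1d()
  fes <- reweight_to_fes(res$trajectory, res$ledger, res$reweight,
                         bin_width = 0.5)
  rw2 <- res$reweight
  rw2$c_of_t <- rw2$c_of_t + 7.3   # constant added to V cancels through c(t)
  tr2 <- res$trajectory
  fes2 <- reweight_to_fes(tr2, res$ledger, rw2, bin_width = 0.5)
  expect_equal(fes$F[fes$mask], fes2$F[fes2$mask], tolerance = 1e-6)
})

test_that("marginalization projects a 2D surface onto one axis", {
  sf2 <- make_membrane_potential(model_potential(
    2, interfacial_min_depth = 10, core_barrier_height = 5,
    interfacial_min_position = 5, widths = c(well = 2, core = 2.5,
                                             coupling = 4),
    coupling_strength = 8, z_max = 10))
  fes2 <- fes_from_surface(sf2, bin_width = 0.25, thermo = thermo310)
  m <- fes_marginal(fes2, 1)
  expect_identical(m$d, 1L)
  # marginal keeps the interfacial minimum location
  expect_lt(abs(abs(m$axes[[1]][which.min(m$F)]) - 5), 0.5)
})
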