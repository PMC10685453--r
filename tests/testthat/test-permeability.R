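# Diffusion estimation and the inhomogeneous solubility-diffusion model.

flat_fes_z <- function(L = 50, bw = 0.5, val = 0, thermo = thermo310) {
  sf <- flat_surface(1, z_max = L / 2)
  fes <- fes_from_surface(sf, breaks = seq(-L / 2, L / 2, bw),
                          thermo = thermo)
  fes$F <- fes$F + val
  fes
}

test_that("OU window recovers the true diffusion coefficient", {
  tr <- ou_run(k = 10, D = 0.5)
  est <- estimate_D_at(tr)
  expect_equal(est$D, 0.5, tolerance = 0.15)
  # implied tau = var/D matches the OU relaxation time kT/(k D)
  expect_equal(est$tau, thermo310$kT / (10 * 0.5), tolerance = 0.25)
  # longer trajectories shrink the resampling error
  tr_short <- ou_run(k = 10, D = 0.5, n_steps = 2e5, seed = 7)
  expect_lt(est$error, estimate_D_at(tr_short)$error)
})

test_that("non-stationary input is rejected", {
  tr <- ou_run(k = 10, D = 0.5)
  heat <- tr
  n <- nrow(heat$values)
  heat$values[(n %/% 2):n, 1] <- 3 * heat$values[(n %/% 2):n, 1]
  expect_error(estimate_D_at(heat), "non-stationary")
})

test_that("window ladder recovers flat and two-level D(z) profiles", {
  centers <- seq(-10, 10, by = 2.5)
  run_ladder <- function(dm) {
    lapply(seq_along(centers), function(i) {
      sf <- harmonic_surface(10, centers[i], z_max = 25)
      simulate_overdamped(sf, dm, thermo310, dt = 0.01, n_steps = 4e5,
                          seed = 100 + i, stride = 1, init = centers[i])
    })
  }
  flat <- build_D_profile(run_ladder(diffusion_model("constant", 0.5)),
                          centers)
  expect_equal(flat$D, rep(0.5, length(flat$D)), tolerance = 0.2)
  expect_equal(flat$D, rev(flat$D), tolerance = 1e-12)  # symmetrized

  two <- build_D_profile(
    run_ladder(diffusion_model("smooth", D_bulk = 0.6, D_core = 0.2,
                               transition_width = 4)), centers)
  expect_equal(two$D[abs(two$z) >= 10], rep(0.6, sum(abs(two$z) >= 10)),
               tolerance = 0.2)
  expect_equal(two$D[two$z == 0], 0.2, tolerance = 0.2)
})

test_that("ISD closed forms: flat slab and square barrier", {
  th <- thermo310
  # flat F, constant D: P = D/L exactly
  fes <- flat_fes_z(L = 50)
  res <- isd_permeability(fes, 0.5, bounds = c(-25, 25))
  expect_equal(res$P_A_ps, 0.5 / 50, tolerance = 1e-9)
  expect_equal(res$P, 100, tolerance = 1e-9)

  # square barrier B over width w inside bulk segments
  B <- 11; w <- 10
  fes2 <- flat_fes_z(L = 50, bw = 0.05)
  z <- fes2$axes[[1]]
  fes2$F <- array(ifelse(abs(z) < w / 2, B, 0), length(z))
  res2 <- isd_permeability(fes2, 0.5, bounds = c(-25, 25))
  oneoverP <- (40 + 10 * exp(th$beta * B)) / 0.5
  expect_equal(1 / res2$P_A_ps, oneoverP, tolerance = 1e-3)

  # P falls monotonically with barrier height
  Ps <- sapply(c(5, 10, 15), function(b) {
    f <- fes2; f$F <- array(ifelse(abs(z) < w / 2, b, 0), length(z))
    isd_permeability(f, 0.5)$P
  })
  expect_true(all(diff(Ps) < 0))
})

test_that("ISD contracts: referencing, resistance additivity, units", {
  fes <- flat_fes_z(L = 50, val = 3)
  expect_error(isd_permeability(fes, 0.5), "bulk-referenced")

  # resistance additivity at an arbitrary interior split
  sf <- make_membrane_potential(model_potential(
    1, interfacial_min_depth = 8, core_barrier_height = 6,
    interfacial_min_position = 6, widths = c(well = 2, core = 3),
    z_max = 20))
  fes2 <- fes_from_surface(sf, bin_width = 0.1, reference = "bulk-zero",
                           bulk_cut = 17)
  whole <- isd_permeability(fes2, 0.5, bounds = c(-18, 18))
  zsplit <- 4.3   # arbitrary interior split, not a grid node
  left <- isd_permeability(fes2, 0.5, bounds = c(-18, zsplit),
                           check_reference = FALSE)
  right <- isd_permeability(fes2, 0.5, bounds = c(zsplit, 18),
                            check_reference = FALSE)
  expect_equal(1 / left$P_A_ps + 1 / right$P_A_ps, 1 / whole$P_A_ps,
               tolerance = 1e-10)

  # units round trip
  expect_equal(whole$P / 1e4, whole$P_A_ps, tolerance = 1e-12)
})

test_that("field energy scale converts units correctly", {
  fs <- field_spec(E = 10, mu = 5.8)
  val <- field_energy_scale(fs)
  expect_equal(val, 2.33, tolerance = 1e-3)
  expect_gt(val, 2); expect_lt(val, 3)
  expect_equal(field_energy_scale(field_spec(E = 0, mu = 5.8)), 0)
  expect_equal(field_energy_scale(field_spec(E = 10, mu = 11.6)), 2 * val,
               tolerance = 1e-12)
})

test_that("field tilt perturbs the surface within the dipole bound", {
  sf <- make_membrane_potential(model_potential(
    1, interfacial_min_depth = 10, core_barrier_height = 5,
    interfacial_min_position = 6, widths = c(well = 2, core = 3),
    z_max = 15))
  fes <- fes_from_surface(sf, bin_width = 0.25)
  fs <- field_spec(E = 10, mu = 5.8)
  # no coupling, no change
  expect_equal(apply_field_tilt(fes, fs, function(z) 0 * z)$F, fes$F)
  # antisymmetric constant-magnitude coupling splits the minima by 2 E mu c0
  c0 <- 0.9
  tilted <- apply_field_tilt(fes, fs, function(z) c0 * sign(z) *
                               (abs(z) > 1e-9))
  z <- fes$axes[[1]]
  zmin <- abs(z[which.min(fes$F)])   # exact mirror pair of bin centres
  Fm <- tilted$F[which.min(abs(z + zmin))]
  Fp <- tilted$F[which.min(abs(z - zmin))]
  expect_equal(abs(Fp - Fm), field_energy_scale(fs) * c0, tolerance = 1e-9)
  # bound: perturbation never exceeds E mu
  expect_lte(max(abs(tilted$F - fes$F)), field_energy_scale(fs) / 2 + 1e-12)
  expect_error(apply_field_tilt(fes, fs, function(z) 1.5 + 0 * z), "within")
})
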