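# Protomer coupling: aqueous shift arithmetic, populations, combined
# surface identities and bounds, difference map.

fes_const <- function(vals, thermo = thermo310) {
  n <- length(vals)
  z <- seq(-n / 2 + 0.5, n / 2 - 0.5)
  sf <- flat_surface(1, z_max = n / 2)
  fes <- fes_from_surface(sf, breaks = seq(-n / 2, n / 2, 1), thermo = thermo)
  fes$F <- array(vals, n)
  fes$error <- array(0, n)
  fes$reference <- "none"
  fes
}

test_that("aqueous shift is kT ln10 (pKa - pH)", {
  th <- thermo_state(310)
  expect_equal(aqueous_shift(7, 7, th), 0)
  expect_equal(aqueous_shift(10.4, 7, th),
               log(10) * th$kT * 3.4, tolerance = 1e-12)
  expect_equal(aqueous_shift(10.4, 7, th), 20.18, tolerance = 1e-3)
  expect_equal(aqueous_shift(10.4, 7, th), -aqueous_shift(7, 10.4, th))
})

test_that("populations follow two-state Boltzmann statistics", {
  th <- thermo310
  f0 <- fes_const(rep(5, 4)); fp <- fes_const(rep(5, 4))
  p <- protomer_populations(f0, fp)
  expect_equal(as.numeric(p$p_neutral), rep(0.5, 4), tolerance = 1e-14)

  shift <- aqueous_shift(10.4, 7, th)
  p2 <- protomer_populations(fes_const(rep(shift, 4)), fes_const(rep(0, 4)))
  expect_equal(as.numeric(p2$p_neutral),
               rep(1 / (1 + exp(th$beta * shift)), 4), tolerance = 1e-12)
  expect_lt(p2$p_neutral[1], 5e-4)   # neutral form ~1 in 2500 in water
  expect_gt(p2$p_neutral[1], 1e-4)

  p3 <- protomer_populations(fes_const(rep(0, 4)), fes_const(rep(50, 4)))
  expect_lt(max(p3$p_protonated), 1e-8)
  expect_equal(as.numeric(p3$p_neutral + p3$p_protonated), rep(1, 4),
               tolerance = 1e-12)
  expect_error(protomer_populations(fes_const(rep(0, 4)),
                                    fes_const(rep(0, 6))), "axes")
})

test_that("combined surface obeys the exact two-state identities", {
  th <- thermo310
  set.seed(9)
  a <- fes_const(runif(20, -5, 30))
  b <- fes_const(runif(20, -5, 30))
  comb <- combine_surfaces(a, b)
  # identical inputs: F - kT ln 2
  same <- combine_surfaces(a, a)
  expect_equal(same$F, a$F - th$kT * log(2), tolerance = 1e-12)
  # dominance: a surface 100 kJ/mol higher vanishes
  hi <- fes_const(a$F + 100)
  expect_equal(combine_surfaces(a, hi)$F, a$F, tolerance = 1e-10)
  # mixing bounds per bin
  lo <- pmin(a$F, b$F)
  expect_true(all(comb$F <= lo + 1e-12))
  expect_true(all(comb$F >= lo - th$kT * log(2) - 1e-12))
  # -kT ln p_i = F_i - F_comb
  p <- protomer_populations(a, b)
  expect_equal(-th$kT * log(p$p_neutral), a$F - comb$F, tolerance = 1e-10)
  expect_equal(-th$kT * log(p$p_protonated), b$F - comb$F, tolerance = 1e-10)
  # round trip: F_i = F_comb - kT ln p_i recovers the inputs
  expect_equal(comb$F - th$kT * log(p$p_neutral), a$F, tolerance = 1e-10)
  expect_equal(comb$F - th$kT * log(p$p_protonated), b$F, tolerance = 1e-10)
  # and equals the population-weighted mean minus mixing entropy
  wmean <- p$p_neutral * a$F + p$p_protonated * b$F
  smix <- -th$kT * (p$p_neutral * log(p$p_neutral) +
                      p$p_protonated * log(p$p_protonated))
  expect_equal(comb$F, wmean - smix, tolerance = 1e-9)
})

test_that("difference map sign convention and bulk value", {
  expect_true(all(delta_surface(fes_const(rep(2, 4)),
                                fes_const(rep(2, 4)))$F == 0))
  th <- thermo310
  shift <- aqueous_shift(10.4, 7, th)
  # synthetic protomer pair; wide domain so the penalty fully decays in bulk
  base <- make_membrane_potential(model_potential(
    2, interfacial_min_depth = 15, core_barrier_height = 5,
    interfacial_min_position = 6, widths = c(well = 2, core = 3,
                                             coupling = 5),
    coupling_strength = 10, z_max = 45))
  pair <- make_protomer_pair(base, core_penalty = 50, core_width = 7.4)
  f0 <- shift_fes(fes_from_surface(pair$neutral, bin_width = 1,
                                   reference = "bulk-zero", bulk_cut = 40),
                  shift)
  fp <- fes_from_surface(pair$charged, bin_width = 1,
                         reference = "bulk-zero", bulk_cut = 40)
  dmap <- delta_surface(fp, f0)
  expect_true(dmap$signed)
  # bulk value is -shift by construction
  corner <- which.max(dmap$axes[[1]])
  expect_equal(dmap$F[corner, corner], -shift, tolerance = 1e-6)
  # protonated preferred (negative) in bulk, neutral preferred in the core
  i0 <- which.min(abs(dmap$axes[[1]]))
  expect_lt(dmap$F[corner, corner], 0)
  expect_gt(dmap$F[i0, i0], 0)
  # zero crossing along the tail axis where the core penalty equals the
  # shift: 50 exp(-t^2/(2 7.4^2)) = shift  =>  |t| ~ 9.9 A
  t_cross <- sqrt(-2 * 7.4^2 * log(shift / 50))
  prof <- dmap$F[i0, ]   # vary CV_tail at ring fixed in the core
  tt <- dmap$axes[[2]]
  sgn <- sign(prof)
  flips <- tt[which(diff(sgn) != 0)]
  expect_true(any(abs(abs(flips) - t_cross) < 1))
})

test_that("combined barrier sits between the protomer barriers", {
  base <- make_membrane_potential(model_potential(
    1, interfacial_min_depth = 15, core_barrier_height = 5,
    interfacial_min_position = 6, widths = c(well = 2, core = 3),
    z_max = 14))
  pair <- make_protomer_pair(base, core_penalty = 30, core_width = 5)
  shift <- aqueous_shift(10.4, 7, thermo310)
  f0 <- shift_fes(fes_from_surface(pair$neutral, bin_width = 0.25,
                                   reference = "bulk-zero", bulk_cut = 12),
                  shift)
  fp <- fes_from_surface(pair$charged, bin_width = 0.25,
                         reference = "bulk-zero", bulk_cut = 12)
  comb <- combine_surfaces(f0, fp)
  barrier <- function(f) max(f$F[abs(f$axes[[1]]) < 2]) - min(f$F)
  expect_gte(barrier(comb), min(barrier(f0), barrier(fp)) - 1e-9)
  expect_lte(barrier(comb), max(barrier(f0), barrier(fp)) + 1e-9)
})
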