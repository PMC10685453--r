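# Protonation-state coupling: combine neutral and protonated permeation
# surfaces through the aqueous acid-base equilibrium. The neutral surface is
# first raised by kT ln(10) (pKa - pH) so the two share the bulk-water
# reference, then per-bin protomer populations and the exact
# partition-function (log-sum-exp) combined surface follow.

#' Aqueous acid-base shift between protomer surfaces
#'
#' `kT ln(10) (pKa - pH)`: the free energy by which the neutral form is
#' raised relative to the protonated form in bulk water. Defaults reflect a
#' weak base with pKa 10.4 at pH 7 and 310 K, where the neutral fraction in
#' water is about 1 in 2500.
#'
#' @param pKa Acid dissociation constant of the protonated form.
#' @param pH Solution pH.
#' @param thermo A [thermo_state()].
#' @return Shift in kJ/mol (positive when pKa > pH).
#' @export
aqueous_shift <- function(pKa = 10.4, pH = 7, thermo = thermo_state()) {
  thermo <- .as_thermo(thermo)
  stopifnot(is.finite(pKa), is.finite(pH))
  thermo$kT * log(10) * (pKa - pH)
}

.check_shared_axes <- function(a, b) {
  stopifnot(inherits(a, "fes"), inherits(b, "fes"))
  if (a$d != b$d || !isTRUE(all.equal(a$axes, b$axes, tolerance = 1e-9))) {
    stop("surfaces must share identical axes")
  }
  invisible(TRUE)
}

#' Per-bin protomer populations
#'
#' Boltzmann fractions `p_i(s) = e^{-beta F_i(s)} / sum_j e^{-beta F_j(s)}`
#' from two surfaces on shared axes, with the aqueous shift already applied
#' to the neutral one. Bins masked in either input are masked in both
#' outputs; visited fractions sum to 1 per bin.
#'
#' @param f_neutral_shifted Shifted neutral-form `fes`.
#' @param f_protonated Protonated-form `fes`.
#' @return List with arrays `p_neutral`, `p_protonated` and logical `mask`.
#' @export
protomer_populations <- function(f_neutral_shifted, f_protonated) {
  .check_shared_axes(f_neutral_shifted, f_protonated)
  beta <- f_neutral_shifted$thermo$beta
  mask <- f_neutral_shifted$mask & f_protonated$mask
  dF <- f_protonated$F - f_neutral_shifted$F   # F+ - F0'
  p0 <- array(NA_real_, dim = dim(f_neutral_shifted$F))
  p0[mask] <- 1 / (1 + exp(-beta * dF[mask]))
  pp <- 1 - p0
  list(p_neutral = p0, p_protonated = pp, mask = mask)
}

#' Combine protomer surfaces
#'
#' Exact two-state partition function per bin:
#' `F_comb(s) = -kT ln(e^{-beta F0'(s)} + e^{-beta F+(s)})`. Equals the
#' population-weighted mean of the two surfaces minus the mixing-entropy
#' term (the identity is enforced internally), lies between
#' `min(F0', F+) - kT ln 2` and `min(F0', F+)`, and reduces to the lower
#' surface wherever one protomer dominates.
#'
#' @inheritParams protomer_populations
#' @param reference Reference convention applied to the result (default
#'   keep: `"none"`).
#' @param bulk_cut Passed to [reference_fes()] if re-referencing.
#' @return The combined `fes`.
#' @export
combine_surfaces <- function(f_neutral_shifted, f_protonated,
                             reference = c("none", "bulk-zero", "min-zero"),
                             bulk_cut = NULL) {
  .check_shared_axes(f_neutral_shifted, f_protonated)
  reference <- match.arg(reference)
  beta <- f_neutral_shifted$thermo$beta
  kT <- f_neutral_shifted$thermo$kT
  mask <- f_neutral_shifted$mask & f_protonated$mask
  a <- f_neutral_shifted$F; b <- f_protonated$F
  F <- array(NA_real_, dim = dim(a))
  lo <- pmin(a[mask], b[mask]); hi <- pmax(a[mask], b[mask])
  F[mask] <- lo - kT * log1p(exp(-beta * (hi - lo)))
  err <- array(NA_real_, dim = dim(a))
  if (!all(is.na(f_neutral_shifted$error)) || !all(is.na(f_protonated$error))) {
    # population-weighted first-order propagation
    p <- protomer_populations(f_neutral_shifted, f_protonated)
    e0 <- f_neutral_shifted$error; ep <- f_protonated$error
    err[mask] <- sqrt((p$p_neutral[mask] * e0[mask])^2 +
                        (p$p_protonated[mask] * ep[mask])^2)
  }
  out <- .new_fes(f_neutral_shifted$axes, F, err, mask, reference = "none",
                  thermo = f_neutral_shifted$thermo)
  if (reference != "none") out <- reference_fes(out, reference, bulk_cut)
  out
}

#' Protomer free-energy difference map
#'
#' `dF(s) = F_protonated(s) - F_neutral_shifted(s)`: negative where the
#' protonated form is preferred. In bulk water it equals minus the aqueous
#' shift by construction; its zero-crossing band marks where deprotonation
#' becomes favourable (at the lipid/water interface for a membrane
#' landscape), the natural candidate region for proton transfer.
#'
#' @inheritParams protomer_populations
#' @return A signed `fes`-like difference map.
#' @export
delta_surface <- function(f_protonated, f_neutral_shifted) {
  .check_shared_axes(f_protonated, f_neutral_shifted)
  mask <- f_protonated$mask & f_neutral_shifted$mask
  dF <- array(NA_real_, dim = dim(f_protonated$F))
  dF[mask] <- f_protonated$F[mask] - f_neutral_shifted$F[mask]
  err <- array(NA_real_, dim = dim(dF))
  if (!all(is.na(f_protonated$error)) && !all(is.na(f_neutral_shifted$error))) {
    err[mask] <- sqrt(f_protonated$error[mask]^2 +
                        f_neutral_shifted$error[mask]^2)
  }
  .new_fes(f_protonated$axes, dF, err, mask, reference = "none",
           thermo = f_protonated$thermo, signed = TRUE)
}
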