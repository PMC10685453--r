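# End-to-end orchestration: synthetic landscape -> biased sampling ->
# reweighted/symmetrized surfaces -> MFEP -> protomer combination ->
# diffusion windows -> permeability, all driven by one config and one seed.
# Every stage draws its seed from a named substream of the master seed and
# every artifact embeds the config hash.

.substream <- function(seed, k) as.integer((as.numeric(seed) * 97 + k) %%
                                             2147483629)

.log_line <- function(logfile, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = logfile, append = TRUE, sep = "")
}

#' Run the full permeation pipeline from one configuration
#'
#' Stages: (1) well-tempered metadynamics on the configured landscape,
#' (2) reweighted surface with three-block errors, symmetrization and the
#' asymmetry check, (3) string-method MFEP between the two interfacial
#' minima (2D), (4) optional protomer branch: a second biased run on the
#' charged landscape, aqueous pKa shift, combined surface and difference
#' map, (5) restrained diffusion windows and the D(z) profile, (6) the
#' solubility-diffusion permeability. Artifacts are written as PLUMED-
#' dialect text files embedding the config hash; a JSON-lines log records
#' parameters and seeds per stage.
#'
#' @param config A `run_config`, a list coercible to one, or a YAML path.
#' @param seed Optional master seed overriding `config$seed`.
#' @param outdir Optional output directory overriding `config$outdir`.
#' @param quiet Suppress progress messages.
#' @return A list with every intermediate object plus `permeability`
#'   (and `permeability_combined` when the protomer branch runs).
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else
    as_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hset <- list(config_hash = hash)
  logfile <- file.path(cfg$outdir, "pipeline.log.jsonl")
  if (file.exists(logfile)) file.remove(logfile)
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- function(name) file.path(cfg$outdir, name)

  thermo <- thermo_state(cfg$thermo$temperature)
  pot <- do.call(model_potential, cfg$landscape)
  surface <- make_membrane_potential(pot)
  diff_mod <- do.call(diffusion_model, cfg$diffusion)
  d <- surface$d
  .log_line(logfile, "setup", seed = cfg$seed, config_hash = hash,
            dimensionality = d)

  run_one <- function(sf, gamma, seed_sub, tag) {
    say("metadynamics run (%s): %g steps", tag, cfg$run$n_steps)
    res <- run_wtmetad(sf, diff_mod, thermo,
                       dt = cfg$run$dt, n_steps = cfg$run$n_steps,
                       seed = seed_sub, stride = cfg$run$stride,
                       w0 = cfg$metad$w0, sigma = cfg$metad$sigma,
                       pace = cfg$metad$pace, bias_factor = gamma,
                       grid_spacing = cfg$metad$grid_spacing)
    write_colvar(res$trajectory, art(paste0("COLVAR.", tag)), hset)
    write_hills(res$ledger, art(paste0("HILLS.", tag)), hset)
    .log_line(logfile, paste0("metad_", tag), seed = seed_sub,
              bias_factor = gamma, kernels = length(res$ledger),
              c_end = utils::tail(res$reweight$c_of_t, 1))
    res
  }
  make_fes <- function(res, tag) {
    fes <- block_error(res$trajectory, res$ledger, res$reweight,
                       n_blocks = cfg$fes$n_blocks,
                       burn_in = cfg$fes$burn_in,
                       bin_width = cfg$fes$bin_width,
                       breaks = .fes_breaks(surface$z_max, cfg$fes$bin_width),
                       reference = "bulk-zero", bulk_cut = cfg$fes$bulk_cut)
    sym <- symmetrize(fes)
    asym <- asymmetry(fes)
    write_fes(sym, art(paste0("fes_", tag, ".dat")), hset)
    .log_line(logfile, paste0("fes_", tag), asymmetry = asym,
              mean_block_error = mean(fes$error[fes$mask], na.rm = TRUE))
    list(fes = fes, sym = sym, asymmetry = asym)
  }

  res0 <- run_one(surface, cfg$metad$bias_factor, .substream(cfg$seed, 1L),
                  "neutral")
  f0 <- make_fes(res0, "neutral")

  mfep <- NULL
  if (d == 2L) {
    minima <- find_minima(f0$sym)
    m1 <- minima[1, ]
    path <- string_mfep(f0$sym, start = -abs(m1), end = abs(m1),
                        n_images = cfg$mfep$n_images, tol = cfg$mfep$tol,
                        max_iter = cfg$mfep$max_iter)
    write_path(path, art("mfep_neutral.dat"), hset)
    .log_line(logfile, "mfep", converged = path$converged,
              iterations = path$iterations,
              barrier = max(path$F_along) - min(path$F_along))
    mfep <- path
  }

  prot <- NULL
  if (isTRUE(cfg$protomer$enabled)) {
    pair <- make_protomer_pair(surface, cfg$protomer$core_penalty,
                               cfg$protomer$core_width)
    resp <- run_one(pair$charged, cfg$protomer$bias_factor_charged,
                    .substream(cfg$seed, 2L), "charged")
    fp <- make_fes(resp, "charged")
    shift <- aqueous_shift(cfg$protomer$pKa, cfg$protomer$pH, thermo)
    f0s <- shift_fes(f0$sym, shift)
    comb <- combine_surfaces(f0s, fp$sym, reference = "bulk-zero",
                             bulk_cut = cfg$fes$bulk_cut)
    dmap <- delta_surface(fp$sym, f0s)
    write_fes(comb, art("fes_combined.dat"), hset)
    write_fes(dmap, art("fes_delta.dat"), hset)
    .log_line(logfile, "protomer", aqueous_shift = shift,
              pKa = cfg$protomer$pKa, pH = cfg$protomer$pH)
    prot <- list(charged = fp, shifted_neutral = f0s, combined = comb,
                 delta = dmap, shift = shift, run = resp)
  }

  say("diffusion windows: %d centres", length(cfg$permeability$window_centers))
  centers <- cfg$permeability$window_centers
  wtrajs <- lapply(seq_along(centers), function(i) {
    sf <- harmonic_surface(cfg$permeability$window_k, centers[i], d = 1L,
                           z_max = surface$z_max)
    simulate_overdamped(sf, diff_mod, thermo, dt = cfg$run$dt,
                        n_steps = cfg$permeability$window_steps,
                        seed = .substream(cfg$seed, 100L + i),
                        stride = cfg$permeability$window_stride,
                        init = centers[i])
  })
  dprof <- build_D_profile(wtrajs, centers)
  utils::write.table(
    data.frame(z = dprof$z, D = .fmt_num(dprof$D),
               error = .fmt_num(dprof$error)),
    art("D_profile.dat"), quote = FALSE, row.names = FALSE)

  to_z_profile <- function(fes2) {
    prof <- if (d == 2L) fes_marginal(fes2, axis = 1L) else fes2
    prof <- reference_fes(prof, "bulk-zero", bulk_cut = cfg$fes$bulk_cut)
    # resample F onto a fine grid so the exp(beta F) quadrature is smooth
    z <- prof$axes[[1]]
    zf <- seq(min(z), max(z), by = 0.1)
    Ff <- stats::approx(z, as.numeric(prof$F), zf)$y
    Ef <- stats::approx(z, ifelse(is.finite(prof$error), prof$error, 0), zf)$y
    fine <- prof
    fine$axes <- list(zf)
    fine$F <- array(Ff, length(zf))
    fine$error <- array(Ef, length(zf))
    fine$mask <- array(!is.na(Ff), length(zf))
    fine
  }
  b <- cfg$permeability$bounds
  perm <- isd_permeability(to_z_profile(f0$sym), dprof, bounds = c(-b, b))
  .log_line(logfile, "permeability", P_cm_s = perm$P, error = perm$error)
  perm_comb <- NULL
  if (!is.null(prot)) {
    perm_comb <- isd_permeability(to_z_profile(prot$combined), dprof,
                                  bounds = c(-b, b))
    .log_line(logfile, "permeability_combined", P_cm_s = perm_comb$P,
              error = perm_comb$error)
  }
  summary <- list(
    config_hash = hash, seed = cfg$seed,
    asymmetry_neutral = f0$asymmetry,
    P_cm_s = perm$P, P_err_cm_s = perm$error,
    P_combined_cm_s = if (!is.null(perm_comb)) perm_comb$P else NULL,
    mfep_barrier = if (!is.null(mfep)) max(mfep$F_along) - min(mfep$F_along)
      else NULL
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             art("summary.json"))
  say("pipeline done: P = %.4g +/- %.2g cm/s", perm$P, perm$error)
  invisible(list(config = cfg, surface = surface, neutral = res0,
                 fes_neutral = f0, mfep = mfep, protomer = prot,
                 D_profile = dprof, permeability = perm,
                 permeability_combined = perm_comb, summary = summary))
}
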