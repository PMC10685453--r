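# PLUMED-dialect text I/O: COLVAR (CV time series), HILLS (kernel ledgers),
# grid files (free energy surfaces with an error column), and path tables.
# Everything is whitespace-separated text printed to 12 significant digits,
# which round-trips doubles losslessly for practical purposes and keeps
# fixtures diff-able.

.fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g", width = 1)
  out[!is.finite(x)] <- "nan"
  out
}

.read_plumed <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#! FIELDS")) {
    stop("missing '#! FIELDS' header in ", path)
  }
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  setl <- grep("^#! SET ", lines, value = TRUE)
  sets <- list()
  for (s in setl) {
    tok <- strsplit(sub("^#! SET\\s+", "", s), "\\s+")[[1]]
    sets[[tok[1]]] <- paste(tok[-1], collapse = " ")
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    return(list(fields = fields, sets = sets,
                data = matrix(numeric(0), 0, length(fields),
                              dimnames = list(NULL, fields))))
  }
  toks <- strsplit(trimws(body), "\\s+")
  nf <- lengths(toks)
  bad <- which(nf != length(fields))
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: %d fields, expected %d",
                 bad[1] + 1L, path, nf[bad[1]], length(fields)))
  }
  dat <- matrix(suppressWarnings(as.numeric(unlist(toks))),
                ncol = length(fields), byrow = TRUE,
                dimnames = list(NULL, fields))
  list(fields = fields, sets = sets, data = dat)
}

.write_plumed <- function(path, fields, data, sets = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  for (nm in names(sets)) {
    writeLines(paste("#! SET", nm, sets[[nm]]), con)
  }
  if (nrow(data)) {
    txt <- apply(matrix(.fmt_num(data), nrow = nrow(data)), 1, paste,
                 collapse = " ")
    writeLines(txt, con)
  }
  invisible(path)
}

#' Write a CV trajectory as a PLUMED-dialect COLVAR file
#'
#' Header `#! FIELDS time <cv names>`, one frame per line, time in ps, CVs
#' in Angstrom, 12 significant digits.
#'
#' @param traj A `cv_trajectory`.
#' @param path Output file.
#' @param sets Named list of extra `#! SET` metadata lines.
#' @return The path, invisibly.
#' @export
write_colvar <- function(traj, path, sets = list()) {
  stopifnot(inherits(traj, "cv_trajectory"))
  sets <- c(list(temperature = .fmt_num(traj$thermo$temperature),
                 seed = as.character(traj$seed)), sets)
  .write_plumed(path, c("time", colnames(traj$values)),
                cbind(traj$times, traj$values), sets)
  invisible(path)
}

#' Read a PLUMED-dialect COLVAR file
#'
#' Columns are mapped by header name: `time` must be present; every column
#' starting with `cv` becomes a CV, in file order; other columns are
#' ignored.
#'
#' @param path COLVAR file.
#' @param thermo A [thermo_state()]; overridden by a `temperature` SET line
#'   if present.
#' @return A `cv_trajectory`.
#' @export
read_colvar <- function(path, thermo = thermo_state()) {
  p <- .read_plumed(path)
  if (!"time" %in% p$fields) stop("COLVAR has no 'time' column")
  cvs <- grep("^cv", p$fields, value = TRUE)
  if (!length(cvs)) stop("COLVAR has no cv* columns")
  times <- p$data[, "time"]
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("non-monotone time column in ", path)
  }
  if (!is.null(p$sets$temperature)) {
    thermo <- thermo_state(as.numeric(p$sets$temperature))
  }
  seed <- if (!is.null(p$sets$seed)) as.integer(p$sets$seed) else NA_integer_
  stride <- if (length(times) > 1) times[2] - times[1] else NA_real_
  traj <- .new_cv_trajectory(times, p$data[, cvs, drop = FALSE], thermo,
                             stride, seed)
  colnames(traj$values) <- cvs
  traj
}

#' Write a kernel ledger as a PLUMED-dialect HILLS file
#'
#' Header `#! FIELDS time <cv> ... sigma_<cv> ... height biasf`, one kernel
#' per line.
#'
#' @param ledger A [hills_ledger()].
#' @param path Output file.
#' @param sets Named list of extra `#! SET` metadata lines.
#' @return The path, invisibly.
#' @export
write_hills <- function(ledger, path, sets = list()) {
  stopifnot(inherits(ledger, "hills_ledger"))
  cvn <- .cv_names(ledger$d)
  fields <- c("time", cvn, paste0("sigma_", cvn), "height", "biasf")
  dat <- cbind(ledger$time, ledger$center, ledger$sigma, ledger$height,
               rep(ledger$bias_factor, length(ledger$time)))
  sets <- c(list(temperature = .fmt_num(ledger$thermo$temperature),
                 pace = .fmt_num(ledger$pace)), sets)
  .write_plumed(path, fields, dat, sets)
  invisible(path)
}

#' Read a PLUMED-dialect HILLS file
#'
#' @param path HILLS file.
#' @param thermo A [thermo_state()]; overridden by a `temperature` SET line.
#' @return A [hills_ledger()]; the `biasf` column must be constant and the
#'   kernel times strictly increasing.
#' @export
read_hills <- function(path, thermo = thermo_state()) {
  p <- .read_plumed(path)
  cvs <- grep("^cv", p$fields, value = TRUE)
  cvs <- setdiff(cvs, grep("^sigma_", p$fields, value = TRUE))
  need <- c("time", cvs, paste0("sigma_", cvs), "height", "biasf")
  miss <- setdiff(need, p$fields)
  if (length(miss)) stop("HILLS missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(p$data) == 0L) stop("HILLS file has no kernels")
  bf <- unique(p$data[, "biasf"])
  if (length(bf) != 1L) stop("inconsistent biasf column in ", path)
  if (!is.null(p$sets$temperature)) {
    thermo <- thermo_state(as.numeric(p$sets$temperature))
  }
  times <- p$data[, "time"]
  pace <- if (!is.null(p$sets$pace)) as.numeric(p$sets$pace) else
    if (length(times) > 1) stats::median(diff(times)) else 1
  hills_ledger(times, p$data[, cvs, drop = FALSE],
               p$data[, paste0("sigma_", cvs), drop = FALSE],
               p$data[, "height"], bias_factor = bf, thermo = thermo,
               pace = pace)
}

#' Write a free-energy surface as a PLUMED-style grid file
#'
#' Header `#! FIELDS <cv> ... free error` plus `#! SET min_/max_/nbins_`
#' lines per axis; one node per line, first axis fastest. Masked bins print
#' `nan`. Difference maps carry `#! SET signed 1`.
#'
#' @param fes An `fes`.
#' @param path Output file.
#' @param sets Named list of extra `#! SET` metadata lines.
#' @return The path, invisibly.
#' @export
write_fes <- function(fes, path, sets = list()) {
  stopifnot(inherits(fes, "fes"))
  cvn <- .cv_names(fes$d)
  pts <- as.matrix(do.call(expand.grid, fes$axes))
  F <- as.numeric(fes$F)
  F[!fes$mask] <- NaN
  E <- as.numeric(fes$error)
  E[!fes$mask] <- NaN
  ax_sets <- list()
  for (j in seq_len(fes$d)) {
    ax <- fes$axes[[j]]
    ax_sets[[paste0("min_", cvn[j])]] <- .fmt_num(min(ax))
    ax_sets[[paste0("max_", cvn[j])]] <- .fmt_num(max(ax))
    ax_sets[[paste0("nbins_", cvn[j])]] <- as.character(length(ax))
  }
  sets <- c(ax_sets,
            list(reference = fes$reference,
                 signed = if (isTRUE(fes$signed)) "1" else "0",
                 temperature = .fmt_num(fes$thermo$temperature)),
            sets)
  .write_plumed(path, c(cvn, "free", "error"), cbind(pts, F, E), sets)
  invisible(path)
}

#' Read a free-energy surface grid file
#' @param path Grid file written by [write_fes()].
#' @return An `fes` (bins whose `free` is `nan` come back masked).
#' @export
read_fes <- function(path) {
  p <- .read_plumed(path)
  cvn <- setdiff(p$fields, c("free", "error"))
  d <- length(cvn)
  n <- vapply(cvn, function(nm) as.integer(p$sets[[paste0("nbins_", nm)]]), 1L)
  axes <- lapply(seq_len(d), function(j) {
    seq(as.numeric(p$sets[[paste0("min_", cvn[j])]]),
        as.numeric(p$sets[[paste0("max_", cvn[j])]]), length.out = n[j])
  })
  F <- array(p$data[, "free"], dim = n)
  E <- array(p$data[, "error"], dim = n)
  mask <- !is.na(F)
  thermo <- if (!is.null(p$sets$temperature)) {
    thermo_state(as.numeric(p$sets$temperature))
  } else thermo_state()
  .new_fes(axes, F, E, mask,
           reference = if (!is.null(p$sets$reference)) p$sets$reference else "none",
           thermo = thermo, signed = identical(p$sets$signed, "1"))
}

#' Write a string path as a whitespace table
#'
#' Columns: image index, CV coordinates, arc length, free energy.
#'
#' @param path_obj A `string_path`.
#' @param path Output file.
#' @param sets Named list of extra `#! SET` metadata lines.
#' @return The path, invisibly.
#' @export
write_path <- function(path_obj, path, sets = list()) {
  stopifnot(inherits(path_obj, "string_path"))
  d <- ncol(path_obj$images)
  fields <- c("image", .cv_names(d), "arc_length", "free")
  dat <- cbind(seq_len(nrow(path_obj$images)), path_obj$images,
               path_obj$arc_length, path_obj$F_along)
  sets <- c(list(converged = if (path_obj$converged) "1" else "0",
                 iterations = as.character(path_obj$iterations)), sets)
  .write_plumed(path, fields, dat, sets)
  invisible(path)
}

#' Read a string path table written by [write_path()]
#' @param path File path.
#' @return A `string_path`.
#' @export
read_path <- function(path) {
  p <- .read_plumed(path)
  cvn <- setdiff(p$fields, c("image", "arc_length", "free"))
  structure(
    list(images = p$data[, cvn, drop = FALSE],
         arc_length = p$data[, "arc_length"],
         F_along = p$data[, "free"],
         converged = identical(p$sets$converged, "1"),
         iterations = as.integer(p$sets$iterations %||% NA),
         max_perp_grad = NA_real_),
    class = "string_path"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a pipeline configuration file
#'
#' YAML with blocks `thermo`, `landscape`, `diffusion`, `metad`, `run`,
#' `fes`, `mfep`, `protomer`, `permeability`, plus top-level `seed` and
#' `outdir`. Missing keys fall back to [default_config()] values; every
#' block is validated before any stage runs.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Coerce a list to a validated run configuration
#' @param cfg A (possibly partial) configuration list.
#' @return A `run_config`.
#' @export
as_run_config <- function(cfg) {
  base <- default_config()
  for (blk in names(base)) {
    if (is.list(base[[blk]])) {
      for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
    } else if (!is.null(cfg[[blk]])) base[[blk]] <- cfg[[blk]]
  }
  # validate everything up front, before any stage runs
  thermo_state(base$thermo$temperature)
  do.call(model_potential, base$landscape)
  do.call(diffusion_model, base$diffusion)
  wtmetad_bias(base$metad$w0, base$metad$sigma, base$metad$pace,
               base$metad$bias_factor, base$metad$grid_spacing)
  stopifnot(base$run$dt > 0, base$run$n_steps >= 1, base$run$stride >= 1,
            base$fes$burn_in >= 0, base$fes$burn_in < 1,
            base$fes$n_blocks >= 2,
            base$permeability$window_k > 0)
  if (base$protomer$enabled && base$protomer$bias_factor_charged <= 1) {
    stop("protomer bias_factor_charged must be > 1")
  }
  structure(base, class = "run_config")
}

#' Default pipeline configuration (desk-scale 2D demo)
#'
#' A small two-CV membrane landscape sized so the whole chain (two biased
#' runs, surfaces, path, protomer combination, diffusion windows,
#' permeability) completes in well under ten minutes on one CPU.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "memperm-run",
    thermo = list(temperature = 310),
    landscape = list(dimensionality = 2L, interfacial_min_depth = 12,
                     core_barrier_height = 5, interfacial_min_position = 5,
                     widths = c(well = 2, core = 2.5, coupling = 4),
                     coupling_strength = 10, z_max = 12),
    diffusion = list(form = "constant", D_bulk = 0.5, D_core = 0.5,
                     transition_width = 8),
    metad = list(w0 = 1.2, sigma = 1.0, pace = 0.5, bias_factor = 15,
                 grid_spacing = 0.1),
    run = list(dt = 0.01, n_steps = 400000, stride = 10),
    fes = list(bin_width = 1.0, burn_in = 1 / 9, n_blocks = 3,
               bulk_cut = 9.5),
    mfep = list(n_images = 32, tol = 1.0, max_iter = 3000),
    protomer = list(enabled = TRUE, pKa = 10.4, pH = 7, core_penalty = 28,
                    core_width = 3, bias_factor_charged = 25),
    permeability = list(window_centers = seq(-10, 10, by = 2.5),
                        window_k = 10, window_steps = 200000,
                        window_stride = 1, bounds = 11)
  )
}

# stable 32-bit-ish polynomial hash of the canonical YAML text of a config;
# the output location is not part of the scientific configuration
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  txt <- yaml::as.yaml(cfg)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configuration hash embedded in artifacts
#' @param cfg A `run_config` (or coercible list).
#' @return An 8-hex-digit hash string.
#' @export
config_hash <- function(cfg) .config_hash(as_run_config(cfg))

#' Check that an artifact was produced by a given configuration
#'
#' Compares the `config_hash` SET line embedded in the artifact against the
#' hash of `cfg`.
#'
#' @param path Artifact file.
#' @param cfg A `run_config` (or coercible list).
#' @return `TRUE`/`FALSE`.
#' @export
verify_artifact <- function(path, cfg) {
  p <- .read_plumed(path)
  identical(p$sets$config_hash, config_hash(cfg))
}
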