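# Configuration files, snapshot persistence and tabular outputs.

.CONFIG_MAP <- c(
  h_d = "hd", h_p = "hp", p0 = "p0", h_r = "hr", D_d = "Dd", beta = "beta",
  gamma = "gamma", delta = "delta", mu = "mu", pi = "piReactive",
  domain_cm = "domainCm", sigma_mean = "sigmaMean", sigma_min = "sigmaMin",
  I_range = "iRange", p_T = "pT", p_A = "pA", n_CI = "nCI",
  detection = "detectionCount"
)
.CONFIG_RUN_KEYS <- c("tau_T", "tau_H", "dx_um", "dt_hours", "schedule",
                      "horizon", "seed", "snapshot_cadence", "out_dir")

#' Load a run configuration
#'
#' Reads a YAML configuration whose keys mirror the model parameter names
#' (\code{h_d}, \code{h_p}, \code{p0}, \code{h_r}, \code{D_d}, \code{beta},
#' \code{gamma}, \code{delta}, \code{mu}, \code{pi}, \code{tau_T},
#' \code{tau_H}, \code{domain_cm}, \code{dx_um}, \code{dt_hours},
#' \code{sigma_mean}, \code{sigma_min}, \code{I_range}, \code{p_T},
#' \code{p_A}, \code{n_CI}, \code{seed}), plus run settings
#' (\code{schedule}: none/continuous/intermittent, \code{horizon},
#' \code{snapshot_cadence}, \code{out_dir}, \code{detection}). Missing keys
#' take the reference defaults; unknown keys and out-of-range values are
#' named validation errors.
#'
#' @param path path to a YAML file. An empty file yields all defaults.
#' @return list with elements \code{params} (\linkS4class{SimParams}),
#'   \code{schedule} (\linkS4class{TreatmentSchedule}), \code{horizon},
#'   \code{seed}, \code{snapshotCadence}, \code{outDir}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), c(names(.CONFIG_MAP), .CONFIG_RUN_KEYS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  pargs <- list()
  for (k in intersect(names(cfg), names(.CONFIG_MAP))) {
    pargs[[.CONFIG_MAP[[k]]]] <- cfg[[k]]
  }
  if (!is.null(cfg$dx_um)) pargs$dxCm <- cfg$dx_um * 1e-4
  if (!is.null(cfg$dt_hours)) pargs$dtDays <- cfg$dt_hours / 24
  params <- tryCatch(
    do.call(simParams, pargs),
    error = function(e) stop("config validation: ", conditionMessage(e),
                             call. = FALSE)
  )
  mode <- if (is.null(cfg$schedule)) "none" else cfg$schedule
  schedule <- tryCatch(
    treatmentSchedule(mode,
                      tauT = if (is.null(cfg$tau_T)) 0 else cfg$tau_T,
                      tauH = if (is.null(cfg$tau_H)) 0 else cfg$tau_H),
    error = function(e) stop("config validation: ", conditionMessage(e),
                             call. = FALSE)
  )
  list(
    params = params,
    schedule = schedule,
    horizon = if (is.null(cfg$horizon)) 590 else cfg$horizon,
    seed = cfg$seed,
    snapshotCadence = if (is.null(cfg$snapshot_cadence)) 1 else
      cfg$snapshot_cadence,
    outDir = cfg$out_dir
  )
}

.SNAPSHOT_VERSION <- 1L

.configHash <- function(params) {
  rlang::hash(lapply(slotNames("SimParams"), function(s) slot(params, s)))
}

#' Persist / restore a simulation state
#'
#' A versioned container (R native serialisation) holding every lattice
#' layer, the vessel layout, the time stamp, a hash of the parameter set for
#' provenance, and the RNG state at the moment of writing — so a resumed run
#' continues the exact stochastic trajectory of an uninterrupted one.
#' Round-trips are bitwise lossless.
#'
#' @param state a \linkS4class{SimState}.
#' @param path file path.
#' @return \code{writeSnapshot} returns \code{path} invisibly.
#' @export
writeSnapshot <- function(state, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  obj <- list(
    version = .SNAPSHOT_VERSION,
    time = state@time,
    occupancy = state@cells@occupancy,
    activated = state@cells@activated,
    clock = state@cells@clock,
    imt = state@cells@imt,
    drug = state@drug@values,
    signal = state@signal@values,
    vesselCoordinates = state@vessels@coordinates,
    domainDim = state@vessels@domainDim,
    params = state@params,
    configHash = .configHash(state@params),
    rngState = rng
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeSnapshot
#' @param restoreRNG restore the RNG state stored in the snapshot, so
#'   continuing the run reproduces the uninterrupted trajectory.
#' @param domainDim optional expected lattice dimensions; a snapshot from a
#'   different grid shape is a shape-mismatch error.
#' @return \code{readSnapshot} returns the \linkS4class{SimState}.
#' @export
readSnapshot <- function(path, restoreRNG = FALSE, domainDim = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot parse snapshot file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || is.null(obj$version)) {
    stop("cannot parse snapshot file '", path, "': not a snapshot container")
  }
  if (obj$version != .SNAPSHOT_VERSION) {
    stop("snapshot version ", obj$version, " is incompatible with this ",
         "package (expected ", .SNAPSHOT_VERSION, ")")
  }
  if (!is.null(domainDim) &&
      !identical(as.integer(domainDim), as.integer(obj$domainDim))) {
    stop("snapshot grid shape (", paste(obj$domainDim, collapse = "x"),
         ") does not match the expected shape (",
         paste(domainDim, collapse = "x"), ")")
  }
  if (!identical(obj$configHash, .configHash(obj$params))) {
    stop("snapshot provenance hash does not match its parameter set")
  }
  if (restoreRNG && !is.null(obj$rngState)) {
    assign(".Random.seed", obj$rngState, envir = globalenv())
  }
  vessels <- new("VesselSet", coordinates = obj$vesselCoordinates,
                 domainDim = as.integer(obj$domainDim), dx = obj$params@dxCm)
  new("SimState",
    time = obj$time,
    cells = new("CellGrid", occupancy = obj$occupancy,
                activated = obj$activated, clock = obj$clock,
                imt = obj$imt),
    drug = new("LatticeField", values = obj$drug, kind = "drug",
               dx = obj$params@dxCm),
    signal = new("LatticeField", values = obj$signal, kind = "signal",
                 dx = obj$params@dxCm),
    vessels = vessels, params = obj$params
  )
}

#' Write trajectory counts as CSV
#'
#' Plain CSV (one row per macro step: time, populations, mean fields,
#' delivering flag), inspectable without the package.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  utils::write.csv(traj@counts, path, row.names = FALSE)
  invisible(path)
}
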