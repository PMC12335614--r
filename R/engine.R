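# Orchestration: the per-step update cycle, treatment scheduling, homeostatic
# tissue construction, tumour initiation and full simulation runs.

setMethod("isDelivering", "TreatmentSchedule", function(schedule, t) {
  stopifnot(all(t >= 0))
  switch(schedule@mode,
    none = rep(FALSE, length(t)),
    continuous = rep(TRUE, length(t)),
    intermittent = (t %% (schedule@tauT + schedule@tauH)) < schedule@tauT
  )
})

#' Assemble a simulation state
#'
#' Builds a \linkS4class{SimState} from an agent layer and a vessel layout,
#' with zero drug and signal fields unless supplied.
#'
#' @param cells a \linkS4class{CellGrid}; vessel sites must carry the vessel
#'   occupancy code.
#' @param vessels a \linkS4class{VesselSet}.
#' @param params a \linkS4class{SimParams}.
#' @param time simulation time in days.
#' @param drug,signal optional \linkS4class{LatticeField}s.
#' @return a \linkS4class{SimState}.
#' @export
simState <- function(cells, vessels, params = simParams(), time = 0,
                     drug = NULL, signal = NULL) {
  d <- dim(cells@occupancy)
  zero <- function(kind) {
    new("LatticeField", values = matrix(0, d[1], d[2]), kind = kind,
        dx = params@dxCm)
  }
  new("SimState",
    time = time, cells = cells,
    drug = if (is.null(drug)) zero("drug") else drug,
    signal = if (is.null(signal)) zero("signal") else signal,
    vessels = vessels, params = params
  )
}

# Raw-matrix simulation loop. Mutates nothing the caller owns: all layers are
# copied on entry. Returns matrices, count records and snapshots. The compiled
# phase kernels mutate the private copies in place, which keeps allocation out
# of the hot loop.
.runRaw <- function(state, schedule, horizon, snapshotCadence = 1,
                    keepFields = FALSE, stopCancerAtLeast = NULL) {
  params <- state@params
  occ <- .copyInt(state@cells@occupancy)
  act <- .copyLgl(state@cells@activated)
  clk <- .copyNum(state@cells@clock)
  imt <- .copyNum(state@cells@imt)
  d <- .copyNum(state@drug@values)
  p <- .copyNum(state@signal@values)
  vmask <- .vesselMask(state@vessels)
  nsub <- chooseSubsteps(params)
  .checkStability(params, nsub)
  dt <- params@dtDays
  t <- state@time
  nSteps <- ceiling((horizon - t) / dt - 1e-9)
  if (nSteps < 0) nSteps <- 0
  rec <- matrix(NA_real_, nSteps + 1L, 8L)
  colnames(rec) <- c("time", "cancer", "stroma_passive", "stroma_reactive",
                     "activated", "mean_drug", "mean_signal", "delivering")
  snapshots <- list()
  takeSnap <- function(tt) {
    s <- list(time = tt, occupancy = .copyInt(occ), activated = .copyLgl(act))
    if (keepFields) {
      s$drug <- .copyNum(d)
      s$signal <- .copyNum(p)
    }
    s
  }
  record <- function(row, tt, deliv) {
    tab <- tabulate(occ + 1L, 5L)
    rec[row, ] <<- c(tt, tab[3L], tab[4L], tab[5L], sum(act), mean(d),
                     mean(p), as.numeric(deliv))
  }
  record(1L, t, isDelivering(schedule, t))
  if (!is.null(snapshotCadence)) {
    snapshots[[1L]] <- takeSnap(t)
    nextSnap <- t + snapshotCadence
  }
  stopped <- FALSE
  i <- 0L
  while (i < nSteps && !stopped) {
    i <- i + 1L
    deliv <- isDelivering(schedule, t)
    # fields
    if (deliv || max(d) > 0) {
      cpp_step_drug(d, vmask, deliv, nsub, params@Dd, params@mu, dt,
                    params@dxCm)
    }
    cancerNow <- rec[i, 2L]
    if (cancerNow > 0 || max(p) > 0) {
      cpp_step_signal(p, d, occ, act, params@beta, params@gamma,
                      params@delta, dt)
    }
    # stroma state changes, then cancer demography, then stroma demography
    cpp_update_reactive(occ, act, d, dt, params@pA, params@hr)
    if (cancerNow > 0) {
      cpp_advance_cancer(occ, act, clk, imt, p, dt, params@hd, params@hp,
                         params@p0, params@iRange[1], params@iRange[2])
    }
    cpp_advance_stroma(occ, act, clk, imt, dt, params@pT, params@nCI,
                       params@iRange[1], params@iRange[2])
    t <- t + dt
    record(i + 1L, t, deliv)
    if (!is.null(snapshotCadence) && t >= nextSnap - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- takeSnap(t)
      nextSnap <- nextSnap + snapshotCadence
    }
    if (!is.null(stopCancerAtLeast) && rec[i + 1L, 2L] >= stopCancerAtLeast) {
      stopped <- TRUE
    }
  }
  if (i < nSteps) rec <- rec[seq_len(i + 1L), , drop = FALSE]
  # final snapshot if the run ended between snapshot times
  if (!is.null(snapshotCadence) && length(snapshots) &&
      snapshots[[length(snapshots)]]$time < t - 1e-9) {
    snapshots[[length(snapshots) + 1L]] <- takeSnap(t)
  }
  list(
    occ = occ, act = act, clk = clk, imt = imt, d = d, p = p, time = t,
    counts = as.data.frame(rec), snapshots = snapshots,
    reachedStop = stopped
  )
}

.rawToState <- function(raw, state) {
  new("SimState",
    time = raw$time,
    cells = new("CellGrid", occupancy = raw$occ, activated = raw$act,
                clock = raw$clk, imt = raw$imt),
    drug = new("LatticeField", values = raw$d, kind = "drug",
               dx = state@params@dxCm),
    signal = new("LatticeField", values = raw$p, kind = "signal",
                 dx = state@params@dxCm),
    vessels = state@vessels, params = state@params
  )
}

#' Advance the full system one macro step
#'
#' Fixed phase order per macro step dt: (1) drug field (with the delivery flag
#' evaluated at the step's start time); (2) proliferation signal from the
#' current cell configuration; (3) reactive-stroma activation/deactivation;
#' (4) cancer death, clocks and divisions (with birth floor); (5) stroma
#' turnover and divisions; (6) time advances by dt.
#'
#' @param state a \linkS4class{SimState}.
#' @param schedule a \linkS4class{TreatmentSchedule}.
#' @return the advanced \linkS4class{SimState}.
#' @export
simStep <- function(state, schedule = treatmentSchedule("none")) {
  params <- state@params
  deliv <- isDelivering(schedule, state@time)
  drug <- stepDrug(state@drug, state@vessels, deliv, params)
  signal <- stepSignal(state@signal, drug, state@cells, params)
  cells <- updateReactiveStates(state@cells, drug, params)
  canc <- advanceCancer(cells, signal, params)
  str <- advanceStroma(canc$cells, params)
  new("SimState",
    time = state@time + params@dtDays, cells = str$cells, drug = drug,
    signal = canc$signal, vessels = state@vessels, params = params
  )
}

#' Construct a homeostatic stromal tissue
#'
#' Fills every non-vessel lattice site with stroma (reactive with probability
#' \code{piReactive}, passive otherwise), assigns fresh intermitotic times and
#' uniformly staggered clocks, and runs the model drug- and cancer-free for
#' \code{duration} days so turnover and contact inhibition settle into a
#' dynamic equilibrium. A warning is issued when the occupied fraction still
#' drifts by more than 2\% between the last two quarters of the burn-in.
#'
#' @param vessels a \linkS4class{VesselSet}; built with
#'   \code{\link{placeVesselsPacked}} when NULL.
#' @param params a \linkS4class{SimParams}.
#' @param duration burn-in length in days.
#' @return a \linkS4class{SimState} at \code{time = 0} holding the
#'   equilibrated tissue.
#' @export
equilibrateStroma <- function(vessels = NULL, params = simParams(),
                              duration = 100) {
  n <- latticeSide(params)
  if (is.null(vessels)) {
    vessels <- placeVesselsPacked(c(n, n), params@sigmaMean, params@sigmaMin,
                                  params@dxCm)
  }
  dd <- vessels@domainDim
  occ <- matrix(.OCC[["stroma_passive"]], dd[1], dd[2])
  reactive <- matrix(stats::runif(prod(dd)) < params@piReactive, dd[1], dd[2])
  occ[reactive] <- .OCC[["stroma_reactive"]]
  occ[.vesselMask(vessels)] <- .OCC[["vessel"]]
  imt <- matrix(stats::runif(prod(dd), params@iRange[1], params@iRange[2]),
                dd[1], dd[2])
  clk <- matrix(stats::runif(prod(dd)), dd[1], dd[2]) * imt
  isCell <- occ %in% .OCC[c("stroma_passive", "stroma_reactive")]
  imt[!isCell] <- 0
  clk[!isCell] <- 0
  cells <- new("CellGrid", occupancy = occ,
               activated = matrix(FALSE, dd[1], dd[2]), clock = clk,
               imt = imt)
  state <- simState(cells, vessels, params)
  if (duration <= 0) return(state)
  raw <- .runRaw(state, treatmentSchedule("none"), duration,
                 snapshotCadence = NULL)
  occFrac <- rowSums(raw$counts[, c("stroma_passive", "stroma_reactive")]) /
    prod(dd)
  nr <- length(occFrac)
  if (nr > 20L) {
    # compare the final tenth of the burn-in with the preceding tenth
    last <- mean(occFrac[seq(floor(9 * nr / 10), nr)])
    prev <- mean(occFrac[seq(floor(8 * nr / 10), floor(9 * nr / 10))])
    if (abs(last - prev) > 0.02 * max(last, 1e-12)) {
      warning("stromal tissue may not have reached dynamic equilibrium ",
              sprintf("(occupancy drift %.1f%% at the end of the burn-in)",
                      100 * abs(last - prev) / last))
    }
  }
  out <- .rawToState(raw, state)
  out@time <- 0
  out
}

#' Seed a tumour and grow it to the detection level
#'
#' Places a single cancer cell on a uniformly random Moore neighbour of the
#' vessel nearest the domain centre (displacing any stroma cell there, as a
#' metastatic cell lodging in tissue), sets the local proliferation signal to
#' at least \code{p0}, and runs the model drug-free until the cancer count
#' reaches \code{detection}. The returned state (time reset to 0) is the
#' standard initial condition for treatment experiments.
#'
#' @param state a homeostatic \linkS4class{SimState} (see
#'   \code{\link{equilibrateStroma}}).
#' @param detection cancer-cell count defining the detection level; defaults
#'   to \code{params@detectionCount}.
#' @param maxDays cap on simulated growth time; exceeding it without reaching
#'   detection is an error.
#' @return a \linkS4class{SimState} at \code{time = 0} with the detected
#'   tumour.
#' @export
seedAndGrowTumour <- function(state, detection = NULL, maxDays = 400) {
  params <- state@params
  if (is.null(detection)) detection <- params@detectionCount
  dd <- dim(state@cells@occupancy)
  co <- state@vessels@coordinates
  if (nrow(co) == 0L) stop("tumour seeding requires at least one vessel")
  centre <- (dd + 1) / 2
  iv <- which.min((co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2)
  nb <- cbind(co[iv, 1] + .moore[, 1], co[iv, 2] + .moore[, 2])
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= dd[1] &
             nb[, 2] >= 1 & nb[, 2] <= dd[2], , drop = FALSE]
  nb <- nb[state@cells@occupancy[nb] != .OCC[["vessel"]], , drop = FALSE]
  if (nrow(nb) == 0L) stop("no non-vessel site adjacent to the central vessel")
  seedSite <- nb[sample.int(nrow(nb), 1L), ]
  occ <- .copyInt(state@cells@occupancy)
  act <- .copyLgl(state@cells@activated)
  clk <- .copyNum(state@cells@clock)
  imt <- .copyNum(state@cells@imt)
  occ[seedSite[1], seedSite[2]] <- .OCC[["cancer"]]
  act[seedSite[1], seedSite[2]] <- FALSE
  clk[seedSite[1], seedSite[2]] <- 0
  imt[seedSite[1], seedSite[2]] <- stats::runif(1, params@iRange[1],
                                                params@iRange[2])
  p <- .copyNum(state@signal@values)
  p[seedSite[1], seedSite[2]] <- max(p[seedSite[1], seedSite[2]], params@p0)
  seeded <- new("SimState",
    time = 0,
    cells = new("CellGrid", occupancy = occ, activated = act, clock = clk,
                imt = imt),
    drug = state@drug,
    signal = new("LatticeField", values = p, kind = "signal",
                 dx = params@dxCm),
    vessels = state@vessels, params = params
  )
  raw <- .runRaw(seeded, treatmentSchedule("none"), maxDays,
                 snapshotCadence = NULL, stopCancerAtLeast = detection)
  if (!raw$reachedStop) {
    stop("tumour failed to reach the detection level of ", detection,
         " cells within ", maxDays, " days (final count ",
         raw$counts$cancer[nrow(raw$counts)], ")")
  }
  out <- .rawToState(raw, seeded)
  out@time <- 0
  out
}

#' Run a simulation
#'
#' Steps the system until \code{time >= horizon} (days, on the simulation
#' clock, so a resumed state continues where it left off). Population counts
#' and mean fields are recorded every macro step; full snapshots are stored at
#' \code{snapshotCadence} (default daily), including the initial state and the
#' final one.
#'
#' @param state a \linkS4class{SimState}.
#' @param schedule a \linkS4class{TreatmentSchedule}.
#' @param horizon target end time in days.
#' @param snapshotCadence days between snapshots (NULL for none).
#' @param keepFields store the drug and signal fields in snapshots (needed
#'   for threshold-highlight analysis).
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the trajectory is fully reproducible.
#' @return a \linkS4class{Trajectory}; the final state is attached as
#'   attribute \code{"finalState"}.
#' @export
runSim <- function(state, schedule, horizon, snapshotCadence = 1,
                   keepFields = FALSE, seed = NULL) {
  if (horizon <= state@time) stop("'horizon' must exceed the state's time")
  if (!is.null(seed)) set.seed(seed)
  raw <- .runRaw(state, schedule, horizon, snapshotCadence = snapshotCadence,
                 keepFields = keepFields)
  counts <- raw$counts
  counts$delivering <- as.logical(counts$delivering)
  for (col in c("cancer", "stroma_passive", "stroma_reactive", "activated")) {
    counts[[col]] <- as.integer(counts[[col]])
  }
  traj <- new("Trajectory", counts = counts, snapshots = raw$snapshots,
              params = state@params, schedule = schedule)
  attr(traj, "finalState") <- .rawToState(raw, state)
  traj
}

#' Final state of a run
#'
#' @param traj a \linkS4class{Trajectory} returned by \code{\link{runSim}}.
#' @return the \linkS4class{SimState} at the end of the run.
#' @export
finalState <- function(traj) attr(traj, "finalState")
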