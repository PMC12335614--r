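# Quantitative readouts: burden trade-offs, longitudinal occupancy,
# activation-window neighbourhood composition, threshold-highlight maps and
# niche labelling.

.CLASSES <- c("cancer", "stroma_passive", "stroma_reactive",
              "stroma_activated", "stroma", "vessel", "empty")

# logical mask of a cell class on a snapshot (list with occupancy/activated)
.classMask <- function(snap, cellClass) {
  occ <- snap$occupancy
  switch(cellClass,
    cancer = occ == .OCC[["cancer"]],
    stroma_passive = occ == .OCC[["stroma_passive"]],
    stroma_reactive = occ == .OCC[["stroma_reactive"]],
    stroma_activated = snap$activated,
    stroma = occ == .OCC[["stroma_passive"]] |
      occ == .OCC[["stroma_reactive"]],
    vessel = occ == .OCC[["vessel"]],
    empty = occ == .OCC[["empty"]],
    stop("unknown cell class '", cellClass, "'")
  )
}

.snapshotsInWindow <- function(traj, window) {
  sn <- traj@snapshots
  if (!length(sn)) stop("trajectory holds no snapshots")
  tt <- vapply(sn, `[[`, numeric(1), "time")
  sn[tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9]
}

#' Tumour burden time series
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return data.frame with columns \code{time} and \code{cancer}.
#' @export
tumourBurden <- function(traj) {
  traj@counts[, c("time", "cancer")]
}

#' Cumulative days of drug delivery
#'
#' \eqn{\int_0^{horizon} 1[\mathrm{delivering}(t)]\, dt}, evaluated in closed
#' form from the schedule's modular arithmetic.
#'
#' @param schedule a \linkS4class{TreatmentSchedule}.
#' @param horizon window length in days.
#' @return delivery days (numeric).
#' @examples
#' cumulativeDrugDays(treatmentSchedule("intermittent", 50, 20), 590) # 430
#' @export
cumulativeDrugDays <- function(schedule, horizon) {
  if (horizon <= 0) stop("'horizon' must be positive")
  switch(schedule@mode,
    none = 0,
    continuous = horizon,
    intermittent = {
      period <- schedule@tauT + schedule@tauH
      full <- floor(horizon / period)
      rem <- horizon - full * period
      full * schedule@tauT + min(rem, schedule@tauT)
    }
  )
}

#' Tumour burden relative to a reference run
#'
#' Sum of cancer counts over the shared sampling grid, normalised to the
#' reference trajectory (e.g. continuous treatment).
#'
#' @param traj,referenceTraj \linkS4class{Trajectory}s on the same sampling
#'   grid.
#' @param window optional time window \code{c(t0, t1)} to integrate over.
#' @return a scalar; 1 when the two runs carry identical burden.
#' @export
relativeTumourBurden <- function(traj, referenceTraj, window = NULL) {
  a <- traj@counts
  b <- referenceTraj@counts
  if (!is.null(window)) {
    a <- a[a$time >= window[1] - 1e-9 & a$time <= window[2] + 1e-9, ]
    b <- b[b$time >= window[1] - 1e-9 & b$time <= window[2] + 1e-9, ]
  }
  if (nrow(a) != nrow(b) || max(abs(a$time - b$time)) > 1e-6) {
    stop("trajectories are not on the same sampling grid")
  }
  sum(a$cancer) / sum(b$cancer)
}

#' Longitudinal occupancy of a cell class
#'
#' Fraction of sampled snapshots, within a time window, in which each lattice
#' site is occupied by the given cell class. High cancer occupancy after the
#' initial transient marks residual-disease regions; high activated-stroma
#' occupancy marks EMDR-driven survival niches.
#'
#' @param traj a \linkS4class{Trajectory} (or list of trajectories, averaged
#'   with equal weight per snapshot).
#' @param cellClass one of \code{"cancer"}, \code{"stroma_passive"},
#'   \code{"stroma_reactive"}, \code{"stroma_activated"}, \code{"stroma"},
#'   \code{"vessel"}, \code{"empty"}.
#' @param window time window in days, default \code{c(150, 590)} (discarding
#'   the initial transient).
#' @return an \linkS4class{OccupancyMap}.
#' @export
longitudinalOccupancy <- function(traj, cellClass = "cancer",
                                  window = c(150, 590)) {
  cellClass <- match.arg(cellClass, .CLASSES)
  trajs <- if (is(traj, "Trajectory")) list(traj) else traj
  total <- NULL
  n <- 0L
  for (tr in trajs) {
    for (sn in .snapshotsInWindow(tr, window)) {
      m <- .classMask(sn, cellClass)
      total <- if (is.null(total)) m + 0 else total + m
      n <- n + 1L
    }
  }
  if (n == 0L) stop("no snapshots inside the requested window")
  new("OccupancyMap", values = total / n, cellClass = cellClass,
      window = as.numeric(window), nSnapshots = n)
}

#' Stroma activation windows of an intermittent schedule
#'
#' The activation window is the final part of each drug delivery period, when
#' the drug concentration has built up past the activation threshold and
#' activated stroma is present — by default the last 60\% of the delivery
#' window. Cycle k (0-based) spans
#' \code{[k (tauT + tauH) + (1 - fraction) tauT, k (tauT + tauH) + tauT)}.
#'
#' @param schedule an intermittent \linkS4class{TreatmentSchedule}.
#' @param fraction final fraction of the delivery period (default 0.6).
#' @param horizon window end in days; cycles are enumerated up to it.
#' @return data.frame with columns \code{cycle}, \code{start}, \code{end}.
#' @examples
#' activationWindow(treatmentSchedule("intermittent", 50, 20), horizon = 140)
#' @export
activationWindow <- function(schedule, fraction = 0.6, horizon = 590) {
  if (schedule@mode != "intermittent") {
    stop("activation windows are defined for intermittent schedules")
  }
  stopifnot(fraction > 0, fraction <= 1)
  period <- schedule@tauT + schedule@tauH
  k <- seq(0L, max(0L, ceiling(horizon / period) - 1L))
  start <- k * period + (1 - fraction) * schedule@tauT
  end <- k * period + schedule@tauT
  keep <- start < horizon
  data.frame(cycle = k[keep], start = start[keep],
             end = pmin(end[keep], horizon))
}

#' Moore-neighbourhood composition of a cell class
#'
#' Over all snapshots inside \code{window} (or inside the explicit
#' \code{intervals}, e.g. the activation windows) and all focal cells of
#' \code{focalClass}, tallies the number of \code{neighbourClass} cells in
#' the focal cell's Moore neighbourhood. With several replicate trajectories,
#' \code{mode = "per_run"} reports the mean of per-run means with the
#' standard error across runs; \code{mode = "pooled"} pools all cells.
#'
#' @param traj a \linkS4class{Trajectory} or list of replicates.
#' @param focalClass,neighbourClass cell classes (see
#'   \code{\link{longitudinalOccupancy}}).
#' @param window time window in days (ignored when \code{intervals} given).
#' @param intervals optional data.frame with \code{start}, \code{end}
#'   columns; snapshots in any interval are used.
#' @param mode \code{"per_run"} or \code{"pooled"}.
#' @return a \linkS4class{NeighbourhoodHistogram}.
#' @export
neighbourhoodDistribution <- function(traj, focalClass = "cancer",
                                      neighbourClass = "cancer",
                                      window = c(150, 590),
                                      intervals = NULL,
                                      mode = c("per_run", "pooled")) {
  mode <- match.arg(mode)
  focalClass <- match.arg(focalClass, .CLASSES)
  neighbourClass <- match.arg(neighbourClass, .CLASSES)
  trajs <- if (is(traj, "Trajectory")) list(traj) else traj
  inWindow <- function(tt) {
    if (is.null(intervals)) {
      tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
    } else {
      Reduce(`|`, lapply(seq_len(nrow(intervals)), function(i) {
        tt >= intervals$start[i] - 1e-9 & tt < intervals$end[i] + 1e-9
      }))
    }
  }
  counts <- numeric(9L)
  runMeans <- numeric(0)
  nFocal <- 0
  for (tr in trajs) {
    sn <- tr@snapshots
    if (!length(sn)) stop("trajectory holds no snapshots")
    tt <- vapply(sn, `[[`, numeric(1), "time")
    sn <- sn[inWindow(tt)]
    runTotal <- 0
    runN <- 0
    for (s in sn) {
      focal <- .classMask(s, focalClass)
      if (!any(focal)) next
      nb <- .neighbourCounts(.classMask(s, neighbourClass))
      v <- nb[focal]
      counts <- counts + tabulate(v + 1L, 9L)
      runTotal <- runTotal + sum(v)
      runN <- runN + length(v)
    }
    nFocal <- nFocal + runN
    if (runN > 0) runMeans <- c(runMeans, runTotal / runN)
  }
  if (nFocal == 0) {
    return(new("NeighbourhoodHistogram",
      counts = stats::setNames(counts, 0:8), mean = NaN, se = NaN,
      nFocal = 0, focalClass = focalClass, neighbourClass = neighbourClass,
      window = if (is.null(intervals)) as.numeric(window) else
        range(intervals$start, intervals$end),
      mode = mode
    ))
  }
  if (mode == "per_run" && length(runMeans) > 1) {
    m <- mean(runMeans)
    se <- stats::sd(runMeans) / sqrt(length(runMeans))
  } else {
    vals <- rep(0:8, counts)
    m <- mean(vals)
    se <- stats::sd(vals) / sqrt(length(vals))
  }
  new("NeighbourhoodHistogram",
    counts = stats::setNames(counts, 0:8), mean = m,
    se = if (is.na(se)) NaN else se, nFocal = nFocal,
    focalClass = focalClass, neighbourClass = neighbourClass,
    window = if (is.null(intervals)) as.numeric(window) else
      range(intervals$start, intervals$end),
    mode = mode
  )
}

#' Threshold-highlight mask of a field
#'
#' Boolean mask marking sites where a field is at or above (\code{"ge"}) or
#' strictly below (\code{"lt"}) a threshold — e.g. where the drug exceeds the
#' stroma activation threshold, or where the signal sits in the death window.
#'
#' @param field a \linkS4class{LatticeField} or numeric matrix.
#' @param threshold the threshold.
#' @param direction \code{"ge"} or \code{"lt"}.
#' @return logical matrix.
#' @export
thresholdHighlight <- function(field, threshold, direction = c("ge", "lt")) {
  direction <- match.arg(direction)
  v <- if (is(field, "LatticeField")) field@values else field
  if (direction == "ge") v >= threshold else v < threshold
}

#' Label residual-disease niches
#'
#' Operationalises the visual identification of niches: a site is a
#' \emph{survival} niche when cancer occupancy and activated-stroma occupancy
#' are both high (EMDR-driven survival); a \emph{persistence} niche when
#' cancer occupancy is high without stroma activation (dormancy under poor
#' perfusion); an \emph{eradication} niche otherwise. The thresholds are
#' declared heuristics, not calibrated values.
#'
#' @param cancerOcc,actStromaOcc \linkS4class{OccupancyMap}s on the same grid
#'   and window.
#' @param thetaC,thetaA occupancy thresholds (defaults 0.5 and 0.1).
#' @return a \linkS4class{NicheMap}.
#' @export
classifyNiches <- function(cancerOcc, actStromaOcc, thetaC = 0.5,
                           thetaA = 0.1) {
  if (!identical(dim(cancerOcc@values), dim(actStromaOcc@values))) {
    stop("occupancy maps are on different grids")
  }
  cv <- cancerOcc@values
  av <- actStromaOcc@values
  lab <- matrix("eradication", nrow(cv), ncol(cv))
  lab[cv >= thetaC & av >= thetaA] <- "survival"
  lab[cv >= thetaC & av < thetaA] <- "persistence"
  new("NicheMap", labels = lab, thetaC = thetaC, thetaA = thetaA)
}
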