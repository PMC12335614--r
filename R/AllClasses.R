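# Central S4 classes of the hybrid discrete-continuum model.
#
# The lattice is a square grid of side dx (cm). Per-site occupancy is integer
# coded; the codes are part of the snapshot serialisation contract.

#' Occupancy codes
#'
#' Integer codes used in the occupancy layer of a \linkS4class{CellGrid}:
#' 0 empty, 1 vessel, 2 cancer, 3 passive stroma, 4 reactive stroma.
#' Activation of reactive stroma is carried by a separate logical layer.
#'
#' @format named integer vector.
#' @export
OCC_CODES <- c(
  empty = 0L, vessel = 1L, cancer = 2L,
  stroma_passive = 3L, stroma_reactive = 4L
)

.OCC <- OCC_CODES

#' Model parameters
#'
#' All tunable parameters of the model, with defaults reproducing the
#' reference parameterisation: signal thresholds for cancer death
#' (\code{hd = 0.2}) and proliferation (\code{hp = 0.8}); signal birth floor
#' \code{p0 = 0.256}; drug threshold for stroma activation \code{hr = 0.93};
#' drug diffusion coefficient \code{Dd = 1e-5} cm^2/day; autocrine signal
#' production \code{beta = 1.25}/day; paracrine production
#' \code{gamma = 4.242}/day/cell; drug-driven signal degradation
#' \code{delta = 6.68}/day; drug clearance at vessels \code{mu = 500}/day;
#' reactive stroma proportion \code{piReactive = 0.5}; lattice spacing
#' \code{dxCm = 1e-3} cm (10 um); macro time step \code{dtDays = 0.044/24}
#' days (0.044 h); square domain side \code{domainCm = 0.3} cm; mean and
#' minimum inter-vessel distances \code{sigmaMean = 0.016},
#' \code{sigmaMin = 0.008} cm; intermitotic time range
#' \code{iRange = c(0.9, 1.1)} days; stroma turnover \code{pT = 0.0042}/day;
#' stroma activation \code{pA = 0.042}/day; contact inhibition threshold
#' \code{nCI = 2} occupied neighbours; tumour detection level
#' \code{detectionCount = 1e4} cancer cells.
#'
#' @slot hd,hp,p0,hr,Dd,beta,gamma,delta,mu,piReactive,dxCm,dtDays,domainCm,sigmaMean,sigmaMin,pT,pA numeric scalars, see description.
#' @slot iRange numeric(2), uniform intermitotic-time bounds in days.
#' @slot nCI integer scalar.
#' @slot detectionCount numeric scalar.
#' @seealso \code{\link{simParams}}
#' @export
setClass("SimParams", representation(
  hd = "numeric", hp = "numeric", p0 = "numeric", hr = "numeric",
  Dd = "numeric", beta = "numeric", gamma = "numeric", delta = "numeric",
  mu = "numeric", piReactive = "numeric", dxCm = "numeric",
  dtDays = "numeric", domainCm = "numeric", sigmaMean = "numeric",
  sigmaMin = "numeric", iRange = "numeric", pT = "numeric", pA = "numeric",
  nCI = "integer", detectionCount = "numeric"
), prototype(
  hd = 0.2, hp = 0.8, p0 = 0.256, hr = 0.93, Dd = 1e-5, beta = 1.25,
  gamma = 4.242, delta = 6.68, mu = 500, piReactive = 0.5, dxCm = 1e-3,
  dtDays = 0.044 / 24, domainCm = 0.3, sigmaMean = 0.016, sigmaMin = 0.008,
  iRange = c(0.9, 1.1), pT = 0.0042, pA = 0.042, nCI = 2L,
  detectionCount = 1e4
))

setValidity("SimParams", function(object) {
  msg <- character()
  sc <- c(
    "hd", "hp", "p0", "hr", "Dd", "beta", "gamma", "delta", "mu",
    "piReactive", "dxCm", "dtDays", "domainCm", "sigmaMean", "sigmaMin",
    "pT", "pA", "detectionCount"
  )
  for (s in sc) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    } else if (v < 0) msg <- c(msg, sprintf("'%s' must be non-negative", s))
  }
  if (!length(msg)) {
    if (object@hd >= object@hp) msg <- c(msg, "'hd' must be < 'hp'")
    if (object@p0 <= object@hd || object@p0 > 1) {
      msg <- c(msg, "'p0' must satisfy hd < p0 <= 1")
    }
    if (object@piReactive > 1) msg <- c(msg, "'piReactive' must be in [0, 1]")
    if (object@hr > 1) msg <- c(msg, "'hr' must be in [0, 1]")
    if (object@sigmaMin > object@sigmaMean) {
      msg <- c(msg, "'sigmaMin' must be <= 'sigmaMean'")
    }
    if (length(object@iRange) != 2L || object@iRange[1] > object@iRange[2] ||
        object@iRange[1] < 0) {
      msg <- c(msg, "'iRange' must be an ordered non-negative pair")
    }
    if (length(object@nCI) != 1L || object@nCI < 0L) {
      msg <- c(msg, "'nCI' must be a non-negative integer")
    }
    if (object@dxCm == 0 || object@dtDays == 0 || object@domainCm == 0) {
      msg <- c(msg, "'dxCm', 'dtDays' and 'domainCm' must be positive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Static vessel layout
#'
#' A set of lattice sites occupied by blood vessels. Vessels cut the tissue
#' plane perpendicularly, occupy a single lattice position each, act as point
#' sources (during delivery) and sinks (clearance) for the inhibitor drug, and
#' exclude cells from their site permanently.
#'
#' @slot coordinates integer matrix, one (row, col) 1-based position per
#'   vessel.
#' @slot domainDim integer(2), lattice dimensions.
#' @slot dx numeric, lattice spacing in cm (used to express distances in
#'   physical units).
#' @seealso \code{\link{placeVesselsPacked}}, \code{\link{placeVesselsRegular}}
#' @export
setClass("VesselSet", representation(
  coordinates = "matrix", domainDim = "integer", dx = "numeric"
))

setValidity("VesselSet", function(object) {
  co <- object@coordinates
  dd <- object@domainDim
  if (length(dd) != 2L || any(dd < 1L)) {
    return("'domainDim' must be two positive integers")
  }
  if (ncol(co) != 2L) return("'coordinates' must have two columns (row, col)")
  if (nrow(co)) {
    if (any(co < 1L) || any(co[, 1] > dd[1]) || any(co[, 2] > dd[2])) {
      return("vessel positions must lie inside the domain")
    }
    if (anyDuplicated(paste(co[, 1], co[, 2]))) {
      return("duplicate vessel positions")
    }
  }
  if (length(object@dx) != 1L || object@dx <= 0) {
    return("'dx' must be a positive scalar")
  }
  TRUE
})

#' Scalar lattice field
#'
#' A per-site scalar in [0, 1]; two kinds are used by the model: the inhibitor
#' \code{"drug"} concentration d(x, t) and the proliferation \code{"signal"}
#' p(x, t).
#'
#' @slot values numeric matrix in [0, 1].
#' @slot kind \code{"drug"} or \code{"signal"}.
#' @slot dx lattice spacing in cm.
#' @export
setClass("LatticeField", representation(
  values = "matrix", kind = "character", dx = "numeric"
))

setValidity("LatticeField", function(object) {
  if (!object@kind %in% c("drug", "signal")) {
    return("'kind' must be \"drug\" or \"signal\"")
  }
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  tol <- 1e-9
  if (any(v < -tol) || any(v > 1 + tol)) {
    return(sprintf("field values outside [0, 1] (range %.3g..%.3g)",
                   min(v), max(v)))
  }
  if (length(object@dx) != 1L || object@dx <= 0) {
    return("'dx' must be a positive scalar")
  }
  TRUE
})

#' Per-site agent state
#'
#' The discrete agent layer: integer-coded occupancy (see
#' \code{\link{OCC_CODES}}), an activation flag for reactive stroma, and the
#' cell-cycle bookkeeping layers (clock: days of cell-cycle progress; imt:
#' intermitotic time I drawn from U[0.9, 1.1] days at birth).
#'
#' @slot occupancy integer matrix of occupancy codes.
#' @slot activated logical matrix; may only be TRUE on reactive stroma sites.
#' @slot clock numeric matrix, 0 <= clock <= imt.
#' @slot imt numeric matrix; 0 on unoccupied/vessel sites.
#' @export
setClass("CellGrid", representation(
  occupancy = "matrix", activated = "matrix", clock = "matrix", imt = "matrix"
))

setValidity("CellGrid", function(object) {
  occ <- object@occupancy
  d <- dim(occ)
  for (s in c("activated", "clock", "imt")) {
    if (!identical(dim(slot(object, s)), d)) {
      return(sprintf("layer '%s' has mismatched dimensions", s))
    }
  }
  if (!all(occ %in% .OCC)) return("unknown occupancy codes")
  if (any(object@activated & occ != .OCC[["stroma_reactive"]])) {
    return("'activated' may only be TRUE on reactive stroma sites")
  }
  if (any(object@clock < 0) ||
      any(object@clock > object@imt + 1e-9)) {
    return("clocks must satisfy 0 <= clock <= imt")
  }
  TRUE
})

#' Treatment schedule
#'
#' Drug delivery regime: \code{"none"}, \code{"continuous"}, or
#' \code{"intermittent"} with regular alternating delivery periods of length
#' \code{tauT} days and holidays of length \code{tauH} days (delivery first).
#'
#' @slot mode character.
#' @slot tauT,tauH numeric, period lengths in days (ignored unless
#'   intermittent).
#' @seealso \code{\link{isDelivering}}, \code{\link{cumulativeDrugDays}}
#' @export
setClass("TreatmentSchedule", representation(
  mode = "character", tauT = "numeric", tauH = "numeric"
), prototype(mode = "none", tauT = 0, tauH = 0))

setValidity("TreatmentSchedule", function(object) {
  if (!object@mode %in% c("none", "continuous", "intermittent")) {
    return("mode must be one of none/continuous/intermittent")
  }
  if (object@mode == "intermittent") {
    if (object@tauT <= 0) return("intermittent schedules require tauT > 0")
    if (object@tauH < 0) return("tauH must be >= 0")
  }
  TRUE
})

#' Full simulation state
#'
#' The complete system state at a time point: agent layer, both continuum
#' fields, the static vasculature and the parameter set.
#'
#' @slot time simulation time in days.
#' @slot cells a \linkS4class{CellGrid}.
#' @slot drug,signal \linkS4class{LatticeField}s.
#' @slot vessels a \linkS4class{VesselSet}.
#' @slot params a \linkS4class{SimParams}.
#' @export
setClass("SimState", representation(
  time = "numeric", cells = "CellGrid", drug = "LatticeField",
  signal = "LatticeField", vessels = "VesselSet", params = "SimParams"
))

setValidity("SimState", function(object) {
  d <- dim(object@cells@occupancy)
  if (!identical(dim(object@drug@values), d) ||
      !identical(dim(object@signal@values), d)) {
    return("fields and cell grid must share dimensions")
  }
  if (!identical(unname(object@vessels@domainDim), unname(as.integer(d)))) {
    return("vessel set domain does not match the grid")
  }
  co <- object@vessels@coordinates
  if (nrow(co)) {
    idx <- cbind(co[, 1], co[, 2])
    if (!all(object@cells@occupancy[idx] == .OCC[["vessel"]])) {
      return("every vessel position must carry the vessel occupancy code")
    }
  }
  if (sum(object@cells@occupancy == .OCC[["vessel"]]) != nrow(co)) {
    return("vessel occupancy codes not accounted for by the vessel set")
  }
  TRUE
})

#' Simulation trajectory
#'
#' Time-stamped population counts and mean fields recorded every macro step,
#' plus periodic full snapshots for spatial analysis.
#'
#' @slot counts data.frame with columns \code{time}, \code{cancer},
#'   \code{stroma_passive}, \code{stroma_reactive}, \code{activated},
#'   \code{mean_drug}, \code{mean_signal}, \code{delivering}.
#' @slot snapshots list; each element has \code{time}, \code{occupancy},
#'   \code{activated} and (if requested) \code{drug}, \code{signal} matrices.
#' @slot params the \linkS4class{SimParams} used.
#' @slot schedule the \linkS4class{TreatmentSchedule} used.
#' @export
setClass("Trajectory", representation(
  counts = "data.frame", snapshots = "list", params = "SimParams",
  schedule = "TreatmentSchedule"
))

setValidity("Trajectory", function(object) {
  ct <- object@counts
  need <- c("time", "cancer", "stroma_passive", "stroma_reactive",
            "activated", "mean_drug", "mean_signal", "delivering")
  if (!all(need %in% names(ct))) return("missing trajectory count columns")
  if (nrow(ct) > 1 && any(diff(ct$time) <= 0)) {
    return("times must be strictly increasing")
  }
  if (any(ct$cancer < 0)) return("counts must be non-negative")
  TRUE
})

#' Longitudinal occupancy map
#'
#' Per-site fraction of sampled snapshots, within a time window, in which the
#' site is occupied by a given cell class.
#'
#' @slot values numeric matrix in [0, 1].
#' @slot cellClass the cell class measured.
#' @slot window numeric(2), time window in days.
#' @slot nSnapshots number of snapshots averaged.
#' @seealso \code{\link{longitudinalOccupancy}}
#' @export
setClass("OccupancyMap", representation(
  values = "matrix", cellClass = "character", window = "numeric",
  nSnapshots = "integer"
))

setValidity("OccupancyMap", function(object) {
  if (any(object@values < 0) || any(object@values > 1)) {
    return("occupancy fractions must be in [0, 1]")
  }
  if (length(object@window) != 2L) return("'window' must be length 2")
  TRUE
})

#' Residual-disease niche labels
#'
#' Per-site classification into survival (cancer persists with activated
#' stroma), persistence (cancer persists without activated stroma, i.e.
#' dormancy under poor perfusion) and eradication niches.
#'
#' @slot labels character matrix with entries \code{"survival"},
#'   \code{"persistence"}, \code{"eradication"}.
#' @slot thetaC,thetaA thresholds applied to the cancer and activated-stroma
#'   occupancy maps.
#' @seealso \code{\link{classifyNiches}}
#' @export
setClass("NicheMap", representation(
  labels = "matrix", thetaC = "numeric", thetaA = "numeric"
))

setValidity("NicheMap", function(object) {
  ok <- c("survival", "persistence", "eradication")
  if (!all(object@labels %in% ok)) return("unknown niche labels")
  TRUE
})

#' Moore-neighbourhood composition histogram
#'
#' Distribution of the number of neighbours of one cell class around focal
#' cells of another class, pooled over snapshots in a time window (and,
#' optionally, over replicate simulations).
#'
#' @slot counts numeric vector of length 9 (0..8 neighbours).
#' @slot mean,se mean neighbour count and its standard error.
#' @slot nFocal number of focal observations.
#' @slot focalClass,neighbourClass cell classes.
#' @slot window numeric(2).
#' @slot mode \code{"pooled"} (cells pooled across runs) or \code{"per_run"}
#'   (mean of per-run means, SE across runs).
#' @seealso \code{\link{neighbourhoodDistribution}}
#' @export
setClass("NeighbourhoodHistogram", representation(
  counts = "numeric", mean = "numeric", se = "numeric", nFocal = "numeric",
  focalClass = "character", neighbourClass = "character", window = "numeric",
  mode = "character"
))

setValidity("NeighbourhoodHistogram", function(object) {
  if (length(object@counts) != 9L) return("'counts' must cover 0..8")
  if (is.finite(object@mean) && (object@mean < 0 || object@mean > 8)) {
    return("mean neighbour count must be in [0, 8]")
  }
  TRUE
})
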