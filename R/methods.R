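# Accessors, show methods and small shared utilities.

# explicit copies so compiled in-place kernels never touch caller-owned data
.copyNum <- function(m) m + 0
.copyInt <- function(m) m + 0L
.copyLgl <- function(m) m | FALSE

.moore <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Moore-neighbour count of TRUE sites of `mask` around every site (vectorised
# shift-sum; boundaries truncated).
.neighbourCounts <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  out <- matrix(0L, nr, nc)
  for (k in seq_len(8)) {
    dr <- .moore[k, 1L]
    dc <- .moore[k, 2L]
    out <- out + pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  out
}

#' Construct a lattice field
#'
#' @param values numeric matrix in [0, 1].
#' @param kind \code{"drug"} or \code{"signal"}.
#' @param dx lattice spacing in cm.
#' @return a \linkS4class{LatticeField}.
#' @export
latticeField <- function(values, kind = c("drug", "signal"), dx = 1e-3) {
  kind <- match.arg(kind)
  new("LatticeField", values = values, kind = kind, dx = dx)
}

#' Construct a treatment schedule
#'
#' @param mode \code{"none"}, \code{"continuous"} or \code{"intermittent"}.
#' @param tauT,tauH delivery / holiday period lengths in days (intermittent
#'   only).
#' @return a \linkS4class{TreatmentSchedule}.
#' @examples
#' treatmentSchedule("intermittent", tauT = 50, tauH = 20)
#' @export
treatmentSchedule <- function(mode = c("none", "continuous", "intermittent"),
                              tauT = 0, tauH = 0) {
  mode <- match.arg(mode)
  new("TreatmentSchedule", mode = mode, tauT = tauT, tauH = tauH)
}

#' @name accessors
#' @title Accessors for simulation objects
#' @description Slot accessors: prefer these over direct \code{@} access.
#' @param x the object.
#' @return the corresponding component.
NULL

setMethod("meanField", "matrix", function(x) mean(x))
setMethod("meanField", "LatticeField", function(x) mean(x@values))
setMethod("meanField", "OccupancyMap", function(x) mean(x@values))

setMethod("domainDim", "VesselSet", function(x) x@domainDim)
setMethod("domainDim", "LatticeField", function(x) dim(x@values))
setMethod("domainDim", "CellGrid", function(x) dim(x@occupancy))
setMethod("domainDim", "SimState", function(x) dim(x@cells@occupancy))

setMethod("cellCounts", "CellGrid", function(x) {
  occ <- x@occupancy
  c(
    cancer = sum(occ == .OCC[["cancer"]]),
    stroma_passive = sum(occ == .OCC[["stroma_passive"]]),
    stroma_reactive = sum(occ == .OCC[["stroma_reactive"]]),
    activated = sum(x@activated),
    vessel = sum(occ == .OCC[["vessel"]]),
    empty = sum(occ == .OCC[["empty"]])
  )
})
setMethod("cellCounts", "SimState", function(x) cellCounts(x@cells))

setMethod("cellGrid", "SimState", function(x) x@cells)
setMethod("drugField", "SimState", function(x) x@drug)
setMethod("signalField", "SimState", function(x) x@signal)
setMethod("vesselSet", "SimState", function(x) x@vessels)
setMethod("modelParams", "SimState", function(x) x@params)
setMethod("simTime", "SimState", function(x) x@time)
setMethod("occupancyMatrix", "CellGrid", function(x) x@occupancy)
setMethod("occupancyMatrix", "SimState", function(x) x@cells@occupancy)
setMethod("vesselCoords", "VesselSet", function(x) x@coordinates)
setMethod("fieldValues", "LatticeField", function(x) x@values)
setMethod("trajectoryCounts", "Trajectory", function(x) x@counts)
setMethod("trajectorySnapshots", "Trajectory", function(x) x@snapshots)

#' @describeIn VesselSet number of vessels
#' @param x a \linkS4class{VesselSet}.
#' @export
setMethod("length", "VesselSet", function(x) nrow(x@coordinates))

setMethod("show", "VesselSet", function(object) {
  cat(sprintf(
    "VesselSet: %d vessels on a %d x %d lattice (dx = %.3g cm)\n",
    nrow(object@coordinates), object@domainDim[1], object@domainDim[2],
    object@dx
  ))
  invisible(NULL)
})

setMethod("show", "LatticeField", function(object) {
  cat(sprintf(
    "LatticeField <%s>: %d x %d, mean = %.4g, range = [%.4g, %.4g]\n",
    object@kind, nrow(object@values), ncol(object@values),
    mean(object@values), min(object@values), max(object@values)
  ))
  invisible(NULL)
})

setMethod("show", "CellGrid", function(object) {
  ct <- cellCounts(object)
  cat(sprintf("CellGrid %d x %d:", nrow(object@occupancy),
              ncol(object@occupancy)),
      paste(names(ct), ct, sep = "=", collapse = " "), "\n")
  invisible(NULL)
})

setMethod("show", "TreatmentSchedule", function(object) {
  if (object@mode == "intermittent") {
    cat(sprintf("TreatmentSchedule: intermittent (tauT = %g d, tauH = %g d)\n",
                object@tauT, object@tauH))
  } else {
    cat(sprintf("TreatmentSchedule: %s\n", object@mode))
  }
  invisible(NULL)
})

setMethod("show", "SimState", function(object) {
  ct <- cellCounts(object)
  cat(sprintf("SimState at t = %.3f days (%d x %d lattice)\n", object@time,
              nrow(object@cells@occupancy), ncol(object@cells@occupancy)))
  cat("  cells: ", paste(names(ct), ct, sep = "=", collapse = " "), "\n")
  cat(sprintf("  mean drug = %.4g, mean signal = %.4g\n",
              mean(object@drug@values), mean(object@signal@values)))
  invisible(NULL)
})

setMethod("show", "Trajectory", function(object) {
  ct <- object@counts
  cat(sprintf(
    "Trajectory: %d records over t = [%.3g, %.3g] days, %d snapshots\n",
    nrow(ct), min(ct$time), max(ct$time), length(object@snapshots)
  ))
  cat(sprintf("  final counts: cancer=%d activated=%d\n",
              ct$cancer[nrow(ct)], ct$activated[nrow(ct)]))
  invisible(NULL)
})

setMethod("show", "OccupancyMap", function(object) {
  cat(sprintf(
    "OccupancyMap <%s>: %d x %d, window [%g, %g] d, %d snapshots, mean = %.4g\n",
    object@cellClass, nrow(object@values), ncol(object@values),
    object@window[1], object@window[2], object@nSnapshots,
    mean(object@values)
  ))
  invisible(NULL)
})

setMethod("show", "NicheMap", function(object) {
  tab <- table(factor(object@labels,
                      c("eradication", "survival", "persistence")))
  cat(sprintf("NicheMap (thetaC = %g, thetaA = %g): ", object@thetaC,
              object@thetaA),
      paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
  invisible(NULL)
})

setMethod("show", "NeighbourhoodHistogram", function(object) {
  cat(sprintf(
    "NeighbourhoodHistogram: %s neighbours of %s cells (%s)\n",
    object@neighbourClass, object@focalClass, object@mode
  ))
  cat(sprintf("  window [%g, %g] d, n focal = %g, mean = %.3f (se %.3f)\n",
              object@window[1], object@window[2], object@nFocal, object@mean,
              object@se))
  invisible(NULL)
})
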