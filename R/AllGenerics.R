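#' @include AllClasses.R
NULL

#' Spatial mean of a lattice field
#'
#' Arithmetic mean over all lattice sites, e.g. the mean-field drug
#' concentration of a snapshot or the mean vessel density of a layout.
#'
#' @param x a \linkS4class{LatticeField}, \linkS4class{OccupancyMap} or plain
#'   matrix.
#' @return a single numeric value.
#' @examples
#' meanField(matrix(c(0, 1, 0, 1), 2))
#' @export
setGeneric("meanField", function(x) standardGeneric("meanField"))

#' Domain dimensions
#'
#' @param x an object living on the simulation lattice.
#' @return integer vector \code{c(nrow, ncol)} in lattice units.
#' @export
setGeneric("domainDim", function(x) standardGeneric("domainDim"))

#' Population counts
#'
#' Number of cells of each class on the lattice.
#'
#' @param x a \linkS4class{CellGrid} or \linkS4class{SimState}.
#' @return named integer vector with elements \code{cancer},
#'   \code{stroma_passive}, \code{stroma_reactive}, \code{activated},
#'   \code{vessel} and \code{empty}.
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))

#' Treatment delivery predicate
#'
#' Whether the inhibitor drug is being delivered at simulation time \code{t}.
#' Intermittent schedules alternate a delivery period of length
#' \eqn{\tau_T} and a holiday of length \eqn{\tau_H}, delivery first, with
#' half-open boundaries: delivery iff
#' \eqn{t \bmod (\tau_T + \tau_H) < \tau_T}.
#'
#' @param schedule a \linkS4class{TreatmentSchedule}.
#' @param t simulation time in days (vectorised).
#' @return logical vector.
#' @examples
#' sch <- treatmentSchedule("intermittent", tauT = 50, tauH = 20)
#' isDelivering(sch, c(49.9, 55, 70))
#' @export
setGeneric("isDelivering", function(schedule, t) standardGeneric("isDelivering"))

#' @rdname accessors
#' @export
setGeneric("cellGrid", function(x) standardGeneric("cellGrid"))

#' @rdname accessors
#' @export
setGeneric("drugField", function(x) standardGeneric("drugField"))

#' @rdname accessors
#' @export
setGeneric("signalField", function(x) standardGeneric("signalField"))

#' @rdname accessors
#' @export
setGeneric("vesselSet", function(x) standardGeneric("vesselSet"))

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname accessors
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' @rdname accessors
#' @export
setGeneric("occupancyMatrix", function(x) standardGeneric("occupancyMatrix"))

#' @rdname accessors
#' @export
setGeneric("vesselCoords", function(x) standardGeneric("vesselCoords"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("trajectoryCounts", function(x) standardGeneric("trajectoryCounts"))

#' @rdname accessors
#' @export
setGeneric("trajectorySnapshots", function(x) standardGeneric("trajectorySnapshots"))
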