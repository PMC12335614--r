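#' Construct a parameter set
#'
#' Returns a validated \linkS4class{SimParams}, starting from the reference
#' parameterisation (see the class documentation for values and units) and
#' overriding any named slot.
#'
#' @param ... named overrides of \linkS4class{SimParams} slots.
#' @return a \linkS4class{SimParams}.
#' @examples
#' simParams()                      # reference parameterisation
#' simParams(domainCm = 0.06)       # a 60 x 60 lattice at dx = 10 um
#' @export
simParams <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == ""))) {
    stop("all arguments to simParams() must be named")
  }
  known <- slotNames("SimParams")
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  if ("nCI" %in% names(args)) args$nCI <- as.integer(args$nCI)
  do.call(new, c(list("SimParams"), args))
}

#' Number of lattice sites per side implied by a parameter set
#'
#' @param params a \linkS4class{SimParams}.
#' @return integer, \code{round(domainCm / dxCm)}.
#' @export
latticeSide <- function(params) {
  as.integer(round(params@domainCm / params@dxCm))
}

#' @describeIn SimParams compact parameter listing
#' @param object a \linkS4class{SimParams}.
#' @export
setMethod("show", "SimParams", function(object) {
  cat("SimParams (hybrid discrete-continuum EMDR model)\n")
  cat(sprintf("  thresholds: hd=%.3g hp=%.3g p0=%.3g hr=%.3g\n",
              object@hd, object@hp, object@p0, object@hr))
  cat(sprintf("  signal:     beta=%.4g gamma=%.4g delta=%.4g [1/day]\n",
              object@beta, object@gamma, object@delta))
  cat(sprintf("  drug:       Dd=%.3g cm^2/day, mu=%.4g 1/day\n",
              object@Dd, object@mu))
  cat(sprintf("  stroma:     pi=%.3g pT=%.4g pA=%.4g nCI=%d\n",
              object@piReactive, object@pT, object@pA, object@nCI))
  cat(sprintf(
    "  lattice:    %d x %d (dx=%.3g cm), dt=%.6g days\n",
    latticeSide(object), latticeSide(object), object@dxCm, object@dtDays
  ))
  cat(sprintf("  vessels:    sigmaMean=%.3g sigmaMin=%.3g cm\n",
              object@sigmaMean, object@sigmaMin))
  cat(sprintf("  cycle:      I ~ U[%.3g, %.3g] days, detection=%g cells\n",
              object@iRange[1], object@iRange[2], object@detectionCount))
  invisible(NULL)
})
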