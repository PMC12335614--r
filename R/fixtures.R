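# Small deterministic states exercising every rule branch; used throughout
# the test-suite and handy for interactive exploration.

#' Deterministic test fixtures
#'
#' Small simulation states (20 x 20 or smaller) covering the model's rule
#' branches:
#' \describe{
#'   \item{empty}{no agents, zero fields.}
#'   \item{single-vessel}{one central vessel, empty elsewhere.}
#'   \item{cancer-block}{a 3 x 3 cancer block in the centre with signal 1
#'     inside.}
#'   \item{stroma-sheet}{every site stroma, reactive with probability
#'     \code{piReactive} (seed-fixed reproducible mask).}
#'   \item{checkerboard}{alternating cancer / reactive stroma, signal 1 at
#'     cancer sites.}
#' }
#'
#' @param kind fixture name.
#' @param n lattice side (default 20).
#' @param params a \linkS4class{SimParams}; its geometry slots are overridden
#'   to match \code{n}.
#' @return a \linkS4class{SimState}.
#' @examples
#' cellCounts(makeFixture("cancer-block"))
#' @export
makeFixture <- function(kind = c("empty", "single-vessel", "cancer-block",
                                 "stroma-sheet", "checkerboard"),
                        n = 20L, params = simParams()) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  params@domainCm <- n * params@dxCm
  occ <- matrix(.OCC[["empty"]], n, n)
  act <- matrix(FALSE, n, n)
  clk <- matrix(0, n, n)
  imt <- matrix(0, n, n)
  p <- matrix(0, n, n)
  vcoords <- matrix(integer(0), 0L, 2L,
                    dimnames = list(NULL, c("row", "col")))
  mid <- as.integer(ceiling(n / 2))
  newborn <- function(mask) {
    imt[mask] <<- mean(params@iRange)
    clk[mask] <<- 0
  }
  if (kind == "single-vessel") {
    occ[mid, mid] <- .OCC[["vessel"]]
    vcoords <- cbind(row = mid, col = mid)
  } else if (kind == "cancer-block") {
    idx <- (mid - 1L):(mid + 1L)
    occ[idx, idx] <- .OCC[["cancer"]]
    p[idx, idx] <- 1
    newborn(occ == .OCC[["cancer"]])
  } else if (kind == "stroma-sheet") {
    occ[] <- .OCC[["stroma_passive"]]
    occ[matrix(stats::runif(n * n) < params@piReactive, n, n)] <-
      .OCC[["stroma_reactive"]]
    newborn(occ != .OCC[["empty"]])
  } else if (kind == "checkerboard") {
    board <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2 == 0)
    occ[board] <- .OCC[["cancer"]]
    occ[!board] <- .OCC[["stroma_reactive"]]
    p[board] <- 1
    newborn(TRUE)
  }
  cells <- new("CellGrid", occupancy = occ, activated = act, clock = clk,
               imt = imt)
  vessels <- new("VesselSet", coordinates = vcoords,
                 domainDim = c(n, n), dx = params@dxCm)
  simState(cells, vessels, params,
           signal = new("LatticeField", values = p, kind = "signal",
                        dx = params@dxCm))
}
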