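# Per-cell rules: cancer viability and division, stroma turnover and contact
# inhibition, reactive-stroma activation and deactivation.

#' Cancer viability class from the local proliferation signal
#'
#' Cancer cell fate is set by two thresholds \eqn{h_d < h_p}: death below
#' \eqn{h_d} (insufficient signal for viability), proliferation at or above
#' \eqn{h_p}, quiescence (cell cycle paused) in between. Boundary convention:
#' \code{"dead"} iff p < hd; \code{"proliferative"} iff p >= hp.
#'
#' @param p local proliferation-signal value(s) in [0, 1] (vectorised).
#' @param hd,hp death and proliferation thresholds.
#' @return character vector in \code{c("dead", "quiescent",
#'   "proliferative")}.
#' @examples
#' classifyViability(c(0.19, 0.5, 0.8))
#' @export
classifyViability <- function(p, hd = 0.2, hp = 0.8) {
  stopifnot(hd < hp, all(p >= 0), all(p <= 1))
  ifelse(p < hd, "dead", ifelse(p < hp, "quiescent", "proliferative"))
}

#' Advance cancer cells one macro step
#'
#' Visits every cancer cell (uniform random order): cells below the death
#' threshold are removed, quiescent cells keep their clock frozen,
#' proliferative cells advance their clock by \code{dt} and attempt division
#' once the clock reaches the intermitotic time. Division is free of contact
#' inhibition: it succeeds whenever an empty Moore site exists; otherwise the
#' clock is held at I and retried next step. Both daughters receive clock 0, a
#' fresh I ~ U[0.9, 1.1] and the signal birth floor \code{p0} at their sites
#' (which is why the signal field is returned alongside the cells).
#'
#' @param cells a \linkS4class{CellGrid}.
#' @param signal the proliferation-signal \linkS4class{LatticeField}.
#' @param params a \linkS4class{SimParams}.
#' @param dt step length in days.
#' @return list with elements \code{cells}, \code{signal}, \code{births},
#'   \code{deaths}.
#' @export
advanceCancer <- function(cells, signal, params, dt = params@dtDays) {
  occ <- .copyInt(cells@occupancy)
  act <- .copyLgl(cells@activated)
  clk <- .copyNum(cells@clock)
  imt <- .copyNum(cells@imt)
  p <- .copyNum(signal@values)
  bd <- cpp_advance_cancer(occ, act, clk, imt, p, dt, params@hd, params@hp,
                           params@p0, params@iRange[1], params@iRange[2])
  list(
    cells = new("CellGrid", occupancy = occ, activated = act, clock = clk,
                imt = imt),
    signal = new("LatticeField", values = p, kind = "signal",
                 dx = signal@dx),
    births = bd[1], deaths = bd[2]
  )
}

#' Attempt a single cell division
#'
#' The division rule applied to the cell at \code{site} once its clock has
#' reached its intermitotic time. Cancer cells are blocked (clock held,
#' retried next step) when no empty Moore site exists; stroma cells abort
#' (clock reset, fresh I drawn) when either no empty site exists or the number
#' of occupied Moore neighbours (any class, vessels included) exceeds
#' \code{nCI}. On success one daughter keeps the mother's site, the other is
#' placed uniformly at random on an empty Moore site; both get clock 0 and
#' fresh independent I; daughters inherit type and activation state; cancer
#' daughters receive the signal birth floor at both sites.
#'
#' @param cells a \linkS4class{CellGrid}.
#' @param signal the proliferation-signal \linkS4class{LatticeField}.
#' @param site integer(2), (row, col) of the dividing cell.
#' @param params a \linkS4class{SimParams}.
#' @return list with \code{cells}, \code{signal}, \code{outcome} (one of
#'   \code{"divided"}, \code{"blocked"}, \code{"aborted"}) and
#'   \code{daughterSite} (or NULL).
#' @export
attemptDivision <- function(cells, signal, site, params) {
  occ <- .copyInt(cells@occupancy)
  act <- .copyLgl(cells@activated)
  clk <- .copyNum(cells@clock)
  imt <- .copyNum(cells@imt)
  p <- .copyNum(signal@values)
  r <- site[1]
  cc <- site[2]
  type <- occ[r, cc]
  if (type %in% .OCC[c("empty", "vessel")]) {
    stop("attemptDivision() called on an empty or vessel site")
  }
  isCancer <- type == .OCC[["cancer"]]
  nr <- nrow(occ)
  ncol_ <- ncol(occ)
  nb <- cbind(r + .moore[, 1], cc + .moore[, 2])
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= ncol_,
           , drop = FALSE]
  occNb <- occ[nb]
  empties <- nb[occNb == .OCC[["empty"]], , drop = FALSE]
  drawI <- function() stats::runif(1, params@iRange[1], params@iRange[2])
  finish <- function(outcome, daughter = NULL) {
    list(
      cells = new("CellGrid", occupancy = occ, activated = act, clock = clk,
                  imt = imt),
      signal = new("LatticeField", values = p, kind = "signal",
                   dx = signal@dx),
      outcome = outcome, daughterSite = daughter
    )
  }
  if (!isCancer && sum(occNb != .OCC[["empty"]]) > params@nCI) {
    clk[r, cc] <- 0
    imt[r, cc] <- drawI()
    return(finish("aborted"))
  }
  if (nrow(empties) == 0L) {
    if (isCancer) {
      clk[r, cc] <- imt[r, cc] # held at I, retried next step
      return(finish("blocked"))
    }
    clk[r, cc] <- 0
    imt[r, cc] <- drawI()
    return(finish("aborted"))
  }
  tgt <- empties[sample.int(nrow(empties), 1L), ]
  occ[tgt[1], tgt[2]] <- type
  act[tgt[1], tgt[2]] <- act[r, cc] # daughters inherit activation state
  clk[tgt[1], tgt[2]] <- 0
  imt[tgt[1], tgt[2]] <- drawI()
  clk[r, cc] <- 0
  imt[r, cc] <- drawI()
  if (isCancer) {
    p[r, cc] <- max(p[r, cc], params@p0)
    p[tgt[1], tgt[2]] <- max(p[tgt[1], tgt[2]], params@p0)
  }
  finish("divided", daughter = as.integer(tgt))
}

#' Advance stroma cells one macro step
#'
#' Each stroma cell (passive or reactive, uniform random order) dies with
#' per-step probability \code{pT * dt}; survivors advance their clock by
#' \code{dt} unconditionally (stroma ignores the proliferation signal) and
#' attempt division under contact inhibition once the clock reaches I. A
#' failed attempt consumes the cycle (clock reset, fresh I).
#'
#' @inheritParams advanceCancer
#' @return list with \code{cells}, \code{births}, \code{deaths}.
#' @export
advanceStroma <- function(cells, params, dt = params@dtDays) {
  occ <- .copyInt(cells@occupancy)
  act <- .copyLgl(cells@activated)
  clk <- .copyNum(cells@clock)
  imt <- .copyNum(cells@imt)
  bd <- cpp_advance_stroma(occ, act, clk, imt, dt, params@pT, params@nCI,
                           params@iRange[1], params@iRange[2])
  list(
    cells = new("CellGrid", occupancy = occ, activated = act, clock = clk,
                imt = imt),
    births = bd[1], deaths = bd[2]
  )
}

#' Update reactive-stroma activation states
#'
#' Deactivated reactive stroma with local drug concentration at or above
#' \code{hr} AND at least one cancer cell in its Moore neighbourhood activates
#' with per-step probability \code{pA * dt}. An activated cell whose local
#' drug concentration falls below \code{hr} deactivates immediately and
#' deterministically. Passive stroma never changes state.
#'
#' @param cells a \linkS4class{CellGrid}.
#' @param drug the drug \linkS4class{LatticeField}.
#' @param params a \linkS4class{SimParams}.
#' @param dt step length in days.
#' @return the updated \linkS4class{CellGrid}.
#' @export
updateReactiveStates <- function(cells, drug, params, dt = params@dtDays) {
  if (!identical(dim(cells@occupancy), dim(drug@values))) {
    stop("cell grid and drug field have mismatched dimensions")
  }
  act <- .copyLgl(cells@activated)
  cpp_update_reactive(cells@occupancy, act, drug@values, dt, params@pA,
                      params@hr)
  new("CellGrid", occupancy = cells@occupancy, activated = act,
      clock = cells@clock, imt = cells@imt)
}
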