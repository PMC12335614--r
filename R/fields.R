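# Explicit finite-difference stepping of the drug and proliferation-signal
# fields.

#' Number of drug-solver substeps per macro step
#'
#' The drug equation is advanced on a finer time grid than the agents: the
#' macro step dt is split into the smallest number of substeps n such that the
#' diffusion factor satisfies \eqn{4 D_d (dt/n) / dx^2 \le 0.25} and the
#' (stiff) clearance factor satisfies \eqn{\mu (dt/n) \le 0.1}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return integer number of substeps (>= 1).
#' @examples
#' chooseSubsteps(simParams())  # 10 for the reference parameterisation
#' @export
chooseSubsteps <- function(params) {
  stopifnot(params@Dd >= 0, params@mu >= 0, params@dtDays > 0,
            params@dxCm > 0)
  eps <- 1e-12
  nDiff <- ceiling(4 * params@Dd * params@dtDays / (0.25 * params@dxCm^2) -
                     eps)
  nClear <- ceiling(params@mu * params@dtDays / 0.1 - eps)
  max(1L, as.integer(nDiff), as.integer(nClear))
}

.vesselMask <- function(vessels) {
  m <- matrix(FALSE, vessels@domainDim[1], vessels@domainDim[2])
  co <- vessels@coordinates
  if (nrow(co)) m[cbind(co[, 1], co[, 2])] <- TRUE
  m
}

.checkStability <- function(params, nSubsteps) {
  dts <- params@dtDays / nSubsteps
  if (4 * params@Dd * dts / params@dxCm^2 > 0.25 + 1e-9) {
    stop("drug solver unstable: diffusion factor 4*Dd*dt_sub/dx^2 = ",
         signif(4 * params@Dd * dts / params@dxCm^2, 4), " > 0.25; ",
         "increase the number of substeps")
  }
  if (params@mu * dts > 0.1 + 1e-9) {
    stop("drug solver inaccurate: clearance factor mu*dt_sub = ",
         signif(params@mu * dts, 4), " > 0.1; increase the number of ",
         "substeps")
  }
  invisible(TRUE)
}

#' Advance the drug field one macro step
#'
#' Explicit Euler on a finer time grid (see \code{\link{chooseSubsteps}}):
#' 5-point Laplacian diffusion with zero-flux (reflecting) boundaries, and
#' clearance \eqn{-\mu d} at vessel sites only. During delivery the
#' concentration is clamped to 1 at every vessel site after each substep
#' (Dirichlet delivery); during holidays vessels act as pure sinks.
#'
#' @param drug a \linkS4class{LatticeField} of kind \code{"drug"}.
#' @param vessels a \linkS4class{VesselSet} on the same lattice.
#' @param delivering logical, whether the drug is being delivered.
#' @param params a \linkS4class{SimParams}.
#' @param nSubsteps number of substeps; defaults to
#'   \code{chooseSubsteps(params)}. A value violating the stability bounds is
#'   an error, never a silent blow-up.
#' @return the advanced \linkS4class{LatticeField}.
#' @export
stepDrug <- function(drug, vessels, delivering, params,
                     nSubsteps = chooseSubsteps(params)) {
  if (!identical(unname(as.integer(dim(drug@values))),
                 unname(as.integer(vessels@domainDim)))) {
    stop("drug field and vessel set have mismatched dimensions")
  }
  .checkStability(params, nSubsteps)
  v <- .copyNum(drug@values)
  cpp_step_drug(v, .vesselMask(vessels), isTRUE(delivering),
                as.integer(nSubsteps), params@Dd, params@mu, params@dtDays,
                params@dxCm)
  if (any(!is.finite(v)) || min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    stop("drug field left [0, 1]: numerical instability")
  }
  new("LatticeField", values = v, kind = "drug", dx = drug@dx)
}

#' Advance the proliferation-signal field one macro step
#'
#' Per-site explicit Euler of
#' \deqn{dp/dt = (\beta + \gamma A(x)) H(1 - p) s(x) - \delta d p,}
#' where \eqn{s(x) = 1} iff a cancer cell occupies x, \eqn{A(x)} is the
#' number of activated reactive stroma cells in the Moore neighbourhood of x,
#' and the Heaviside factor shuts production off at saturation
#' (\eqn{H(0) = 0}). The signal does not diffuse (chemokines are consumed
#' locally or anchored to the ECM). The result is clipped to [0, 1].
#'
#' @param signal a \linkS4class{LatticeField} of kind \code{"signal"}.
#' @param drug a \linkS4class{LatticeField} of kind \code{"drug"} on the same
#'   grid.
#' @param cells a \linkS4class{CellGrid} on the same grid.
#' @param params a \linkS4class{SimParams}.
#' @param dt step length in days (defaults to the macro step).
#' @return the advanced \linkS4class{LatticeField}.
#' @export
stepSignal <- function(signal, drug, cells, params, dt = params@dtDays) {
  if (!identical(dim(signal@values), dim(drug@values)) ||
      !identical(dim(signal@values), dim(cells@occupancy))) {
    stop("signal, drug and cell grids have mismatched dimensions")
  }
  v <- .copyNum(signal@values)
  cpp_step_signal(v, drug@values, cells@occupancy, cells@activated,
                  params@beta, params@gamma, params@delta, dt)
  new("LatticeField", values = v, kind = "signal", dx = signal@dx)
}

#' Apply the birth floor to the proliferation signal
#'
#' Each newborn cancer cell starts with a local proliferation signal of at
#' least \code{p0}: \code{p(site) <- max(p(site), p0)}.
#'
#' @param signal a \linkS4class{LatticeField} of kind \code{"signal"}.
#' @param site integer(2), (row, col) lattice position.
#' @param p0 the birth floor.
#' @return the updated \linkS4class{LatticeField}.
#' @examples
#' f <- latticeField(matrix(0.1, 3, 3), "signal")
#' fieldValues(applyBirthFloor(f, c(2, 2), 0.256))[2, 2]
#' @export
applyBirthFloor <- function(signal, site, p0) {
  d <- dim(signal@values)
  if (site[1] < 1 || site[1] > d[1] || site[2] < 1 || site[2] > d[2]) {
    stop("'site' outside the domain")
  }
  v <- .copyNum(signal@values)
  v[site[1], site[2]] <- max(v[site[1], site[2]], p0)
  new("LatticeField", values = v, kind = signal@kind, dx = signal@dx)
}
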