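# Vessel layout generation and the local vessel-density measure.

#' Number of vessels implied by the mean inter-vessel distance
#'
#' The target vessel count for a domain of given area is
#' \eqn{N_v = |\Omega| / \sigma_{mean}^2}, floored to an integer so the target
#' density is never exceeded.
#'
#' @param domainArea domain area in cm^2.
#' @param sigmaMean mean inter-vessel distance in cm.
#' @return integer vessel count.
#' @examples
#' computeVesselCount(0.09, 0.016)  # 351 for the reference tissue
#' @export
computeVesselCount <- function(domainArea, sigmaMean) {
  if (!is.numeric(domainArea) || length(domainArea) != 1L ||
      !is.finite(domainArea) || domainArea <= 0) {
    stop("'domainArea' must be a positive number")
  }
  if (!is.numeric(sigmaMean) || length(sigmaMean) != 1L ||
      !is.finite(sigmaMean) || sigmaMean <= 0) {
    stop("'sigmaMean' must be a positive number")
  }
  # small tolerance so exact ratios are not floored away by round-off
  as.integer(floor(domainArea / sigmaMean^2 + 1e-9))
}

#' Irregular (circle-packed) vessel layout
#'
#' Places \code{computeVesselCount(...)} vessels uniformly at random on the
#' lattice subject to a hard minimum pairwise distance \code{sigmaMin}
#' (physical units), emulating experimentally measured vascular spacing
#' statistics. Placement is rejection sampling with a retry cap per vessel and
#' a bounded number of restarts.
#'
#' @param domainDim integer(2), lattice dimensions.
#' @param sigmaMean mean inter-vessel distance (cm), sets the vessel count.
#' @param sigmaMin minimum pairwise distance (cm).
#' @param dx lattice spacing (cm).
#' @param nVessels optional explicit vessel count overriding the
#'   \code{sigmaMean}-derived value.
#' @param maxProposals rejection proposals allowed per vessel before a
#'   restart.
#' @param maxRestarts restarts before giving up.
#' @return a \linkS4class{VesselSet}. Layouts are reproducible for a fixed
#'   RNG seed.
#' @examples
#' set.seed(1)
#' v <- placeVesselsPacked(c(60, 60), sigmaMean = 0.016, sigmaMin = 0.008)
#' length(v)
#' @export
placeVesselsPacked <- function(domainDim, sigmaMean = 0.016,
                               sigmaMin = 0.008, dx = 1e-3,
                               nVessels = NULL, maxProposals = 1e4,
                               maxRestarts = 10L) {
  domainDim <- as.integer(domainDim)
  if (sigmaMin > sigmaMean) stop("'sigmaMin' must be <= 'sigmaMean'")
  area <- prod(domainDim) * dx^2
  n <- if (is.null(nVessels)) {
    computeVesselCount(area, sigmaMean)
  } else {
    as.integer(nVessels)
  }
  if (n < 1L) stop("vessel count is zero; domain too small for sigmaMean")
  minLat2 <- (sigmaMin / dx)^2 # squared minimum distance, lattice units
  for (restart in seq_len(maxRestarts)) {
    rows <- integer(n)
    cols <- integer(n)
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (prop in seq_len(maxProposals)) {
        r <- sample.int(domainDim[1], 1L)
        cc <- sample.int(domainDim[2], 1L)
        if (placed == 0L) {
          ok <- TRUE
        } else {
          i <- seq_len(placed)
          d2 <- (rows[i] - r)^2 + (cols[i] - cc)^2
          ok <- all(d2 >= minLat2) && all(d2 > 0)
        }
        if (ok) {
          placed <- placed + 1L
          rows[placed] <- r
          cols[placed] <- cc
          break
        }
      }
      if (!ok) break # restart from scratch
    }
    if (placed == n) {
      return(new("VesselSet",
        coordinates = cbind(row = rows, col = cols),
        domainDim = domainDim, dx = dx
      ))
    }
  }
  stop(
    "circle packing failed after ", maxRestarts, " restarts: could not ",
    "place ", n, " vessels at minimum spacing ", sigmaMin, " cm; ",
    "reduce the vessel count (larger sigmaMean) or sigmaMin"
  )
}

#' Regular-grid vessel layout
#'
#' Vessels on a centred square grid with the given spacing (lattice units),
#' used to sweep vessel density systematically. The grid is centred: leftover
#' margin is split evenly. A spacing larger than the domain yields a single
#' central vessel.
#'
#' @param domainDim integer(2), lattice dimensions.
#' @param spacing grid spacing in lattice units (>= 1).
#' @param dx lattice spacing (cm).
#' @return a \linkS4class{VesselSet}.
#' @examples
#' length(placeVesselsRegular(c(60, 60), 20)) # 3 x 3 grid
#' @export
placeVesselsRegular <- function(domainDim, spacing, dx = 1e-3) {
  domainDim <- as.integer(domainDim)
  if (spacing < 1) stop("'spacing' must be >= 1 lattice unit")
  axisCoords <- function(n) {
    k <- max(1L, as.integer(floor(n / spacing)))
    span <- as.integer(round((k - 1L) * spacing))
    start <- as.integer(floor((n - span) / 2)) + 1L
    as.integer(round(start + spacing * (seq_len(k) - 1L)))
  }
  r <- axisCoords(domainDim[1])
  cc <- axisCoords(domainDim[2])
  grid <- expand.grid(row = r, col = cc, KEEP.OUT.ATTRS = FALSE)
  new("VesselSet",
    coordinates = cbind(row = grid$row, col = grid$col),
    domainDim = domainDim, dx = dx
  )
}

#' Minimum pairwise vessel distance
#'
#' @param vessels a \linkS4class{VesselSet}.
#' @param units \code{"cm"} or \code{"lattice"}.
#' @return smallest pairwise Euclidean distance (Inf for fewer than two
#'   vessels).
#' @export
minVesselDistance <- function(vessels, units = c("cm", "lattice")) {
  units <- match.arg(units)
  co <- vessels@coordinates
  if (nrow(co) < 2L) return(Inf)
  dmin <- min(stats::dist(co))
  if (units == "cm") dmin * vessels@dx else dmin
}

#' Local vessel-density measure
#'
#' For every lattice site x,
#' \deqn{\rho(x) = \sum_{y \in V} e^{-\hat\alpha \|x - y\|} /
#'       \sum_{y \in \Omega} e^{-\hat\alpha \|x - y\|},}
#' with distances in lattice units. The normaliser sums over all lattice
#' sites, so \eqn{0 \le \rho \le 1} with \eqn{\rho \equiv 1} when every site
#' is a vessel.
#'
#' @param vessels a \linkS4class{VesselSet}.
#' @param alphaHat decay constant per lattice unit (default 0.1).
#' @return numeric matrix of \eqn{\rho} values.
#' @export
vesselDensityMap <- function(vessels, alphaHat = 0.1) {
  if (!is.numeric(alphaHat) || alphaHat <= 0) {
    stop("'alphaHat' must be positive")
  }
  co <- vessels@coordinates
  storage.mode(co) <- "integer"
  cpp_density_map(vessels@domainDim[1], vessels@domainDim[2], co, alphaHat)
}

#' Write / read a vessel layout as CSV
#'
#' Columns \code{row}, \code{col} (1-based lattice coordinates).
#'
#' @param vessels a \linkS4class{VesselSet}.
#' @param path file path.
#' @return \code{writeVesselsCSV} returns \code{path} invisibly;
#'   \code{readVesselsCSV} returns a \linkS4class{VesselSet}.
#' @param domainDim,dx lattice geometry to attach on read.
#' @export
writeVesselsCSV <- function(vessels, path) {
  utils::write.csv(
    as.data.frame(vessels@coordinates),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeVesselsCSV
#' @export
readVesselsCSV <- function(path, domainDim, dx = 1e-3) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df))) {
    stop("vessel CSV must have 'row' and 'col' columns")
  }
  new("VesselSet",
    coordinates = cbind(row = as.integer(df$row), col = as.integer(df$col)),
    domainDim = as.integer(domainDim), dx = dx
  )
}
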