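# Independent brute-force oracles used to pin down expected values.

# Dense-matrix explicit-Euler oracle for the drug solver: builds the full
# N x N one-substep update matrix (reflection boundaries fold into the
# diagonal), applies it nsub times per macro step with the Dirichlet clamp
# after every substep. Deliberately a different code path from the package
# kernel.
oracleDrugMatrix <- function(nr, nc, vmask, params, nsub) {
  n <- nr * nc
  dts <- params@dtDays / nsub
  k <- params@Dd * dts / params@dxCm^2
  A <- matrix(0, n, n)
  id <- function(i, j) (j - 1L) * nr + i
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      me <- id(i, j)
      nbs <- list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
      pres <- 0L
      for (nb in nbs) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          A[me, id(nb[1], nb[2])] <- A[me, id(nb[1], nb[2])] + k
          pres <- pres + 1L
        }
      }
      A[me, me] <- 1 - k * pres - if (vmask[i, j]) params@mu * dts else 0
    }
  }
  A
}

oracleStepDrug <- function(dmat, vmask, delivering, params, nsub,
                           A = oracleDrugMatrix(nrow(dmat), ncol(dmat),
                                                vmask, params, nsub)) {
  v <- as.vector(dmat)
  vs <- which(as.vector(vmask))
  for (s in seq_len(nsub)) {
    v <- as.vector(A %*% v)
    if (delivering) v[vs] <- 1
  }
  matrix(v, nrow(dmat), ncol(dmat))
}

# Closed-form solution of dp/dt = rate - delta * d * p with constant drug d
# (valid while 0 < p < 1): exponential relaxation to rate / (delta * d).
oracleSignalClosedForm <- function(t, p0, rate, delta, d = 1) {
  eq <- rate / (delta * d)
  eq + (p0 - eq) * exp(-delta * d * t)
}

# Time at which the closed-form solution crosses a falling threshold.
oracleSignalCrossing <- function(threshold, p0, rate, delta, d = 1) {
  eq <- rate / (delta * d)
  log((p0 - eq) / (threshold - eq)) / (delta * d)
}

# Exhaustive per-cell Moore neighbour count (loops, no vectorisation).
oracleNeighbourCount <- function(mask, i, j) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  tot <- 0L
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- i + dr
      cc <- j + dc
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc && mask[r, cc]) {
        tot <- tot + 1L
      }
    }
  }
  tot
}

# Brute-force vessel density at one site (direct double sum).
oracleDensityAt <- function(i, j, coords, nr, nc, alphaHat) {
  num <- 0
  if (nrow(coords)) {
    for (v in seq_len(nrow(coords))) {
      num <- num + exp(-alphaHat *
                         sqrt((i - coords[v, 1])^2 + (j - coords[v, 2])^2))
    }
  }
  den <- 0
  for (ii in seq_len(nr)) {
    for (jj in seq_len(nc)) {
      den <- den + exp(-alphaHat * sqrt((i - ii)^2 + (j - jj)^2))
    }
  }
  as.numeric(num / den)
}

# A small parameter set for fast field tests (tiny lattice, same rates).
tinyParams <- function(n = 5L, ...) {
  args <- list(domainCm = n * 1e-3, ...)
  if (!"detectionCount" %in% names(args)) args$detectionCount <- 50
  do.call(simParams, args)
}

# Hold the drug field fixed and advance only the signal at one site;
# returns the trajectory of p at that site.
simulateSignalAtSite <- function(state, site, dHeld, nSteps, params,
                                 dt = params@dtDays) {
  d <- drugField(state)
  dv <- fieldValues(d)
  dv[] <- dHeld
  d <- latticeField(dv, "drug", dx = params@dxCm)
  sig <- signalField(state)
  out <- numeric(nSteps + 1L)
  out[1] <- fieldValues(sig)[site[1], site[2]]
  for (s in seq_len(nSteps)) {
    sig <- stepSignal(sig, d, cellGrid(state), params, dt = dt)
    out[s + 1L] <- fieldValues(sig)[site[1], site[2]]
  }
  out
}
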