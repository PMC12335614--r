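# Scaled-down study conditions shared by the dynamics tests (see the methods
# vignette): 60 x 60 lattice (0.06 cm side at dx = 10 um), regular vessel
# grids, tumour detection at 400 cells (the same detected fraction of the
# domain as 1e4 cells on the 300 x 300 tissue), reference intermittent
# schedule tauT = 50 / tauH = 20 days. Heavy states and runs are cached per
# session so several test blocks can share them.

.accCache <- new.env(parent = emptyenv())

scaledParams <- function() simParams(domainCm = 0.06, detectionCount = 400)

# homeostatic tissue + tumour grown to detection, one per vessel spacing
scaledTumourState <- function(spacing = 16L) {
  key <- paste0("tumour_", spacing)
  if (is.null(.accCache[[key]])) {
    p <- scaledParams()
    set.seed(4000L + spacing)
    v <- placeVesselsRegular(c(60, 60), spacing, dx = p@dxCm)
    st <- suppressWarnings(equilibrateStroma(v, p, duration = 300))
    .accCache[[key]] <- seedAndGrowTumour(st, maxDays = 400)
  }
  .accCache[[key]]
}

# replicate treated runs from the shared initial condition
scaledRuns <- function(spacing, schedule, horizon, seeds,
                       snapshotCadence = NULL) {
  key <- paste0(
    "runs_", spacing, "_", schedule@mode, "_", schedule@tauT, "_",
    schedule@tauH, "_", horizon, "_", paste(seeds, collapse = "."),
    if (is.null(snapshotCadence)) "" else paste0("_snap", snapshotCadence)
  )
  if (is.null(.accCache[[key]])) {
    st <- scaledTumourState(spacing)
    .accCache[[key]] <- lapply(seeds, function(s) {
      runSim(st, schedule, horizon, snapshotCadence = snapshotCadence,
             seed = s)
    })
  }
  .accCache[[key]]
}

dailyBurden <- function(traj) {
  ct <- trajectoryCounts(traj)
  keep <- c(1L, which(diff(floor(ct$time + 1e-9)) > 0) + 1L)
  ct[keep, c("time", "cancer", "activated")]
}
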