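# builds a tiny trajectory by hand from raw snapshot lists
.handTraj <- function(snaps, params = simParams(),
                      schedule = treatmentSchedule("none")) {
  counts <- data.frame(
    time = vapply(snaps, `[[`, numeric(1), "time"),
    cancer = vapply(snaps, function(s) {
      sum(s$occupancy == OCC_CODES[["cancer"]])
    }, integer(1)),
    stroma_passive = 0L, stroma_reactive = 0L,
    activated = vapply(snaps, function(s) sum(s$activated), integer(1)),
    mean_drug = 0, mean_signal = 0, delivering = FALSE
  )
  new("Trajectory", counts = counts, snapshots = snaps, params = params,
      schedule = schedule)
}

.snap <- function(time, occ, act = NULL) {
  if (is.null(act)) act <- matrix(FALSE, nrow(occ), ncol(occ))
  list(time = time, occupancy = occ, activated = act)
}

test_that("tumour burden matches a direct snapshot recount", {
  set.seed(8)
  st <- makeFixture("cancer-block", n = 10L, params = tinyParams(10L))
  tr <- runSim(st, treatmentSchedule("none"), 4, snapshotCadence = 1)
  tb <- tumourBurden(tr)
  for (s in trajectorySnapshots(tr)) {
    i <- which.min(abs(tb$time - s$time))
    expect_identical(tb$cancer[i],
                     sum(s$occupancy == OCC_CODES[["cancer"]]))
  }
  # cancer-free run: all zeros
  st0 <- makeFixture("stroma-sheet", n = 8L, params = tinyParams(8L))
  tr0 <- runSim(st0, treatmentSchedule("none"), 1)
  expect_true(all(tumourBurden(tr0)$cancer == 0L))
})

test_that("cumulative drug days follow the schedule arithmetic exactly", {
  expect_identical(cumulativeDrugDays(treatmentSchedule("continuous"), 590),
                   590)
  expect_identical(
    cumulativeDrugDays(treatmentSchedule("intermittent", 50, 20), 590),
    430
  )
  expect_identical(
    cumulativeDrugDays(treatmentSchedule("intermittent", 10, 20), 30),
    10
  )
  expect_identical(cumulativeDrugDays(treatmentSchedule("none"), 590), 0)
  # additivity over disjoint horizons and the horizon bound
  sch <- treatmentSchedule("intermittent", 13, 7)
  for (h in c(20, 33, 47, 100)) {
    expect_lte(cumulativeDrugDays(sch, h), h)
  }
  whole <- cumulativeDrugDays(sch, 200)
  parts <- cumulativeDrugDays(sch, 20) + sum(vapply(1:9, function(k) {
    cumulativeDrugDays(sch, (k + 1) * 20) - cumulativeDrugDays(sch, k * 20)
  }, numeric(1)))
  expect_equal(whole, parts)
})

test_that("relative tumour burden is a normalised burden ratio", {
  occ1 <- matrix(OCC_CODES[["empty"]], 4, 4)
  occ1[1:2, 1:2] <- OCC_CODES[["cancer"]]
  snapsA <- list(.snap(0, occ1), .snap(1, occ1))
  a <- .handTraj(snapsA)
  expect_identical(relativeTumourBurden(a, a), 1)
  occ2 <- occ1
  occ2[2, 1:2] <- OCC_CODES[["empty"]] # half the cells
  b <- .handTraj(list(.snap(0, occ2), .snap(1, occ2)))
  expect_identical(relativeTumourBurden(b, a), 0.5)
  zero <- .handTraj(list(.snap(0, occ2 * 0L), .snap(1, occ2 * 0L)))
  expect_identical(relativeTumourBurden(zero, a), 0)
  # mismatched grids are an error
  c3 <- .handTraj(list(.snap(0.5, occ1)))
  expect_error(relativeTumourBurden(c3, a), "sampling grid")
})

test_that("longitudinal occupancy is the per-site presence fraction", {
  occA <- matrix(OCC_CODES[["empty"]], 3, 3)
  occA[1, 1] <- OCC_CODES[["cancer"]]
  occB <- occA
  occB[3, 3] <- OCC_CODES[["cancer"]]
  snaps <- list(.snap(0, occA), .snap(1, occB), .snap(2, occB),
                .snap(3, occB))
  tr <- .handTraj(snaps)
  occMap <- longitudinalOccupancy(tr, "cancer", window = c(0, 3))
  expect_identical(occMap@values[1, 1], 1)      # present in all 4
  expect_identical(occMap@values[3, 3], 0.75)   # present in 3 of 4
  expect_identical(occMap@values[2, 2], 0)      # never present
  # window restriction
  occMapLate <- longitudinalOccupancy(tr, "cancer", window = c(1, 3))
  expect_identical(occMapLate@values[3, 3], 1)
  expect_error(longitudinalOccupancy(tr, "cancer", window = c(10, 20)),
               "window")
  # complementary classes partition the lattice
  tot <- Reduce(`+`, lapply(
    c("cancer", "stroma_passive", "stroma_reactive", "vessel", "empty"),
    function(cl) longitudinalOccupancy(tr, cl, window = c(0, 3))@values
  ))
  expect_equal(tot, matrix(1, 3, 3))
})

test_that("activation windows cover the tail of each delivery period", {
  aw <- activationWindow(treatmentSchedule("intermittent", 50, 20),
                         fraction = 0.6, horizon = 140)
  expect_equal(aw$start[1], 20)
  expect_equal(aw$end[1], 50)
  expect_equal(aw$start[2], 90)
  expect_equal(aw$end[2], 120)
  aw2 <- activationWindow(treatmentSchedule("intermittent", 10, 20),
                          fraction = 0.6, horizon = 100)
  expect_equal(aw2$start[2], 34)
  expect_equal(aw2$end[2], 40)
  full <- activationWindow(treatmentSchedule("intermittent", 50, 20),
                           fraction = 1, horizon = 70)
  expect_equal(full$start[1], 0)
  expect_equal(full$end[1], 50)
  expect_error(activationWindow(treatmentSchedule("continuous")),
               "intermittent")
})

test_that("neighbourhood distributions match an exhaustive per-cell count", {
  set.seed(19)
  occ <- matrix(sample(c(OCC_CODES[["empty"]], OCC_CODES[["cancer"]],
                         OCC_CODES[["stroma_reactive"]]), 25, TRUE), 5, 5)
  act <- occ == OCC_CODES[["stroma_reactive"]] &
    matrix(runif(25) < 0.5, 5, 5)
  tr <- .handTraj(list(.snap(0, occ, act)))
  h <- neighbourhoodDistribution(tr, "cancer", "stroma_activated",
                                 window = c(0, 0), mode = "pooled")
  focal <- which(occ == OCC_CODES[["cancer"]], arr.ind = TRUE)
  brute <- vapply(seq_len(nrow(focal)), function(k) {
    oracleNeighbourCount(act, focal[k, 1], focal[k, 2])
  }, integer(1))
  expect_identical(h@nFocal, as.numeric(length(brute)))
  expect_equal(unname(h@counts), tabulate(brute + 1L, 9L) + 0)
  expect_equal(h@mean, mean(brute))
  # histogram mass equals focal observations; histogram mean consistency
  expect_equal(sum(h@counts), h@nFocal)
  expect_equal(sum(0:8 * h@counts) / sum(h@counts), h@mean)
})

test_that("neighbourhood edge cases: isolation and saturation", {
  occ <- matrix(OCC_CODES[["empty"]], 5, 5)
  occ[3, 3] <- OCC_CODES[["cancer"]]
  tr <- .handTraj(list(.snap(0, occ)))
  h <- neighbourhoodDistribution(tr, "cancer", "cancer", window = c(0, 0))
  expect_identical(unname(h@counts[1]), 1)
  expect_identical(h@mean, 0)
  full <- matrix(OCC_CODES[["cancer"]], 3, 3)
  tr2 <- .handTraj(list(.snap(0, full)))
  h2 <- neighbourhoodDistribution(tr2, "cancer", "cancer", window = c(0, 0))
  # the centre cell of a full 3 x 3 block has all 8 neighbours
  expect_identical(unname(h2@counts[9]), 1)
  expect_equal(h2@mean, mean(c(3, 5, 3, 5, 8, 5, 3, 5, 3)))
})

test_that("per-run mode averages replicate means with a standard error", {
  occ1 <- matrix(OCC_CODES[["empty"]], 3, 3)
  occ1[1, 1:2] <- OCC_CODES[["cancer"]] # two adjacent cells: mean 1
  occ2 <- matrix(OCC_CODES[["empty"]], 3, 3)
  occ2[c(1, 9)] <- OCC_CODES[["cancer"]] # two isolated cells: mean 0
  t1 <- .handTraj(list(.snap(0, occ1)))
  t2 <- .handTraj(list(.snap(0, occ2)))
  h <- neighbourhoodDistribution(list(t1, t2), "cancer", "cancer",
                                 window = c(0, 0), mode = "per_run")
  expect_equal(h@mean, 0.5)
  expect_equal(h@se, sd(c(1, 0)) / sqrt(2))
  expect_equal(h@nFocal, 4)
})

test_that("threshold highlights equal elementwise comparison", {
  f <- latticeField(matrix(0.95, 4, 4), "drug")
  expect_true(all(thresholdHighlight(f, 0.93, "ge")))
  expect_false(any(thresholdHighlight(latticeField(matrix(0, 4, 4), "drug"),
                                      0.93, "ge")))
  set.seed(23)
  m <- matrix(runif(16), 4, 4)
  expect_identical(thresholdHighlight(m, 0.5, "ge"), m >= 0.5)
  expect_identical(thresholdHighlight(m, 0.5, "lt"), m < 0.5)
  expect_identical(thresholdHighlight(m, 0.5, "ge") |
                     thresholdHighlight(m, 0.5, "lt"),
                   matrix(TRUE, 4, 4))
})

test_that("niche labelling partitions the domain by occupancy thresholds", {
  cOcc <- new("OccupancyMap", values = matrix(c(0.9, 0.9, 0, 0.6), 2, 2),
              cellClass = "cancer", window = c(0, 1), nSnapshots = 2L)
  aOcc <- new("OccupancyMap", values = matrix(c(0.7, 0.01, 0, 0.2), 2, 2),
              cellClass = "stroma_activated", window = c(0, 1),
              nSnapshots = 2L)
  nm <- classifyNiches(cOcc, aOcc)
  expect_identical(nm@labels[1, 1], "survival")
  expect_identical(nm@labels[2, 1], "persistence")
  expect_identical(nm@labels[1, 2], "eradication")
  expect_identical(nm@labels[2, 2], "survival")
  # exhaustive and exclusive
  expect_true(all(nm@labels %in% c("survival", "persistence",
                                   "eradication")))
  set.seed(29)
  cv <- matrix(runif(100), 10, 10)
  av <- matrix(runif(100), 10, 10)
  cO <- new("OccupancyMap", values = cv, cellClass = "cancer",
            window = c(0, 1), nSnapshots = 1L)
  aO <- new("OccupancyMap", values = av, cellClass = "stroma_activated",
            window = c(0, 1), nSnapshots = 1L)
  lab <- classifyNiches(cO, aO, thetaC = 0.4, thetaA = 0.3)@labels
  expect_identical(lab == "survival", cv >= 0.4 & av >= 0.3)
  expect_identical(lab == "persistence", cv >= 0.4 & av < 0.3)
})

test_that("mean field is the arithmetic site average", {
  expect_identical(meanField(matrix(0.37, 6, 6)), 0.37)
  expect_identical(meanField(matrix(c(0, 1), 4, 4)), 0.5)
  set.seed(33)
  m <- matrix(runif(64), 8, 8)
  expect_equal(meanField(latticeField(m, "drug")), sum(m) / 64)
})
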