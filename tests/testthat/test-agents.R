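test_that("viability classes follow the threshold boundary conventions", {
  expect_identical(classifyViability(0.19), "dead")
  expect_identical(classifyViability(0.5), "quiescent")
  expect_identical(classifyViability(0.8), "proliferative")
  # boundaries: p = hd is quiescent (death is strict), p = hp proliferative
  expect_identical(classifyViability(0.2), "quiescent")
  expect_identical(
    classifyViability(c(0, 0.1999, 0.7999, 1)),
    c("dead", "dead", "quiescent", "proliferative")
  )
  expect_error(classifyViability(0.5, hd = 0.9, hp = 0.8))
})

# a single cancer cell in the middle of an empty n x n grid
.lonelyCancer <- function(n = 7L, pLocal, imt = 1) {
  p <- tinyParams(n)
  occ <- matrix(OCC_CODES[["empty"]], n, n)
  mid <- ceiling(n / 2)
  occ[mid, mid] <- OCC_CODES[["cancer"]]
  clk <- matrix(0, n, n)
  im <- matrix(0, n, n)
  im[mid, mid] <- imt
  cells <- new("CellGrid", occupancy = occ,
               activated = matrix(FALSE, n, n), clock = clk, imt = im)
  sig <- latticeField(matrix(pLocal, n, n), "signal", dx = p@dxCm)
  list(cells = cells, signal = sig, params = p, mid = mid)
}

test_that("quiescent cancer freezes its clock; proliferative cancer divides at I", {
  f <- .lonelyCancer(pLocal = 0.5)
  cells <- f$cells
  for (i in 1:100) {
    out <- advanceCancer(cells, f$signal, f$params)
    cells <- out$cells
  }
  expect_identical(cells@clock[f$mid, f$mid], 0)
  expect_identical(sum(cellCounts(cells)["cancer"]), 1L)

  set.seed(21)
  f <- .lonelyCancer(pLocal = 1, imt = 1)
  cells <- f$cells
  sig <- f$signal
  dt <- f$params@dtDays
  steps <- 0L
  while (cellCounts(cells)["cancer"] < 2L) {
    out <- advanceCancer(cells, sig, f$params)
    cells <- out$cells
    sig <- out$signal
    steps <- steps + 1L
    expect_lt(steps, 1000)
  }
  expect_lt(abs(steps * dt - 1), 2 * dt) # first division at t = I +- dt
  # both daughters carry reset clocks and fresh I in [0.9, 1.1]
  idx <- which(cells@occupancy == OCC_CODES[["cancer"]])
  expect_identical(unname(cells@clock[idx]), c(0, 0))
  expect_true(all(cells@imt[idx] >= 0.9 & cells@imt[idx] <= 1.1))
})

test_that("cancer below the death threshold vacates its site", {
  f <- .lonelyCancer(pLocal = 0.19)
  out <- advanceCancer(f$cells, f$signal, f$params)
  expect_identical(out$cells@occupancy[f$mid, f$mid],
                   OCC_CODES[["empty"]])
  expect_identical(out$deaths, 1L)
  expect_identical(out$births, 0L)
})

test_that("cancer population bookkeeping balances births minus deaths", {
  set.seed(31)
  st <- makeFixture("cancer-block", n = 10L, params = tinyParams(10L))
  cells <- cellGrid(st)
  sig <- signalField(st)
  p <- modelParams(st)
  for (i in 1:600) {
    before <- cellCounts(cells)[["cancer"]]
    out <- advanceCancer(cells, sig, p)
    cells <- out$cells
    sig <- out$signal
    expect_identical(cellCounts(cells)[["cancer"]],
                     before + out$births - out$deaths)
  }
  expect_gt(cellCounts(cells)[["cancer"]], 9L) # the block grew
})

test_that("division rules: cancer ignores crowding, stroma obeys contact inhibition", {
  n <- 5L
  p <- tinyParams(n)
  occ <- matrix(OCC_CODES[["stroma_passive"]], n, n)
  occ[2, 2] <- OCC_CODES[["cancer"]]
  occ[1, 1] <- OCC_CODES[["empty"]] # single empty neighbour of (2,2)
  clk <- matrix(1.05, n, n)
  imt <- matrix(1, n, n)
  cells <- new("CellGrid", occupancy = occ,
               activated = matrix(FALSE, n, n), clock = pmin(clk, imt),
               imt = imt)
  sig <- latticeField(matrix(1, n, n), "signal", dx = p@dxCm)
  # cancer cell with 7 occupied neighbours divides into the one empty site
  set.seed(5)
  out <- attemptDivision(cells, sig, c(2, 2), p)
  expect_identical(out$outcome, "divided")
  expect_identical(unname(out$daughterSite), c(1L, 1L))
  expect_identical(out$cells@occupancy[1, 1], OCC_CODES[["cancer"]])
  # birth floor applied at both daughter sites (signal already 1: unchanged)
  expect_gte(fieldValues(out$signal)[1, 1], p@p0)
  # stroma cell with > nCI occupied neighbours aborts even with space
  occ2 <- matrix(OCC_CODES[["empty"]], n, n)
  occ2[3, 3] <- OCC_CODES[["stroma_passive"]]
  occ2[3, 4] <- OCC_CODES[["stroma_passive"]]
  occ2[4, 3] <- OCC_CODES[["stroma_passive"]]
  occ2[2, 3] <- OCC_CODES[["vessel"]] # vessels count as occupied
  clk2 <- matrix(0, n, n)
  imt2 <- matrix(0, n, n)
  clk2[occ2 == OCC_CODES[["stroma_passive"]]] <- 1
  imt2[occ2 == OCC_CODES[["stroma_passive"]]] <- 1
  cells2 <- new("CellGrid", occupancy = occ2,
                activated = matrix(FALSE, n, n), clock = clk2, imt = imt2)
  out2 <- attemptDivision(cells2, sig, c(3, 3), p)
  expect_identical(out2$outcome, "aborted")
  expect_identical(out2$cells@clock[3, 3], 0) # cycle consumed
  expect_true(out2$cells@imt[3, 3] >= 0.9 && out2$cells@imt[3, 3] <= 1.1)
  # fully enclosed cancer cell is blocked with the grid unchanged
  occ3 <- matrix(OCC_CODES[["stroma_passive"]], 3, 3)
  occ3[2, 2] <- OCC_CODES[["cancer"]]
  clk3 <- matrix(1, 3, 3)
  imt3 <- matrix(1, 3, 3)
  cells3 <- new("CellGrid", occupancy = occ3,
                activated = matrix(FALSE, 3, 3), clock = clk3, imt = imt3)
  sig3 <- latticeField(matrix(1, 3, 3), "signal", dx = p@dxCm)
  out3 <- attemptDivision(cells3, sig3, c(2, 2), p)
  expect_identical(out3$outcome, "blocked")
  expect_identical(out3$cells@occupancy, occ3)
  expect_identical(out3$cells@clock[2, 2], 1) # held at I, retried next step
  # programming error on empty / vessel sites
  expect_error(attemptDivision(cells2, sig, c(1, 1), p), "empty or vessel")
})

test_that("daughters inherit type and activation state", {
  n <- 5L
  p <- tinyParams(n)
  occ <- matrix(OCC_CODES[["empty"]], n, n)
  occ[3, 3] <- OCC_CODES[["stroma_reactive"]]
  act <- matrix(FALSE, n, n)
  act[3, 3] <- TRUE
  clk <- matrix(0, n, n)
  imt <- matrix(0, n, n)
  clk[3, 3] <- 1
  imt[3, 3] <- 1
  cells <- new("CellGrid", occupancy = occ, activated = act, clock = clk,
               imt = imt)
  sig <- latticeField(matrix(0, n, n), "signal", dx = p@dxCm)
  set.seed(9)
  out <- attemptDivision(cells, sig, c(3, 3), p)
  expect_identical(out$outcome, "divided")
  ds <- out$daughterSite
  expect_identical(out$cells@occupancy[ds[1], ds[2]],
                   OCC_CODES[["stroma_reactive"]])
  expect_true(out$cells@activated[ds[1], ds[2]])
})

test_that("stroma turnover matches the binomial expectation and pT = 0 is immortal", {
  p <- simParams(domainCm = 0.1) # 100 x 100 sheet, 10^4 sites
  st <- makeFixture("stroma-sheet", n = 100L,
                    params = simParams(domainCm = 0.1, piReactive = 0))
  cells <- cellGrid(st)
  set.seed(77)
  nSteps <- round(1 / p@dtDays) # one simulated day
  deaths <- 0L
  for (i in seq_len(nSteps)) {
    out <- advanceStroma(cells, p)
    cells <- out$cells
    deaths <- deaths + out$deaths
  }
  # full sheet: every interior cell has 8 occupied neighbours, so no births;
  # deaths ~ Binomial(n ~ 10^4 per step), expectation ~ pT * 1 day * 10^4
  expected <- p@pT * 1 * 100 * 100
  expect_lt(abs(deaths - expected), 3 * sqrt(expected) + 1)
  immortal <- makeFixture("stroma-sheet", n = 20L,
                          params = simParams(domainCm = 0.02,
                                             piReactive = 0, pT = 0))
  cells <- cellGrid(immortal)
  for (i in 1:300) cells <- advanceStroma(cells, modelParams(immortal))$cells
  expect_identical(cellCounts(cells)[["stroma_passive"]], 400L)
})

test_that("stroma activation requires both the drug and the contact gate", {
  n <- 5L
  # per-step activation probability forced to 1 to make the gate test exact
  p <- tinyParams(n, pA = 1 / (0.044 / 24))
  base <- matrix(OCC_CODES[["empty"]], n, n)
  base[3, 3] <- OCC_CODES[["stroma_reactive"]]
  mk <- function(withCancer) {
    occ <- base
    if (withCancer) occ[3, 4] <- OCC_CODES[["cancer"]]
    clk <- matrix(0, n, n)
    imt <- matrix(0, n, n)
    imt[occ != OCC_CODES[["empty"]]] <- 1
    new("CellGrid", occupancy = occ, activated = matrix(FALSE, n, n),
        clock = clk, imt = imt)
  }
  drugAt <- function(level) latticeField(matrix(level, n, n), "drug",
                                         dx = p@dxCm)
  set.seed(13)
  for (case in list(
    list(d = 0.95, cancer = TRUE, expected = TRUE),
    list(d = 0.95, cancer = FALSE, expected = FALSE),
    list(d = 0.90, cancer = TRUE, expected = FALSE),
    list(d = 0.90, cancer = FALSE, expected = FALSE)
  )) {
    out <- updateReactiveStates(mk(case$cancer), drugAt(case$d), p)
    expect_identical(out@activated[3, 3], case$expected)
  }
  # immediate deterministic deactivation when the drug falls below hr
  cells <- mk(TRUE)
  cells <- updateReactiveStates(cells, drugAt(0.95), p)
  expect_true(cells@activated[3, 3])
  cells <- updateReactiveStates(cells, drugAt(0.90), p)
  expect_false(cells@activated[3, 3])
  # passive stroma never activates
  occ <- base
  occ[3, 3] <- OCC_CODES[["stroma_passive"]]
  occ[3, 4] <- OCC_CODES[["cancer"]]
  imt <- matrix(0, n, n)
  imt[occ != OCC_CODES[["empty"]]] <- 1
  passive <- new("CellGrid", occupancy = occ,
                 activated = matrix(FALSE, n, n),
                 clock = matrix(0, n, n), imt = imt)
  out <- updateReactiveStates(passive, drugAt(0.99), p)
  expect_false(any(out@activated))
})

test_that("occupancy exclusivity and vessel permanence survive random stepping", {
  set.seed(55)
  p <- tinyParams(12L)
  st <- makeFixture("stroma-sheet", n = 12L, params = tinyParams(12L))
  occ <- occupancyMatrix(st)
  occ[6, 6] <- OCC_CODES[["vessel"]]
  occ[7, 7] <- OCC_CODES[["cancer"]]
  cg <- cellGrid(st)
  clk <- cg@clock
  imt <- cg@imt
  clk[6, 6] <- 0
  imt[6, 6] <- 0
  cells <- new("CellGrid", occupancy = occ, activated = cg@activated,
               clock = clk, imt = imt)
  vessels <- new("VesselSet", coordinates = cbind(6L, 6L),
                 domainDim = c(12L, 12L), dx = p@dxCm)
  state <- simState(cells, vessels, p,
                    signal = latticeField(matrix(0.9, 12, 12), "signal",
                                          dx = p@dxCm))
  sch <- treatmentSchedule("intermittent", 2, 1)
  for (i in 1:400) {
    state <- simStep(state, sch)
    expect_true(validObject(state, test = TRUE))
  }
  expect_identical(occupancyMatrix(state)[6, 6], OCC_CODES[["vessel"]])
})
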