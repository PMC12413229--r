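test_that("an intact impermeable inert coating is a perfect barrier", {
  lat <- makeToyLattice(15, 21, "coated")
  par <- quietParams(dis_mgf2 = 1, dis_mgo = 1, dis_mg = 1,
                     dis_product = 1, res_h2o = 2, res_cl = 1,
                     reservoir_rows = 1L)
  before <- componentCounts(lat)
  for (i in 1:25) lat <- caStep(lat, params = par)$lattice
  after <- componentCounts(lat)
  expect_equal(after[c("MG", "MGO", "MGF2", "POLY")],
               before[c("MG", "MGO", "MGF2", "POLY")])
  # water accumulated in the electrolyte but never crossed the coating
  expect_gt(sum(speciesCounts(lat, "H2O")), 0)
})

test_that("forced dissolution converts an exposed MG cell in one step", {
  lat <- makeToyLattice(4, 4, "single-interface")
  h2o <- speciesCounts(lat, "H2O")
  h2o[1, , 1] <- 2L
  lat <- methods::initialize(lat, h2o = h2o)
  out <- caStep(lat, params = quietParams(dis_mg = 1, res_h2o = 2,
                                          reservoir_rows = 1L))
  st <- latticeState(out$lattice)
  expect_true(all(st[2, , 1] == stentCA:::.COMPONENTS[["PRODUCT"]]))
  expect_equal(out$report$mg_product, 4)
  # deeper MG untouched (no electrolyte contact yet)
  expect_true(all(st[4, , 1] == stentCA:::.COMPONENTS[["MG"]]))
})

test_that("one-step dissolution frequency matches the binomial oracle", {
  base <- makeToyLattice(2, 2, "single-interface")
  st <- latticeState(base)
  st[2, , ] <- stentCA:::.COMPONENTS[["MGF2"]]
  h2o <- speciesCounts(base, "H2O")
  h2o[1, , 1] <- 1L
  base <- methods::initialize(base, state = st, h2o = h2o)
  par <- quietParams(dis_mgf2 = 0.2, res_h2o = 1, reservoir_rows = 1L)
  set.seed(42)
  n <- 1000
  hits <- vapply(seq_len(n), function(i) {
    out <- caStep(base, params = par)
    sum(latticeState(out$lattice)[2, , 1] == 0L)
  }, numeric(1))
  p <- 0.2
  ntot <- 2 * n
  se <- sqrt(p * (1 - p) / ntot)
  expect_lt(abs(mean(hits) / 2 - p), 3 * se)
})

test_that("one-step outcome distribution matches exhaustive enumeration", {
  lat <- threeByThree()  # walker at (1,2) over an MGF2 row over MG
  dis <- 0.5
  par <- quietParams(dis_mgf2 = dis)

  # independent oracle: enumerate the walker's four equiprobable moves and
  # the reaction coin for each fluoride cell adjacent to the walker
  positions <- list(c(1, 2), c(1, 2), c(1, 1), c(1, 3))  # up,down,left,right
  marg <- rep(0, 3)  # P(MGF2 cell (2,j) dissolves), j = 1..3
  for (pos in positions) {
    for (j in 1:3) {
      adjacent <- (pos[1] == 1 && abs(pos[2] - j) == 0)
      if (adjacent) marg[j] <- marg[j] + (1 / 4) * dis
    }
  }

  set.seed(99)
  n <- 10000
  cnt <- rep(0, 3)
  for (i in seq_len(n)) {
    out <- caStep(lat, params = par)
    cnt <- cnt + (latticeState(out$lattice)[2, , 1] == 0L)
  }
  for (j in 1:3) {
    se <- sqrt(marg[j] * (1 - marg[j]) / n)
    expect_lt(abs(cnt[j] / n - marg[j]), 3 * se)
  }
  # walker is conserved when nothing replenishes
  out <- caStep(lat, params = par)
  expect_equal(sum(speciesCounts(out$lattice, "H2O")), 1L)
})

test_that("every step conserves cells and uses only allowed transitions", {
  cfg <- smallScenario(steps = 60L, seed = 4L)
  run <- runSim(cfg, snapshot_every = 1L)
  total <- prod(dim(latticeState(run$lattice)))
  counts <- run$trace@counts
  for (t in seq_len(dim(counts)[3]))
    expect_equal(sum(counts[1, , t]), total)

  allowed <- list(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 5L, `5` = 0L)
  snaps <- c(list(latticeState(run$initial)), run$snapshots)
  for (k in seq_len(length(snaps) - 1)) {
    old <- as.vector(snaps[[k]]); new <- as.vector(snaps[[k + 1]])
    ch <- which(old != new)
    for (i in ch)
      expect_equal(new[i], allowed[[as.character(old[i])]])
  }
})

test_that("MG converts only with electrolyte or product contact", {
  cfg <- smallScenario(steps = 250L, seed = 11L)
  run <- runSim(cfg, snapshot_every = 1L)
  expect_gt(degradedFraction(run$trace, "MG")[251], 0)
  snaps <- c(list(latticeState(run$initial)), run$snapshots)
  d <- dim(snaps[[1]])
  for (k in seq_len(length(snaps) - 1)) {
    old <- snaps[[k]]; new <- snaps[[k + 1]]
    conv <- which(old == 4L & new == 5L, arr.ind = TRUE)
    for (i in seq_len(nrow(conv))) {
      r <- conv[i, 1]; c <- conv[i, 2]
      nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] &
               nb[, 2] >= 1 & nb[, 2] <= d[2], , drop = FALSE]
      states <- old[cbind(nb, 1L)]
      expect_true(any(states %in% c(0L, 5L)))
    }
  }
})

test_that("identical config and seed reproduce the run bit for bit", {
  cfg <- smallScenario(steps = 40L, seed = 8L)
  a <- runSim(cfg)
  b <- runSim(cfg)
  expect_identical(a$trace@counts, b$trace@counts)
  expect_identical(latticeState(a$lattice), latticeState(b$lattice))
  expect_identical(a$reports, b$reports)
  # a different seed diverges
  c2 <- runSim(smallScenario(steps = 40L, seed = 9L))
  expect_false(identical(a$trace@counts, c2$trace@counts))
})

test_that("zero-step runs record only the initial state", {
  run <- runSim(smallScenario(steps = 0L))
  expect_equal(dim(run$trace@counts)[3], 1L)
  expect_equal(degradedFraction(run$trace, "MG"), 0)
})

test_that("degraded fractions are monotone and bounded on real runs", {
  run <- runSim(smallScenario(steps = 120L, seed = 2L))
  for (cp in c("POLY", "MGF2", "MGO", "MG")) {
    f <- degradedFraction(run$trace, cp)
    expect_equal(f[1], 0)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
  }
})
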