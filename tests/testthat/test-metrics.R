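test_that("degradation rates reduce to finite differences of F", {
  tr <- randomTrace(steps = 40)
  # constant trace -> all-zero rates
  const <- tr
  for (t in 2:41) const@counts[, , t] <- const@counts[, , 1]
  r0 <- degradationRate(const, "MGF2", window = 10)
  expect_equal(r0$rate, rep(0, 4))

  # linear F -> constant rate equal to the per-window increment
  lin <- tr
  n0 <- 1000
  for (t in 1:41) lin@counts[1, 3, t] <- n0 * (1 - 0.001 * (t - 1))
  rl <- degradationRate(lin, "MGF2", window = 10)
  expect_equal(rl$rate, rep(0.01, 4), tolerance = 1e-12)

  # independent recount oracle on a random trace
  f <- degradedFraction(tr, "MG", "high_strain")
  r <- degradationRate(tr, "MG", "high_strain", window = 7)
  n <- componentCountSeries(tr, "MG", "high_strain")
  manual <- vapply(seq_len(nrow(r)), function(k) {
    t_end <- r$step[k] + 1L
    (n[t_end - 7L] - n[t_end]) / n[1]
  }, numeric(1))
  expect_equal(r$rate, manual)
  expect_true(all(r$rate >= 0))

  expect_error(degradationRate(tr, "MG", window = 0), "window")
  expect_error(degradationRate(tr, "XX"), "unknown component")
  expect_error(degradationRate(tr, "MG", "nowhere"), "unknown region")
})

test_that("initial rate averages the leading windows", {
  tr <- randomTrace(steps = 40, seed = 3)
  r <- degradationRate(tr, "POLY", window = 10)
  expect_equal(initialRate(tr, "POLY", window = 10, n_windows = 3),
               mean(r$rate[1:3]))
})

test_that("high-strain mask thresholds the surrogate at half peak", {
  lat <- makeToyLattice(15, 41, "coated")
  env <- strainEnvelope(strainSurrogate("compression", lat),
                        strainSurrogate("tension", lat))
  m <- highStrainMask(env, lat)
  expect_identical(m@mask[, , 1], abs(epsilon(env)) >= 0.15)
  # contiguous block of columns around the apex on each row
  sel <- which(m@mask[1, , 1])
  expect_identical(sel, seq(min(sel), max(sel)))

  # uniform field -> whole lattice
  d <- dim(latticeState(lat))
  uni <- new("StrainField", epsilon = matrix(0.2, d[1], d[2]),
             mode = "envelope", peakInner = 0.2, peakOuter = 0.2,
             width = 0.5)
  expect_true(all(highStrainMask(uni, lat)@mask))

  # above-eb with PBAT's elongation: nothing exceeds 533%
  expect_equal(sum(highStrainMask(env, lat, "above-eb", eb = 5.33)@mask), 0)
  # PDLLA's elongation: exactly the crack zone
  mm <- highStrainMask(env, lat, "above-eb", eb = 0.03)
  expect_identical(mm@mask[, , 1], abs(epsilon(env)) > 0.03)

  # zero field raises the explicit empty-mask condition
  expect_error(highStrainMask(zeroStrain(lat), lat), class = "emptyMask")
})

test_that("onset detection finds the first threshold crossing", {
  expect_true(is.na(detectOnset(rep(0, 10))))
  s <- c(rep(0, 5), 0.5, 0.6)
  expect_equal(detectOnset(s, 0.01), 5)
  expect_error(detectOnset(s, 0), "threshold")
  # monotone in the threshold over random monotone series
  set.seed(5)
  for (i in 1:20) {
    f <- cumsum(runif(50, 0, 0.01))
    o1 <- detectOnset(f, 0.01); o5 <- detectOnset(f, 0.05)
    if (!is.na(o1) && !is.na(o5)) expect_lte(o1, o5)
  }
})

test_that("stabilization detection finds rate plateaus", {
  expect_equal(detectStabilization(rep(0.02, 10), tol = 1e-3), 2L)
  osc <- rep(c(0.1, 0.2), 10)
  expect_true(is.na(detectStabilization(osc, tol = 0.05)))
  # decaying series with a known plateau start
  r <- c(0.5, 0.3, 0.15, 0.05, 0.011, 0.0105, 0.0102, 0.0101, 0.01)
  got <- detectStabilization(r, tol = 0.002)
  expect_true(got >= 5 && got <= 6)
  # data.frame input returns the step value
  df <- data.frame(step = seq(100, 900, by = 100), rate = r)
  expect_equal(detectStabilization(df, tol = 0.002), df$step[got])
})

test_that("region fractions agree with recounts from snapshots", {
  cfg <- smallScenario(steps = 60L, seed = 6L)
  run <- runSim(cfg, snapshot_every = 20L)
  msk <- run$masks$crack_site@mask
  f <- degradedFraction(run$trace, "MGF2", "crack_site")
  n0 <- componentCountSeries(run$trace, "MGF2", "crack_site")[1]
  for (k in seq_along(run$snapshots)) {
    t <- run$snapshotSteps[k]
    recount <- sum(run$snapshots[[k]][msk] == 2L)
    expect_equal(f[t + 1L], 1 - recount / n0)
  }
})

test_that("calibration handles empty, feasible and impossible anchor sets", {
  search <- list("MGF2.dissolution_prob" = c(0.01, 0.4))
  # empty anchors: midpoints, flagged unconstrained
  out0 <- calibrateDefaults(anchors = list(), search = search)
  expect_equal(out0$status, "unconstrained")
  expect_equal(unname(out0$params), 0.205)

  fastFactory <- function(scenario, steps, seed, materials, geometry)
    makeScenario(scenario, steps = steps, seed = seed, materials = materials,
                 geometry = utils::modifyList(smallGeometry(reservoirRows = 5L),
                                              geometry))
  # feasible: crack-site fluoride onset inside a wide band
  anchorA <- list(list(
    id = "crack_mgf2_onset", scenario = "PDLLA-deformed", steps = 80L,
    range = c(1, 80),
    stat = function(runs) stats::median(vapply(runs, function(r)
      as.numeric(detectOnset(
        degradedFraction(r$trace, "MGF2", "crack_site"), 0.05)),
      numeric(1)))))
  outA <- calibrateDefaults(anchorA, search, seeds = 1:2,
                            cfgFactory = fastFactory, gridPoints = 3,
                            maxIter = 1)
  expect_equal(outA$status, "met")
  expect_true(outA$report$ok)

  # impossible: onset below 2 and above 1000 simultaneously
  anchorB <- list(
    anchorA[[1]],
    list(id = "impossible", scenario = "PDLLA-deformed", steps = 80L,
         range = c(1000, 2000), stat = anchorA[[1]]$stat))
  outB <- calibrateDefaults(anchorB, search, seeds = 1:2,
                            cfgFactory = fastFactory, gridPoints = 3,
                            maxIter = 1)
  expect_equal(outB$status, "failed")
  expect_false(all(outB$report$ok))
})
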