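test_that("preset catalogue builds valid configs and rejects unknowns", {
  expect_setequal(listScenarios(),
                  c("PDLLA-deformed", "PBAT-deformed", "PDLLA-undeformed",
                    "PBAT-undeformed", "bare", "F-only"))
  for (nm in listScenarios()) {
    cfg <- makeScenario(nm, steps = 10)
    expect_s4_class(cfg, "SimConfig")
    expect_true(methods::validObject(cfg))
  }
  expect_error(makeScenario("PLGA-deformed"), "available")
})

test_that("deformed presets carry the crimp-expansion peaks, undeformed none", {
  cfg <- makeScenario("PDLLA-deformed", steps = 1)
  expect_true(cfg@strain$deformed)
  expect_equal(cfg@strain$compression$peakInner, 0.30)
  expect_equal(cfg@strain$compression$peakOuter, 0.25)
  expect_equal(cfg@strain$tension$peakInner, 0.20)
  expect_equal(cfg@strain$tension$peakOuter, 0.15)
  expect_false(makeScenario("PBAT-undeformed", steps = 1)@strain$deformed)
})

test_that("crack outcomes split the two coatings at the paper strains", {
  pb <- runSim(smallScenario("PBAT-deformed", steps = 0L))
  expect_false(any(crackedColumns(pb$damage)))
  pd <- runSim(smallScenario("PDLLA-deformed", steps = 0L))
  crk <- crackedColumns(pd$damage)
  expect_true(any(crk))
  eps <- abs(epsilon(pd$field))
  rows_in <- stentCA:::.polymerRows(pd$initial, "inner")
  expect_identical(unname(crk["inner", ]),
                   unname(eps[rows_in[1], ] > 0.03))
})

test_that("bare and F-only stacks drop the right layers", {
  bare <- runSim(smallScenario("bare", steps = 0L,
                               geometry = list(mgf2Um = 0)))
  cc <- componentCounts(bare$initial)
  expect_equal(unname(cc["POLY"]), 0L)
  expect_equal(unname(cc["MGF2"]), 0L)
  expect_gt(cc["MGO"], 0)  # native oxide remains
  fonly <- runSim(smallScenario("F-only", steps = 0L))
  cf <- componentCounts(fonly$initial)
  expect_equal(unname(cf["POLY"]), 0L)
  expect_gt(cf["MGF2"], 0)
})

test_that("presets round-trip through config serialization unchanged", {
  for (nm in c("PDLLA-deformed", "PBAT-undeformed", "bare")) {
    cfg <- makeScenario(nm, steps = 25, seed = 42)
    path <- withr::local_tempfile(fileext = ".yaml")
    writeConfig(cfg, path)
    back <- readConfig(path)
    expect_equal(back@scenario, cfg@scenario)
    expect_equal(back@steps, cfg@steps)
    expect_equal(back@seed, cfg@seed)
    expect_equal(back@geometry, cfg@geometry)
    expect_equal(back@strain, cfg@strain)
    expect_equal(back@engine, cfg@engine)
    expect_equal(back@materials, cfg@materials)
  }
})

test_that("toy lattices are deterministic and match their patterns", {
  a <- makeToyLattice(5, 5, "single-interface")
  b <- makeToyLattice(5, 5, "single-interface")
  expect_identical(latticeState(a), latticeState(b))
  st <- latticeState(a)[, , 1]
  expect_true(all(st[1, ] == 0L))
  expect_true(all(st[2:5, ] == 4L))
  expect_equal(a@reservoirRows, 1L)

  cb <- latticeState(makeToyLattice(4, 4, "checkerboard"))[, , 1]
  expect_equal(sum(cb == 0L), 8)
  expect_true(all(cb[cbind(1:3, 2:4)] != cb[cbind(1:3, 1:3)]))

  ch <- makeToyLattice(8, 7, "crack-channel")
  st <- latticeState(ch)[, , 1]
  expect_true(all(st[2:4, 4] == 0L))         # open channel column
  expect_true(all(st[2:4, c(1:3, 5:7)] == 1L))
  expect_true(all(st[5, ] == 2L))

  expect_error(makeToyLattice(1, 5), "rows and cols")
  expect_error(makeToyLattice(5, 5, "crack-channel"), ">= 7 rows")
})
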