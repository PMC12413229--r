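test_that("porosity law evaluates exactly and respects its domain", {
  expect_equal(porosity(0, 0.5), 50)
  expect_equal(porosity(1, 0.5), 75)
  for (e in c(0, 0.3, 2)) expect_equal(porosity(e, 1), 0)
  # strictly increasing in strain for K < 1, continuous near K -> 1
  eps <- seq(0, 2, by = 0.05)
  p <- porosity(eps, 0.85)
  expect_true(all(diff(p) > 0))
  expect_lt(max(porosity(eps, 1 - 1e-9)), 1e-6)
  expect_error(porosity(0.1, 0), "K must")
  expect_error(porosity(0.1, 1.2), "K must")
  expect_error(porosity(-0.1, 0.5), "eps must")
})

test_that("cracks form exactly where strain exceeds elongation at break", {
  lat <- makeToyLattice(15, 41, "coated")
  env <- strainEnvelope(strainSurrogate("compression", lat),
                        strainSurrogate("tension", lat))
  mat <- defaultMaterials()
  # PDLLA: eb = 0.03 far below the 0.30/0.25 peaks -> through-cracks
  for (seed in c(1, 99)) {
    dmg <- applyDamage(lat, env, mat["PDLLA", ], rng_seed = seed)
    crk <- crackedColumns(dmg$damage)
    rows_in <- stentCA:::.polymerRows(lat, "inner")
    eff_in <- abs(epsilon(env)[rows_in[1], ])
    expect_identical(unname(crk["inner", ]), unname(eff_in > 0.03))
    rows_out <- stentCA:::.polymerRows(lat, "outer")
    eff_out <- abs(epsilon(env)[rows_out[1], ])
    expect_identical(unname(crk["outer", ]), unname(eff_out > 0.03))
    # cracked columns are fully opened through the band
    st <- latticeState(dmg$lattice)
    for (j in which(crk["inner", ]))
      expect_true(all(st[rows_in, j, 1] == 0L))
  }
  # PBAT: eb = 5.33 above every strain -> no cracks anywhere
  dmgB <- applyDamage(lat, env, mat["PBAT", ], rng_seed = 1)
  expect_false(any(crackedColumns(dmgB$damage)))
})

test_that("PDLLA porosity profile dominates PBAT under equal strain", {
  lat <- makeToyLattice(15, 41, "coated")
  env <- strainEnvelope(strainSurrogate("compression", lat),
                        strainSurrogate("tension", lat))
  mat <- defaultMaterials()
  pd <- applyDamage(lat, env, mat["PDLLA", ], 1)$damage
  pb <- applyDamage(lat, env, mat["PBAT", ], 1)$damage
  for (side in c("inner", "outer")) {
    prof_d <- porosityProfile(pd, side)
    prof_b <- porosityProfile(pb, side)
    expect_true(all(prof_d$porosity >= prof_b$porosity))
  }
  # unimodal: porosity peaks at the apex column
  prof <- porosityProfile(pd, "inner")
  expect_equal(which.max(prof$porosity), which.min(abs(prof$s - 0.5)))
})

test_that("zero strain with K = 1 leaves the lattice exactly unchanged", {
  lat <- makeToyLattice(15, 21, "coated")
  mat <- defaultMaterials()["PBAT", ]
  mat$porosity_K <- 1
  dmg <- applyDamage(lat, zeroStrain(lat), mat, rng_seed = 3)
  expect_identical(latticeState(dmg$lattice), latticeState(lat))
  expect_equal(max(dmg$damage@porosity), 0)
})

test_that("realized pore counts match the binomial expectation", {
  # uniform strain so every polymer cell shares one pore probability;
  # oracle: total pores over many seeds ~ Binomial(n_seeds * n_cells, P/100)
  lat <- makeToyLattice(13, 12, "coated")
  K <- 0.7; eps_u <- 0.4
  mat <- defaultMaterials()["PBAT", ]   # no cracks at eps 0.4
  mat$porosity_K <- K
  d <- dim(latticeState(lat))
  field <- new("StrainField",
               epsilon = matrix(eps_u, d[1], d[2]), mode = "envelope",
               peakInner = eps_u, peakOuter = eps_u, width = 0.5)
  n_poly <- sum(componentCounts(lat)["POLY"])
  p <- porosity(eps_u, K) / 100
  nseeds <- 1000
  pores <- vapply(seq_len(nseeds), function(s) {
    dl <- applyDamage(lat, field, mat, rng_seed = s)$lattice
    n_poly - unname(componentCounts(dl)["POLY"])
  }, numeric(1))
  n_tot <- nseeds * n_poly
  se <- sqrt(n_tot * p * (1 - p))
  expect_lt(abs(sum(pores) - n_tot * p), 3 * se)
})

test_that("damage map exports a tidy per-column table", {
  lat <- makeToyLattice(15, 21, "coated")
  env <- strainEnvelope(strainSurrogate("compression", lat),
                        strainSurrogate("tension", lat))
  dm <- applyDamage(lat, env, defaultMaterials()["PDLLA", ], 1)$damage
  path <- withr::local_tempfile(fileext = ".csv")
  writeDamageMap(dm, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 2 * 21)
  expect_named(tab, c("side", "s", "porosity", "cracked"))
})
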