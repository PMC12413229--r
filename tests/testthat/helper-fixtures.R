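# Reduced geometry for fast runs: same layer stack, shorter arc, shallower
# electrolyte band and thinner core than the full-size strut.
smallGeometry <- function(...) {
  utils::modifyList(
    list(arcLengthCells = 60L, elecRows = 6L, reservoirRows = 3L,
         strutUm = 5, polymerUm = 2, mgf2Um = 1, mgoUm = 0.5),
    list(...))
}

smallScenario <- function(name = "PDLLA-deformed", steps = 50L, seed = 1L,
                          geometry = list(), ...) {
  makeScenario(name, steps = steps, seed = seed,
               geometry = utils::modifyList(smallGeometry(), geometry), ...)
}

# Hand-built monotone-decreasing trace for metric oracles: random retained
# counts per component/region, never increasing.
randomTrace <- function(steps = 40L, regions = c("overall", "high_strain"),
                        seed = 7L) {
  set.seed(seed)
  comps <- componentLabels()
  counts <- array(0, dim = c(length(regions), length(comps), steps + 1L))
  for (ri in seq_along(regions)) for (ci in seq_along(comps)) {
    n0 <- sample(50:200, 1)
    losses <- sample(0:3, steps, replace = TRUE)
    counts[ri, ci, ] <- n0 - cumsum(c(0, losses))
    counts[ri, ci, ] <- pmax(counts[ri, ci, ], 0)
    counts[ri, ci, ] <- cummin(counts[ri, ci, ])
  }
  new("DegradationTrace", counts = counts, regions = regions,
      steps = as.integer(steps))
}

# A 3x3 one-walker fixture with a known exact one-step outcome
# distribution (enumerated in the engine tests): electrolyte row with one
# water walker over a fluoride row over magnesium.
threeByThree <- function() {
  lat <- makeToyLattice(3, 3, "single-interface")
  st <- latticeState(lat)
  st[2, , ] <- stentCA:::.COMPONENTS[["MGF2"]]
  h2o <- array(0L, dim(st))
  h2o[1, 2, 1] <- 1L
  initialize(lat, state = st, h2o = h2o)
}

# Kernel parameter list with everything off except explicit overrides.
quietParams <- function(...) {
  utils::modifyList(
    list(perm_poly = 0, hyd_poly = 0, dis_mgf2 = 0, boost_mgf2 = 1,
         dis_mgo = 0, boost_mgo = 1, dis_mg = 0, shielding = 1,
         dis_product = 0, res_h2o = 0, res_cl = 0, res_h = 0,
         reservoir_rows = 0L, moore = FALSE),
    list(...))
}
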