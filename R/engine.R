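.defaultGeometry <- function() {
  list(polymer = "PDLLA", polymerUm = 4, mgf2Um = 1, mgoUm = 0.5,
       strutUm = 30, arcLengthCells = 600L, cellSizeUm = 0.5,
       elecRows = 29L, reservoirRows = 11L, depth = 1L)
}

.defaultStrain <- function(deformed = TRUE) {
  list(deformed = deformed,
       compression = list(peakInner = 0.30, peakOuter = 0.25),
       tension = list(peakInner = 0.20, peakOuter = 0.15),
       width = 0.15)
}

.defaultEngine <- function() {
  list(resH2O = 2, resCL = 1, resH = 0.2, neighborhood = "vonNeumann",
       shielding = 0.2, rateWindow = 100L, snapshotEvery = 0L)
}

#' Assemble a run configuration
#'
#' Builds a validated [SimConfig-class] from parameter blocks, filling every
#' omitted field with the packaged default. Prefer [makeScenario()] for the
#' named presets.
#'
#' @param scenario free-text label.
#' @param steps number of CA steps (>= 0).
#' @param seed master seed; internally spawns one stream for the damage
#'   realization and one for the CA evolution.
#' @param geometry,strain,engine named lists overriding individual defaults
#'   (see [SimConfig-class] for the fields).
#' @param materials material table, defaults to [defaultMaterials()].
#' @return a [SimConfig-class].
#' @export
simConfig <- function(scenario = "custom", steps = 4000L, seed = 1L,
                      geometry = list(), strain = list(), engine = list(),
                      materials = defaultMaterials()) {
  geo <- utils::modifyList(.defaultGeometry(), geometry)
  str <- utils::modifyList(.defaultStrain(), strain)
  eng <- utils::modifyList(.defaultEngine(), engine)
  bad <- validateMaterials(materials)
  if (length(bad)) stop("invalid materials: ", paste(bad, collapse = "; "))
  cfg <- new("SimConfig", scenario = scenario, steps = as.integer(steps),
             seed = as.integer(seed), geometry = geo, materials = materials,
             strain = str, engine = eng)
  validObject(cfg)
  cfg
}

## Layer stack implied by a geometry block (outside inward, excluding the
## Mg core). A NULL/"none" polymer drops the organic layer; mgf2Um/mgoUm of
## 0 drop the conversion films (bare-substrate scenarios).
.cfgLayers <- function(geo) {
  lay <- NULL
  add <- function(lay, material, um)
    if (!is.null(um) && um > 0) rbind(lay, layerSpec(material, um)) else lay
  if (!is.null(geo$polymer) && !identical(geo$polymer, "none"))
    lay <- add(lay, geo$polymer, geo$polymerUm)
  lay <- add(lay, "MGF2", geo$mgf2Um)
  lay <- add(lay, "MGO", geo$mgoUm)
  lay
}

.cfgLattice <- function(cfg) {
  geo <- cfg@geometry
  buildLattice(.cfgLayers(geo), strut_thickness_um = geo$strutUm,
               arc_length_cells = geo$arcLengthCells,
               cell_size_um = geo$cellSizeUm, elec_rows = geo$elecRows,
               reservoir_rows = geo$reservoirRows, depth = geo$depth)
}

.cfgStrainField <- function(cfg, lattice) {
  st <- cfg@strain
  if (!isTRUE(st$deformed)) return(zeroStrain(lattice))
  comp <- strainSurrogate("compression", lattice,
                          peak_inner = st$compression$peakInner,
                          peak_outer = st$compression$peakOuter,
                          width = st$width)
  tens <- strainSurrogate("tension", lattice,
                          peak_inner = st$tension$peakInner,
                          peak_outer = st$tension$peakOuter,
                          width = st$width)
  strainEnvelope(comp, tens)
}

## Kernel parameter list consumed by the C++ step.
.engineParams <- function(cfg, lattice) {
  mat <- cfg@materials
  eng <- cfg@engine
  poly <- cfg@geometry$polymer
  has_poly <- !is.null(poly) && !identical(poly, "none")
  list(perm_poly = if (has_poly) mat[poly, "permeation_prob"] else 0,
       hyd_poly = if (has_poly) mat[poly, "hydrolysis_prob"] else 0,
       dis_mgf2 = mat["MGF2", "dissolution_prob"],
       boost_mgf2 = mat["MGF2", "acid_boost"],
       dis_mgo = mat["MGO", "dissolution_prob"],
       boost_mgo = mat["MGO", "acid_boost"],
       dis_mg = mat["MG", "dissolution_prob"],
       shielding = eng$shielding,
       dis_product = mat["PRODUCT", "dissolution_prob"],
       res_h2o = eng$resH2O, res_cl = eng$resCL, res_h = eng$resH,
       reservoir_rows = lattice@reservoirRows,
       moore = identical(eng$neighborhood, "Moore"))
}

#' Advance the automaton by one step
#'
#' One synchronous two-phase update: (1) transport, where every walker
#' attempts a uniform random neighbor move (into electrolyte freely, into
#' intact polymer with the permeation probability, never into other
#' solids) and the reservoir rows are then reset to the bulk
#' concentrations; (2) reactions, evaluated against a frozen copy of the
#' post-transport state: polymer hydrolysis under water contact, fluoride
#' and oxide dissolution at water-bearing electrolyte (accelerated when a
#' proton is adjacent), magnesium conversion to hydroxide product (at the
#' shielded rate when its only contact is through product), and chloride
#' attack on the product. Each cell changes at most once per step.
#'
#' @param lattice a [StentLattice-class].
#' @param materials material table.
#' @param polymer which polymer the POLY cells are made of (\code{"none"}
#'   for bare lattices).
#' @param engine engine option overrides (see [simConfig()]).
#' @param params full kernel parameter override (advanced; as returned by
#'   the internal parameter builder) -- used by the enumeration oracle
#'   tests.
#' @return list with the updated \code{lattice} and a one-row \code{report}
#'   data.frame of event and walker counts.
#' @export
caStep <- function(lattice, materials = defaultMaterials(),
                   polymer = "PDLLA", engine = list(), params = NULL) {
  stopifnot(is(lattice, "StentLattice"))
  if (is.null(params)) {
    cfg <- simConfig(steps = 1L, engine = engine,
                     geometry = list(polymer = polymer),
                     materials = materials)
    params <- .engineParams(cfg, lattice)
  }
  d <- dim(lattice@state)
  out <- ca_step_cpp(lattice@state, lattice@h2o, lattice@cl, lattice@h,
                     d[1], d[2], d[3], params)
  lat <- initialize(lattice, state = out$state, h2o = out$h2o,
                    cl = out$cl, h = out$h)
  rep <- data.frame(hydrolysis = out$events[1], mgf2 = out$events[2],
                    mgo = out$events[3], mg_product = out$events[4],
                    product = out$events[5], h2o = out$walkers[1],
                    cl = out$walkers[2], h = out$walkers[3])
  list(lattice = lat, report = rep)
}

#' Run a full simulation
#'
#' Builds the lattice, strain field and deformation damage prescribed by
#' the configuration, then iterates the automaton for \code{cfg@steps}
#' steps, recording per-component cell counts every step for the whole
#' lattice and for the high-strain and crack-site regions. Fully
#' reproducible: the master seed spawns one stream for the damage
#' realization and one for the evolution, so identical configurations give
#' bit-identical traces.
#'
#' @param cfg a [SimConfig-class].
#' @param snapshot_every record a state snapshot every this many steps
#'   (0 = none; final state is always returned).
#' @return object of class \code{"SimRun"}: a list with elements
#'   \code{trace} ([DegradationTrace-class]), \code{lattice} (final state),
#'   \code{initial} (damaged initial lattice), \code{damage}
#'   ([DamageMap-class] or NULL), \code{field} (envelope strain),
#'   \code{masks} (named list of [RegionMask-class]), \code{reports}
#'   (per-step event/walker data.frame), \code{snapshots},
#'   \code{snapshotSteps} and \code{config}.
#' @export
#' @examples
#' cfg <- makeScenario("PDLLA-deformed", steps = 5, seed = 1,
#'                     geometry = list(arcLengthCells = 60, elecRows = 4,
#'                                     reservoirRows = 2, strutUm = 5))
#' run <- runSim(cfg)
#' degradedFraction(run$trace, "MGF2")
runSim <- function(cfg, snapshot_every = cfg@engine$snapshotEvery) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  streams <- sample.int(.Machine$integer.max, 2)
  lattice <- .cfgLattice(cfg)
  field <- .cfgStrainField(cfg, lattice)

  poly <- cfg@geometry$polymer
  damage <- NULL
  if (!is.null(poly) && !identical(poly, "none")) {
    dmg <- applyDamage(lattice, field, cfg@materials[poly, ],
                       rng_seed = streams[1])
    lattice <- dmg$lattice
    damage <- dmg$damage
  }

  masks <- list(overall = new("RegionMask", name = "overall",
                              mask = array(TRUE, dim(lattice@state))))
  hs <- tryCatch(highStrainMask(field, lattice), emptyMask = function(e) NULL)
  if (!is.null(hs) && sum(hs@mask) > 0) masks$high_strain <- hs
  if (!is.null(damage) && any(damage@cracked))
    masks$crack_site <- crackSiteMask(damage, lattice)

  d <- dim(lattice@state)
  set.seed(streams[2])
  out <- ca_run_cpp(lattice@state, lattice@h2o, lattice@cl, lattice@h,
                    d[1], d[2], d[3], cfg@steps,
                    .engineParams(cfg, lattice),
                    lapply(masks, function(m) as.vector(m@mask)),
                    as.integer(snapshot_every))

  trace <- new("DegradationTrace", counts = out$counts,
               regions = names(masks), steps = cfg@steps)
  final <- initialize(lattice, state = out$state, h2o = out$h2o,
                      cl = out$cl, h = out$h)
  reports <- as.data.frame(out$reports)
  colnames(reports) <- c("hydrolysis", "mgf2", "mgo", "mg_product",
                         "product", "h2o", "cl", "h")
  structure(list(trace = trace, lattice = final, initial = lattice,
                 damage = damage, field = field, masks = masks,
                 reports = reports, snapshots = out$snapshots,
                 snapshotSteps = out$snapshot_steps, config = cfg,
                 streams = streams),
            class = "SimRun")
}

#' @export
print.SimRun <- function(x, ...) {
  cat(sprintf("SimRun '%s': %d steps, seed %d\n", x$config@scenario,
              x$config@steps, x$config@seed))
  show(x$trace)
  invisible(x)
}
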