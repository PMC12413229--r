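#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib stentCA, .registration = TRUE
NULL

## Integer component codes shared with the C++ kernel. ELEC covers both the
## bulk electrolyte and any pore/dissolved site.
.COMPONENTS <- c(ELEC = 0L, POLY = 1L, MGF2 = 2L, MGO = 3L, MG = 4L,
                 PRODUCT = 5L)
.SPECIES <- c("H2O", "CL", "H")

#' Component labels used on the lattice
#'
#' The six cell states of the corrosion automaton: electrolyte/pore
#' (\code{ELEC}), polymer coating (\code{POLY}), fluoride conversion layer
#' (\code{MGF2}), native oxide (\code{MGO}), magnesium substrate (\code{MG})
#' and hydroxide corrosion product (\code{PRODUCT}).
#'
#' @return Character vector of component labels.
#' @export
#' @examples
#' componentLabels()
componentLabels <- function() names(.COMPONENTS)

#' Layered strut lattice
#'
#' Discrete cross-section of a coated stent strut, unrolled along the arc of
#' the sine-wave unit. Rows run through the thickness (row 1 = outer
#' electrolyte boundary), columns along the arc, and an optional third
#' dimension is a thin extrusion used for voxel renders. Each cell carries
#' exactly one component label plus non-negative counts of mobile walkers
#' (water, chloride, protons).
#'
#' @slot state integer array (rows x cols x depth) of component codes.
#' @slot h2o,cl,h integer arrays of walker counts per cell.
#' @slot cellSizeUm edge length of one cell in micrometres.
#' @slot arcCoord normalized arclength position per column, in [0, 1] with
#'   the arc apex at 0.5.
#' @slot side character vector per row, \code{"outer"} or \code{"inner"},
#'   tagging which face of the strut a row belongs to.
#' @slot reservoirRows number of replenished electrolyte rows at each face.
#' @slot layers data.frame echo of the layer specification used to build
#'   the lattice.
#' @export
setClass("StentLattice",
  representation(state = "array", h2o = "array", cl = "array", h = "array",
                 cellSizeUm = "numeric", arcCoord = "numeric",
                 side = "character", reservoirRows = "integer",
                 layers = "data.frame"))

setValidity("StentLattice", function(object) {
  msg <- character()
  d <- dim(object@state)
  if (length(d) != 3) msg <- c(msg, "state must be a 3-d array")
  for (s in c("h2o", "cl", "h")) {
    sp <- slot(object, s)
    if (!identical(dim(sp), d))
      msg <- c(msg, sprintf("%s dimensions differ from state", s))
    else if (any(sp < 0)) msg <- c(msg, sprintf("%s has negative counts", s))
  }
  if (!all(object@state %in% .COMPONENTS))
    msg <- c(msg, "state contains unknown component codes")
  if (length(object@arcCoord) != d[2])
    msg <- c(msg, "arcCoord length must equal column count")
  if (length(object@side) != d[1])
    msg <- c(msg, "side length must equal row count")
  if (length(object@cellSizeUm) != 1 || object@cellSizeUm <= 0)
    msg <- c(msg, "cellSizeUm must be a single positive number")
  ## walkers may only sit on electrolyte or (transiently) polymer cells
  solid <- !(object@state %in% c(.COMPONENTS[["ELEC"]], .COMPONENTS[["POLY"]]))
  if (any((object@h2o + object@cl + object@h)[solid] > 0))
    msg <- c(msg, "walkers found inside inorganic cells")
  if (length(msg)) msg else TRUE
})

#' Strain field over a strut lattice
#'
#' Per-cell signed strain (as a fraction) from the crimp-expansion
#' deformation surrogate. \code{mode} records whether the field is the
#' compression phase, the tension phase, or the per-cell magnitude envelope
#' of the two.
#'
#' @slot epsilon numeric matrix (rows x cols) of signed strain fractions.
#' @slot mode one of \code{"compression"}, \code{"tension"},
#'   \code{"envelope"}.
#' @slot peakInner,peakOuter apex peak strain magnitude on each face.
#' @slot width half-support of the raised-cosine profile as a fraction of
#'   arclength.
#' @export
setClass("StrainField",
  representation(epsilon = "matrix", mode = "character",
                 peakInner = "numeric", peakOuter = "numeric",
                 width = "numeric"))

setValidity("StrainField", function(object) {
  msg <- character()
  if (!object@mode %in% c("compression", "tension", "envelope"))
    msg <- c(msg, "mode must be compression, tension or envelope")
  pk <- max(object@peakInner, object@peakOuter)
  if (any(abs(object@epsilon) > pk + 1e-12))
    msg <- c(msg, "|epsilon| exceeds the declared peak strain")
  if (length(msg)) msg else TRUE
})

#' Deformation damage map of the polymer coating
#'
#' Per-column, per-face record of the strain-induced coating porosity and
#' of through-thickness cracks, produced by [applyDamage()]. Cracking is
#' deterministic (strain exceeding the elongation at break); porosity is
#' realized stochastically on the lattice but recorded here as the exact
#' percentage from the strain-porosity law.
#'
#' @slot arcCoord arclength position per column.
#' @slot porosity numeric matrix 2 x cols (rows \code{"outer"},
#'   \code{"inner"}), porosity percent in [0, 100).
#' @slot cracked logical matrix 2 x cols, through-crack flags.
#' @slot KUsed porosity constant used.
#' @slot ebUsed elongation at break (fraction) used for the crack test.
#' @export
setClass("DamageMap",
  representation(arcCoord = "numeric", porosity = "matrix",
                 cracked = "matrix", KUsed = "numeric", ebUsed = "numeric"))

setValidity("DamageMap", function(object) {
  msg <- character()
  if (!identical(rownames(object@porosity), c("outer", "inner")))
    msg <- c(msg, "porosity must have rows outer, inner")
  if (any(object@porosity < 0) || any(object@porosity >= 100))
    msg <- c(msg, "porosity must lie in [0, 100)")
  if (!identical(dim(object@porosity), dim(object@cracked)))
    msg <- c(msg, "porosity and cracked dimensions differ")
  if (length(msg)) msg else TRUE
})

#' Named cell region of a lattice
#'
#' @slot name region label, e.g. \code{"high_strain"} or \code{"crack_site"}.
#' @slot mask logical array matching the lattice dimensions.
#' @export
setClass("RegionMask",
  representation(name = "character", mask = "array"))

#' Per-component degradation time series
#'
#' For every component, region and step, the retained cell counts from which
#' degraded fractions are derived. The degraded fraction of component c at
#' step t is \eqn{F_c(t) = 1 - N_c(t)/N_c(0)}; for the magnesium substrate
#' this counts both product and dissolved outcomes as degraded because MG
#' only ever leaves through them.
#'
#' @slot counts numeric array (region x component x step+1) of cell counts.
#' @slot regions character vector of region names (first is
#'   \code{"overall"}).
#' @slot steps number of CA steps recorded (array has steps + 1 planes).
#' @export
setClass("DegradationTrace",
  representation(counts = "array", regions = "character", steps = "integer"))

setValidity("DegradationTrace", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3 || d[2] != length(.COMPONENTS))
    msg <- c(msg, "counts must be region x component x step array")
  if (d[1] != length(object@regions))
    msg <- c(msg, "region dimension does not match region names")
  if (d[3] != object@steps + 1L)
    msg <- c(msg, "step dimension must be steps + 1")
  if (length(msg)) msg else TRUE
})

#' Full reproducible run configuration
#'
#' Bundles every knob of a simulation: scenario label, lattice geometry,
#' material table, strain-surrogate parameters, engine probabilities, step
#' count and master seed. Built by [makeScenario()] or [simConfig()],
#' serialized losslessly by [writeConfig()]/[readConfig()].
#'
#' @slot scenario scenario label.
#' @slot steps number of CA steps.
#' @slot seed master seed; spawns separate damage and engine streams.
#' @slot geometry named list: arcLengthCells, cellSizeUm, layer thicknesses,
#'   electrolyte and reservoir depth, depth of the optional 3-d extrusion.
#' @slot materials material table (see [defaultMaterials()]).
#' @slot strain named list: deformed flag, peak strains and width.
#' @slot engine named list: reservoir concentrations, neighborhood,
#'   shielding factor, snapshot/rate windows.
#' @export
setClass("SimConfig",
  representation(scenario = "character", steps = "integer", seed = "integer",
                 geometry = "list", materials = "data.frame",
                 strain = "list", engine = "list"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@steps < 0) msg <- c(msg, "steps must be >= 0")
  eng <- object@engine
  for (f in c("resH2O", "resCL", "resH"))
    if (!is.null(eng[[f]]) && eng[[f]] < 0)
      msg <- c(msg, sprintf("%s must be >= 0", f))
  if (!is.null(eng$rateWindow) && eng$rateWindow < 1)
    msg <- c(msg, "rateWindow must be >= 1")
  if (!is.null(eng$neighborhood) &&
      !eng$neighborhood %in% c("vonNeumann", "Moore"))
    msg <- c(msg, "neighborhood must be vonNeumann or Moore")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StentLattice", function(object) {
  d <- dim(object@state)
  cat(sprintf("StentLattice: %d x %d x %d cells (%.2f um/cell)\n",
              d[1], d[2], d[3], object@cellSizeUm))
  cc <- componentCounts(object)
  cat("  components:",
      paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
  cat(sprintf("  walkers: H2O=%d CL=%d H=%d\n",
              sum(object@h2o), sum(object@cl), sum(object@h)))
})

setMethod("show", "StrainField", function(object) {
  cat(sprintf("StrainField (%s): peaks inner=%.3f outer=%.3f width=%.2f\n",
              object@mode, object@peakInner, object@peakOuter, object@width))
  cat(sprintf("  |eps| range: [%.4f, %.4f]\n",
              min(abs(object@epsilon)), max(abs(object@epsilon))))
})

setMethod("show", "DamageMap", function(object) {
  cat(sprintf("DamageMap: K=%.3f eb=%.3f; cracked columns inner=%d outer=%d\n",
              object@KUsed, object@ebUsed,
              sum(object@cracked["inner", ]), sum(object@cracked["outer", ])))
})

setMethod("show", "DegradationTrace", function(object) {
  cat(sprintf("DegradationTrace: %d steps, regions: %s\n", object@steps,
              paste(object@regions, collapse = ", ")))
  fin <- sapply(c("POLY", "MGF2", "MGO", "MG"), function(cp)
    degradedFraction(object, cp)[object@steps + 1L])
  cat("  final degraded fraction:",
      paste(sprintf("%s=%.3f", names(fin), fin), collapse = " "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig '%s': %d steps, seed %d, polymer %s, %s\n",
              object@scenario, object@steps, object@seed,
              if (length(object@geometry$polymer)) object@geometry$polymer
              else "none",
              if (isTRUE(object@strain$deformed)) "deformed" else "undeformed"))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %d of %d cells\n", object@name,
              sum(object@mask), length(object@mask)))
})
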