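#' Layer specification helper
#'
#' @param material component or polymer label (\code{"PDLLA"},
#'   \code{"PBAT"}, \code{"MGF2"}, \code{"MGO"}, \code{"MG"}).
#' @param thickness_um layer thickness in micrometres (> 0).
#' @return one-row data.frame.
#' @export
layerSpec <- function(material, thickness_um) {
  stopifnot(length(material) == 1, length(thickness_um) == 1)
  if (thickness_um <= 0) stop("thickness_um must be > 0")
  data.frame(material = material, thickness_um = thickness_um,
             stringsAsFactors = FALSE)
}

## Map a layer material label to the lattice component code. Polymer names
## collapse to POLY; the polymer identity lives in the config/material table.
.layerCode <- function(material) {
  if (material %in% c("PDLLA", "PBAT", "POLY")) return(.COMPONENTS[["POLY"]])
  if (!material %in% names(.COMPONENTS))
    stop("unknown layer material '", material, "'")
  .COMPONENTS[[material]]
}

#' Build the layered strut lattice
#'
#' Constructs the discrete cross-section of a coated strut: an electrolyte
#' band at each outer boundary, then the layer stack applied symmetrically
#' to both faces (outer face top-down, inner face mirrored bottom-up)
#' around the magnesium core. Layers are given from the outside inward,
#' excluding the substrate, e.g. polymer | MgF2 | MgO.
#'
#' @param layers data.frame of layers (rbind of [layerSpec()] rows), ordered
#'   from the electrolyte towards the core; may be empty for a bare strut.
#' @param strut_thickness_um thickness of the magnesium core in micrometres.
#' @param arc_length_cells number of columns along the arc (>= 10).
#' @param cell_size_um cell edge length in micrometres; every layer must be
#'   at least one cell thick at this resolution.
#' @param elec_rows electrolyte rows at each boundary.
#' @param reservoir_rows outermost electrolyte rows held at the bulk
#'   concentration each step (<= elec_rows); the remaining electrolyte rows
#'   start walker-free, so corrosive species reach the coating by diffusion.
#' @param depth cells in the thin extrusion (1 = plain 2-d cross-section).
#' @return a [StentLattice-class] with zero walkers everywhere.
#' @export
#' @examples
#' lat <- buildLattice(rbind(layerSpec("PDLLA", 4), layerSpec("MGF2", 1),
#'                           layerSpec("MGO", 0.5)),
#'                     strut_thickness_um = 30, arc_length_cells = 101,
#'                     cell_size_um = 0.5)
#' componentCounts(lat)
buildLattice <- function(layers, strut_thickness_um, arc_length_cells,
                         cell_size_um = 0.5, elec_rows = 29L,
                         reservoir_rows = 15L, depth = 1L) {
  if (arc_length_cells < 10) stop("arc_length_cells must be >= 10")
  if (cell_size_um <= 0) stop("cell_size_um must be > 0")
  if (reservoir_rows > elec_rows)
    stop("reservoir_rows cannot exceed elec_rows")
  nlay <- if (is.null(layers)) 0L else nrow(layers)
  cells <- integer(0)
  if (nlay > 0) {
    cells <- as.integer(round(layers$thickness_um / cell_size_um))
    thin <- layers$thickness_um / cell_size_um < 0.5
    if (any(thin | cells < 1))
      stop("layer(s) thinner than one cell at cell_size_um = ", cell_size_um,
           ": ", paste(layers$material[thin | cells < 1], collapse = ", "),
           " (resolution too coarse)")
  }
  core <- as.integer(round(strut_thickness_um / cell_size_um))
  if (core < 1) stop("strut thinner than one cell")
  nr <- 2L * (as.integer(elec_rows) + sum(cells)) + core
  nc <- as.integer(arc_length_cells)
  nd <- as.integer(depth)

  col <- rep(.COMPONENTS[["MG"]], nr)
  side <- rep("inner", nr)
  r <- 1L
  fill <- function(code, n) {
    if (n > 0) col[r:(r + n - 1L)] <<- code
    r <<- r + n
  }
  fill(.COMPONENTS[["ELEC"]], as.integer(elec_rows))
  if (nlay > 0) for (i in seq_len(nlay))
    fill(.layerCode(layers$material[i]), cells[i])
  outer_rows <- r - 1L          # outer face: everything above the core
  fill(.COMPONENTS[["MG"]], core)
  if (nlay > 0) for (i in rev(seq_len(nlay)))
    fill(.layerCode(layers$material[i]), cells[i])
  fill(.COMPONENTS[["ELEC"]], as.integer(elec_rows))
  stopifnot(r == nr + 1L)
  ## side split: outer face rows, then core split evenly, then inner face
  side[seq_len(outer_rows + core %/% 2L)] <- "outer"

  state <- array(rep(col, times = nc * nd), dim = c(nr, nc, nd))
  zero <- array(0L, dim = c(nr, nc, nd))
  lay_echo <- if (nlay > 0) {
    data.frame(material = layers$material, thickness_um = layers$thickness_um,
               cells = cells, stringsAsFactors = FALSE)
  } else data.frame(material = character(), thickness_um = numeric(),
                    cells = integer(), stringsAsFactors = FALSE)
  attr(lay_echo, "elec_rows") <- as.integer(elec_rows)
  new("StentLattice", state = state, h2o = zero, cl = zero, h = zero,
      cellSizeUm = cell_size_um, arcCoord = (seq_len(nc) - 0.5) / nc,
      side = side, reservoirRows = as.integer(reservoir_rows),
      layers = lay_echo)
}

#' Count cells per component
#'
#' @param l a [StentLattice-class].
#' @return named integer vector over all six components (zeros included);
#'   sums to the total cell count.
#' @export
componentCounts <- function(l) {
  stopifnot(is(l, "StentLattice"))
  tab <- tabulate(as.vector(l@state) + 1L, nbins = length(.COMPONENTS))
  names(tab) <- names(.COMPONENTS)
  tab
}

#' Extrude a 2-d lattice into a thin 3-d slab
#'
#' Replicates the cross-section along a third axis, for 3-d voxel renders
#' or full 3-d evolution with the same rules (6-neighbor von Neumann).
#'
#' @param l a depth-1 [StentLattice-class].
#' @param depth number of slices (>= 2).
#' @return a [StentLattice-class] with the requested depth.
#' @export
extrudeLattice <- function(l, depth = 20L) {
  stopifnot(is(l, "StentLattice"), depth >= 2)
  d <- dim(l@state)
  if (d[3] != 1) stop("lattice is already 3-d")
  ex <- function(a) array(rep(as.vector(a), times = depth),
                          dim = c(d[1], d[2], as.integer(depth)))
  initialize(l, state = ex(l@state), h2o = ex(l@h2o), cl = ex(l@cl),
             h = ex(l@h))
}

#' Lattice accessors
#'
#' \code{latticeState} returns the component-code array (use
#' \code{componentLabels()} to decode), \code{arcCoord} the per-column
#' normalized arclength, \code{cellSide} the per-row face tag, and
#' \code{speciesCounts} one walker-count array.
#'
#' @param l a [StentLattice-class].
#' @return array / numeric vector / character vector as described.
#' @export
latticeState <- function(l) l@state

#' @rdname latticeState
#' @export
arcCoord <- function(l) l@arcCoord

#' @rdname latticeState
#' @export
cellSide <- function(l) l@side

#' @rdname latticeState
#' @param species one of \code{"H2O"}, \code{"CL"}, \code{"H"}.
#' @export
speciesCounts <- function(l, species = c("H2O", "CL", "H")) {
  species <- match.arg(species)
  switch(species, H2O = l@h2o, CL = l@cl, H = l@h)
}

## Electrolyte band depth per face, recorded at build time.
.elecRows <- function(l) {
  e <- attr(l@layers, "elec_rows")
  if (is.null(e)) stop("electrolyte depth not recorded in lattice")
  e
}

## Row indices of the polymer band on one face, from the initial layer
## stack (independent of later degradation).
.polymerRows <- function(l, side = c("outer", "inner")) {
  side <- match.arg(side)
  lay <- l@layers
  poly <- which(lay$material %in% c("PDLLA", "PBAT", "POLY"))
  if (!length(poly)) return(integer(0))
  elec <- .elecRows(l)
  before <- if (poly > 1) sum(lay$cells[seq_len(poly - 1L)]) else 0L
  n <- lay$cells[poly]
  nr <- dim(l@state)[1]
  if (side == "outer") (elec + before + 1L):(elec + before + n)
  else (nr - elec - before - n + 1L):(nr - elec - before)
}
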