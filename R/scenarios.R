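.SCENARIOS <- c("PDLLA-deformed", "PBAT-deformed", "PDLLA-undeformed",
                "PBAT-undeformed", "bare", "F-only")

#' List the packaged scenario presets
#'
#' @return character vector of preset names.
#' @export
listScenarios <- function() .SCENARIOS

#' Build a preset run configuration
#'
#' The four coated presets pair each polymer (PDLLA, PBAT) with the
#' deformed strut (compression then tension crimp-expansion envelope, peak
#' strains 0.30/0.25 and 0.20/0.15 inner/outer) or the undeformed strut
#' (zero strain; an extension useful for isolating the deformation
#' effect). \code{"bare"} is the uncoated substrate with only its native
#' oxide, \code{"F-only"} the fluoride-converted substrate without
#' polymer.
#'
#' @param name preset name (see [listScenarios()]).
#' @param steps,seed run length and master seed.
#' @param materials material table override.
#' @param geometry,strain,engine block overrides merged over the preset.
#' @return a validated [SimConfig-class].
#' @export
#' @examples
#' makeScenario("PBAT-deformed", steps = 100)
makeScenario <- function(name, steps = 4000L, seed = 1L,
                         materials = defaultMaterials(), geometry = list(),
                         strain = list(), engine = list()) {
  if (!name %in% .SCENARIOS)
    stop("unknown scenario '", name, "'; available: ",
         paste(.SCENARIOS, collapse = ", "))
  geo <- switch(name,
    "PDLLA-deformed" = , "PDLLA-undeformed" = list(polymer = "PDLLA"),
    "PBAT-deformed" = , "PBAT-undeformed" = list(polymer = "PBAT"),
    "bare" = list(polymer = "none", mgf2Um = 0),
    "F-only" = list(polymer = "none"))
  deformed <- grepl("-deformed$", name)
  simConfig(scenario = name, steps = steps, seed = seed,
            geometry = utils::modifyList(geo, geometry),
            strain = utils::modifyList(list(deformed = deformed), strain),
            engine = engine, materials = materials)
}

#' Deterministic toy lattices for tests and small experiments
#'
#' Small hand-specified lattices: \code{"single-interface"} (one
#' replenished electrolyte row over a magnesium block),
#' \code{"checkerboard"} (alternating electrolyte/magnesium, no
#' reservoir), \code{"crack-channel"} (electrolyte row, 3-row polymer band
#' with one open electrolyte column through it, fluoride row, magnesium
#' below; a one-face fixture) and \code{"coated"} (a symmetric miniature
#' of the full layered strut, needs >= 13 rows).
#'
#' @param rows,cols lattice dimensions (>= 2; some patterns need more
#'   rows).
#' @param pattern one of the above.
#' @return a [StentLattice-class]; identical inputs give identical
#'   lattices.
#' @export
#' @examples
#' latticeState(makeToyLattice(5, 5, "single-interface"))[, , 1]
makeToyLattice <- function(rows, cols,
                           pattern = c("single-interface", "checkerboard",
                                       "crack-channel", "coated")) {
  pattern <- match.arg(pattern)
  if (rows < 2 || cols < 2) stop("rows and cols must be >= 2")
  rows <- as.integer(rows); cols <- as.integer(cols)
  emptyLayers <- function(elec) {
    lay <- data.frame(material = character(), thickness_um = numeric(),
                      cells = integer(), stringsAsFactors = FALSE)
    attr(lay, "elec_rows") <- as.integer(elec)
    lay
  }
  mk <- function(state, reservoir, layers) {
    zero <- array(0L, dim = dim(state))
    side <- rep(c("outer", "inner"),
                c(ceiling(rows / 2), rows - ceiling(rows / 2)))
    new("StentLattice", state = state, h2o = zero, cl = zero, h = zero,
        cellSizeUm = 0.5, arcCoord = (seq_len(cols) - 0.5) / cols,
        side = side, reservoirRows = as.integer(reservoir), layers = layers)
  }
  E <- .COMPONENTS[["ELEC"]]; M <- .COMPONENTS[["MG"]]
  P <- .COMPONENTS[["POLY"]]; FL <- .COMPONENTS[["MGF2"]]
  switch(pattern,
    "single-interface" = {
      st <- array(M, dim = c(rows, cols, 1L))
      st[1, , ] <- E
      mk(st, 1L, emptyLayers(1L))
    },
    "checkerboard" = {
      grid <- outer(seq_len(rows), seq_len(cols),
                    function(r, c) ifelse((r + c) %% 2 == 0, E, M))
      mk(array(grid, dim = c(rows, cols, 1L)), 0L, emptyLayers(0L))
    },
    "crack-channel" = {
      if (rows < 7) stop("crack-channel needs >= 7 rows")
      st <- array(M, dim = c(rows, cols, 1L))
      st[1, , ] <- E
      st[2:4, , ] <- P
      st[5, , ] <- FL
      st[2:4, (cols + 1L) %/% 2L, ] <- E  # the open crack column
      lay <- data.frame(material = c("POLY", "MGF2"),
                        thickness_um = c(1.5, 0.5), cells = c(3L, 1L),
                        stringsAsFactors = FALSE)
      attr(lay, "elec_rows") <- 1L
      mk(st, 1L, lay)
    },
    "coated" = {
      if (rows < 13) stop("coated needs >= 13 rows")
      core <- rows - 12L
      buildLattice(rbind(layerSpec("POLY", 1), layerSpec("MGF2", 0.5),
                         layerSpec("MGO", 0.5)),
                   strut_thickness_um = core * 0.5,
                   arc_length_cells = cols, cell_size_um = 0.5,
                   elec_rows = 2L, reservoir_rows = 1L)
    })
}
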