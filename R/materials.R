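#' Packaged material constants
#'
#' Returns the default table of mechanical and kinetic constants for the two
#' candidate coating polymers (PDLLA, PBAT), the inorganic layers (MgF2
#' conversion film, native MgO, Mg substrate) and the Mg(OH)2 corrosion
#' product. Tensile strength and elongation at break are measured film
#' properties; the porosity constant K and all per-step probabilities are
#' calibrated model parameters, fixed once by [calibrateDefaults()] and
#' never changed silently (every run echoes the table it used).
#'
#' Conventions: elongation at break is stored as a strain fraction (PDLLA
#' 0.03, PBAT 5.33), so it compares directly with the strain field.
#' \code{hydrolysis_prob} applies to polymer cells in contact with water;
#' \code{permeation_prob} is the chance a walker steps into an intact cell
#' of that material; \code{dissolution_prob} is the per-step conversion
#' probability of an inorganic cell touching water-bearing electrolyte,
#' multiplied by \code{acid_boost} when a proton walker is adjacent. The
#' hydroxide product is inert to plain water and dissolves only under
#' chloride attack. PDLLA hydrolyses at twice the PBAT rate, and
#' K_PDLLA < K_PBAT so the strained PDLLA coating is always the more porous.
#'
#' @return data.frame with one row per material, rownames = material name.
#' @seealso [validateMaterial()], [calibrateDefaults()]
#' @export
#' @examples
#' defaultMaterials()["PDLLA", "elongation_at_break"]
defaultMaterials <- function() {
  m <- data.frame(
    name = c("PDLLA", "PBAT", "MGF2", "MGO", "MG", "PRODUCT"),
    tensile_strength = c(12.33, 14.49, NA, NA, NA, NA),
    elongation_at_break = c(0.03, 5.33, NA, NA, NA, NA),
    porosity_K = c(0.85, 0.99, NA, NA, NA, NA),
    hydrolysis_prob = c(2.2e-04, 1.1e-04, 0, 0, 0, 0),
    permeation_prob = c(0.01, 0.01, 0, 0, 0, 0),
    dissolution_prob = c(0, 0, 0.012, 0.08, 0.05, 0.05),
    acid_boost = c(1, 1, 2, 2, 1, 1),
    stringsAsFactors = FALSE)
  rownames(m) <- m$name
  m
}

#' Validate a material record
#'
#' Checks the invariants of a single material row: probabilities in [0, 1],
#' acid_boost >= 1, porosity constant K in (0, 1]. Returns descriptions of
#' the violations rather than throwing, so configuration loaders can report
#' all problems at once.
#'
#' @param m one-row data.frame (or list) with the fields of
#'   [defaultMaterials()].
#' @return character vector of violations; empty when the record is valid.
#' @export
#' @examples
#' validateMaterial(defaultMaterials()["PBAT", ])
validateMaterial <- function(m) {
  v <- character()
  chk <- function(x) length(x) == 1 && !is.na(x)
  for (f in c("hydrolysis_prob", "permeation_prob", "dissolution_prob")) {
    x <- m[[f]]
    if (chk(x) && (x < 0 || x > 1))
      v <- c(v, sprintf("%s must lie in [0, 1], got %g", f, x))
  }
  if (chk(m[["acid_boost"]]) && m[["acid_boost"]] < 1)
    v <- c(v, sprintf("acid_boost must be >= 1, got %g", m[["acid_boost"]]))
  K <- m[["porosity_K"]]
  if (chk(K) && (K <= 0 || K > 1))
    v <- c(v, sprintf("porosity_K must lie in (0, 1], got %g", K))
  eb <- m[["elongation_at_break"]]
  if (chk(eb) && eb < 0)
    v <- c(v, sprintf("elongation_at_break must be >= 0, got %g", eb))
  v
}

#' Validate a full material table
#'
#' Applies [validateMaterial()] to every row and additionally checks the
#' cross-material ordering invariants of the defaults: PDLLA's elongation at
#' break below PBAT's, and PDLLA hydrolysing no slower than PBAT.
#'
#' @param tab material table as from [defaultMaterials()].
#' @return character vector of violations; empty when valid.
#' @export
validateMaterials <- function(tab) {
  v <- character()
  for (i in seq_len(nrow(tab))) {
    vi <- validateMaterial(tab[i, ])
    if (length(vi)) v <- c(v, paste0(tab$name[i], ": ", vi))
  }
  if (all(c("PDLLA", "PBAT") %in% rownames(tab))) {
    if (!(tab["PDLLA", "elongation_at_break"] <
          tab["PBAT", "elongation_at_break"]))
      v <- c(v, "PDLLA elongation_at_break must be below PBAT's")
    if (tab["PDLLA", "hydrolysis_prob"] < tab["PBAT", "hydrolysis_prob"])
      v <- c(v, "PDLLA hydrolysis_prob must not be below PBAT's")
  }
  v
}

#' Look up one material
#'
#' @param name material name (row of [defaultMaterials()]).
#' @param materials material table; defaults to the packaged one.
#' @return one-row data.frame.
#' @export
materialProps <- function(name, materials = defaultMaterials()) {
  if (!name %in% rownames(materials))
    stop("unknown material '", name, "'; available: ",
         paste(rownames(materials), collapse = ", "))
  materials[name, ]
}

## Serialize/parse the material table to the key-value block used in config
## files (plain named lists, yaml-friendly).
.materialsToList <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    out <- lapply(names(row), function(f) {
      x <- row[[f]]
      if (is.numeric(x) && is.na(x)) NULL else x
    })
    names(out) <- names(row)
    out[!vapply(out, is.null, logical(1))]
  })
}

.materialsFromList <- function(lst) {
  tmpl <- defaultMaterials()[0, ]
  rows <- lapply(lst, function(rec) {
    row <- as.list(rep(NA_real_, ncol(tmpl)))
    names(row) <- colnames(tmpl)
    for (f in names(rec)) row[[f]] <- rec[[f]]
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$name <- as.character(tab$name)
  rownames(tab) <- tab$name
  tab
}
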