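## Raised-cosine arc profile: 1 at the apex column, 0 beyond +/- width.
## The apex is anchored to the lattice column nearest s = 0.5 so the
## configured peak strain is attained exactly on a cell.
.arcProfile <- function(arc, width) {
  apex <- arc[which.min(abs(arc - 0.5))]
  d <- abs(arc - apex)
  p <- ifelse(d < width, 0.5 * (1 + cos(pi * d / width)), 0)
  p[abs(d - width) < 1e-12] <- 0
  p
}

#' Analytic surrogate for the crimp-expansion strain field
#'
#' Stands in for a finite-element solution of the strut deformation: the
#' strain magnitude along the arc is a raised cosine, peaking at the arc
#' apex (s = 0.5) and vanishing beyond one width, with separate peak values
#' for the inner and outer face of the arc. Under compression the inner
#' face is in tension (positive sign) and the outer in compression; the
#' signs swap under the tension (expansion) phase. Damage downstream
#' consumes only the magnitude.
#'
#' @param mode \code{"compression"} or \code{"tension"}.
#' @param lattice the [StentLattice-class] the field is defined on.
#' @param peak_inner,peak_outer apex strain magnitude on each face, as a
#'   fraction in [0, 1). Defaults are the crimp-expansion peaks of the
#'   scaled strut model: 0.30/0.25 under compression, 0.20/0.15 under
#'   tension.
#' @param width raised-cosine half-support as a fraction of arclength,
#'   in (0, 0.5].
#' @return a [StrainField-class].
#' @export
#' @examples
#' lat <- makeToyLattice(15, 21, "coated")
#' f <- strainSurrogate("compression", lat)
#' max(epsilon(f))  # 0.30 at the inner apex
strainSurrogate <- function(mode = c("compression", "tension"), lattice,
                            peak_inner = NULL, peak_outer = NULL,
                            width = 0.15) {
  mode <- match.arg(mode)
  if (is.null(peak_inner))
    peak_inner <- if (mode == "compression") 0.30 else 0.20
  if (is.null(peak_outer))
    peak_outer <- if (mode == "compression") 0.25 else 0.15
  if (peak_inner >= 1 || peak_outer >= 1)
    stop("peak strains must be below 1 (nonphysical for this surrogate)")
  if (peak_inner < 0 || peak_outer < 0) stop("peak strains must be >= 0")
  if (width <= 0 || width > 0.5) stop("width must lie in (0, 0.5]")
  prof <- .arcProfile(arcCoord(lattice), width)
  inner <- cellSide(lattice) == "inner"
  peak_row <- ifelse(inner, peak_inner, peak_outer)
  ## sign: compression -> inner tensile (+), outer compressive (-)
  sgn <- ifelse(inner, 1, -1) * if (mode == "compression") 1 else -1
  eps <- outer(peak_row * sgn, prof)
  new("StrainField", epsilon = eps, mode = mode,
      peakInner = peak_inner, peakOuter = peak_outer, width = width)
}

#' Per-cell strain envelope of two loading phases
#'
#' The crimp-expansion cycle loads the strut sequentially (compression,
#' then tension); coating damage responds to the worst strain either phase
#' imposed, so the envelope takes the pointwise maximum magnitude.
#'
#' @param compression,tension [StrainField-class] objects on the same
#'   lattice.
#' @return envelope [StrainField-class] with non-negative \code{epsilon}.
#' @export
strainEnvelope <- function(compression, tension) {
  if (!identical(dim(compression@epsilon), dim(tension@epsilon)))
    stop("strain fields are defined on different lattice dimensions")
  eps <- pmax(abs(compression@epsilon), abs(tension@epsilon))
  new("StrainField", epsilon = eps, mode = "envelope",
      peakInner = max(compression@peakInner, tension@peakInner),
      peakOuter = max(compression@peakOuter, tension@peakOuter),
      width = max(compression@width, tension@width))
}

#' Zero strain field (undeformed strut)
#'
#' @param lattice a [StentLattice-class].
#' @return envelope [StrainField-class] that is identically zero.
#' @export
zeroStrain <- function(lattice) {
  d <- dim(latticeState(lattice))
  new("StrainField", epsilon = matrix(0, d[1], d[2]), mode = "envelope",
      peakInner = 0, peakOuter = 0, width = 0.15)
}

#' @rdname strainSurrogate
#' @param field a [StrainField-class].
#' @export
epsilon <- function(field) field@epsilon

#' Read a strain map from a delimited grid file
#'
#' Lets a real finite-element export replace the analytic surrogate. The
#' file is a plain whitespace- or comma-delimited numeric grid with one
#' value per lattice cell (rows x columns).
#'
#' @param path file path.
#' @param lattice lattice the map must match.
#' @param mode stored mode tag.
#' @return a [StrainField-class].
#' @export
loadStrainMap <- function(path, lattice, mode = "envelope") {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "numeric")
  eps <- as.matrix(tab)
  dimnames(eps) <- NULL
  d <- dim(latticeState(lattice))
  if (!identical(dim(eps), d[1:2]))
    stop(sprintf("strain map is %d x %d but lattice is %d x %d",
                 nrow(eps), ncol(eps), d[1], d[2]))
  new("StrainField", epsilon = eps, mode = mode,
      peakInner = max(0, abs(eps)), peakOuter = max(0, abs(eps)),
      width = 0.5)
}

#' Write a strain map as a delimited grid
#'
#' @param field a [StrainField-class].
#' @param path output file.
#' @export
writeStrainMap <- function(field, path) {
  utils::write.table(field@epsilon, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
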