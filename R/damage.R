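#' Strain-to-porosity law for the polymer coating
#'
#' Maps the local strain magnitude to coating porosity through
#' \deqn{P(\epsilon) = (1 - K^{\epsilon + 1}) \times 100\%,}
#' with K in (0, 1] a material constant expressing how sensitive the
#' coating's pore structure is to stretch. P is strictly increasing in
#' strain for K < 1, grows exponentially, equals (1 - K) x 100 at zero
#' strain, and is identically zero in the K = 1 limit of a strain-
#' insensitive, fully dense coating.
#'
#' @param eps strain magnitude(s), >= 0 (callers pass |strain|).
#' @param K porosity constant in (0, 1].
#' @return porosity percent in [0, 100), vectorized over \code{eps}.
#' @export
#' @examples
#' porosity(0, 0.5)   # 50
#' porosity(1, 0.5)   # 75
#' porosity(0.3, 1)   # 0
porosity <- function(eps, K) {
  if (length(K) != 1 || is.na(K) || K <= 0 || K > 1)
    stop("K must lie in (0, 1]")
  if (any(eps < 0)) stop("eps must be >= 0 (pass |strain|)")
  p <- (1 - K^(eps + 1)) * 100
  pmin(pmax(p, 0), 100 - .Machine$double.eps)
}

#' Apply deformation damage to a fresh lattice
#'
#' Converts the strain envelope into the deformed initial condition of the
#' corrosion run. On each face of the strut, every polymer column whose
#' strain magnitude exceeds the coating's elongation at break becomes a
#' through-thickness crack: its whole polymer band is relabeled
#' electrolyte. Elsewhere, each polymer cell independently becomes a pore
#' with probability P(strain)/100 from [porosity()]. Cracking is
#' deterministic; only pore placement consumes randomness. Inorganic layers
#' are untouched.
#'
#' @param lattice fresh [StentLattice-class] (no product, no walkers in
#'   solids).
#' @param field envelope [StrainField-class] on the same lattice.
#' @param material one-row material record of the coating polymer (needs
#'   \code{porosity_K} and \code{elongation_at_break}).
#' @param rng_seed integer seed for the pore realization.
#' @return list with elements \code{lattice} (damaged) and \code{damage}
#'   (a [DamageMap-class]).
#' @export
applyDamage <- function(lattice, field, material, rng_seed = 1L) {
  stopifnot(is(lattice, "StentLattice"), is(field, "StrainField"))
  d <- dim(latticeState(lattice))
  if (!identical(dim(field@epsilon), d[1:2]))
    stop("strain field does not match lattice dimensions")
  K <- material[["porosity_K"]]
  eb <- material[["elongation_at_break"]]
  if (is.na(K) || is.na(eb))
    stop("material record lacks porosity_K or elongation_at_break")

  state <- lattice@state
  nc <- d[2]
  por <- matrix(0, 2, nc, dimnames = list(c("outer", "inner"), NULL))
  crk <- matrix(FALSE, 2, nc, dimnames = list(c("outer", "inner"), NULL))
  set.seed(as.integer(rng_seed))
  for (side in c("outer", "inner")) {
    rows <- .polymerRows(lattice, side)
    if (!length(rows)) next
    ## face strain per column: the face's surface magnitude (uniform over
    ## the band in this surrogate) taken at the band's first row
    eff <- abs(field@epsilon[rows[1], ])
    por[side, ] <- porosity(eff, K)
    crk[side, ] <- eff > eb
    for (j in seq_len(nc)) {
      if (crk[side, j]) {
        state[rows, j, ] <- .COMPONENTS[["ELEC"]]
      } else {
        p <- por[side, j] / 100
        if (p > 0) {
          nz <- length(rows) * d[3]
          hit <- stats::runif(nz) < p
          sub <- state[rows, j, , drop = FALSE]
          sub[hit] <- .COMPONENTS[["ELEC"]]
          state[rows, j, ] <- sub
        }
      }
    }
  }
  dm <- new("DamageMap", arcCoord = arcCoord(lattice), porosity = por,
            cracked = crk, KUsed = K, ebUsed = eb)
  list(lattice = initialize(lattice, state = state), damage = dm)
}

#' Porosity profile along the arc
#'
#' The per-column porosity percent of the coating on one face, aligned to
#' the arclength coordinate; directly comparable between coatings (under
#' equal strain the lower-K coating is everywhere the more porous).
#'
#' @param dm a [DamageMap-class].
#' @param side \code{"inner"} (arc interior, default) or \code{"outer"}.
#' @return data.frame with columns \code{s}, \code{porosity},
#'   \code{cracked}.
#' @export
porosityProfile <- function(dm, side = c("inner", "outer")) {
  side <- match.arg(side)
  data.frame(s = dm@arcCoord, porosity = dm@porosity[side, ],
             cracked = dm@cracked[side, ])
}

#' Export a damage map as a delimited table
#'
#' Writes (arc position, porosity percent, cracked flag) per column and
#' face for comparison against measured porosity-distribution curves.
#'
#' @param dm a [DamageMap-class].
#' @param path output CSV path.
#' @export
writeDamageMap <- function(dm, path) {
  long <- rbind(cbind(side = "outer", porosityProfile(dm, "outer")),
                cbind(side = "inner", porosityProfile(dm, "inner")))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Columns cracked on either face
#'
#' @param dm a [DamageMap-class].
#' @return logical matrix 2 x columns (rows outer, inner).
#' @export
crackedColumns <- function(dm) dm@cracked
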