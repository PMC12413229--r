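.TRACE_SCHEMA <- "stentCA-trace-v1"

#' Write / read a degradation trace as CSV
#'
#' Long-format CSV (region, component, step, count) with the schema
#' version embedded in a comment header; the round trip is lossless.
#'
#' @param trace a [DegradationTrace-class].
#' @param path CSV path.
#' @return \code{writeTrace}: the path, invisibly. \code{readTrace}: the
#'   [DegradationTrace-class].
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "DegradationTrace"))
  comps <- componentLabels()
  d <- dim(trace@counts)
  long <- expand.grid(region = trace@regions, component = comps,
                      step = 0:(d[3] - 1L), stringsAsFactors = FALSE)
  long$count <- as.vector(trace@counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .TRACE_SCHEMA), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  first <- tryCatch(readLines(path, n = 1), error = function(e) character())
  if (!length(first) || !grepl(.TRACE_SCHEMA, first, fixed = TRUE))
    stop("not a ", .TRACE_SCHEMA, " file: ", path)
  long <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("region", "component", "step", "count")
  missing_cols <- setdiff(need, colnames(long))
  if (length(missing_cols))
    stop("trace schema mismatch: expected columns ",
         paste(need, collapse = ", "), "; missing ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(colnames(long), need)
  if (length(extra))
    warning("ignoring unknown trace column(s): ",
            paste(extra, collapse = ", "))
  regions <- unique(long$region)
  comps <- componentLabels()
  steps <- max(long$step)
  counts <- array(0, dim = c(length(regions), length(comps), steps + 1L))
  counts[cbind(match(long$region, regions), match(long$component, comps),
               long$step + 1L)] <- long$count
  new("DegradationTrace", counts = counts, regions = regions,
      steps = as.integer(steps))
}

#' Write / read a run configuration (YAML)
#'
#' Serializes every field of a [SimConfig-class], including the full
#' material table, so a run can be reproduced from its config echo alone.
#'
#' @param cfg a [SimConfig-class].
#' @param path YAML path.
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(is(cfg, "SimConfig"))
  yaml::write_yaml(list(scenario = cfg@scenario, steps = cfg@steps,
                        seed = cfg@seed, geometry = cfg@geometry,
                        strain = cfg@strain, engine = cfg@engine,
                        materials = .materialsToList(cfg@materials)),
                   path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("scenario", "steps", "seed"))
    if (is.null(x[[f]])) stop("config is missing field '", f, "'")
  simConfig(scenario = x$scenario, steps = x$steps, seed = x$seed,
            geometry = x$geometry %||% list(),
            strain = x$strain %||% list(),
            engine = x$engine %||% list(),
            materials = if (is.null(x$materials)) defaultMaterials()
                        else .materialsFromList(x$materials))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Fixed component palette (RGB in [0,1]); bump the version tag if it
## changes, renders are promised byte-stable per palette version.
.PALETTE_VERSION <- 1L
.componentPalette <- function() {
  rbind(ELEC = c(0.92, 0.96, 1.00),
        POLY = c(0.35, 0.70, 0.35),
        MGF2 = c(0.55, 0.35, 0.75),
        MGO  = c(0.95, 0.60, 0.20),
        MG   = c(0.55, 0.55, 0.58),
        PRODUCT = c(0.62, 0.45, 0.30))
}

#' Render a 2-d cross-section as PNG
#'
#' One pixel per cell with the fixed component palette, plus an embedded
#' legend strip (one color block per component) along the bottom edge.
#' Output bytes are deterministic for a given lattice and palette version.
#'
#' @param lattice a [StentLattice-class].
#' @param path PNG output path.
#' @param slice depth slice to render for 3-d lattices.
#' @return the path, invisibly.
#' @export
renderCrossSection <- function(lattice, path, slice = 1L) {
  stopifnot(is(lattice, "StentLattice"))
  st <- latticeState(lattice)[, , slice]
  pal <- .componentPalette()
  nr <- nrow(st); nc <- ncol(st)
  img <- array(0, dim = c(nr + 6L, nc, 3))
  for (ch in 1:3)
    img[1:nr, , ch] <- matrix(pal[st + 1L, ch], nr, nc)
  ## legend: six equal blocks, separated from the section by a white row
  img[nr + 1L, , ] <- 1
  blocks <- floor(seq(1, nc + 1, length.out = 7))
  for (k in 1:6) {
    cols <- blocks[k]:(blocks[k + 1] - 1L)
    for (ch in 1:3) img[(nr + 2L):(nr + 6L), cols, ch] <- pal[k, ch]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Render a 3-d lattice as a voxel cloud image
#'
#' Orthographic projection along the extrusion axis: each pixel shows the
#' first non-electrolyte voxel (electrolyte is transparent), darkened with
#' depth so dissolution pits read as shaded recesses. A fully dissolved
#' lattice produces a background-only image and a message.
#'
#' @param lattice3d a [StentLattice-class] with depth >= 2.
#' @param path PNG output path.
#' @return the path, invisibly.
#' @export
renderCloud <- function(lattice3d, path) {
  stopifnot(is(lattice3d, "StentLattice"))
  st <- latticeState(lattice3d)
  d <- dim(st)
  if (d[3] < 2) stop("renderCloud needs a 3-d lattice (use extrudeLattice)")
  pal <- .componentPalette()
  elec <- .COMPONENTS[["ELEC"]]
  img <- array(1, dim = c(d[1], d[2], 3))  # white background
  solid_any <- FALSE
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    z <- which(st[r, c, ] != elec)
    if (length(z)) {
      solid_any <- TRUE
      z1 <- z[1]
      shade <- 1 - 0.6 * (z1 - 1) / d[3]
      img[r, c, ] <- pal[st[r, c, z1] + 1L, ] * shade
    }
  }
  if (!solid_any)
    message("renderCloud: lattice fully degraded; image is empty")
  png::writePNG(img, path)
  invisible(path)
}

#' Write the full artifact set of a run
#'
#' Creates the run directory and writes: the config echo (with master
#' seed), the trace and per-window rate tables, the step report log, a
#' milestone summary, a cross-section render of the final state and any
#' snapshots (as zero-padded step-indexed files).
#'
#' @param run a \code{"SimRun"} object from [runSim()].
#' @param dir output directory.
#' @param force overwrite an existing directory (default: refuse).
#' @return the directory, invisibly.
#' @export
writeRunArtifacts <- function(run, dir, force = FALSE) {
  if (dir.exists(dir) && !force)
    stop("output directory exists: ", dir, " (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeConfig(run$config, file.path(dir, "config.yaml"))
  writeTrace(run$trace, file.path(dir, "trace.csv"))
  win <- run$config@engine$rateWindow
  rates <- do.call(rbind, lapply(run$trace@regions, function(rg)
    do.call(rbind, lapply(componentLabels(), function(cp) {
      if (run$config@steps < win) return(NULL)
      r <- degradationRate(run$trace, cp, rg, win)
      cbind(region = rg, component = cp, r)
    }))))
  if (!is.null(rates))
    utils::write.csv(rates, file.path(dir, "rates.csv"), row.names = FALSE)
  utils::write.csv(cbind(step = seq_len(nrow(run$reports)), run$reports),
                   file.path(dir, "step_report.csv"), row.names = FALSE)
  writeLines(.milestoneSummary(run), file.path(dir, "milestones.txt"))
  renderCrossSection(run$lattice, file.path(dir, "final_state.png"))
  if (length(run$snapshots)) {
    for (i in seq_along(run$snapshots)) {
      snap <- run$snapshots[[i]]
      f <- file.path(dir, sprintf("snapshot_%06d.rds", run$snapshotSteps[i]))
      saveRDS(snap, f)
    }
  }
  invisible(dir)
}

.milestoneSummary <- function(run) {
  cfg <- run$config
  win <- cfg@engine$rateWindow
  lines <- c(sprintf("scenario: %s", cfg@scenario),
             sprintf("steps: %d  seed: %d", cfg@steps, cfg@seed),
             sprintf("streams: damage=%d engine=%d", run$streams[1],
                     run$streams[2]))
  for (cp in componentLabels()) {
    f <- degradedFraction(run$trace, cp)
    on <- detectOnset(f, 0.01)
    stab <- if (cfg@steps >= 4 * win)
      detectStabilization(degradationRate(run$trace, cp, window = win),
                          tol = 0.005)
    else NA
    lines <- c(lines, sprintf(
      "%s: final F=%.4f onset(0.01)=%s stabilization=%s", cp,
      f[length(f)], ifelse(is.na(on), "none", on),
      ifelse(is.na(stab), "none", stab)))
  }
  lines
}
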