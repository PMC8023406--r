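## Gating: log10 transform, polygon gates on the FL1 x FL3 plane,
## first-match-wins population assignment, counts and concentrations.

#' Log-transform the analysis channels of an EventTable
#'
#' Maps each analysis channel `x -> log10(max(x, 1))`. Values at or below
#' one instrument unit are clipped to 1 before the log so the transform is
#' total on the instrument's non-negative 24-bit scale. The transform is
#' recorded in the object and applied at most once; a second attempt is an
#' error.
#'
#' @param table an [EventTable-class] on the linear scale.
#' @param channels channels to transform; defaults to the analysis channels
#'   (FSC-A, SSC-A, FL1-A, FL3-A) present in the table. Height (-H) and Time
#'   channels are left untouched.
#' @return the transformed [EventTable-class].
#' @examples
#' tab <- EventTable(cbind(`FL1-A` = c(0, 1.5e4), `FL3-A` = c(10, 100)))
#' eventMatrix(transformEvents(tab))
#' @export
transformEvents <- function(table, channels = NULL) {
  stopifnot(is(table, "EventTable"))
  if (isTransformed(table))
    stop("state error: events are already log-transformed", call. = FALSE)
  if (is.null(channels))
    channels <- intersect(.ANALYSIS_CHANNELS, channelNames(table))
  missing <- setdiff(channels, channelNames(table))
  if (length(missing))
    stop("channel error: ", paste(missing, collapse = ", "),
         " not present", call. = FALSE)
  m <- eventMatrix(table)
  if (nrow(m) > 0) m[, channels] <- log10(pmax(m[, channels, drop = FALSE], 1))
  table@exprs <- m
  table@transformed <- TRUE
  table@keywords[["#TRANSFORMCHANNELS"]] <- paste(channels, collapse = ",")
  table
}

#' Construct a polygon Gate
#'
#' @param name gate name.
#' @param vertices n x 2 matrix (or 2-column data.frame) of vertex
#'   coordinates in log10 intensity units, ordered around a simple polygon.
#' @param channelX,channelY gating channels (default `FL1-A` x `FL3-A`).
#' @return a [Gate-class] object.
#' @export
Gate <- function(name, vertices, channelX = "FL1-A", channelY = "FL3-A") {
  vertices <- as.matrix(vertices)
  colnames(vertices) <- c("x", "y")
  new("Gate", name = name, channelX = channelX, channelY = channelY,
      vertices = vertices)
}

#' @rdname Gate
#' @param xlim,ylim numeric length-2 ranges for an axis-aligned rectangle.
#' @export
rectangleGate <- function(name, xlim, ylim, channelX = "FL1-A",
                          channelY = "FL3-A") {
  Gate(name, cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
                   c(ylim[1], ylim[1], ylim[2], ylim[2])),
       channelX = channelX, channelY = channelY)
}

#' Construct a GateSet
#'
#' @param gates list of [Gate-class] objects (named by gate name if unnamed).
#' @param priority evaluation order; first match wins. Defaults to the order
#'   of `gates`.
#' @param acquisitionThreshold minimum intensity on `thresholdChannel` for an
#'   event to be counted (default 800, the acquisition trigger used with
#'   SYBR-Green-stained samples).
#' @param thresholdChannel channel the threshold applies to (default FL1-H;
#'   ignored with a warning if the channel is absent from a sample).
#' @return a [GateSet-class] object.
#' @export
GateSet <- function(gates, priority = NULL, acquisitionThreshold = 800,
                    thresholdChannel = "FL1-H") {
  if (is.null(names(gates)))
    names(gates) <- vapply(gates, function(g) g@name, character(1))
  if (is.null(priority)) priority <- names(gates)
  new("GateSet", gates = gates, priority = priority,
      acquisitionThreshold = acquisitionThreshold,
      thresholdChannel = thresholdChannel)
}

#' The default gating strategy for microalgal-bacterial cocultures
#'
#' Rectangular gates in log10(FL1-A) x log10(FL3-A) space separating the
#' chlorophyll-autofluorescent microalgal population (high FL3) from
#' prokaryotic fractions with high (HNA_p) and low (LNA_p) nucleic-acid
#' content, plus an elevated-red-fluorescence prokaryotic cluster (HFL3_p).
#' The HNA_p/LNA_p boundary sits at FL1-A = 1.5e4 (log10 = 4.176), the
#' adaptation required for prokaryotes growing in coculture with
#' *Chlorella vulgaris*; all other vertices are qualitative reference
#' positions and are meant to be adjusted per experiment (gates are data).
#' The acquisition threshold is 800 on FL1-H. Events in no gate are labelled
#' ungated (background) and kept in totals but excluded from population
#' counts.
#'
#' Evaluation priority is microalgal > HFL3_p > HNA_p > LNA_p; the default
#' gate interiors are pairwise disjoint, so priority only matters for
#' user-edited gates (and for the shared HNA_p/LNA_p boundary line, which
#' resolves to HNA_p).
#'
#' @return a [GateSet-class] with gates `microalgal`, `HFL3_p`, `HNA_p`,
#'   `LNA_p`.
#' @examples
#' gs <- defaultGateSet()
#' gs@priority
#' @export
defaultGateSet <- function() {
  fl1 <- log10(1.5e4)  # HNA_p / LNA_p boundary on the green channel
  hi <- 7.25
  gates <- list(
    microalgal = rectangleGate("microalgal", c(3.80, hi), c(4.30, hi)),
    HFL3_p = rectangleGate("HFL3_p", c(2.30, 4.10), c(2.90, 4.20)),
    HNA_p = rectangleGate("HNA_p", c(fl1, hi), c(0.00, 4.25)),
    LNA_p = rectangleGate("LNA_p", c(2.30, fl1), c(0.00, 2.80))
  )
  GateSet(gates, priority = c("microalgal", "HFL3_p", "HNA_p", "LNA_p"),
          acquisitionThreshold = 800, thresholdChannel = "FL1-H")
}

#' Gate membership for each event
#'
#' Point-in-polygon with a closed boundary: events exactly on a gate edge or
#' vertex are inside. Requires a log-transformed table.
#'
#' @param table a log-transformed [EventTable-class].
#' @param gate a [Gate-class].
#' @return logical vector, one entry per event.
#' @export
applyGate <- function(table, gate) {
  stopifnot(is(table, "EventTable"), is(gate, "Gate"))
  if (!isTransformed(table))
    stop("events must be log-transformed before gating; see transformEvents()",
         call. = FALSE)
  ch <- c(gate@channelX, gate@channelY)
  missing <- setdiff(ch, channelNames(table))
  if (length(missing))
    stop("channel error: ", paste(missing, collapse = ", "),
         " not present", call. = FALSE)
  m <- eventMatrix(table)
  if (nrow(m) == 0) return(logical(0))
  .pointsInPolygon(m[, gate@channelX], m[, gate@channelY], gate@vertices)
}

#' Count events per gate and convert to concentrations
#'
#' Events below the acquisition threshold are discarded first; the remaining
#' events are assigned to the first gate in priority order that contains them
#' (first match wins); events in no gate are counted as ungated. Nothing is
#' dropped from the total. Concentrations refer to the undiluted culture:
#' `count * dilutionFactor / acquiredVolumeuL` (cells/uL).
#'
#' @param table a log-transformed [EventTable-class].
#' @param gates a [GateSet-class].
#' @param timeH elapsed time since inoculation in hours (optional; carried
#'   into the result for time-series assembly).
#' @return a [CountResult-class].
#' @examples
#' gs <- defaultGateSet()
#' m <- cbind(`FL1-A` = rep(1e5, 61), `FL3-A` = rep(10, 61),
#'            `FL1-H` = rep(9e4, 61))
#' tab <- transformEvents(EventTable(m))  # 61 HNA_p events
#' gateConcentrations(countPopulations(tab, gs))[["HNA_p"]]  # 100 cells/uL
#' @export
countPopulations <- function(table, gates, timeH = NA_real_) {
  stopifnot(is(table, "EventTable"), is(gates, "GateSet"))
  if (!isTransformed(table))
    stop("events must be log-transformed before gating; see transformEvents()",
         call. = FALSE)
  if (acquiredVolume(table) <= 0)
    stop("metadata error: acquired volume must be positive", call. = FALSE)
  m <- eventMatrix(table)
  n <- nrow(m)

  keep <- rep(TRUE, n)
  thrCh <- gates@thresholdChannel
  if (gates@acquisitionThreshold > 0 && n > 0) {
    if (thrCh %in% channelNames(table)) {
      keep <- m[, thrCh] >= gates@acquisitionThreshold
    } else if (!is.na(thrCh) && nzchar(thrCh)) {
      warning("threshold channel ", thrCh,
              " absent; acquisition threshold not applied", call. = FALSE)
    }
  }
  subThreshold <- sum(!keep)

  counts <- setNames(numeric(length(gates@priority)), gates@priority)
  unassigned <- keep
  for (g in gates@priority) {
    if (!any(unassigned)) break
    idx <- which(unassigned)
    inGate <- applyGate(table, gates@gates[[g]])[idx]
    counts[g] <- sum(inGate)
    unassigned[idx[inGate]] <- FALSE
  }
  ungated <- sum(unassigned)

  conc <- counts * dilutionFactor(table) / acquiredVolume(table)
  new("CountResult", sampleId = sampleId(table), timeH = timeH,
      counts = counts, concentrations = conc, ungated = ungated,
      subThreshold = subThreshold, totalEvents = as.numeric(n))
}

#' Gate every sample of a measurement series
#'
#' Transforms samples that are still on the linear scale, then applies
#' [countPopulations()] with the elapsed time filled in.
#'
#' @param series a [MeasurementSeries-class].
#' @param gates a [GateSet-class].
#' @return list of [CountResult-class], one per sample.
#' @export
countSeries <- function(series, gates) {
  stopifnot(is(series, "MeasurementSeries"))
  eh <- elapsedHours(series)
  lapply(seq_len(length(series)), function(i) {
    tab <- series[[i]]
    if (!isTransformed(tab)) tab <- transformEvents(tab)
    countPopulations(tab, gates, timeH = eh[i])
  })
}

#' Check that gate interiors are pairwise disjoint
#'
#' Samples a fine grid over each pair's bounding-box overlap and verifies no
#' point is strictly inside two gates (shared boundary lines are allowed;
#' priority resolves them deterministically).
#'
#' @param gates a [GateSet-class].
#' @param n grid resolution per axis (default 151).
#' @return `TRUE` if all gate interiors are disjoint.
#' @export
gatesDisjoint <- function(gates, n = 151) {
  gl <- gates@gates
  nm <- names(gl)
  for (a in seq_along(gl)) {
    for (b in seq_along(gl)) {
      if (b <= a) next
      va <- gl[[a]]@vertices; vb <- gl[[b]]@vertices
      lo <- pmax(apply(va, 2, min), apply(vb, 2, min))
      hi <- pmin(apply(va, 2, max), apply(vb, 2, max))
      if (any(lo >= hi)) next  # bounding boxes do not overlap
      gx <- seq(lo[1], hi[1], length.out = n)
      gy <- seq(lo[2], hi[2], length.out = n)
      px <- rep(gx, times = n); py <- rep(gy, each = n)
      ra <- .pipRaw(px, py, va); rb <- .pipRaw(px, py, vb)
      both <- (ra$inside & !ra$boundary) & (rb$inside & !rb$boundary)
      if (any(both)) return(FALSE)
    }
  }
  TRUE
}

#' Read / write gate definitions as YAML
#'
#' The YAML schema mirrors the [GateSet-class]: `acquisition_threshold`,
#' `threshold_channel`, `priority`, and a `gates` mapping of
#' `name: {channels: [x, y], vertices: [[x1, y1], ...]}` with vertex
#' coordinates in log10 units.
#'
#' @param path YAML file path.
#' @return `readGateSet` returns a [GateSet-class]; `writeGateSet` returns
#'   `path` invisibly.
#' @export
readGateSet <- function(path) {
  y <- yaml::read_yaml(path)
  gates <- lapply(names(y$gates), function(nm) {
    g <- y$gates[[nm]]
    verts <- do.call(rbind, lapply(g$vertices, unlist))
    Gate(nm, verts, channelX = g$channels[[1]], channelY = g$channels[[2]])
  })
  names(gates) <- names(y$gates)
  GateSet(gates, priority = unlist(y$priority),
          acquisitionThreshold = y$acquisition_threshold,
          thresholdChannel = y$threshold_channel)
}

#' @rdname readGateSet
#' @param gates a [GateSet-class].
#' @export
writeGateSet <- function(gates, path) {
  y <- list(
    acquisition_threshold = gates@acquisitionThreshold,
    threshold_channel = gates@thresholdChannel,
    priority = as.list(gates@priority),
    gates = lapply(gates@gates, function(g) list(
      channels = list(g@channelX, g@channelY),
      vertices = lapply(seq_len(nrow(g@vertices)),
                        function(i) as.list(unname(g@vertices[i, ])))
    ))
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
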