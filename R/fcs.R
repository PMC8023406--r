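## FCS 3.0/3.1 input and FCS 3.1 output.
##
## The format: a 58-byte ASCII header (version + six 8-byte segment offsets),
## a delimited TEXT segment of keyword/value pairs, and a binary DATA segment.
## We write list-mode ($MODE=L) single-precision floats ($DATATYPE=F),
## little-endian ($BYTEORD=1,2,3,4), and read F or D data in either byte
## order. Acquisition metadata travels in $VOL (nanolitres, FCS 3.1
## standard keyword) and the custom keywords #DILUTION, #TIMESTAMP,
## #SAMPLEID, #TRANSFORMED; synthetic files carry #SIMULATED.

.FCS_DELIM <- "\x0c"

#' Write an EventTable to an FCS 3.1 file
#'
#' Events are stored as little-endian single-precision floats, so the
#' numeric round trip through [readFCS()] is lossless at single precision.
#' Acquisition volume (as `$VOL`, in nanolitres), dilution factor, sample id,
#' timestamp and the log-transform flag are stored as keywords and recovered
#' on read.
#'
#' @param table an [EventTable-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readFCS()]
#' @export
writeFCS <- function(table, path) {
  stopifnot(is(table, "EventTable"))
  validObject(table)
  m <- eventMatrix(table)
  n <- nrow(m); p <- ncol(m)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n),
    "$VOL" = sprintf("%.6g", acquiredVolume(table) * 1000),
    "#DILUTION" = sprintf("%.6g", dilutionFactor(table)),
    "#SAMPLEID" = sampleId(table),
    "#TRANSFORMED" = if (isTransformed(table)) "TRUE" else "FALSE"
  )
  if (!is.na(table@timestamp))
    kw["#TIMESTAMP"] <- format(table@timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- colnames(m)[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "16777216"
  }
  extra <- table@keywords
  extra <- extra[!names(extra) %in% names(kw)]
  if (length(extra)) kw <- c(kw, vapply(extra, as.character, character(1)))

  buildText <- function(kv) {
    paste0(.FCS_DELIM,
           paste(rbind(names(kv), unname(kv)), collapse = .FCS_DELIM),
           .FCS_DELIM)
  }
  # fixed-width data offsets so the TEXT length does not depend on them
  kw["$BEGINDATA"] <- sprintf("%12d", 0L)
  kw["$ENDDATA"] <- sprintf("%12d", 0L)
  textStart <- 58L
  textLen <- nchar(buildText(kw), type = "bytes")
  textEnd <- textStart + textLen - 1L
  nbytes <- 4L * n * p
  if (n > 0) {
    dataStart <- textEnd + 1L
    dataEnd <- dataStart + nbytes - 1L
    kw["$BEGINDATA"] <- sprintf("%12d", dataStart)
    kw["$ENDDATA"] <- sprintf("%12d", dataEnd)
  } else {
    dataStart <- 0L; dataEnd <- 0L
  }
  txt <- buildText(kw)

  fmtOff <- function(x) {
    s <- sprintf("%8d", x)
    if (nchar(s) > 8) s <- sprintf("%8d", 0L)  # too large for header: rely on TEXT
    s
  }
  header <- paste0("FCS3.1    ",
                   fmtOff(textStart), fmtOff(textEnd),
                   fmtOff(dataStart), fmtOff(dataEnd),
                   fmtOff(0L), fmtOff(0L))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path, "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeChar(paste0(header, txt), con, eos = NULL)
  if (n > 0) writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file into an EventTable
#'
#' Parses the header, TEXT and DATA segments of a list-mode FCS file with
#' float (`$DATATYPE F`) or double (`D`) data in either byte order. Analyzed
#' volume and dilution are taken from keywords (`$VOL` in nanolitres,
#' `#DILUTION`); failing that, from a sidecar metadata file (`<path>.yaml`,
#' `<path>.yml` or `<path>.json` with fields `volume_uL`, `dilution`,
#' `sample_id`, `timestamp` in ISO-8601); failing that, the defaults 61 uL
#' and 1:100 are used with a warning.
#'
#' @param path path to an FCS file.
#' @param require character vector of channel names that must be present;
#'   a missing channel raises an error listing the channels found.
#' @param defaultVolumeuL,defaultDilution fallbacks when no metadata source
#'   provides them.
#' @return an [EventTable-class] object.
#' @examples
#' tab <- EventTable(cbind(`FL1-A` = runif(5, 1, 100), `FL3-A` = runif(5, 1, 100)))
#' f <- tempfile(fileext = ".fcs")
#' writeFCS(tab, f)
#' readFCS(f)
#' @export
readFCS <- function(path, require = NULL, defaultVolumeuL = 61,
                    defaultDilution = 100) {
  if (!file.exists(path)) stop("FCS file not found: ", path, call. = FALSE)
  sz <- file.size(path)
  raw <- readBin(path, "raw", n = sz)
  if (sz < 58) stop("malformed FCS header in '", path, "': file too short",
                    call. = FALSE)

  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("malformed FCS header in '", path, "': unsupported version '",
         version, "'", call. = FALSE)
  offs <- suppressWarnings(as.integer(vapply(0:5, function(i) {
    trimws(rawToChar(raw[(11 + 8 * i):(18 + 8 * i)]))
  }, character(1))))
  if (anyNA(offs[1:2]) || offs[1] <= 0 || offs[2] < offs[1])
    stop("malformed FCS header in '", path, "': bad TEXT segment offsets",
         call. = FALSE)

  txtRaw <- raw[(offs[1] + 1):(offs[2] + 1)]
  delim <- rawToChar(txtRaw[1])
  body <- rawToChar(txtRaw[-1])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) && parts[length(parts)] == "" &&
      length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  if (length(parts) %% 2 != 0)
    stop("malformed TEXT segment in '", path, "': odd keyword/value count",
         call. = FALSE)
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  keys <- ifelse(startsWith(keys, "$"), toupper(keys), keys)
  kw <- as.list(vals)
  names(kw) <- keys

  need <- function(k) {
    if (is.null(kw[[k]]))
      stop("malformed TEXT segment in '", path, "': missing keyword ", k,
           call. = FALSE)
    kw[[k]]
  }
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D"))
    stop("malformed DATA segment in '", path, "': unsupported $DATATYPE '",
         dtype, "'", call. = FALSE)
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("malformed DATA segment in '", path,
                      "': unsupported $BYTEORD '", byteord, "'", call. = FALSE)
  chans <- vapply(seq_len(p), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))

  size <- if (dtype == "F") 4L else 8L
  if (n > 0) {
    dataStart <- offs[3]
    if (is.na(dataStart) || dataStart <= 0)
      dataStart <- suppressWarnings(as.integer(trimws(need("$BEGINDATA"))))
    nbytes <- size * n * p
    if (is.na(dataStart) || dataStart + nbytes - 1 >= sz + 1)
      stop("malformed DATA segment in '", path,
           "': offsets exceed file size", call. = FALSE)
    vals <- readBin(raw[(dataStart + 1):(dataStart + nbytes)], "numeric",
                    n = n * p, size = size, endian = endian)
    m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  } else {
    m <- matrix(numeric(0), nrow = 0, ncol = p)
  }
  colnames(m) <- chans

  if (!is.null(require)) {
    missing <- setdiff(require, chans)
    if (length(missing))
      stop("required channel(s) ", paste(missing, collapse = ", "),
           " not in '", path, "'; channels found: ",
           paste(chans, collapse = ", "), call. = FALSE)
  }

  side <- .readSidecar(path)
  vol <- NULL; dil <- NULL
  if (!is.null(kw[["$VOL"]])) vol <- as.numeric(kw[["$VOL"]]) / 1000
  if (!is.null(kw[["#DILUTION"]])) dil <- as.numeric(kw[["#DILUTION"]])
  if (is.null(vol) && !is.null(side$volume_uL)) vol <- as.numeric(side$volume_uL)
  if (is.null(dil) && !is.null(side$dilution)) dil <- as.numeric(side$dilution)
  if (is.null(vol) || is.null(dil)) {
    warning("'", basename(path), "': acquisition metadata incomplete; using ",
            "defaults (volume ", defaultVolumeuL, " uL, dilution 1:",
            defaultDilution, ")", call. = FALSE)
    if (is.null(vol)) vol <- defaultVolumeuL
    if (is.null(dil)) dil <- defaultDilution
  }

  ts <- .naTime()
  if (!is.null(kw[["#TIMESTAMP"]])) {
    ts <- as.POSIXct(kw[["#TIMESTAMP"]], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  } else if (!is.null(side$timestamp)) {
    ts <- as.POSIXct(side$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  } else if (!is.null(kw[["$DATE"]]) && !is.null(kw[["$BTIM"]])) {
    ts <- as.POSIXct(paste(kw[["$DATE"]], kw[["$BTIM"]]),
                     format = "%d-%b-%Y %H:%M:%S", tz = "UTC")
  }

  sid <- kw[["#SAMPLEID"]]
  if (is.null(sid)) sid <- side$sample_id
  if (is.null(sid)) sid <- sub("\\.fcs$", "", basename(path), ignore.case = TRUE)

  transformed <- identical(kw[["#TRANSFORMED"]], "TRUE")
  keep <- kw[!names(kw) %in% c("#SAMPLEID", "#DILUTION", "#TIMESTAMP",
                               "#TRANSFORMED")]
  keep <- keep[!startsWith(names(keep), "$")]

  EventTable(m, acquiredVolumeuL = vol, dilutionFactor = dil, timestamp = ts,
             sampleId = as.character(sid), transformed = transformed,
             keywords = keep)
}

.readSidecar <- function(path) {
  for (ext in c(".yaml", ".yml", ".json")) {
    f <- paste0(path, ext)
    if (file.exists(f)) {
      if (ext == ".json") return(jsonlite::fromJSON(f))
      return(yaml::read_yaml(f))
    }
  }
  list()
}

#' Assemble FCS files into a time-ordered MeasurementSeries
#'
#' Timestamps are taken from each file's keywords (or sidecar metadata).
#' Files lacking a timestamp are assigned `t0 + (i-1) * intervalMin` in file
#' order, with a warning. Duplicate or decreasing timestamps raise an error.
#'
#' @param paths FCS file paths, in acquisition order.
#' @param t0 inoculation time (`POSIXct` or a string parseable as one).
#' @param intervalMin nominal sampling cadence in minutes (default 25).
#' @return a [MeasurementSeries-class] object.
#' @export
loadSeries <- function(paths, t0, intervalMin = 25) {
  if (length(paths) < 1) stop("at least one FCS path is required", call. = FALSE)
  if (!inherits(t0, "POSIXct")) t0 <- as.POSIXct(t0, tz = "UTC")
  tables <- lapply(paths, readFCS)
  ts <- do.call(c, lapply(tables, function(s) s@timestamp))
  if (anyNA(ts)) {
    warning("timestamp keywords missing for ", sum(is.na(ts)), " file(s); ",
            "assigning t0 + i * ", intervalMin, " min in file order",
            call. = FALSE)
    fallback <- t0 + (seq_along(tables) - 1) * intervalMin * 60
    for (i in which(is.na(ts))) tables[[i]]@timestamp <- fallback[i]
    ts <- do.call(c, lapply(tables, function(s) s@timestamp))
  }
  tn <- as.numeric(ts)
  if (anyDuplicated(tn)) stop("series error: duplicate timestamps", call. = FALSE)
  if (is.unsorted(tn, strictly = TRUE))
    stop("series error: timestamps not in increasing order", call. = FALSE)
  MeasurementSeries(tables, t0 = t0, samplingIntervalMin = intervalMin)
}
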