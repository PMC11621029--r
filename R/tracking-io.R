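#' Construct a TrackingRecording
#'
#' @param x,y,likelihood numeric N x P matrices with identical dimensions and
#'   column names (one column per body point). `likelihood` defaults to all 1.
#' @param fps frames per second.
#' @param recordingId identifier.
#' @param arena optional [ArenaGeometry-class].
#' @return A [TrackingRecording-class].
#' @export
TrackingRecording <- function(x, y, likelihood = NULL, fps = 25,
                              recordingId = "recording", arena = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    likelihood <- as.matrix(likelihood)
  }
  new("TrackingRecording", recordingId = recordingId, fps = fps,
      x = x, y = y, likelihood = likelihood, arena = arena)
}

#' Body point names of a recording
#' @param recording a [TrackingRecording-class].
#' @return Character vector of tracked point names.
#' @export
pointNames <- function(recording) colnames(recording@x)

#' Number of frames
#' @param recording a [TrackingRecording-class].
#' @export
nFrames <- function(recording) nrow(recording@x)

#' Read a pose-estimation tracking table
#'
#' Reads the CSV dialects emitted by markerless pose-estimation tools.
#' The `"dlc"` dialect has three header rows (scorer / bodyparts / coords)
#' with an x, y and optional likelihood column per body point and a leading
#' frame-index column. The `"flat"` dialect has a single header row with
#' columns `<point>_x`, `<point>_y`, `<point>_likelihood`. Missing likelihood
#' columns default to 1.0.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"dlc"` or `"flat"`.
#' @param fps frames per second to record (default 25).
#' @param recordingId identifier; defaults to the file base name.
#' @return A [TrackingRecording-class].
#' @export
readPoseTable <- function(path, dialect = c("auto", "dlc", "flat"),
                          fps = 25, recordingId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(recordingId))
    recordingId <- sub("\\.[^.]*$", "", basename(path))
  head2 <- readLines(path, n = 2L)
  if (dialect == "auto") {
    dialect <- if (grepl("^scorer|^bodyparts", head2[1]) ||
                   grepl("^bodyparts", head2[2])) "dlc" else "flat"
  }
  if (dialect == "dlc") .readDlc(path, fps, recordingId)
  else .readFlat(path, fps, recordingId)
}

.readDlc <- function(path, fps, recordingId) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 4L) stop("malformed tracking table: fewer than 4 rows")
  parts <- as.character(unlist(raw[2, -1]))
  coords <- as.character(unlist(raw[3, -1]))
  ok <- coords %in% c("x", "y", "likelihood")
  if (!all(ok))
    stop("malformed header: unknown coords entry in column ",
         which(!ok)[1] + 1L, " ('", coords[which(!ok)[1]], "')")
  vals <- as.matrix(raw[-(1:3), -1, drop = FALSE])
  storage.mode(vals) <- "double"
  pts <- unique(parts)
  n <- nrow(vals)
  getcol <- function(pt, co) {
    j <- which(parts == pt & coords == co)
    if (length(j) == 0L) return(NULL)
    if (length(j) > 1L)
      stop("malformed header: duplicated column for point '", pt,
           "' coordinate '", co, "'")
    vals[, j]
  }
  x <- y <- lk <- matrix(NA_real_, n, length(pts),
                         dimnames = list(NULL, pts))
  for (pt in pts) {
    cx <- getcol(pt, "x"); cy <- getcol(pt, "y")
    if (is.null(cx) || is.null(cy))
      stop("malformed header: point '", pt, "' lacks x or y column")
    x[, pt] <- cx; y[, pt] <- cy
    cl <- getcol(pt, "likelihood")
    lk[, pt] <- if (is.null(cl)) 1 else cl
  }
  TrackingRecording(x, y, lk, fps = fps, recordingId = recordingId)
}

.readFlat <- function(path, fps, recordingId) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  nm <- names(df)
  suf <- sub(".*_", "", nm)
  ok <- suf %in% c("x", "y", "likelihood")
  if (!all(ok))
    stop("malformed header: column '", nm[which(!ok)[1]],
         "' lacks an _x/_y/_likelihood suffix")
  pts <- unique(sub("_(x|y|likelihood)$", "", nm))
  n <- nrow(df)
  x <- y <- lk <- matrix(NA_real_, n, length(pts),
                         dimnames = list(NULL, pts))
  for (pt in pts) {
    cx <- paste0(pt, "_x"); cy <- paste0(pt, "_y")
    if (!cx %in% nm || !cy %in% nm)
      stop("malformed header: point '", pt, "' lacks x or y column")
    x[, pt] <- df[[cx]]; y[, pt] <- df[[cy]]
    cl <- paste0(pt, "_likelihood")
    lk[, pt] <- if (cl %in% nm) df[[cl]] else 1
  }
  TrackingRecording(x, y, lk, fps = fps, recordingId = recordingId)
}

#' Write a tracking table
#'
#' Emits either CSV dialect accepted by [readPoseTable()].
#'
#' @param recording a [TrackingRecording-class].
#' @param path output CSV path.
#' @param dialect `"dlc"` or `"flat"`.
#' @export
writePoseTable <- function(recording, path, dialect = c("dlc", "flat")) {
  dialect <- match.arg(dialect)
  pts <- pointNames(recording)
  n <- nFrames(recording)
  if (dialect == "flat") {
    cols <- list()
    for (pt in pts) {
      cols[[paste0(pt, "_x")]] <- recording@x[, pt]
      cols[[paste0(pt, "_y")]] <- recording@y[, pt]
      cols[[paste0(pt, "_likelihood")]] <- recording@likelihood[, pt]
    }
    utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                     row.names = FALSE)
  } else {
    p3 <- rep(pts, each = 3L)
    c3 <- rep(c("x", "y", "likelihood"), length(pts))
    body <- matrix(0, n, length(p3))
    for (j in seq_along(p3)) {
      body[, j] <- switch(c3[j],
        x = recording@x[, p3[j]],
        y = recording@y[, p3[j]],
        likelihood = recording@likelihood[, p3[j]])
    }
    lines <- c(
      paste(c("scorer", rep("bflow", length(p3))), collapse = ","),
      paste(c("bodyparts", p3), collapse = ","),
      paste(c("coords", c3), collapse = ","),
      vapply(seq_len(n), function(i)
        paste(c(i - 1L, format(body[i, ], trim = TRUE, digits = 15)),
              collapse = ","), character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Infer arena geometry from tracked corner points
#'
#' The arena polygon vertices are the per-corner median x/y positions over
#' all frames; the pixel-to-centimeter factor is the square root of the
#' ratio between the polygon area in pixels squared and the measured arena
#' size in centimeters squared.
#'
#' @param recording a [TrackingRecording-class].
#' @param cornerNames tracked point names of the arena corners, in boundary
#'   order.
#' @param realSizeCm2 measured arena area in cm^2.
#' @param centerScale linear scale of the default center zone relative to
#'   the arena polygon (default 0.5). Set `NA` to skip zone creation.
#' @param existenceScale scale of the existence polygon (default 1.3).
#' @param zones optional named list of zone polygons overriding the default
#'   center/periphery pair.
#' @return An [ArenaGeometry-class].
#' @export
inferArena <- function(recording, cornerNames, realSizeCm2,
                       centerScale = 0.5, existenceScale = 1.3,
                       zones = NULL) {
  if (length(cornerNames) < 3L)
    stop("need at least 3 corner points to define an arena")
  missing <- setdiff(cornerNames, pointNames(recording))
  if (length(missing))
    stop("corner points not tracked: ", paste(missing, collapse = ", "))
  if (realSizeCm2 <= 0) stop("realSizeCm2 must be positive")
  corners <- cbind(
    x = apply(recording@x[, cornerNames, drop = FALSE], 2, stats::median,
              na.rm = TRUE),
    y = apply(recording@y[, cornerNames, drop = FALSE], 2, stats::median,
              na.rm = TRUE))
  rownames(corners) <- cornerNames
  areaPx <- polygonArea(corners)
  if (areaPx <= 0) stop("corner polygon has zero area")
  pxPerCm <- sqrt(areaPx / realSizeCm2)
  if (is.null(zones) && !is.na(centerScale)) {
    zones <- list(center = scalePolygon(corners, centerScale),
                  periphery = corners)
  }
  if (is.null(zones)) zones <- list()
  new("ArenaGeometry", corners = corners, zones = zones,
      pxPerCm = pxPerCm, existenceScale = existenceScale)
}

#' Existence polygon of an arena
#'
#' The corner polygon scaled about its centroid by the arena's
#' `existenceScale`; tracked positions outside it are treated as tracking
#' failures.
#'
#' @param arena an [ArenaGeometry-class].
#' @export
existencePolygon <- function(arena) {
  scalePolygon(arena@corners, arena@existenceScale)
}

#' Clean a recording and compute kinematics
#'
#' Frames where a point's likelihood falls below `likelihoodThreshold`, or
#' where its position lies outside the existence polygon, are masked and
#' refilled by linear interpolation in time (leading/trailing gaps take the
#' nearest valid value). Frames that pass both filters are never modified.
#' Per-point speed (cm/s) and acceleration (cm/s^2) are then computed by
#' first and second finite differences of the cleaned positions, with the
#' leading frame(s) padded by replication.
#'
#' @param recording a [TrackingRecording-class] with an inferred arena.
#' @param likelihoodThreshold minimum tracking likelihood (default 0.95).
#' @param existenceScale overrides the arena's existence scale if given.
#' @return The cleaned [TrackingRecording-class] with kinematics.
#' @export
preprocessRecording <- function(recording, likelihoodThreshold = 0.95,
                                existenceScale = NULL) {
  arena <- recording@arena
  if (is.null(arena)) stop("arena must be inferred before preprocessing")
  if (!is.null(existenceScale)) arena@existenceScale <- existenceScale
  exPoly <- existencePolygon(arena)
  pts <- pointNames(recording)
  x <- recording@x; y <- recording@y; lk <- recording@likelihood
  for (pt in pts) {
    pos <- cbind(x[, pt], y[, pt])
    inside <- .pointsInPolygon(exPoly, pos)
    bad <- is.na(lk[, pt]) | lk[, pt] < likelihoodThreshold | !inside |
      is.na(pos[, 1]) | is.na(pos[, 2])
    if (all(bad))
      stop("point '", pt, "' has zero valid frames; cannot interpolate")
    x[, pt] <- .fillSeries(x[, pt], bad)
    y[, pt] <- .fillSeries(y[, pt], bad)
  }
  fps <- recording@fps
  pxPerCm <- arena@pxPerCm
  n <- nrow(x)
  speed <- acc <- matrix(0, n, length(pts), dimnames = list(NULL, pts))
  for (pt in pts) {
    d <- sqrt(diff(x[, pt])^2 + diff(y[, pt])^2) / pxPerCm * fps
    sp <- c(d[1], d)
    a <- diff(sp) * fps
    speed[, pt] <- sp
    acc[, pt] <- c(a[1], a)
  }
  new("TrackingRecording", recordingId = recording@recordingId,
      fps = fps, x = x, y = y, likelihood = lk, arena = arena,
      speed = speed, acceleration = acc)
}

## Per-frame zone membership of a point; zones are matched in list order so
## an inner zone listed first takes priority over an enclosing one. Frames
## in no zone get "outside".
.zoneMembership <- function(arena, pos) {
  member <- rep("outside", nrow(pos))
  for (zn in rev(names(arena@zones))) {
    inz <- .pointsInPolygon(arena@zones[[zn]], pos)
    member[inz] <- zn
  }
  ## rev() above means earlier-listed zones overwrite later ones
  member
}

#' Classical behavioral readouts
#'
#' Computes the standard tracking-based measures: total distance moved (cm)
#' of a reference point, time spent in each arena zone (s), and counts of
#' zone-to-zone transitions.
#'
#' @param recording a preprocessed [TrackingRecording-class].
#' @param referencePoint body point used for all measures
#'   (default "bodycentre").
#' @return A list with `distanceMoved`, `timeInZone` (named numeric, seconds;
#'   includes an `"outside"` entry when frames fall in no zone) and
#'   `zoneTransitions` (named counts, `"from->to"`).
#' @export
classicalReadouts <- function(recording, referencePoint = "bodycentre") {
  if (!referencePoint %in% pointNames(recording))
    stop("unknown reference point: ", referencePoint)
  arena <- recording@arena
  if (is.null(arena)) stop("arena must be inferred first")
  pos <- cbind(recording@x[, referencePoint], recording@y[, referencePoint])
  distanceMoved <- sum(sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)) /
    arena@pxPerCm
  member <- .zoneMembership(arena, pos)
  timeInZone <- table(factor(member,
    levels = unique(c(names(arena@zones), "outside")))) / recording@fps
  timeInZone <- stats::setNames(as.numeric(timeInZone), names(timeInZone))
  r <- rle(member)$values
  zoneTransitions <- integer(0)
  if (length(r) > 1L) {
    lab <- paste0(r[-length(r)], "->", r[-1])
    zoneTransitions <- c(table(lab))
  }
  list(distanceMoved = distanceMoved, timeInZone = timeInZone,
       zoneTransitions = zoneTransitions)
}
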