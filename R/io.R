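# Motion-capture file formats (OpenSim dialect): TRC marker trajectories and
# MOT/STO time-series tables.  Tab-delimited, `endheader` sentinel for MOT;
# TRC positions are written in millimeters (format convention) while all
# in-memory values are meters.  All writes are atomic (temp-then-rename).

write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("could not write file: ", path)
  invisible(path)
}

num_fmt <- function(x, digits = 6) {
  out <- formatC(x, format = "f", digits = digits)
  out[!is.finite(x)] <- ""
  out
}

#' Construct a marker trajectory series
#'
#' @param time Time stamps (s), uniformly sampled.
#' @param positions A `3 x M x T` array of world positions in meters (marker
#'   names on dimension 2), or a list of per-frame `3 x M` named matrices.
#' @param names Marker names (taken from `positions` dimnames if omitted).
#' @param rate Sample rate (Hz); inferred from `time` when omitted.
#' @return A `marker_series` object.  Missing observations are NA.
#' @export
marker_series <- function(time, positions, names = NULL, rate = NULL) {
  if (is.list(positions)) {
    positions <- array(unlist(positions),
                       dim = c(3, ncol(positions[[1]]), length(positions)),
                       dimnames = list(NULL, colnames(positions[[1]]), NULL))
  }
  if (is.null(names)) names <- dimnames(positions)[[2]]
  if (is.null(names)) stop("marker names are required")
  if (anyDuplicated(names)) stop("duplicate marker names in series")
  dimnames(positions) <- list(NULL, names, NULL)
  time <- as.numeric(time)
  if (dim(positions)[3] != length(time))
    stop("time length does not match number of frames")
  if (length(time) > 2) {
    dt <- diff(time)
    if (max(abs(dt - mean(dt))) > 1e-6)
      stop("marker series must be uniformly sampled (within 1e-6 s)")
  }
  if (is.null(rate)) rate <- if (length(time) > 1) 1 / mean(diff(time)) else NA_real_
  structure(list(time = time, pos = positions, names = names, rate = rate),
            class = "marker_series")
}

#' Number of frames in a series or trajectory
#' @param x A `marker_series` or `coordinate_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "marker_series")) dim(x$pos)[3] else nrow(x$q)
}

#' Extract one frame of a marker series as a 3 x M named matrix
#' @param series A `marker_series`.
#' @param f Frame index (1-based).
#' @return 3 x M matrix of world positions (m), columns named.
#' @export
frame_markers <- function(series, f) {
  m <- series$pos[, , f, drop = FALSE]
  dim(m) <- dim(series$pos)[1:2]
  colnames(m) <- series$names
  m
}

#' Time-average marker positions over a series
#' @param series A `marker_series`.
#' @return 3 x M named matrix of mean positions (NA components ignored).
#' @export
average_markers <- function(series) {
  out <- apply(series$pos, c(1, 2), mean, na.rm = TRUE)
  colnames(out) <- series$names
  out
}

#' @export
print.marker_series <- function(x, ...) {
  cat("<marker_series> ", n_frames(x), " frames x ", length(x$names),
      " markers @ ", format(x$rate, digits = 5), " Hz\n", sep = "")
  invisible(x)
}

#' Write a marker series as a TRC file
#'
#' Positions are converted to the units declared in the header (mm by
#' default); missing observations become blank cells.  Frame numbers are
#' written 1-based per the format convention.
#'
#' @param series A `marker_series`.
#' @param path Output path.
#' @param units `"mm"` or `"m"`.
#' @return `path`, invisibly.
#' @export
write_trc <- function(series, path, units = "mm") {
  scale <- if (units == "mm") 1000 else 1
  tN <- n_frames(series); M <- length(series$names)
  rate <- series$rate
  l1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  l2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
              "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t")
  l3 <- paste(num_fmt(rate, 1), num_fmt(rate, 1), tN, M, units,
              num_fmt(rate, 1), 1, tN, sep = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(series$names, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", as.vector(t(outer(seq_len(M), c("X", "Y", "Z"),
                                          function(i, a) paste0(a, i))))),
              collapse = "\t")
  rows <- vapply(seq_len(tN), function(f) {
    vals <- as.vector(frame_markers(series, f)) * scale
    paste(c(f, num_fmt(series$time[f], 6), num_fmt(vals, 6)), collapse = "\t")
  }, character(1))
  write_lines_atomic(c(l1, l2, l3, l4, l5, rows), path)
}

#' Read a TRC file
#'
#' @param path Path to a TRC file (two header lines, a column-header pair,
#'   tab-delimited frames).  The `Units` header (mm or m) is honored; blank
#'   cells are parsed as missing markers (NA).
#' @return A `marker_series` in meters.
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop("TRC file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5)
    stop("malformed TRC file '", path, "': fewer than 5 lines")
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  if (length(vals) < length(keys))
    vals <- c(vals, rep("", length(keys) - length(vals)))
  hdr <- stats::setNames(as.list(vals), keys)
  if (is.null(hdr$NumMarkers) || is.null(hdr$Units))
    stop("malformed TRC header at line 2-3 of '", path,
         "': need NumMarkers and Units")
  M <- as.integer(hdr$NumMarkers)
  scale <- if (trimws(hdr$Units) == "mm") 1e-3 else 1
  cols <- strsplit(lines[4], "\t")[[1]]
  if (length(cols) < 2 || cols[1] != "Frame#")
    stop("malformed TRC column header at line 4 of '", path, "'")
  names_raw <- cols[-(1:2)]
  mnames <- names_raw[names_raw != ""]
  if (length(mnames) != M)
    stop("TRC header of '", path, "' declares ", M, " markers but line 4 names ",
         length(mnames))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  tN <- length(data_lines)
  time <- numeric(tN)
  pos <- array(NA_real_, c(3, M, tN), dimnames = list(NULL, mnames, NULL))
  for (f in seq_len(tN)) {
    cells <- strsplit(data_lines[f], "\t")[[1]]
    if (length(cells) < 2)
      stop("malformed TRC data at line ", f + 5, " of '", path, "'")
    expected <- 2 + 3 * M
    if (length(cells) > expected)
      stop("inconsistent column count at line ", f + 5, " of '", path, "'")
    cells <- c(cells, rep("", expected - length(cells)))
    time[f] <- as.numeric(cells[2])
    v <- suppressWarnings(as.numeric(cells[-(1:2)]))
    pos[, , f] <- matrix(v, 3, M) * scale
  }
  marker_series(time, pos)
}

#' Write a time-series table as a MOT/STO file
#'
#' @param table Data frame whose first column is `time`.
#' @param path Output path.
#' @param name Header name field.
#' @param in_degrees Value written to the `inDegrees` header line.
#' @return `path`, invisibly.
#' @export
write_mot <- function(table, path, name = "gaitreg", in_degrees = FALSE) {
  stopifnot(names(table)[1] == "time")
  hdr <- c(name,
           "version=1",
           paste0("nRows=", nrow(table)),
           paste0("nColumns=", ncol(table)),
           paste0("inDegrees=", if (in_degrees) "yes" else "no"),
           "endheader",
           paste(names(table), collapse = "\t"))
  rows <- apply(table, 1, function(r) paste(num_fmt(as.numeric(r), 8), collapse = "\t"))
  write_lines_atomic(c(hdr, rows), path)
}

#' Read a MOT/STO file
#'
#' @param path Path to a MOT/STO file (header terminated by the `endheader`
#'   sentinel, then a tab-delimited table with `time` first).
#' @return List with `data` (data frame), `in_degrees` (logical), `name`.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("MOT file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0)
    stop("malformed MOT file '", path, "': missing 'endheader' sentinel")
  end <- end[1]
  hdr <- lines[seq_len(end - 1)]
  in_degrees <- any(grepl("^inDegrees\\s*=\\s*yes", hdr, ignore.case = TRUE))
  nm <- if (end >= 2) hdr[1] else ""
  cols <- strsplit(lines[end + 1], "\t")[[1]]
  body <- lines[-(seq_len(end + 1))]
  body <- body[trimws(body) != ""]
  mat <- do.call(rbind, lapply(body, function(l)
    suppressWarnings(as.numeric(strsplit(l, "\t")[[1]]))))
  df <- as.data.frame(mat)
  names(df) <- cols
  list(data = df, in_degrees = in_degrees, name = nm)
}

#' Write a coordinate trajectory as MOT (angles in degrees)
#'
#' Rotational coordinates are converted to degrees at this boundary; the
#' model tells which columns are rotational.
#'
#' @param traj A `coordinate_trajectory`.
#' @param model The `kinematic_model` the columns belong to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordinates_mot <- function(traj, model, path) {
  qd <- traj$q
  rot <- model$coords$type == "rotation"
  qd[, rot] <- qd[, rot] * 180 / pi
  write_mot(data.frame(time = traj$time, qd, check.names = FALSE), path,
            name = "coordinates", in_degrees = TRUE)
}

#' Read a coordinate trajectory from MOT (convert to radians)
#'
#' @param path MOT file path.
#' @param model The target `kinematic_model`; rotational columns are
#'   converted from degrees to radians when the header declares
#'   `inDegrees=yes`.
#' @return A `coordinate_trajectory` (columns restricted to model
#'   coordinates that appear in the file).
#' @export
read_coordinates_mot <- function(path, model) {
  m <- read_mot(path)
  df <- m$data
  keep <- intersect(coord_names(model), names(df))
  q <- as.matrix(df[, keep, drop = FALSE])
  if (m$in_degrees) {
    rot <- model$coords$type[match(keep, model$coords$name)] == "rotation"
    q[, rot] <- q[, rot] * pi / 180
  }
  coordinate_trajectory(df$time, q)
}
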