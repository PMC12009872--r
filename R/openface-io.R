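#' Read an OpenFace-dialect CSV into a landmark series
#'
#' Accepts the standard OpenFace per-frame output headers (`timestamp`,
#' `confidence`, `success`, `x_0`..`x_67`, `y_0`..`y_67`, `AU01_r`..`AU45_r`,
#' `AU01_c`..`AU45_c`), tolerating the leading whitespace OpenFace emits in
#' its header row. Frames flagged as tracking failures (success = 0 or
#' confidence < 0.75) are repaired by linear interpolation of coordinates
#' from neighboring good frames when they make up less than 10% of the
#' recording; otherwise the recording is rejected.
#'
#' @param path CSV file path.
#' @param participant_id,task,group recording metadata (see
#'   [landmark_series()]).
#' @param repair_frames apply the low-quality-frame interpolation policy.
#' @return a validated [landmark_series()].
#' @export
read_openface_csv <- function(path, participant_id, task, group,
                              repair_frames = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  if (nrow(df) == 0L)
    stop("empty input: no data rows in ", path, call. = FALSE)

  xcols <- paste0("x_", 0:67)
  ycols <- paste0("y_", 0:67)
  need <- c("timestamp", xcols, ycols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- grep("^[xy]_\\d+$", names(df), value = TRUE)
  bad <- setdiff(extra, c(xcols, ycols))
  if (length(bad))
    stop("format error: unexpected landmark column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)

  pcols <- paste0("AU", AU_PRESENCE_IDS, "_c")
  icols <- paste0("AU", AU_INTENSITY_IDS, "_r")
  missing_au <- setdiff(c(pcols, icols), names(df))
  if (length(missing_au))
    stop("format error: missing AU column(s) ",
         paste(missing_au, collapse = ", "), call. = FALSE)

  ts <- df$timestamp
  if (nrow(df) > 1L && any(diff(ts) <= 0))
    stop("ordering error: timestamps not strictly increasing", call. = FALSE)

  nf <- nrow(df)
  coords <- array(NA_real_, c(nf, 68L, 2L))
  coords[, , 1] <- as.matrix(df[xcols])
  coords[, , 2] <- as.matrix(df[ycols])
  conf <- if ("confidence" %in% names(df)) df$confidence else rep(1, nf)
  succ <- if ("success" %in% names(df)) df$success else rep(1L, nf)

  low <- succ == 0L | conf < 0.75
  if (repair_frames && any(low)) {
    if (mean(low) >= 0.10)
      stop(sprintf("data quality: %d/%d frames unusable (>= 10%%)",
                   sum(low), nf), call. = FALSE)
    coords <- interpolate_frames(coords, ts, low)
  }

  landmark_series(participant_id, task, group, ts, coords,
                  confidence = conf, success = succ,
                  au_presence = as.matrix(df[pcols]),
                  au_intensity = as.matrix(df[icols]),
                  check_duration = TRUE)
}

# Linear interpolation of flagged frames per landmark/axis; flagged frames
# at the ends carry the nearest good frame forward/backward.
interpolate_frames <- function(coords, ts, low) {
  good <- which(!low)
  if (length(good) < 2L) stop("data quality: too few usable frames", call. = FALSE)
  for (j in 1:68) for (ax in 1:2) {
    v <- coords[, j, ax]
    coords[, j, ax] <- stats::approx(ts[good], v[good], xout = ts,
                                     rule = 2)$y
  }
  coords
}

#' Write a landmark series as an OpenFace-dialect CSV
#'
#' Emits the column layout [read_openface_csv()] expects, so generated
#' recordings round-trip through the reader unchanged.
#'
#' @param series a [landmark_series()].
#' @param path output file path.
#' @export
write_openface_csv <- function(series, path) {
  stopifnot(inherits(series, "landmark_series"))
  nf <- nframes(series)
  df <- data.frame(frame = seq_len(nf) - 1L,
                   timestamp = series$timestamps,
                   confidence = series$confidence,
                   success = series$success)
  xs <- as.data.frame(matrix(series$coords[, , 1], nrow = nf))
  names(xs) <- paste0("x_", 0:67)
  ys <- as.data.frame(matrix(series$coords[, , 2], nrow = nf))
  names(ys) <- paste0("y_", 0:67)
  ip <- as.data.frame(series$au_intensity)
  names(ip) <- paste0("AU", AU_INTENSITY_IDS, "_r")
  pp <- as.data.frame(series$au_presence)
  names(pp) <- paste0("AU", AU_PRESENCE_IDS, "_c")
  out <- cbind(df, xs, ys, ip, pp)
  write_table(out, path)
  invisible(path)
}

#' Write a pipeline artifact as a plain CSV table
#'
#' All tabular artifacts are written comma-delimited UTF-8 with a single
#' header row and floats at 9 significant digits, so that write-then-read
#' round-trips values within float-printing tolerance.
#'
#' @param records a data frame or an object with an `as.data.frame` method
#'   (e.g. an [pairwise_emd()] matrix).
#' @param path output file path.
#' @export
write_table <- function(records, path) {
  UseMethod("write_table")
}

#' @export
write_table.default <- function(records, path) {
  df <- as.data.frame(records)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.emd_matrix <- function(records, path) {
  m <- unclass(records)
  df <- data.frame(label = rownames(m), signif(m, 9), check.names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read back an EMD matrix written by [write_table()]
#' @param path CSV path produced by `write_table` on an `emd_matrix`.
#' @export
read_emd_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = "emd_matrix")
}
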