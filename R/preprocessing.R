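#' Trigeminal parcellation of the 68-point face grid
#'
#' Divides the landmark indices 0--67 into three subregions mirroring the
#' trigeminal nerve's innervation territories: V1 (ophthalmic: eyebrows and
#' eyes, 26 points), V2 (maxillary: nose and upper mouth, 17 points) and
#' V3 (mandibular: jawline and lower mouth, 25 points).
#'
#' @return a `region_partition`: a named list of ascending 0-based landmark
#'   index vectors for V1, V2 and V3.
#' @export
trigeminal_partition <- function() {
  p <- list(
    V1 = c(17:30, 36:47),
    V2 = c(31:35, 48:54, 60:64),
    V3 = c(0:16, 55:59, 65:67))
  structure(lapply(p, as.integer), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>\n")
  for (r in names(x))
    cat(sprintf("  %s: %d landmarks (%s)\n", r, length(x[[r]]),
                paste(collapse_ranges(x[[r]]), collapse = " ")))
  invisible(x)
}

collapse_ranges <- function(idx) {
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else paste0(r[1], ":", r[length(r)])
  }, character(1))
}

validate_partition <- function(partition) {
  stopifnot(is.list(partition), all(c("V1", "V2", "V3") %in% names(partition)))
  all_idx <- sort(unlist(partition, use.names = FALSE))
  if (!identical(as.integer(all_idx), 0:67))
    stop("partition must cover landmark indices 0..67 exactly once",
         call. = FALSE)
  invisible(partition)
}

#' Per-frame z-score normalization of landmark coordinates
#'
#' For each frame, each coordinate axis is centered at the frame mean and
#' scaled by the frame (population) standard deviation over the 68 points,
#' producing a series of normalized faces with per-frame mean 0 and sd 1 on
#' each axis. This removes translation along the optical axis and overall
#' face scale; it does not compensate head rotation or lens distortion.
#'
#' @param series a [landmark_series()].
#' @return the series with normalized coordinates, classed additionally as
#'   `normalized_series`.
#' @export
zscore_frames <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  coords <- series$coords
  for (ax in 1:2) {
    m <- matrix(coords[, , ax], nrow = nframes(series))
    mu <- rowMeans(m)
    sd_pop <- sqrt(rowMeans((m - mu)^2))
    if (any(sd_pop < 1e-12))
      stop("degenerate frame: zero coordinate variance on axis ",
           c("x", "y")[ax], " at frame ",
           which(sd_pop < 1e-12)[1], call. = FALSE)
    coords[, , ax] <- (m - mu) / sd_pop
  }
  series$coords <- coords
  class(series) <- unique(c("normalized_series", class(series)))
  series
}

#' Interpolating cubic-spline representation of a coordinate trajectory
#'
#' Fits an interpolating cubic spline through the samples and returns a
#' twice-differentiable curve queryable for value and first derivative at
#' arbitrary times in range.
#'
#' @param t strictly increasing sample times (seconds), length >= 4.
#' @param x coordinate samples at `t`.
#' @return a `smooth_trajectory`: list with functions `value(t)` and
#'   `deriv(t)`.
#' @export
smooth_trajectory <- function(t, x) {
  if (length(t) < 4L)
    stop("insufficient data: need at least 4 samples for spline smoothing",
         call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  f <- stats::splinefun(t, x, method = "fmm")
  structure(list(value = function(tt) f(tt),
                 deriv = function(tt) f(tt, deriv = 1),
                 range = range(t)),
            class = "smooth_trajectory")
}

#' Per-landmark speed from spline-differentiated normalized trajectories
#'
#' Each landmark's z-scored x(t) and y(t) trajectories are represented as
#' interpolating cubic splines, differentiated analytically, and evaluated
#' at the original frame timestamps; speed is the Euclidean norm
#' sqrt(zx'(t)^2 + zy'(t)^2), so every landmark contributes exactly F speed
#' samples in normalized units per second.
#'
#' @param series a normalized series from [zscore_frames()].
#' @param partition a [trigeminal_partition()] (recorded for downstream
#'   gluing).
#' @return a `speed_series`: F x 68 matrix of non-negative speeds with the
#'   timestamps and partition attached as attributes.
#' @export
compute_speed <- function(series, partition = trigeminal_partition()) {
  if (!inherits(series, "normalized_series"))
    stop("compute_speed expects a z-scored series (see zscore_frames)",
         call. = FALSE)
  validate_partition(partition)
  ts <- series$timestamps
  nf <- length(ts)
  sp <- matrix(NA_real_, nf, 68L)
  for (j in 1:68) {
    dx <- smooth_trajectory(ts, series$coords[, j, 1])$deriv(ts)
    dy <- smooth_trajectory(ts, series$coords[, j, 2])$deriv(ts)
    sp[, j] <- sqrt(dx^2 + dy^2)
  }
  colnames(sp) <- paste0("p", 0:67)
  structure(sp, timestamps = ts, partition = partition,
            participant_id = series$participant_id, task = series$task,
            group = series$group, class = c("speed_series", "matrix", "array"))
}
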