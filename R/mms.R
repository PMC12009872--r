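#' Glue per-landmark speed segments of a face region
#'
#' Concatenates the speed sample sequences of a region's landmarks in a
#' fixed ascending landmark-index order. The resulting series has
#' |region| x F samples; its peak-amplitude distribution is invariant to
#' the glue order (only the order of samples changes, not their multiset).
#'
#' @param speeds a `speed_series` from [compute_speed()].
#' @param region `"V1"`, `"V2"` or `"V3"`.
#' @param partition a region partition; defaults to the one recorded on
#'   `speeds`.
#' @param order optional permutation of the region's landmark indices
#'   (0-based) overriding the default ascending glue order.
#' @return a `glued_speed` numeric vector with `region`, `landmarks` and
#'   `n_frames` attributes.
#' @export
glue_region <- function(speeds, region, partition = attr(speeds, "partition"),
                        order = NULL) {
  stopifnot(inherits(speeds, "speed_series"))
  validate_partition(partition)
  region <- match.arg(region, names(partition))
  idx <- partition[[region]]
  if (!is.null(order)) {
    if (!setequal(order, idx))
      stop("glue order must be a permutation of the region's landmarks",
           call. = FALSE)
    idx <- as.integer(order)
  }
  cols <- idx + 1L
  if (any(cols < 1L | cols > ncol(speeds)))
    stop("incomplete region: landmark out of range", call. = FALSE)
  m <- unclass(speeds)[, cols, drop = FALSE]
  if (anyNA(m)) stop("incomplete region: missing speed samples", call. = FALSE)
  structure(as.vector(m), region = region, landmarks = idx,
            n_frames = nrow(speeds), class = "glued_speed")
}

#' Strict local maxima of a sample sequence
#'
#' Returns all strict interior local maxima (`s[i-1] < s[i] > s[i+1]`).
#' A plateau of equal values flanked by strictly lower values counts as a
#' single peak at the first plateau index; series endpoints are never
#' peaks.
#'
#' @param series numeric vector, length >= 3.
#' @return a `peak_set`: list with `indices` (1-based positions in the
#'   series) and `amplitudes`.
#' @export
extract_peaks <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 3L)
    stop("insufficient data: need at least 3 samples to find peaks",
         call. = FALSE)
  r <- rle(series)
  k <- length(r$values)
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  is_peak <- logical(k)
  if (k >= 3L) {
    inner <- 2:(k - 1)
    is_peak[inner] <- r$values[inner] > r$values[inner - 1] &
      r$values[inner] > r$values[inner + 1]
  }
  structure(list(indices = first_idx[is_peak],
                 amplitudes = r$values[is_peak]),
            class = "peak_set")
}

# Local minima under the same run-compression convention: strict interior
# minima, plus a boundary sample strictly lower than its single neighbor.
# A plateau yields one minimum at its first index.
extract_minima <- function(series) {
  series <- as.numeric(series)
  r <- rle(series)
  k <- length(r$values)
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  is_min <- logical(k)
  if (k >= 2L) {
    is_min[1] <- r$values[1] < r$values[2]
    is_min[k] <- r$values[k] < r$values[k - 1]
  }
  if (k >= 3L) {
    inner <- 2:(k - 1)
    is_min[inner] <- r$values[inner] < r$values[inner - 1] &
      r$values[inner] < r$values[inner + 1]
  }
  list(indices = first_idx[is_min], values = r$values[is_min])
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks; amplitude range [%.4g, %.4g]\n",
              length(x$indices),
              if (length(x$amplitudes)) min(x$amplitudes) else NA,
              if (length(x$amplitudes)) max(x$amplitudes) else NA))
  invisible(x)
}

#' Empirical Gamma mean of speed-peak amplitudes
#'
#' Fits the two-parameter Gamma family to the peak amplitudes by maximum
#' likelihood and returns the fitted mean a*b — the region's empirical
#' Gamma mean used as the reference level for micro-movement deviations.
#'
#' @param peaks a [extract_peaks()] result (or a numeric vector of
#'   amplitudes).
#' @param min_peaks statistical-power floor on the number of positive
#'   amplitudes (default 30).
#' @return scalar Gamma mean, with the full [fit_gamma_mle()] signature
#'   attached as attribute `signature`.
#' @export
empirical_gamma_mean <- function(peaks, min_peaks = 30L) {
  amps <- if (inherits(peaks, "peak_set")) peaks$amplitudes else as.numeric(peaks)
  nonpos <- sum(amps <= 0)
  if (length(amps) && nonpos / length(amps) > 0.05)
    stop(sprintf("data quality: %d/%d non-positive peak amplitudes (> 5%%)",
                 nonpos, length(amps)), call. = FALSE)
  amps <- amps[amps > 0]
  if (length(amps) < min_peaks)
    stop(sprintf("insufficient data: %d positive peaks < floor of %d",
                 length(amps), min_peaks), call. = FALSE)
  sig <- fit_gamma_mle(amps, min_n = min_peaks)
  structure(sig$mean, signature = sig)
}

#' Absolute deviations from the empirical Gamma mean
#'
#' @param glued a [glue_region()] series (or numeric vector).
#' @param gamma_mu positive scalar, the region's empirical Gamma mean.
#' @return a `deviation_series` numeric vector, same length as `glued`.
#' @export
deviation_series <- function(glued, gamma_mu) {
  if (!is.numeric(gamma_mu) || length(gamma_mu) != 1L || gamma_mu <= 0)
    stop("gamma_mu must be a positive scalar", call. = FALSE)
  structure(abs(as.numeric(glued) - as.numeric(gamma_mu)),
            gamma_mu = as.numeric(gamma_mu),
            region = attr(glued, "region"), class = "deviation_series")
}

#' Standardize deviation peaks into micro-movement spikes (MMS)
#'
#' Each strict local maximum P of the deviation series is scaled by its
#' neighborhood: spike = P / (P + (m_left + m_right)/2), where m_left and
#' m_right are the values of the nearest local minima flanking the peak.
#' A peak with only one flanking minimum (at a series boundary) uses that
#' single minimum. The scaling removes amplitude units, bounding every
#' spike in (0, 1]; spikes reach 1 exactly when both flanking minima are 0.
#'
#' @param dev a [deviation_series()] (or numeric vector of non-negative
#'   deviations).
#' @return an `mms_series`: list with `spike_values` in (0,1\],
#'   `positions` (peak indices) and `full_series` (spikes at peak
#'   positions, zeros elsewhere, same length as `dev`).
#' @export
mms_standardize <- function(dev) {
  v <- as.numeric(dev)
  pk <- extract_peaks(v)
  mins <- extract_minima(v)
  # Nearest flanking minima: peaks and minima strictly alternate in index,
  # so findInterval locates the last minimum before each peak.
  npos <- findInterval(pk$indices, mins$indices)
  m_left <- ifelse(npos >= 1L, mins$values[pmax(npos, 1L)], NA_real_)
  m_right <- ifelse(npos < length(mins$indices),
                    mins$values[pmin(npos + 1L, length(mins$indices))],
                    NA_real_)
  avg <- rowMeans(cbind(m_left, m_right), na.rm = TRUE)
  avg[is.nan(avg)] <- 0
  denom <- pk$amplitudes + avg
  if (any(denom == 0))
    stop("undefined spike: peak and flanking minima all zero", call. = FALSE)
  spikes <- pk$amplitudes / denom
  full <- numeric(length(v))
  full[pk$indices] <- spikes
  structure(list(spike_values = spikes, positions = pk$indices,
                 full_series = full, region = attr(dev, "region")),
            class = "mms_series")
}

#' @export
print.mms_series <- function(x, ...) {
  cat(sprintf("<mms_series> %d spikes over %d samples; spike range [%.3f, %.3f]\n",
              length(x$spike_values), length(x$full_series),
              if (length(x$spike_values)) min(x$spike_values) else NA,
              if (length(x$spike_values)) max(x$spike_values) else NA))
  invisible(x)
}
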