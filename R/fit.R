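#' Fit micro-movement-spike Gamma signatures to a landmark recording
#'
#' The package's central model fit. The recording is z-scored per frame,
#' spline-differentiated into per-landmark speeds, and analyzed per
#' trigeminal region: the region's speed segments are glued in fixed
#' landmark order; speed-amplitude peaks are extracted and their Gamma MLE
#' fit gives the empirical Gamma mean a*b; absolute deviations from that
#' mean are standardized into micro-movement spikes (MMS) in (0, 1\]; and
#' the Gamma family is fitted by maximum likelihood to the MMS peak
#' values, yielding the region's stochastic signature (shape, scale = NSR,
#' skewness 2/sqrt(shape)) with 95% confidence intervals.
#'
#' @param series a [landmark_series()] (raw pixel coordinates).
#' @param partition region partition (default [trigeminal_partition()]).
#' @param min_peaks statistical-power floor on peak counts for the Gamma
#'   fits (default 30).
#' @return an `mms_fit` object: per-region components `glued`,
#'   `speed_peaks`, `gamma_mu`, `mu_signature`, `mms`, `signature`, plus
#'   cohort-level summaries `nsr_vector`, `skew_vector`, `nsr_norm`,
#'   `skew_norm`.
#' @seealso [summary.mms_fit()], [coef.mms_fit()], [plot.mms_fit()],
#'   [simulate.mms_fit()]
#' @examples
#' rec <- generate_recording(group_profile("TD"), seed = 7)
#' fit <- mms_fit(rec)
#' coef(fit)
#' @export
mms_fit <- function(series, partition = trigeminal_partition(),
                    min_peaks = 30L) {
  stopifnot(inherits(series, "landmark_series"))
  validate_partition(partition)
  speeds <- compute_speed(zscore_frames(series), partition)
  regions <- lapply(names(partition), function(r) {
    glued <- glue_region(speeds, r, partition)
    pk <- extract_peaks(glued)
    mu <- empirical_gamma_mean(pk, min_peaks = min_peaks)
    dev <- deviation_series(glued, mu)
    mms <- mms_standardize(dev)
    sig <- fit_gamma_mle(mms$spike_values, min_n = min_peaks)
    list(region = r, glued = glued, speed_peaks = pk,
         gamma_mu = as.numeric(mu), mu_signature = attr(mu, "signature"),
         mms = mms, signature = sig)
  })
  names(regions) <- names(partition)
  sigs <- lapply(regions, `[[`, "signature")
  pt <- signature_space_point(sigs, series$participant_id, series$task)
  structure(
    list(participant_id = series$participant_id, task = series$task,
         group = series$group, partition = partition,
         n_frames = nframes(series), regions = regions,
         nsr_vector = pt$nsr_vector, skew_vector = pt$skew_vector,
         nsr_norm = pt$nsr_norm, skew_norm = pt$skew_norm),
    class = "mms_fit")
}

#' @export
print.mms_fit <- function(x, ...) {
  cat(sprintf("MMS Gamma signatures: %s | %s | %s (%d frames)\n",
              x$participant_id, x$group, x$task, x$n_frames))
  for (r in names(x$regions)) {
    s <- x$regions[[r]]$signature
    cat(sprintf("  %s: a = %.3f, b (NSR) = %.3f, skewness = %.3f (%d MMS peaks)\n",
                r, s$shape, s$scale, s$skewness, s$n))
  }
  cat(sprintf("  NSR norm = %.3f; skewness norm = %.3f\n",
              x$nsr_norm, x$skew_norm))
  invisible(x)
}

#' Per-region signature table of an MMS fit
#'
#' @param object an `mms_fit`.
#' @param ... unused.
#' @return data frame: one row per region with shape/scale estimates,
#'   95% CIs, empirical Gamma mean, NSR, skewness, peak counts.
#' @export
summary.mms_fit <- function(object, ...) {
  rows <- lapply(object$regions, function(rg) {
    s <- rg$signature
    data.frame(participant = object$participant_id, group = object$group,
               task = object$task, region = rg$region,
               a = s$shape, b = s$scale,
               a_lo = s$ci_shape[[1]], a_hi = s$ci_shape[[2]],
               b_lo = s$ci_scale[[1]], b_hi = s$ci_scale[[2]],
               gamma_mu = rg$gamma_mu, nsr = s$nsr, skewness = s$skewness,
               n_speed_peaks = length(rg$speed_peaks$indices),
               n_mms_peaks = s$n)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("summary.mms_fit", "data.frame")
  out
}

#' @export
print.summary.mms_fit <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mms_fit <- function(object, ...) {
  t(vapply(object$regions,
           function(rg) coef(rg$signature), numeric(2)))
}

#' MMS peak samples of a fitted recording
#' @param object an `mms_fit`.
#' @param region region label, or NULL for a named list over all regions.
#' @export
mms_peaks <- function(object, region = NULL) {
  stopifnot(inherits(object, "mms_fit"))
  out <- lapply(object$regions, function(rg) rg$mms$spike_values)
  if (is.null(region)) out else out[[match.arg(region, names(out))]]
}

#' Simulate MMS peak values from a fitted signature
#'
#' Draws from the fitted Gamma law of each region's MMS peaks — the
#' model's parametric account of the spike-amplitude distribution.
#'
#' @param object an `mms_fit`.
#' @param nsim draws per region.
#' @param seed optional seed.
#' @param ... unused.
#' @return named list of numeric vectors, one per region.
#' @export
simulate.mms_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() lapply(object$regions, function(rg) {
    s <- rg$signature
    stats::rgamma(nsim, shape = s$shape, scale = s$scale)
  })
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Diagnostic plot of an MMS fit
#'
#' One panel per region: histogram of the MMS peak values with the fitted
#' Gamma density overlaid.
#'
#' @param x an `mms_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.mms_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$regions)))
  on.exit(graphics::par(old))
  for (r in names(x$regions)) {
    rg <- x$regions[[r]]
    s <- rg$signature
    graphics::hist(rg$mms$spike_values, freq = FALSE, breaks = "FD",
                   main = sprintf("%s: a=%.2f b=%.2f", r, s$shape, s$scale),
                   xlab = "MMS peak value", col = "grey85", border = "white",
                   ...)
    xs <- seq(1e-4, 1, length.out = 200)
    graphics::lines(xs, stats::dgamma(xs, shape = s$shape, scale = s$scale),
                    col = "firebrick", lwd = 2)
  }
  invisible(x)
}
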