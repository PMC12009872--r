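#' Maximum-likelihood Gamma signature of a positive sample
#'
#' Fits the two-parameter Gamma family (shape a, scale b; no location
#' shift) by maximum likelihood. The shape solves the profile-likelihood
#' score equation log(a) - digamma(a) = log(mean(x)) - mean(log(x)) by a
#' safeguarded scalar root solve; the scale is then mean(x)/a. 95%
#' confidence intervals come from the inverse observed Fisher information
#' at the MLE. Derived quantities follow from the Gamma family: mean a*b,
#' sd sqrt(a)*b, noise-to-signal ratio (sd/mean) = b, skewness 2/sqrt(a).
#'
#' @param samples positive numeric values, at least `min_n` of them.
#' @param conf confidence level for the intervals (default 0.95).
#' @param min_n minimum sample count (default 30, the floor below which
#'   the intervals carry no useful information).
#' @return a `gamma_signature` object with components `shape`, `scale`,
#'   `ci_shape`, `ci_scale`, `n`, `mean`, `sd`, `nsr`, `skewness`,
#'   `loglik`, `vcov`.
#' @examples
#' set.seed(1)
#' fit_gamma_mle(rgamma(500, shape = 4, scale = 0.25))
#' @export
fit_gamma_mle <- function(samples, conf = 0.95, min_n = 30L) {
  x <- as.numeric(samples)
  if (any(!is.finite(x))) stop("samples must be finite", call. = FALSE)
  if (any(x <= 0))
    stop("domain error: Gamma samples must be strictly positive",
         call. = FALSE)
  n <- length(x)
  if (n < min_n)
    stop(sprintf("insufficient data: n = %d < %d", n, min_n), call. = FALSE)
  mx <- mean(x)
  mlx <- mean(log(x))
  s <- log(mx) - mlx
  if (s <= 1e-12)
    stop("degenerate fit: zero sample variance", call. = FALSE)

  # Minka's closed-form start, then bracketed root of the score equation.
  a0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  score <- function(a) log(a) - digamma(a) - s
  lo <- a0 / 16; hi <- a0 * 16
  while (score(lo) < 0 && lo > 1e-12) lo <- lo / 16
  while (score(hi) > 0 && hi < 1e12) hi <- hi * 16
  if (score(lo) < 0 || score(hi) > 0)
    stop("fit failure: could not bracket the Gamma shape score equation",
         call. = FALSE)
  a <- stats::uniroot(score, c(lo, hi), tol = 1e-12)$root
  b <- mx / a

  ll <- sum(stats::dgamma(x, shape = a, scale = b, log = TRUE))
  # Observed information of (a, b) at the MLE.
  info <- n * matrix(c(trigamma(a), 1 / b, 1 / b, a / b^2), 2, 2)
  vc <- solve(info)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf) / 2)

  structure(
    list(shape = a, scale = b,
         ci_shape = c(lo = a - z * se[1], hi = a + z * se[1]),
         ci_scale = c(lo = b - z * se[2], hi = b + z * se[2]),
         n = n, mean = a * b, sd = sqrt(a) * b,
         nsr = b, skewness = 2 / sqrt(a),
         conf = conf, loglik = ll, vcov = vc),
    class = "gamma_signature")
}

#' @export
print.gamma_signature <- function(x, digits = 4, ...) {
  cat("Gamma stochastic signature (MLE)\n")
  cat(sprintf("  shape a = %.*g  [%.*g, %.*g]\n", digits, x$shape,
              digits, x$ci_shape[1], digits, x$ci_shape[2]))
  cat(sprintf("  scale b = %.*g  [%.*g, %.*g]\n", digits, x$scale,
              digits, x$ci_scale[1], digits, x$ci_scale[2]))
  cat(sprintf("  mean a*b = %.*g   NSR = %.*g   skewness = %.*g   (n = %d)\n",
              digits, x$mean, digits, x$nsr, digits, x$skewness, x$n))
  invisible(x)
}

#' @export
coef.gamma_signature <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' @export
vcov.gamma_signature <- function(object, ...) {
  structure(object$vcov, dimnames = list(c("shape", "scale"),
                                         c("shape", "scale")))
}

#' @export
logLik.gamma_signature <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
confint.gamma_signature <- function(object, parm = c("shape", "scale"),
                                    level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  m <- rbind(shape = object$ci_shape, scale = object$ci_scale)
  m[parm, , drop = FALSE]
}

#' Noise-to-signal ratio of a Gamma signature
#'
#' The NSR is the Gamma sd over the Gamma mean, sqrt(a)*b / (a*b), which
#' reduces identically to the scale parameter b.
#' @param sig a `gamma_signature`.
#' @export
derive_nsr <- function(sig) {
  stopifnot(inherits(sig, "gamma_signature"))
  sig$scale
}

#' Skewness of a Gamma signature
#'
#' Standard Gamma skewness 2/sqrt(a); decreases toward the Gaussian limit
#' 0 as the shape grows, and equals 2 for the exponential (a = 1).
#' @param sig a `gamma_signature`.
#' @export
derive_skewness <- function(sig) {
  stopifnot(inherits(sig, "gamma_signature"))
  2 / sqrt(sig$shape)
}

#' @export
as.data.frame.gamma_signature <- function(x, ...) {
  data.frame(a = x$shape, b = x$scale,
             a_lo = x$ci_shape[[1]], a_hi = x$ci_shape[[2]],
             b_lo = x$ci_scale[[1]], b_hi = x$ci_scale[[2]],
             n = x$n, mean = x$mean, nsr = x$nsr, skewness = x$skewness)
}

#' Per-participant point in the NSR-norm / skewness-norm parameter plane
#'
#' Combines a participant's three regional signatures into the vectors
#' (b_V1, b_V2, b_V3) and (2/sqrt(a_V1), 2/sqrt(a_V2), 2/sqrt(a_V3)) and
#' their Euclidean norms.
#'
#' @param sigs named list of `gamma_signature`s for regions V1, V2, V3.
#' @param participant_id,task metadata carried through.
#' @return a `signature_space_point` list with `nsr_vector`,
#'   `skew_vector`, `nsr_norm`, `skew_norm`.
#' @export
signature_space_point <- function(sigs, participant_id = NA_character_,
                                  task = NA_character_) {
  regions <- c("V1", "V2", "V3")
  if (!all(regions %in% names(sigs)))
    stop("incomplete signature: need fitted V1, V2 and V3", call. = FALSE)
  nsr <- vapply(sigs[regions], derive_nsr, numeric(1))
  skw <- vapply(sigs[regions], derive_skewness, numeric(1))
  structure(list(participant_id = participant_id, task = task,
                 signatures = sigs[regions],
                 nsr_vector = nsr, skew_vector = skw,
                 nsr_norm = sqrt(sum(nsr^2)),
                 skew_norm = sqrt(sum(skw^2))),
            class = "signature_space_point")
}

#' Build the signature-space table for a cohort
#'
#' @param fits list of [mms_fit()] objects (one per participant/task).
#' @return data frame with one row per fit: participant, group, task,
#'   per-region NSR and skewness, and the two Euclidean norms.
#' @export
build_signature_space <- function(fits) {
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "mms_fit"))
    pt <- signature_space_point(lapply(f$regions, `[[`, "signature"),
                                f$participant_id, f$task)
    data.frame(participant = f$participant_id, group = f$group,
               task = f$task,
               nsr_V1 = pt$nsr_vector[["V1"]], nsr_V2 = pt$nsr_vector[["V2"]],
               nsr_V3 = pt$nsr_vector[["V3"]],
               skew_V1 = pt$skew_vector[["V1"]],
               skew_V2 = pt$skew_vector[["V2"]],
               skew_V3 = pt$skew_vector[["V3"]],
               nsr_norm = pt$nsr_norm, skew_norm = pt$skew_norm)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise Wilcoxon rank-sum comparisons across groups
#'
#' Two-sided rank-sum (Mann-Whitney) tests between every pair of cells in
#' a named list of samples. No multiplicity correction is applied by
#' default; Benjamini-Hochberg adjustment is available behind a flag.
#'
#' @param cells named list of numeric vectors (e.g. MMS spike samples per
#'   group/task/region, or participant-level scalars per group).
#' @param adjust if TRUE, append Benjamini-Hochberg adjusted p-values.
#' @param min_n cells with fewer samples are skipped with a warning.
#' @return data frame (cellA, cellB, n_A, n_B, statistic, p) for every
#'   unordered pair, plus `p_adj` when `adjust` is TRUE.
#' @export
pairwise_ranksum <- function(cells, adjust = FALSE, min_n = 5L) {
  stopifnot(is.list(cells), !is.null(names(cells)))
  sizes <- lengths(cells)
  if (any(sizes < min_n)) {
    warning("skipping cell(s) with < ", min_n, " samples: ",
            paste(names(cells)[sizes < min_n], collapse = ", "),
            call. = FALSE)
    cells <- cells[sizes >= min_n]
  }
  nm <- names(cells)
  if (length(nm) < 2L) stop("need at least two usable cells", call. = FALSE)
  pairs <- utils::combn(nm, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    wt <- stats::wilcox.test(cells[[pr[1]]], cells[[pr[2]]],
                             alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
    data.frame(cellA = pr[1], cellB = pr[2],
               n_A = length(cells[[pr[1]]]), n_B = length(cells[[pr[2]]]),
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
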