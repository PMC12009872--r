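#' Modal action-unit presence pattern of a recording
#'
#' The most frequent full-row binary pattern across frames denotes which
#' AUs are present in the recording. Ties are broken in favor of the
#' pattern whose first occurrence is earliest in time.
#'
#' @param au_presence F x 18 binary matrix (or a [landmark_series()]).
#' @return integer vector of 18 bits, named by AU.
#' @export
modal_pattern <- function(au_presence) {
  m <- presence_matrix(au_presence)
  keys <- apply(m, 1L, paste, collapse = "")
  counts <- table(keys)
  winners <- names(counts)[counts == max(counts)]
  first_seen <- vapply(winners, function(k) match(k, keys), integer(1))
  best <- winners[which.min(first_seen)]
  bits <- as.integer(m[match(best, keys), ])
  names(bits) <- colnames(m)
  bits
}

presence_matrix <- function(au_presence) {
  if (inherits(au_presence, "landmark_series"))
    au_presence <- au_presence$au_presence
  m <- as.matrix(au_presence)
  if (!all(m %in% c(0, 1)))
    stop("domain error: presence matrix must be {0,1}-valued", call. = FALSE)
  if (is.null(colnames(m)) && ncol(m) == 18L)
    colnames(m) <- paste0("AU", AU_PRESENCE_IDS)
  m
}

#' Pattern-switching index of AU presence across frames
#'
#' For equal-length binary strings the edit distance reduces to the
#' Hamming distance. The whole-face index is the mean Hamming distance
#' between consecutive frame patterns (in \[0, number of AUs\]); the
#' per-AU index is the fraction of consecutive frame pairs in which that
#' AU's bit flips (in \[0, 1\]).
#'
#' @param au_presence F x 18 binary matrix (or a [landmark_series()]),
#'   F >= 2.
#' @return list with `per_au` (named numeric) and `whole_face` (scalar).
#' @export
switching_index <- function(au_presence) {
  m <- presence_matrix(au_presence)
  if (nrow(m) < 2L)
    stop("insufficient data: need >= 2 frames", call. = FALSE)
  flips <- abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  list(per_au = colMeans(flips), whole_face = mean(rowSums(flips)))
}

#' Pool AU intensities across a group's participants
#'
#' Concatenates, per AU, all intensity values at or above the threshold
#' across every participant and frame of a group/task cell, and summarizes
#' them as frequency histograms (Freedman-Diaconis bins). AUs with an
#' empty pool are reported absent for the group.
#'
#' @param intensities list of F x 17 intensity matrices (or
#'   [landmark_series()] objects), one per participant.
#' @param threshold inclusive lower bound on saved intensities (default
#'   0.001).
#' @param group,task labels carried through to the summary.
#' @return a `group_au_summary`: per-AU pools, histogram breaks/counts,
#'   presence consensus (fraction of participants contributing at least
#'   one qualifying value) and a `table` data frame.
#' @export
pool_intensities <- function(intensities, threshold = 0.001,
                             group = NA_character_, task = NA_character_) {
  stopifnot(threshold >= 0)
  mats <- lapply(intensities, function(x) {
    if (inherits(x, "landmark_series")) x <- x$au_intensity
    m <- as.matrix(x)
    if (any(m < 0))
      stop("data quality: negative AU intensity", call. = FALSE)
    if (is.null(colnames(m)) && ncol(m) == 17L)
      colnames(m) <- paste0("AU", AU_INTENSITY_IDS)
    m
  })
  aus <- colnames(mats[[1]])
  pools <- stats::setNames(vector("list", length(aus)), aus)
  consensus <- stats::setNames(numeric(length(aus)), aus)
  for (au in aus) {
    per_part <- lapply(mats, function(m) {
      v <- m[, au]
      v[v >= threshold]
    })
    pools[[au]] <- unlist(per_part, use.names = FALSE)
    consensus[[au]] <- mean(lengths(per_part) > 0L)
  }
  hists <- lapply(pools, function(v) {
    if (length(v) < 2L || length(unique(v)) < 2L) return(NULL)
    h <- graphics::hist(v, breaks = "FD", plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  tab <- data.frame(
    group = group, task = task, AU = aus,
    presence_consensus = unname(consensus),
    pool_size = unname(lengths(pools)),
    median_intensity = vapply(pools, function(v)
      if (length(v)) stats::median(v) else NA_real_, numeric(1)),
    row.names = NULL)
  structure(list(group = group, task = task, threshold = threshold,
                 pools = pools, histograms = hists,
                 presence_consensus = consensus, table = tab),
            class = "group_au_summary")
}

#' @export
print.group_au_summary <- function(x, ...) {
  present <- sum(x$table$pool_size > 0L)
  cat(sprintf("<group_au_summary> %s / %s: %d of %d AUs present (threshold %g)\n",
              x$group, x$task, present, nrow(x$table), x$threshold))
  invisible(x)
}

#' Compare AU profiles between two groups
#'
#' Per AU: presence status (both / A only / B only / neither, from
#' non-empty intensity pools), and for AUs shared by both groups a
#' two-sided rank-sum p-value and the difference in median intensity
#' (A - B).
#'
#' @param summaryA,summaryB [pool_intensities()] results for the same
#'   task.
#' @return data frame with one row per AU.
#' @export
compare_groups <- function(summaryA, summaryB) {
  stopifnot(inherits(summaryA, "group_au_summary"),
            inherits(summaryB, "group_au_summary"))
  if (!identical(summaryA$task, summaryB$task) &&
      !(is.na(summaryA$task) && is.na(summaryB$task)))
    stop("summaries must describe the same task", call. = FALSE)
  aus <- names(summaryA$pools)
  rows <- lapply(aus, function(au) {
    a <- summaryA$pools[[au]]
    b <- summaryB$pools[[au]]
    status <- if (length(a) && length(b)) "both"
              else if (length(a)) "A only"
              else if (length(b)) "B only"
              else "neither"
    p <- NA_real_; med_diff <- NA_real_
    if (status == "both") {
      p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
      med_diff <- stats::median(a) - stats::median(b)
    }
    data.frame(AU = au, status = status, n_A = length(a), n_B = length(b),
               p = p, median_diff = med_diff)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
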