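#' 1-D Earth Mover's Distance between two empirical samples
#'
#' First-order Wasserstein distance between the empirical distributions of
#' two sample sets (each sample carrying equal weight within its set),
#' computed as the integral of the absolute difference between the two
#' empirical CDFs.
#'
#' @param a,b non-empty numeric sample vectors (sizes may differ).
#' @return non-negative scalar distance.
#' @export
emd_1d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("domain error: empty sample set", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  v <- sort(unique(c(a, b)))
  if (length(v) == 1L) return(0)
  # ECDF difference is piecewise constant between pooled support points.
  fa <- cumsum(tabulate(match(a, v), nbins = length(v))) / length(a)
  fb <- cumsum(tabulate(match(b, v), nbins = length(v))) / length(b)
  k <- length(v)
  sum(abs(fa[-k] - fb[-k]) * diff(v))
}

#' Pairwise EMD matrix over a cohort's MMS peak distributions
#'
#' @param peak_sets named list of numeric vectors, keyed for example by
#'   `participant.region`; keys become row/column labels.
#' @param normalize if TRUE, divide by the maximum off-diagonal entry so
#'   the largest distance is 1.
#' @return a symmetric `emd_matrix` with zero diagonal and attribute
#'   `normalized`.
#' @export
pairwise_emd <- function(peak_sets, normalize = FALSE) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  empty <- lengths(peak_sets) == 0L
  if (any(empty)) {
    warning("excluding empty peak set(s): ",
            paste(names(peak_sets)[empty], collapse = ", "), call. = FALSE)
    peak_sets <- peak_sets[!empty]
  }
  n <- length(peak_sets)
  if (n < 2L) stop("need at least two non-empty peak sets", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(names(peak_sets), names(peak_sets)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- emd_1d(peak_sets[[i]], peak_sets[[j]])
    m[i, j] <- d
    m[j, i] <- d
  }
  if (normalize) {
    mx <- max(m)
    if (mx > 0) m <- m / mx
  }
  structure(m, normalized = normalize,
            class = c("emd_matrix", "matrix", "array"))
}

#' Tree clustering of an EMD matrix with group-composition report
#'
#' Agglomerative hierarchical clustering (average linkage) on the
#' precomputed distance matrix, cut into the requested number of subtype
#' clusters; each leaf cluster reports the percentage of every group label
#' among its rows.
#'
#' @param emd an `emd_matrix` (or symmetric distance matrix with labels).
#' @param k number of subtype clusters, 2 <= k <= nrow.
#' @param labels group label per row (recycled names are not assumed);
#'   defaults to the portion of each row label before the first ".".
#' @return a `cluster_report`: list with `k`, `assignments` (named leaf id
#'   per row), `composition` (data frame: leaf, group, n, percent),
#'   `linkage` (the `hclust` object).
#' @export
tree_cluster <- function(emd, k, labels = NULL) {
  m <- as.matrix(emd)
  n <- nrow(m)
  if (k < 2L || k > n)
    stop("domain error: need 2 <= k <= number of rows", call. = FALSE)
  if (is.null(labels))
    labels <- sub("\\..*$", "", rownames(m))
  stopifnot(length(labels) == n)
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  assign <- stats::cutree(hc, k = k)
  comp <- do.call(rbind, lapply(sort(unique(assign)), function(leaf) {
    in_leaf <- labels[assign == leaf]
    tab <- table(in_leaf)
    data.frame(leaf = leaf, group = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(in_leaf))
  }))
  structure(list(k = k, assignments = assign, composition = comp,
                 linkage = hc),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d leaves over %d rows (average linkage)\n",
              x$k, length(x$assignments)))
  for (leaf in sort(unique(x$composition$leaf))) {
    rows <- x$composition[x$composition$leaf == leaf, ]
    cat(sprintf("  leaf %d (n=%d): %s\n", leaf, sum(rows$n),
                paste(sprintf("%s %.0f%%", rows$group, rows$percent),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.cluster_report <- function(x, ...) {
  plot(x$linkage, main = sprintf("EMD tree (%d leaves)", x$k),
       xlab = "", sub = "", ...)
  stats::rect.hclust(x$linkage, k = x$k)
  invisible(x)
}
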