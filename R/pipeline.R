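#' Run the full analysis over a cohort of recordings
#'
#' Fits [mms_fit()] to every recording, assembles the signature-space
#' table, computes per-task pairwise EMD matrices over the MMS peak
#' distributions (one row per participant x region), cuts the average-
#' linkage tree into `k` subtype clusters with group-composition reports,
#' pools AU intensities per group/task, and runs pairwise rank-sum
#' comparisons of participant-level NSR and skewness norms between
#' groups.
#'
#' @param recordings named list of [landmark_series()] (names used as
#'   keys; a corrupt or unusable recording is quarantined with a warning
#'   rather than aborting the run).
#' @param k subtype cluster count (default 6 = 3 regions x 2 groups).
#' @param normalize_emd normalize each EMD matrix to max 1.
#' @param au_threshold inclusive AU intensity threshold (default 0.001).
#' @return a `cohort_analysis` list: `fits`, `signatures` (wide data
#'   frame, one row per participant), `signature_table` (long, one row
#'   per participant x region),
#'   `emd` (per task), `clusters` (per task), `au_summaries`,
#'   `au_comparisons`, `ranksum`, `quarantined`.
#' @export
analyze_cohort <- function(recordings, k = 6L, normalize_emd = FALSE,
                           au_threshold = 0.001) {
  stopifnot(is.list(recordings), length(recordings) >= 2L)
  if (is.null(names(recordings)))
    names(recordings) <- sprintf("rec%03d", seq_along(recordings))
  fits <- list()
  quarantined <- character(0)
  for (key in names(recordings)) {
    f <- tryCatch(mms_fit(recordings[[key]]), error = function(e) e)
    if (inherits(f, "error")) {
      warning("quarantined ", key, ": ", conditionMessage(f), call. = FALSE)
      quarantined <- c(quarantined, key)
    } else fits[[key]] <- f
  }
  if (!length(fits)) stop("no valid recordings", call. = FALSE)

  signatures <- build_signature_space(fits)
  signature_table <- do.call(rbind, c(lapply(unname(fits), summary),
                                      list(make.row.names = FALSE)))
  class(signature_table) <- "data.frame"
  tasks <- unique(vapply(fits, `[[`, character(1), "task"))

  emd <- list(); clusters <- list()
  for (task in tasks) {
    tf <- Filter(function(f) f$task == task, fits)
    peak_sets <- list(); labels <- character(0)
    for (f in tf) for (r in names(f$regions)) {
      key <- paste(f$participant_id, r, sep = ".")
      peak_sets[[key]] <- f$regions[[r]]$mms$spike_values
      labels <- c(labels, f$group)
    }
    if (length(peak_sets) >= 2L) {
      m <- pairwise_emd(peak_sets, normalize = normalize_emd)
      emd[[task]] <- m
      if (k <= nrow(m))
        clusters[[task]] <- tree_cluster(m, k = k, labels = labels)
    }
  }

  groups <- unique(vapply(fits, `[[`, character(1), "group"))
  au_summaries <- list(); au_comparisons <- list()
  for (task in tasks) {
    for (g in groups) {
      sel <- Filter(function(key) {
        recordings[[key]]$group == g && recordings[[key]]$task == task &&
          !(key %in% quarantined)
      }, names(recordings))
      if (length(sel))
        au_summaries[[paste(g, task, sep = ".")]] <-
          pool_intensities(recordings[sel], threshold = au_threshold,
                           group = g, task = task)
    }
    if (length(groups) >= 2L) {
      for (pair in utils::combn(groups, 2L, simplify = FALSE)) {
        a <- au_summaries[[paste(pair[1], task, sep = ".")]]
        b <- au_summaries[[paste(pair[2], task, sep = ".")]]
        if (!is.null(a) && !is.null(b))
          au_comparisons[[paste(pair[1], pair[2], task, sep = ".")]] <-
            compare_groups(a, b)
      }
    }
  }

  # Rank-sum comparisons at two granularities: pooled MMS spike values
  # per group x region (always well powered), and participant-level
  # signature norms when each group has enough participants.
  ranksum <- list(spikes = NULL, norms = NULL)
  if (length(groups) >= 2L) {
    spike_cells <- list()
    for (g in groups) for (r in c("V1", "V2", "V3")) {
      v <- unlist(lapply(Filter(function(f) f$group == g, fits),
                         function(f) f$regions[[r]]$mms$spike_values),
                  use.names = FALSE)
      spike_cells[[paste(g, r, sep = ".")]] <- v
    }
    ranksum$spikes <- pairwise_ranksum(spike_cells)
    if (all(table(signatures$group) >= 5L)) {
      ranksum$norms <- do.call(rbind, lapply(
        c("nsr_norm", "skew_norm"), function(measure) {
          cells <- lapply(stats::setNames(groups, groups), function(g)
            signatures[signatures$group == g, measure])
          cbind(measure = measure, pairwise_ranksum(cells))
        }))
    }
  }

  structure(list(fits = fits, signatures = signatures,
                 signature_table = signature_table, emd = emd,
                 clusters = clusters, au_summaries = au_summaries,
                 au_comparisons = au_comparisons, ranksum = ranksum,
                 quarantined = quarantined, k = k),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d fits (%d quarantined); tasks: %s\n",
              length(x$fits), length(x$quarantined),
              paste(names(x$emd), collapse = ", ")))
  for (task in names(x$clusters)) {
    cat(sprintf("-- %s clusters --\n", task))
    print(x$clusters[[task]])
  }
  invisible(x)
}

#' Read a directory of OpenFace CSVs as a cohort
#'
#' File names are expected as `<participant>.<task>.csv` (the layout
#' [write_cohort()] emits); group labels come from a `truth.csv` table if
#' present, else from the participant prefix. Unreadable files are
#' quarantined with a warning.
#'
#' @param dir directory of per-recording CSVs.
#' @param default_group group assigned when no truth table matches.
#' @return named list of [landmark_series()], with attribute
#'   `quarantined`.
#' @export
read_cohort_dir <- function(dir, default_group = "TD") {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "truth.csv"]
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  recs <- list(); quarantined <- character(0)
  for (f in files) {
    stem <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(stem, ".", fixed = TRUE)[[1]]
    pid <- parts[1]
    task <- if (length(parts) > 1L && parts[2] %in% FACE_TASKS)
      parts[2] else "resting"
    group <- default_group
    if (!is.null(truth) && pid %in% truth$participant)
      group <- truth$group[match(pid, truth$participant)]
    rec <- tryCatch(read_openface_csv(f, pid, task, group),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      warning("quarantined ", basename(f), ": ", conditionMessage(rec),
              call. = FALSE)
      quarantined <- c(quarantined, basename(f))
    } else recs[[stem]] <- rec
  }
  attr(recs, "quarantined") <- quarantined
  recs
}

#' Write a cohort analysis to disk with a run manifest
#'
#' Emits CSV tables for signatures, per-task EMD matrices, cluster
#' assignments and compositions, AU summaries and rank-sum results, plus
#' a JSON manifest recording the configuration digest and per-stage
#' record counts.
#'
#' @param analysis a [analyze_cohort()] result.
#' @param dir output directory (created if absent).
#' @param seed seed recorded in the manifest (informational).
#' @return invisibly, the manifest path.
#' @export
write_analysis <- function(analysis, dir, seed = NA_integer_) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(analysis$signatures, file.path(dir, "signatures.csv"))
  write_table(analysis$signature_table,
              file.path(dir, "signatures_by_region.csv"))
  for (task in names(analysis$emd))
    write_table(analysis$emd[[task]],
                file.path(dir, sprintf("emd_%s.csv", task)))
  for (task in names(analysis$clusters)) {
    cl <- analysis$clusters[[task]]
    write_table(data.frame(row = names(cl$assignments),
                           leaf = unname(cl$assignments)),
                file.path(dir, sprintf("clusters_%s.csv", task)))
    write_table(cl$composition,
                file.path(dir, sprintf("cluster_composition_%s.csv", task)))
  }
  if (length(analysis$au_summaries)) {
    au_tab <- do.call(rbind, lapply(analysis$au_summaries, `[[`, "table"))
    rownames(au_tab) <- NULL
    write_table(au_tab, file.path(dir, "au_summary.csv"))
  }
  if (!is.null(analysis$ranksum$spikes))
    write_table(analysis$ranksum$spikes, file.path(dir, "ranksum_spikes.csv"))
  if (!is.null(analysis$ranksum$norms))
    write_table(analysis$ranksum$norms, file.path(dir, "ranksum_norms.csv"))
  manifest <- list(
    package = "facemms",
    version = as.character(utils::packageVersion("facemms")),
    seed = seed,
    k = analysis$k,
    n_fits = length(analysis$fits),
    n_quarantined = length(analysis$quarantined),
    quarantined = analysis$quarantined,
    tasks = names(analysis$emd),
    config_digest = fnv1a(jsonlite::toJSON(list(
      k = analysis$k, fits = names(analysis$fits)), auto_unbox = TRUE)),
    record_counts = list(
      signatures = nrow(analysis$signatures),
      emd_rows = vapply(analysis$emd, nrow, integer(1)),
      au_summaries = length(analysis$au_summaries)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# 31-bit polynomial rolling digest (stable run-configuration fingerprint).
fnv1a <- function(s) {
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Parameter-recovery experiment on a synthetic cohort
#'
#' Generates a cohort, runs the full pipeline on every recording, and
#' reports (i) the relative error between Gamma signatures fitted directly
#' to the injected step-length amplitudes and their generating values, and
#' (ii) the orderings of group NSR/skewness medians recovered from the
#' pipeline's speed-amplitude-stage signatures. Exact parameter recovery
#' is only meaningful on the injected amplitudes — smoothing,
#' differentiation and MMS standardization transform the law nonlinearly —
#' so pipeline outputs are judged on regime ordering, not parameter
#' equality; and because the MMS scaling removes amplitude units, the
#' orderings are read from the pre-standardization speed-peak fits.
#'
#' @param config a [cohort_config()]; needs at least one TD-like and one
#'   ASD-like group for the ordering checks.
#' @return a `recovery_report`: list with `injected` (per
#'   participant/region fit vs truth), `pipeline` (per-group/region median
#'   NSR and skewness), `orderings` (logical checks) and the underlying
#'   `signatures` table.
#' @export
recovery_experiment <- function(config = cohort_config()) {
  cohort <- generate_cohort(config)
  region_of <- integer(68)
  part <- trigeminal_partition()
  for (r in seq_along(part)) region_of[part[[r]] + 1L] <- r

  injected <- list()
  fits <- list()
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    fits[[key]] <- mms_fit(rec)
    steps <- attr(rec, "step_lengths")
    for (r in 1:3) {
      amps <- as.vector(steps[, region_of == r])
      sig <- fit_gamma_mle(amps)
      tr <- cohort$truth[cohort$truth$participant == rec$participant_id &
                           cohort$truth$task == rec$task &
                           cohort$truth$region == names(part)[r], ][1, ]
      injected[[length(injected) + 1L]] <- data.frame(
        participant = rec$participant_id, group = rec$group, task = rec$task,
        region = names(part)[r],
        shape_true = tr$shape, shape_hat = sig$shape,
        scale_true = tr$scale * config$step_scale, scale_hat = sig$scale,
        rel_err_shape = abs(sig$shape - tr$shape) / tr$shape,
        rel_err_scale = abs(sig$scale - tr$scale * config$step_scale) /
          (tr$scale * config$step_scale))
    }
  }
  injected <- do.call(rbind, c(injected, list(make.row.names = FALSE)))
  signatures <- build_signature_space(fits)

  # Ordering checks run on the speed-amplitude-stage signatures: the MMS
  # local scaling deliberately removes amplitude units, so an injected
  # scale change is only visible before standardization.
  amp <- do.call(rbind, lapply(unname(fits), function(f) {
    s <- lapply(f$regions, `[[`, "mu_signature")
    data.frame(participant = f$participant_id, group = f$group,
               nsr_V1 = s$V1$scale, nsr_V2 = s$V2$scale,
               nsr_V3 = s$V3$scale,
               skew_V1 = s$V1$skewness, skew_V2 = s$V2$skewness,
               skew_V3 = s$V3$skewness,
               nsr_norm = sqrt(s$V1$scale^2 + s$V2$scale^2 + s$V3$scale^2),
               skew_norm = sqrt(s$V1$skewness^2 + s$V2$skewness^2 +
                                  s$V3$skewness^2))
  }))

  med <- function(g, col) stats::median(amp[amp$group == g, col])
  groups <- names(config$counts)
  td_groups <- intersect(groups, c("TD", "TD-Mom", "TD-MomM", "TD-Dad"))
  asd_groups <- setdiff(groups, td_groups)
  pipeline <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g,
               nsr_V1 = med(g, "nsr_V1"), nsr_V2 = med(g, "nsr_V2"),
               nsr_V3 = med(g, "nsr_V3"),
               skew_V1 = med(g, "skew_V1"), skew_V2 = med(g, "skew_V2"),
               skew_V3 = med(g, "skew_V3"),
               nsr_norm = med(g, "nsr_norm"), skew_norm = med(g, "skew_norm"))
  }))

  orderings <- list()
  if (length(td_groups) && length(asd_groups)) {
    orderings$nsr_asd_gt_td <- all(outer(
      vapply(asd_groups, med, numeric(1), col = "nsr_norm"),
      vapply(td_groups, med, numeric(1), col = "nsr_norm"), `>`))
    orderings$skew_asd_gt_td <- all(outer(
      vapply(asd_groups, med, numeric(1), col = "skew_norm"),
      vapply(td_groups, med, numeric(1), col = "skew_norm"), `>`))
  }
  if ("ASD-HS-apraxia" %in% groups) {
    orderings$apraxia_v3_dominant <-
      med("ASD-HS-apraxia", "nsr_V3") > med("ASD-HS-apraxia", "nsr_V1") &&
      med("ASD-HS-apraxia", "nsr_V3") > med("ASD-HS-apraxia", "nsr_V2")
  }

  structure(list(injected = injected, pipeline = pipeline,
                 orderings = orderings, signatures = signatures,
                 config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  injected-amplitude fit: median rel. err shape %.3f, scale %.3f\n",
              stats::median(x$injected$rel_err_shape),
              stats::median(x$injected$rel_err_scale)))
  cat("  pipeline group medians:\n")
  print.data.frame(x$pipeline, digits = 3, row.names = FALSE)
  for (nm in names(x$orderings))
    cat(sprintf("  %s: %s\n", nm, x$orderings[[nm]]))
  invisible(x)
}
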