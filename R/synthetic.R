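#' Schematic 68-point base face template
#'
#' Canonical landmark layout (jawline 0-16, eyebrows 17-26, nose 27-35,
#' eyes 36-47, outer lip 48-59, inner lip 60-67) in pixel coordinates of a
#' nominal 640 x 480 frame, face height about 300 px. Any template with
#' non-degenerate per-frame coordinate variance works; this one is a
#' deterministic schematic, not a measured face.
#'
#' @return 68 x 2 matrix of (x, y) pixel coordinates.
#' @export
face_template <- function() {
  pts <- matrix(NA_real_, 68, 2)
  th <- seq(-pi / 2, pi / 2, length.out = 17)
  pts[1:17, ] <- cbind(0.90 * sin(th), -1.00 * cos(th) + 0.05)  # jaw 0-16
  bx <- seq(-0.68, -0.16, length.out = 5)
  pts[18:22, ] <- cbind(bx, 0.52 + 0.10 * cos((bx + 0.42) * 6))  # brow 17-21
  pts[23:27, ] <- cbind(-rev(bx), 0.52 + 0.10 * cos((rev(bx) + 0.42) * 6))
  pts[28:31, ] <- cbind(0, seq(0.42, 0.02, length.out = 4))      # bridge 27-30
  pts[32:36, ] <- cbind(seq(-0.16, 0.16, length.out = 5),
                        -0.10 + 0.04 * c(1, 0, -1, 0, 1))        # nose 31-35
  ey <- seq(0, 2 * pi, length.out = 7)[-7]
  pts[37:42, ] <- cbind(-0.42 + 0.14 * cos(ey), 0.36 + 0.06 * sin(ey))
  pts[43:48, ] <- cbind(0.42 + 0.14 * cos(ey), 0.36 + 0.06 * sin(ey))
  ol <- seq(pi, -pi, length.out = 13)[-13]
  pts[49:60, ] <- cbind(0.28 * cos(ol), -0.48 + 0.13 * sin(ol))  # outer lip
  il <- seq(pi, -pi, length.out = 9)[-9]
  pts[61:68, ] <- cbind(0.17 * cos(il), -0.48 + 0.05 * sin(il))  # inner lip
  cbind(x = 320 + 150 * pts[, 1], y = 240 - 150 * pts[, 2])
}

#' Group profile for the synthetic cohort generator
#'
#' Per-region Gamma laws for the per-frame step-length amplitudes of the
#' landmark random walk, plus AU presence/intensity/switching parameters.
#' Defaults encode the qualitative regimes the pipeline is meant to
#' resolve: typically-developing (TD) profiles have high shape / low scale
#' (low noise-to-signal ratio, low skewness); autistic (ASD) profiles have
#' low shape / high scale (broader variability, heavier right tails); the
#' ASD-HS-apraxia profile doubles the mandibular-region (V3) scale so its
#' V3 noise dominates.
#'
#' @param group one of [FACE_GROUPS].
#' @return a `group_profile` list: `group`, `gamma` (data frame region /
#'   shape / scale), `au` (presence probability, switching rate, intensity
#'   Beta parameters on \[0, 5\]) and `step_scale` (pixels).
#' @export
group_profile <- function(group = FACE_GROUPS) {
  group <- match.arg(group)
  td_like <- group %in% c("TD", "TD-Mom", "TD-MomM", "TD-Dad")
  gp <- if (td_like) {
    list(shape = c(8, 8, 8), scale = c(0.1, 0.1, 0.1),
         switch = 0.02, ishape1 = 2.0, ishape2 = 8.0)
  } else if (group == "ASD-LS") {
    list(shape = c(1.5, 1.5, 1.5), scale = c(0.8, 0.8, 0.8),
         switch = 0.08, ishape1 = 1.2, ishape2 = 4.0)
  } else if (group == "ASD-HS") {
    list(shape = c(1.2, 1.2, 1.2), scale = c(1.0, 1.0, 1.0),
         switch = 0.10, ishape1 = 1.2, ishape2 = 4.0)
  } else { # ASD-HS-apraxia: mandibular (V3) noise dominates
    list(shape = c(1.2, 1.2, 1.2), scale = c(1.0, 1.0, 2.0),
         switch = 0.10, ishape1 = 1.2, ishape2 = 4.0)
  }
  structure(
    list(group = group,
         gamma = data.frame(region = c("V1", "V2", "V3"),
                            shape = gp$shape, scale = gp$scale),
         au = list(presence_prob = rep(0.3, 18L),
                   switch_rate = rep(gp$switch, 18L),
                   intensity_shape1 = gp$ishape1,
                   intensity_shape2 = gp$ishape2),
         step_scale = 1.0),
    class = "group_profile")
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic landmark recording
#'
#' Starting from the base template, every landmark performs a random walk:
#' at each frame its step length is drawn i.i.d. from the Gamma law of its
#' region (times `step_scale` pixels) and its step direction uniformly on
#' the circle. AU presence follows an independent 2-state Markov chain per
#' AU at the profile's switching rate; intensities are drawn from the
#' profile's Beta law scaled to \[0, 5\] while present, 0 otherwise. Fully
#' deterministic given the seed.
#'
#' @param profile a [group_profile()].
#' @param task one of [FACE_TASKS].
#' @param seed integer seed.
#' @param participant_id identifier for the recording.
#' @param n_frames frames (default 150 = 5 s at 30 Hz).
#' @param fps frame rate in Hz (default 30).
#' @param partition region partition used to look up each landmark's
#'   Gamma law.
#' @param template base face (68 x 2 pixel coordinates).
#' @return a [landmark_series()] carrying the injected per-step lengths as
#'   attribute `step_lengths` ((F-1) x 68 matrix) and the generating
#'   profile as attribute `profile`.
#' @export
generate_recording <- function(profile, task = "resting", seed = 1L,
                               participant_id = "synthetic-01",
                               n_frames = 150L, fps = 30,
                               partition = trigeminal_partition(),
                               template = face_template()) {
  stopifnot(inherits(profile, "group_profile"))
  task <- match.arg(task, FACE_TASKS)
  validate_partition(partition)
  region_of <- integer(68)
  for (r in seq_along(partition)) region_of[partition[[r]] + 1L] <- r

  with_seed(seed, {
    shp <- profile$gamma$shape[region_of]
    scl <- profile$gamma$scale[region_of]
    nstep <- n_frames - 1L
    steps <- matrix(stats::rgamma(nstep * 68L, shape = rep(shp, each = nstep),
                                  scale = rep(scl, each = nstep)),
                    nstep, 68L) * profile$step_scale
    angles <- matrix(stats::runif(nstep * 68L, 0, 2 * pi), nstep, 68L)
    coords <- array(NA_real_, c(n_frames, 68L, 2L))
    coords[1, , 1] <- template[, 1]
    coords[1, , 2] <- template[, 2]
    dx <- apply(steps * cos(angles), 2L, cumsum)
    dy <- apply(steps * sin(angles), 2L, cumsum)
    dx <- matrix(dx, nstep, 68L)
    dy <- matrix(dy, nstep, 68L)
    coords[-1, , 1] <- rep(template[, 1], each = nstep) + dx
    coords[-1, , 2] <- rep(template[, 2], each = nstep) + dy

    au <- profile$au
    pres <- matrix(0L, n_frames, 18L)
    for (j in 1:18) {
      p <- au$presence_prob[j]
      r <- au$switch_rate[j]
      q01 <- min(1, 2 * r * p)
      q10 <- min(1, 2 * r * (1 - p))
      st <- stats::rbinom(1L, 1L, p)
      pres[1, j] <- st
      if (n_frames > 1L) {
        u <- stats::runif(n_frames - 1L)
        for (f in 2:n_frames) {
          flip <- if (st == 0L) u[f - 1L] < q01 else u[f - 1L] < q10
          if (flip) st <- 1L - st
          pres[f, j] <- st
        }
      }
    }
    icols <- match(AU_INTENSITY_IDS, AU_PRESENCE_IDS)
    inten <- matrix(0, n_frames, 17L)
    on_mask <- pres[, icols, drop = FALSE] == 1L
    n_on <- sum(on_mask)
    if (n_on > 0)
      inten[on_mask] <- 5 * stats::rbeta(n_on, au$intensity_shape1,
                                         au$intensity_shape2)

    ts <- (seq_len(n_frames) - 1L) / fps
    out <- landmark_series(participant_id, task, profile$group, ts, coords,
                           confidence = rep(0.98, n_frames),
                           success = rep(1L, n_frames),
                           au_presence = pres, au_intensity = inten)
    attr(out, "step_lengths") <- steps
    attr(out, "profile") <- profile
    out
  })
}

#' Cohort configuration for the synthetic generator
#'
#' @param counts named integer vector of participants per group (names
#'   from [FACE_GROUPS]).
#' @param tasks tasks to simulate per participant.
#' @param seed master seed; per-recording seeds are derived from it by the
#'   counter scheme `(seed * 1000003 + counter) mod (2^31 - 1)`.
#' @param n_frames,fps recording geometry (defaults 150 frames at 30 Hz,
#'   i.e. 5 s).
#' @param step_scale random-walk step scale in pixels.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(counts = c(TD = 10L, `ASD-LS` = 10L),
                          tasks = "resting", seed = 1L,
                          n_frames = 150L, fps = 30, step_scale = 1.0) {
  stopifnot(!is.null(names(counts)), all(names(counts) %in% FACE_GROUPS),
            all(counts >= 0))
  if (n_frames < 90L)
    stop("need at least 90 frames (3 s at 30 Hz) for statistical power",
         call. = FALSE)
  structure(list(counts = counts, tasks = match.arg(tasks, FACE_TASKS,
                                                    several.ok = TRUE),
                 seed = as.integer(seed), n_frames = as.integer(n_frames),
                 fps = fps, step_scale = step_scale),
            class = "cohort_config")
}

derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1000003 + counter) %% 2147483647)
}

#' Generate a synthetic cohort with its ground-truth table
#'
#' One recording per participant x task; per-recording seeds derive from
#' the master seed by a counter scheme so the whole cohort is a pure
#' function of its configuration.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `recordings` (list of
#'   [landmark_series()]) and `truth` (data frame: participant, group,
#'   task, region, shape, scale, step_scale, seed).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list()
  truth <- list()
  counter <- 0L
  for (g in names(config$counts)) {
    prof <- group_profile(g)
    prof$step_scale <- config$step_scale
    for (i in seq_len(config$counts[[g]])) {
      pid <- sprintf("%s_%02d", gsub("-", "", g), i)
      for (task in config$tasks) {
        counter <- counter + 1L
        sd_i <- derive_seed(config$seed, counter)
        rec <- generate_recording(prof, task = task, seed = sd_i,
                                  participant_id = pid,
                                  n_frames = config$n_frames,
                                  fps = config$fps)
        recs[[paste(pid, task, sep = ".")]] <- rec
        truth[[length(truth) + 1L]] <-
          data.frame(participant = pid, group = g, task = task,
                     region = prof$gamma$region, shape = prof$gamma$shape,
                     scale = prof$gamma$scale,
                     step_scale = config$step_scale, seed = sd_i)
      }
    }
  }
  structure(list(recordings = recs,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d recordings (%s); tasks: %s; seed %d\n",
              length(x$recordings),
              paste(sprintf("%s n=%d", names(x$config$counts),
                            x$config$counts), collapse = ", "),
              paste(x$config$tasks, collapse = ", "), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk in OpenFace dialect
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (key in names(cohort$recordings)) {
    p <- file.path(dir, paste0(key, ".csv"))
    write_openface_csv(cohort$recordings[[key]], p)
    paths <- c(paths, p)
  }
  write_table(cohort$truth, file.path(dir, "truth.csv"))
  invisible(c(paths, file.path(dir, "truth.csv")))
}
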