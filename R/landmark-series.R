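#' Recognized task labels
#'
#' The resting baseline plus the seven universal facial micro-expressions.
#' @export
FACE_TASKS <- c("resting", "anger", "contempt", "disgust", "fear",
                "happiness", "sadness", "surprise")

#' Recognized cohort group labels
#' @export
FACE_GROUPS <- c("TD", "TD-Mom", "TD-MomM", "TD-Dad",
                 "ASD-LS", "ASD-HS", "ASD-HS-apraxia")

#' Action units with binary presence estimates (18) and continuous
#' intensity estimates (17); AU28 has presence only.
#' @export
AU_PRESENCE_IDS <- c("01", "02", "04", "05", "06", "07", "09", "10", "12",
                     "14", "15", "17", "20", "23", "25", "26", "28", "45")

#' @rdname AU_PRESENCE_IDS
#' @export
AU_INTENSITY_IDS <- setdiff(AU_PRESENCE_IDS, "28")

#' Construct a per-frame facial landmark series
#'
#' The pipeline's input container: one 5-second, 30-Hz recording of the
#' 68-point facial grid together with per-frame action-unit (AU) presence
#' and intensity estimates, as produced by OpenFace-style trackers.
#'
#' @param participant_id character scalar identifying the participant.
#' @param task one of [FACE_TASKS].
#' @param group one of [FACE_GROUPS].
#' @param timestamps strictly increasing frame times in seconds, length F.
#' @param coords numeric array F x 68 x 2 of landmark pixel coordinates
#'   (x in `coords[, , 1]`, y in `coords[, , 2]`).
#' @param confidence per-frame tracker confidence in \[0, 1\].
#' @param success per-frame binary tracking-success flag.
#' @param au_presence F x 18 binary matrix of AU presence.
#' @param au_intensity F x 17 non-negative matrix of AU intensity.
#' @param check_duration if TRUE, warn when the frame count falls outside
#'   the nominal 150 +/- 2 frames of a 5-s, 30-Hz recording.
#' @return an object of class `landmark_series`.
#' @export
landmark_series <- function(participant_id, task, group, timestamps, coords,
                            confidence = NULL, success = NULL,
                            au_presence = NULL, au_intensity = NULL,
                            check_duration = FALSE) {
  task <- match.arg(task, FACE_TASKS)
  group <- match.arg(group, FACE_GROUPS)
  nf <- length(timestamps)
  if (nf < 1L) stop("empty input: no frames", call. = FALSE)
  if (nf > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  coords <- as_coord_array(coords, nf)
  if (is.null(confidence)) confidence <- rep(1, nf)
  if (is.null(success)) success <- rep(1L, nf)
  if (is.null(au_presence)) au_presence <- matrix(0L, nf, 18L)
  if (is.null(au_intensity)) au_intensity <- matrix(0, nf, 17L)
  au_presence <- as.matrix(au_presence)
  au_intensity <- as.matrix(au_intensity)
  if (!identical(dim(au_presence), c(nf, 18L)))
    stop("au_presence must be F x 18", call. = FALSE)
  if (!identical(dim(au_intensity), c(nf, 17L)))
    stop("au_intensity must be F x 17", call. = FALSE)
  if (!all(au_presence %in% c(0, 1)))
    stop("au_presence must be {0,1}-valued", call. = FALSE)
  if (any(au_intensity < 0))
    stop("au_intensity values must be >= 0", call. = FALSE)
  if (length(confidence) != nf || length(success) != nf)
    stop("confidence and success must have one value per frame", call. = FALSE)
  if (check_duration && (nf < 148L || nf > 152L))
    warning(sprintf("frame count %d outside nominal 150 +/- 2", nf),
            call. = FALSE)
  colnames(au_presence) <- paste0("AU", AU_PRESENCE_IDS)
  colnames(au_intensity) <- paste0("AU", AU_INTENSITY_IDS)
  structure(
    list(participant_id = as.character(participant_id), task = task,
         group = group, timestamps = as.numeric(timestamps), coords = coords,
         confidence = as.numeric(confidence), success = as.integer(success),
         au_presence = au_presence, au_intensity = au_intensity),
    class = "landmark_series")
}

as_coord_array <- function(coords, nf) {
  coords <- unclass(coords)
  d <- dim(coords)
  if (is.null(d) || length(d) != 3L || d[1] != nf || d[2] != 68L || d[3] != 2L)
    stop("coords must be an F x 68 x 2 array", call. = FALSE)
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop("coords must be finite", call. = FALSE)
  coords
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series> %s | %s | %s\n",
              x$participant_id, x$group, x$task))
  cat(sprintf("  %d frames over %.2f s (%.1f Hz), 68 landmarks\n",
              nframes(x), diff(range(x$timestamps)),
              (nframes(x) - 1) / diff(range(x$timestamps))))
  cat(sprintf("  AU presence: %d cols; AU intensity: %d cols; %d low-quality frames\n",
              ncol(x$au_presence), ncol(x$au_intensity),
              sum(x$success == 0L | x$confidence < 0.75)))
  invisible(x)
}

nframes <- function(x) length(x$timestamps)
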