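# Shared fixtures, all generated in code at test time.

# A tiny landmark series with controllable coordinates; defaults to the
# static schematic face repeated over F frames.
make_series <- function(n_frames = 10L, coords = NULL, fps = 30,
                        group = "TD", task = "resting", ...) {
  if (is.null(coords)) {
    tmpl <- face_template()
    coords <- array(NA_real_, c(n_frames, 68L, 2L))
    coords[, , 1] <- matrix(tmpl[, 1], n_frames, 68L, byrow = TRUE)
    coords[, , 2] <- matrix(tmpl[, 2], n_frames, 68L, byrow = TRUE)
  }
  landmark_series("p1", task, group, (seq_len(n_frames) - 1) / fps, coords,
                  ...)
}

# Mark a series as normalized without re-deriving coordinates, for tests
# that exercise differentiation on hand-built trajectories.
as_normalized <- function(series) {
  class(series) <- unique(c("normalized_series", class(series)))
  series
}

# Population-sd z-score of a vector (independent of the package's
# implementation).
pop_z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

# Equal-weight 1-D transport cost by exhaustive assignment enumeration
# (independent oracle; n! permutations, so keep n <= 6).
brute_force_emd_equal <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1)))
}
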