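# Fixtures are built in code; no data files.

default_test_arena <- function() arena()

# Build a fly_track from a matrix of sub-segment displacements, starting
# from mid-arena so everything stays in bounds for modest displacements.
track_from_disp <- function(disp, start = c(25, 75), dt = 0.25, ...) {
  pos <- rbind(start,
               cbind(start[1] + cumsum(disp[, 1]),
                     start[2] + cumsum(disp[, 2])))
  fly_track("fx", pos, dt = dt, ...)
}

# One 5-s segment with the given 20 displacement rows.
segment_from_disp <- function(disp, ...) {
  stopifnot(nrow(disp) == 20L)
  segment_track(track_from_disp(disp, ...))[[1]]
}

# Straight-line positions along the arena diagonal.
diagonal_line_points <- function(n = 5000, a = arena()) {
  t <- seq(0, 1, length.out = n)
  cbind(t * a$width, t * a$height)
}

# A quiet preset that mostly walks with no slips, handy for fast tests.
test_preset <- function(...) {
  args <- utils::modifyList(
    list(name = "test", move_speed_mean = 3, move_speed_sd = 1,
         p_stop_entry = 0.2, p_stop_exit = 0.6, turn_sd = 0.5,
         geotaxis_drift = 0.2, slip_rate = 0.5, slip_depth_mean = 2.08,
         food_attraction = 0),
    list(...))
  do.call(behavior_preset, args)
}

# Exhaustive-scan BMU oracle, independent of find_bmu's vectorized path.
bmu_scan <- function(x, weights) {
  d <- apply(weights, 1, function(w) sqrt(sum((x - w)^2)))
  which.min(d)
}

# Brute-force box-count oracle: enumerate every grid cell and test point
# membership directly.
box_count_enum <- function(points, r, a = arena()) {
  nx <- ceiling(a$width / r + 1e-9)
  ny <- ceiling(a$height / r + 1e-9)
  cnt <- 0L
  for (i in seq_len(nx) - 1L) {
    for (j in seq_len(ny) - 1L) {
      xin <- points[, 1] >= i * r & (points[, 1] < (i + 1) * r |
        (points[, 1] == a$width & (i + 1) * r >= a$width))
      yin <- points[, 2] >= j * r & (points[, 2] < (j + 1) * r |
        (points[, 2] == a$height & (j + 1) * r >= a$height))
      if (any(xin & yin)) cnt <- cnt + 1L
    }
  }
  cnt
}

# Nine codebook archetypes embodying the four movement-pattern semantics
# (columns: speed, acceleration, locomotory_rate, meander, stop_duration,
# slipping_number on the normalized 0-1 scale).
pattern_archetypes <- function() {
  m <- rbind(
    active1  = c(0.90, 0.80, 0.90, 0.10, 0.05, 0.10),
    active2  = c(0.85, 0.75, 0.85, 0.20, 0.10, 0.15),
    active3  = c(0.80, 0.85, 0.80, 0.15, 0.05, 0.05),
    circling = c(0.30, 0.30, 0.35, 0.70, 0.20, 0.10),
    zigzag1  = c(0.45, 0.50, 0.50, 0.95, 0.15, 0.60),
    zigzag2  = c(0.40, 0.45, 0.45, 0.90, 0.20, 0.55),
    zigzag3  = c(0.42, 0.40, 0.48, 0.85, 0.15, 0.50),
    stop1    = c(0.02, 0.05, 0.00, 0.00, 0.95, 0.00),
    stop2    = c(0.05, 0.08, 0.05, 0.05, 0.90, 0.05))
  colnames(m) <- feature_names()
  m
}

# A som_model whose 140 nodes are noisy copies of the nine archetypes,
# with identity bounds (raw scale == normalized scale).
archetype_model <- function(noise = 0.01, seed = 5) {
  set.seed(seed)
  arch <- pattern_archetypes()
  assign_to <- rep(seq_len(9), length.out = 140)
  w <- arch[assign_to, ] + matrix(rnorm(140 * 6, 0, noise), 140)
  w[w < 0] <- 0
  colnames(w) <- feature_names()
  bounds <- rbind(min = rep(0, 6), max = rep(1, 6))
  colnames(bounds) <- feature_names()
  model <- ethoscreen:::new_som_model(w, c(14L, 10L), bounds,
                                      default_som_schedule(), seed,
                                      trained = TRUE)
  attr(model, "truth") <- assign_to
  model
}
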