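SEG_SUBSEGMENTS <- 20L
SEG_SECONDS <- 5
MOVE_THRESHOLD_MM <- 0.1  # displacements below ~1/10 body size count as "stopped"
# strict comparison with a guard against accumulated floating-point error,
# so a displacement of exactly 0.1 mm always counts as movement
is_stopped <- function(mag) mag < MOVE_THRESHOLD_MM - 1e-9

#' Split a track into 5-s segments
#'
#' Partitions a 0.25-s track into non-overlapping 5-s windows of 20
#' consecutive sub-segment displacement vectors. Trailing sub-segments that
#' do not fill a whole window are discarded, so a track of `n` positions
#' yields `floor((n - 1) / 20)` segments.
#'
#' @param track A [fly_track()] sampled at 0.25 s.
#' @return List of segments; each has the 20 x 2 displacement matrix
#'   `disp` (mm), the index of its first position `start`, and `dt`.
#' @export
segment_track <- function(track) {
  stopifnot(inherits(track, "fly_track"))
  if (abs(track$dt - 0.25) > 1e-9) {
    stop("segmentation assumes 0.25-s sampling; resampling is unsupported",
         call. = FALSE)
  }
  disp <- diff(track$positions)
  n_seg <- nrow(disp) %/% SEG_SUBSEGMENTS
  lapply(seq_len(n_seg), function(i) {
    rows <- ((i - 1L) * SEG_SUBSEGMENTS + 1L):(i * SEG_SUBSEGMENTS)
    structure(list(disp = disp[rows, , drop = FALSE],
                   start = rows[1L], dt = track$dt),
              class = "track_segment")
  })
}

seg_disp <- function(segment) {
  stopifnot(inherits(segment, "track_segment"),
            nrow(segment$disp) == SEG_SUBSEGMENTS)
  segment$disp
}

#' Per-segment speed (mm/s)
#'
#' Total path length of the 20 sub-segments divided by the 5-s segment
#' duration.
#' @param segment A segment from [segment_track()].
#' @return Speed in mm/s.
#' @export
compute_speed <- function(segment) {
  d <- seg_disp(segment)
  sum(sqrt(rowSums(d^2))) / SEG_SECONDS
}

#' Per-segment acceleration (mm/s^2)
#'
#' Mean absolute difference between consecutive sub-segment speeds, divided
#' by the 0.25-s sub-segment duration.
#' @inheritParams compute_speed
#' @return Acceleration in mm/s^2.
#' @export
compute_acceleration <- function(segment) {
  d <- seg_disp(segment)
  v <- sqrt(rowSums(d^2)) / segment$dt
  mean(abs(diff(v))) / segment$dt
}

#' Per-segment stop duration (s)
#'
#' 0.25 s for every sub-segment whose displacement is strictly below the
#' 0.1-mm movement threshold (about 1/10 of the body size).
#' @inheritParams compute_speed
#' @return Stop duration in seconds, in `[0, 5]`.
#' @export
compute_stop_duration <- function(segment) {
  d <- seg_disp(segment)
  sum(is_stopped(sqrt(rowSums(d^2)))) * segment$dt
}

#' Per-segment locomotory rate (mm/s)
#'
#' Path length divided by the time spent moving (5 s minus the stop
#' duration); always at least the speed. `NA` for a fully stopped segment,
#' where no moving time exists.
#' @inheritParams compute_speed
#' @return Locomotory rate in mm/s, or `NA`.
#' @export
compute_locomotory_rate <- function(segment) {
  d <- seg_disp(segment)
  stop_s <- compute_stop_duration(segment)
  if (stop_s >= SEG_SECONDS) return(NA_real_)
  sum(sqrt(rowSums(d^2))) / (SEG_SECONDS - stop_s)
}

#' Per-segment meander (rad/mm)
#'
#' Accumulated absolute heading change between consecutive *moving*
#' sub-segments divided by the path length of the moving sub-segments.
#' Stopped sub-segments are skipped because their heading is undefined.
#' `NA` when fewer than two moving sub-segments exist.
#' @inheritParams compute_speed
#' @return Meander in rad/mm, or `NA`.
#' @export
compute_meander <- function(segment) {
  d <- seg_disp(segment)
  mag <- sqrt(rowSums(d^2))
  mov <- !is_stopped(mag)
  if (sum(mov) < 2L) return(NA_real_)
  head_ang <- atan2(d[mov, 2], d[mov, 1])
  turns <- abs(wrap_angle(diff(head_ang)))
  sum(turns) / sum(mag[mov])
}

#' Per-segment slipping number
#'
#' A slip event is a maximal run of consecutive sub-segments whose downward
#' vertical displacement exceeds `slip_threshold` mm per 0.25 s; each
#' maximal run counts once.
#' @inheritParams compute_speed
#' @param slip_threshold Downward displacement threshold in mm per
#'   sub-segment (default 2, i.e. 8 mm/s downward).
#' @return Integer slip count.
#' @export
count_slips <- function(segment, slip_threshold = 2) {
  d <- seg_disp(segment)
  sl <- -d[, 2] > slip_threshold
  sum(sl & !c(FALSE, sl[-length(sl)]))
}

#' Zone occupancy of a track
#'
#' Assigns each 0.25-s sub-segment to the zone of its end position and
#' accumulates stay durations per zone, both per 30-s window and overall.
#'
#' @param track A [fly_track()].
#' @param arena The [arena()] defining the zones (default: the standard
#'   arena).
#' @param window Window length in seconds (default 30).
#' @return A data.frame with one row per window (columns `window`,
#'   `t_start`, and seconds per zone), with the overall per-zone totals in
#'   attribute `"overall"`.
#' @export
zone_occupancy <- function(track, arena = ethoscreen::arena(), window = 30) {
  stopifnot(inherits(track, "fly_track"))
  ends <- track$positions[-1L, , drop = FALSE]
  zones <- factor(zone_of(ends, arena), levels = zone_levels())
  idx <- ((seq_len(nrow(ends)) - 1L) %/% as.integer(round(window / track$dt)))
  tab <- table(window = idx, zone = zones) * track$dt
  out <- data.frame(window = as.integer(rownames(tab)),
                    t_start = as.integer(rownames(tab)) * window)
  for (z in zone_levels()) out[[z]] <- as.numeric(tab[, z])
  attr(out, "overall") <- colSums(tab)
  out
}

# Vectorized per-track feature computation; kept numerically identical to
# the per-segment operations above (tested against them).
track_features <- function(track, slip_threshold = 2) {
  if (abs(track$dt - 0.25) > 1e-9) {
    stop("feature extraction assumes 0.25-s sampling", call. = FALSE)
  }
  dt <- track$dt
  disp <- diff(track$positions)
  n_seg <- nrow(disp) %/% SEG_SUBSEGMENTS
  if (n_seg == 0L) return(NULL)
  used <- seq_len(n_seg * SEG_SUBSEGMENTS)
  mag <- matrix(sqrt(rowSums(disp[used, , drop = FALSE]^2)),
                nrow = SEG_SUBSEGMENTS)
  dy <- matrix(disp[used, 2], nrow = SEG_SUBSEGMENTS)
  speed <- colSums(mag) / SEG_SECONDS
  v <- mag / dt
  accel <- colMeans(abs(diff(v))) / dt
  stopped <- is_stopped(mag)
  stop_dur <- colSums(stopped) * dt
  loco <- ifelse(stop_dur < SEG_SECONDS,
                 colSums(mag) / (SEG_SECONDS - stop_dur), NA_real_)
  sl <- -dy > slip_threshold
  starts <- sl & !rbind(FALSE, sl[-SEG_SUBSEGMENTS, , drop = FALSE])
  slips <- colSums(starts)
  ang <- matrix(atan2(disp[used, 2], disp[used, 1]), nrow = SEG_SUBSEGMENTS)
  meander <- vapply(seq_len(n_seg), function(j) {
    mov <- !stopped[, j]
    if (sum(mov) < 2L) return(NA_real_)
    sum(abs(wrap_angle(diff(ang[mov, j])))) / sum(mag[mov, j])
  }, numeric(1))
  data.frame(individual_id = track$individual_id, strain = track$strain,
             treatment = track$treatment, session = track$session,
             segment = seq_len(n_seg),
             t_start = (seq_len(n_seg) - 1L) * SEG_SECONDS,
             speed = speed, acceleration = accel,
             locomotory_rate = loco, meander = meander,
             stop_duration = stop_dur, slipping_number = slips)
}

#' Segment-feature table of a track set
#'
#' Computes the six movement parameters for every 5-s segment of every
#' track: speed, acceleration, locomotory rate, meander, stop duration and
#' slipping number, alongside the cohort labels. Parameters that are
#' undefined on fully stopped segments (locomotory rate, meander) are
#' flagged as `NA`, never silently zeroed; [normalize_features()] decides
#' how to impute them for SOM input.
#'
#' @param trackset A [track_set()] (or a single [fly_track()]).
#' @param slip_threshold Passed to the slip detector (mm per sub-segment).
#' @return A data.frame with one row per segment.
#' @export
extract_features <- function(trackset, slip_threshold = 2) {
  tracks <- if (inherits(trackset, "fly_track")) list(trackset)
  else {
    stopifnot(inherits(trackset, "track_set"))
    trackset$tracks
  }
  out <- do.call(rbind, lapply(tracks, track_features,
                               slip_threshold = slip_threshold))
  if (is.null(out)) {
    stop("no complete 5-s segment in the input tracks", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Names of the six movement parameters
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("speed", "acceleration", "locomotory_rate",
    "meander", "stop_duration", "slipping_number")
}
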