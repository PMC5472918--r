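#' Simulation configuration
#'
#' @param arena The [arena()] to simulate in.
#' @param dt Sampling interval in seconds (the analysis assumes 0.25 s).
#' @param duration Track duration in seconds; must be an integer multiple of
#'   `dt`. The default of 1800 s is one 30-min observation window, the
#'   window length the fractal analysis of movement tracks uses.
#' @param n_individuals Tracks per group (default 15, the cohort size).
#' @param seed Master seed; per-individual seeds are derived from it
#'   deterministically.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(arena = ethoscreen::arena(), dt = 0.25,
                              duration = 1800, n_individuals = 15, seed = 1) {
  stopifnot(inherits(arena, "arena"), dt > 0, duration > 0)
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("duration must be an integer multiple of dt", call. = FALSE)
  }
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  structure(list(arena = arena, dt = dt, duration = duration,
                 n_steps = as.integer(round(n_steps)),
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Expected value of N(m, s) truncated below at 0.
truncnorm_mean <- function(m, s) {
  if (s <= 0) return(max(m, 0))
  z <- m / s
  m + s * stats::dnorm(z) / stats::pnorm(z)
}

# Location parameter m such that the 0-truncated normal N(m, s) has the
# requested mean. Inverted numerically; the mapping is monotone in m.
truncnorm_location <- function(target, s) {
  if (s <= 0 || target <= 0) return(target)
  stats::uniroot(function(m) truncnorm_mean(m, s) - target,
                 lower = target - 6 * s, upper = target + s,
                 tol = 1e-10)$root
}

# Mean displacement of a stationary ("stop") sub-segment; draws are
# U(0, 2 * STOP_JITTER_MEAN), safely below the 0.1-mm movement threshold.
STOP_JITTER_MEAN <- 0.04

# Per-preset derived step parameters. Solves the per-segment path budget
#   slip_path + (20 - slip_steps) * (f * mu_move + (1 - f) * jitter) = 5 * v
# for the expected moving-step displacement mu_move, then inverts the
# truncated normal so the realized mean matches, and thins the slip trigger
# so that executed (= detected) events arrive at slip_rate per 5 s despite
# the steps consumed by slip runs and the one-step refractory gap.
calibrate_preset <- function(preset, dt = 0.25) {
  steps_per_seg <- 5 / dt
  lambda <- preset$slip_rate
  depth <- preset$slip_depth_mean
  slip_len <- max(1L, min(3L, as.integer(ceiling(depth / 2.5))))
  pe <- preset$p_stop_entry
  px <- preset$p_stop_exit
  f_move <- if (pe + px > 0) px / (pe + px) else 1
  if (lambda * slip_len >= steps_per_seg) {
    stop(sprintf("preset '%s': slip_rate x run length exceeds the segment",
                 preset$name), call. = FALSE)
  }
  # slips persist only if the fly climbs back: the sustainable event rate
  # is bounded by the expected upward flux of the moving path. The heading
  # is an AR(1) walk around "up" with coefficient (1 - drift), so its
  # stationary spread is turn_sd / sqrt(1 - (1 - drift)^2) and the mean
  # upward fraction of a step is exp(-spread^2 / 2). Above that bound the
  # realized rate saturates; the speed budget uses the saturated value.
  total_path <- 5 * preset$move_speed_mean
  lambda_eff <- lambda
  if (lambda > 0 && preset$geotaxis_drift > 0 && preset$geotaxis_drift < 1) {
    h_var <- preset$turn_sd^2 / (1 - (1 - preset$geotaxis_drift)^2)
    e_up <- exp(-h_var / 2)
    lambda_eff <- min(lambda, e_up * total_path / (depth * (1 + e_up)))
  }
  non_slip <- steps_per_seg - lambda_eff * slip_len
  budget <- total_path - lambda_eff * depth -
    non_slip * (1 - f_move) * STOP_JITTER_MEAN
  mu_move <- if (f_move > 1e-9) budget / (non_slip * f_move) else 0
  sd_step <- preset$move_speed_sd * dt
  m_loc <- if (mu_move > 0) truncnorm_location(mu_move, sd_step) else 0
  # per-step trigger probability: one renewal cycle is the geometric wait
  # to a trigger (the triggering step is the first slip step) plus the
  # L - 1 remaining slip steps plus the refractory step, so the event rate
  # is p / (1 + p * slip_len); invert for the target rate per step
  ev <- lambda / steps_per_seg
  p_trig <- if (lambda > 0) ev / max(1 - ev * slip_len, 1e-9) else 0
  p_trig <- min(p_trig, 1)
  list(slip_len = slip_len, f_move = f_move, mu_move = mu_move,
       m_loc = m_loc, sd_step = sd_step, p_trig = p_trig)
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a
}

#' Simulate one movement track
#'
#' Generates a fixed-rate trajectory from a [behavior_preset()]: a two-state
#' (move/stop) Markov chain over `dt`-steps; while moving, the step length
#' is drawn from a positive-truncated normal calibrated so the measured
#' per-segment speed matches the preset nominal, and the heading performs a
#' correlated walk blended toward "up" with weight `geotaxis_drift` (the
#' upward bias relaxes within 10 mm of the top edge, where geotaxis is
#' satisfied); while stopped, displacements stay below the 0.1-mm movement
#' threshold. Slip events arrive as a thinned Poisson process at
#' `slip_rate` per 5 s and insert 1-3 consecutive steep downward steps
#' totaling about `slip_depth_mean`. A step that would leave the arena is
#' reflected off the wall before it is taken, preserving its length.
#'
#' The executed slip events are attached as attribute `"slip_events"`
#' (a data.frame of start step and total drop) so detector sensitivity can
#' be measured against ground truth. Identical seeds give identical tracks.
#'
#' @param preset A [behavior_preset()].
#' @param config A [simulation_config()].
#' @param individual_seed Integer seed for this individual.
#' @param individual_id Identifier for the track (default derived from the
#'   preset name and seed).
#' @param session Session label, `"pre"` or `"post"`.
#' @return A [fly_track()].
#' @export
generate_track <- function(preset, config, individual_seed,
                           individual_id = NULL, session = "pre") {
  stopifnot(inherits(preset, "behavior_preset"),
            inherits(config, "simulation_config"))
  a <- config$arena
  if (preset$slip_depth_mean > a$height) {
    stop(sprintf("preset '%s': slip_depth_mean exceeds the arena height",
                 preset$name), call. = FALSE)
  }
  if (is.null(individual_id)) {
    individual_id <- sprintf("%s_%d", preset$name, individual_seed)
  }
  cal <- calibrate_preset(preset, config$dt)
  n <- config$n_steps

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(individual_seed)

  # pre-drawn randomness; slip-event details are drawn inline when triggered
  u_state <- stats::runif(n)
  turn <- stats::rnorm(n, 0, preset$turn_sd)
  u_len <- stats::runif(n)
  u_trig <- stats::runif(n)
  jit_len <- stats::runif(n, 0, 2 * STOP_JITTER_MEAN)
  jit_dir <- stats::runif(n, 0, 2 * pi)
  p0 <- stats::pnorm(0, cal$m_loc, cal$sd_step)
  step_len <- stats::qnorm(p0 + u_len * (1 - p0), cal$m_loc, cal$sd_step)
  step_len[!is.finite(step_len)] <- cal$mu_move

  drift <- preset$geotaxis_drift
  relax_y <- a$height - 10
  food_c <- if (!is.null(a$food_region))
    c(mean(a$food_region[1:2]), mean(a$food_region[3:4])) else NULL
  gate_y <- 1.1 * preset$slip_depth_mean + 1

  pos <- matrix(0, n + 1L, 2L)
  x <- a$width / 2
  y <- a$height / 2
  pos[1L, ] <- c(x, y)
  h <- stats::runif(1, -pi, pi)
  moving <- stats::runif(1) < cal$f_move
  slip_left <- 0L
  slip_drop <- 0
  refractory <- FALSE
  ev_start <- integer(0)
  ev_drop <- numeric(0)

  for (i in seq_len(n)) {
    if (slip_left > 0L) {
      vx <- stats::runif(1, -0.2, 0.2)
      vy <- -slip_drop
      slip_left <- slip_left - 1L
      if (slip_left == 0L) refractory <- TRUE
      h <- atan2(vy, vx)
    } else {
      start_slip <- !refractory && cal$p_trig > 0 &&
        u_trig[i] < cal$p_trig && y >= gate_y
      refractory <- FALSE
      if (start_slip) {
        total <- preset$slip_depth_mean * stats::runif(1, 0.97, 1.03)
        slip_drop <- total / cal$slip_len
        ev_start <- c(ev_start, i)
        ev_drop <- c(ev_drop, total)
        vx <- stats::runif(1, -0.2, 0.2)
        vy <- -slip_drop
        slip_left <- cal$slip_len - 1L
        if (slip_left == 0L) refractory <- TRUE
        h <- atan2(vy, vx)
      } else {
        if (moving) {
          if (u_state[i] < preset$p_stop_entry) moving <- FALSE
        } else if (u_state[i] < preset$p_stop_exit) moving <- TRUE
        if (moving) {
          h <- h + turn[i]
          if (drift > 0 && y > relax_y) {
            # geotaxis satisfied near the top: follow the wall instead of
            # pushing into it (tangential blending avoids ballistic
            # reflections that would mimic slips)
            tangent <- if (cos(h) >= 0) 0 else pi
            h <- h + max(drift, 0.5) * wrap_angle(tangent - h)
          } else if (drift != 0) {
            h <- h + drift * wrap_angle(pi / 2 - h)
          }
          if (preset$food_attraction > 0 && !is.null(food_c)) {
            to_food <- atan2(food_c[2] - y, food_c[1] - x)
            h <- h + min(preset$food_attraction, 1) * wrap_angle(to_food - h)
          }
          len <- step_len[i]
          vx <- len * cos(h)
          vy <- len * sin(h)
        } else {
          vx <- jit_len[i] * cos(jit_dir[i])
          vy <- jit_len[i] * sin(jit_dir[i])
        }
      }
    }
    # reflect the step off any wall it would cross (length-preserving)
    if (x + vx < 0 || x + vx > a$width) vx <- -vx
    if (y + vy < 0 || y + vy > a$height) vy <- -vy
    x <- min(max(x + vx, 0), a$width)
    y <- min(max(y + vy, 0), a$height)
    if (vx != 0 || vy != 0) h <- atan2(vy, vx)
    pos[i + 1L, ] <- c(x, y)
  }

  tr <- fly_track(individual_id, pos,
                  strain = preset$strain, treatment = preset$treatment,
                  session = session, dt = config$dt, arena = a)
  attr(tr, "slip_events") <- data.frame(start_step = ev_start,
                                        total_drop = ev_drop)
  attr(tr, "preset_name") <- preset$name
  tr
}

#' Simulate a cohort of tracks
#'
#' Generates `config$n_individuals` tracks for each preset, with
#' per-individual seeds derived deterministically from the master seed
#' (`config$seed`), so the same master seed reproduces the identical
#' [track_set()].
#'
#' @param presets Named list of [behavior_preset()] objects (for example
#'   [default_presets()], or a subset of it).
#' @param config A [simulation_config()].
#' @param session Session label applied to all generated tracks.
#' @return A [track_set()] with `length(presets) * n_individuals` tracks.
#' @export
generate_cohort <- function(presets, config = simulation_config(),
                            session = "pre") {
  if (inherits(presets, "behavior_preset")) presets <- list(presets)
  if (!length(presets) || !all(vapply(presets, inherits, logical(1),
                                      "behavior_preset"))) {
    stop("presets must be a non-empty list of behavior_preset objects",
         call. = FALSE)
  }
  if (is.null(names(presets)) || any(!nzchar(names(presets)))) {
    names(presets) <- vapply(presets, function(p) p$name, character(1))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      length(presets) * config$n_individuals)
  tracks <- vector("list", length(seeds))
  k <- 0L
  for (nm in names(presets)) {
    for (j in seq_len(config$n_individuals)) {
      k <- k + 1L
      tracks[[k]] <- generate_track(
        presets[[nm]], config, individual_seed = seeds[k],
        individual_id = sprintf("%s_%02d_%s", nm, j, session),
        session = session)
    }
  }
  track_set(tracks, config$arena)
}

#' Simulate the full pre/post study design
#'
#' Emulates the observation design of the screening study: for every strain
#' x treatment group, a pre-treatment session drawn from the strain's
#' control preset and a post-treatment session drawn from the strain x
#' treatment preset, `n_individuals` flies each.
#'
#' @param config A [simulation_config()].
#' @param presets Preset registry (default [default_presets()]).
#' @return A [track_set()] with `2 * length(presets) * n_individuals`
#'   tracks.
#' @export
generate_study <- function(config = simulation_config(),
                           presets = default_presets()) {
  strains <- unique(vapply(presets, function(p) p$strain, character(1)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      2L * length(presets) * config$n_individuals)
  tracks <- vector("list", length(seeds))
  k <- 0L
  for (nm in names(presets)) {
    p <- presets[[nm]]
    ctrl_name <- paste(p$strain, "control", sep = ".")
    if (!ctrl_name %in% names(presets)) {
      stop(sprintf("missing control preset for strain '%s'", p$strain),
           call. = FALSE)
    }
    pre_preset <- presets[[ctrl_name]]
    # the pre session shows the strain's untreated behavior but keeps the
    # group's treatment label, as in a paired pre/post design
    pre_preset$treatment <- p$treatment
    for (j in seq_len(config$n_individuals)) {
      k <- k + 1L
      tracks[[k]] <- generate_track(
        pre_preset, config, individual_seed = seeds[k],
        individual_id = sprintf("%s_%02d_pre", nm, j), session = "pre")
      k <- k + 1L
      tracks[[k]] <- generate_track(
        p, config, individual_seed = seeds[k],
        individual_id = sprintf("%s_%02d_post", nm, j), session = "post")
    }
  }
  track_set(tracks, config$arena)
}
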