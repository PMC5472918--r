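#' Behavioral preset for the track simulator
#'
#' Bundles the parameters of the two-state (move/stop) correlated random
#' walk with Poisson slip events used by [generate_track()]. The two
#' calibrated nominals are *observables*: `move_speed_mean` is the target
#' mean per-segment speed (total path per 5 s divided by 5 s) and
#' `slip_rate` the target mean number of detected slip events per 5-s
#' segment. The simulator solves internally for the moving-step length
#' distribution that realizes `move_speed_mean` given the stop fraction and
#' slip displacement budget (see the methods vignette).
#'
#' @param name Preset label, conventionally `"<strain>.<treatment>"`.
#' @param move_speed_mean Nominal mean per-segment speed, mm/s (> 0).
#' @param move_speed_sd Spread of the moving-step speed, mm/s (>= 0).
#' @param p_stop_entry Per-sub-segment probability of entering a stop bout,
#'   in `[0, 1]`.
#' @param p_stop_exit Per-sub-segment probability of leaving a stop bout,
#'   in `[0, 1]`.
#' @param turn_sd Heading-change spread while moving, radians (>= 0).
#' @param geotaxis_drift Upward heading bias in `[-1, 1]`; 0 is drift-free.
#' @param slip_rate Nominal slip events per 5-s segment (>= 0).
#' @param slip_depth_mean Mean total downward displacement of one slip
#'   event, mm.
#' @param food_attraction Heading bias toward the food region, `>= 0`.
#' @param strain,treatment Optional cohort labels carried onto generated
#'   tracks.
#' @return An object of class `"behavior_preset"`.
#' @seealso [default_presets()], [generate_track()]
#' @export
behavior_preset <- function(name, move_speed_mean, move_speed_sd,
                            p_stop_entry, p_stop_exit,
                            turn_sd, geotaxis_drift,
                            slip_rate, slip_depth_mean = 2.08,
                            food_attraction = 0,
                            strain = "wild_type", treatment = "control") {
  probs <- c(p_stop_entry = p_stop_entry, p_stop_exit = p_stop_exit)
  if (any(probs < 0 | probs > 1)) {
    stop("stop entry/exit probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!(move_speed_mean > 0)) stop("move_speed_mean must be > 0", call. = FALSE)
  if (move_speed_sd < 0) stop("move_speed_sd must be >= 0", call. = FALSE)
  if (slip_rate < 0) stop("slip_rate must be >= 0", call. = FALSE)
  if (!(slip_depth_mean > 0)) stop("slip_depth_mean must be > 0", call. = FALSE)
  if (abs(geotaxis_drift) > 1) {
    stop("geotaxis_drift must lie in [-1, 1]", call. = FALSE)
  }
  if (turn_sd < 0) stop("turn_sd must be >= 0", call. = FALSE)
  if (food_attraction < 0) stop("food_attraction must be >= 0", call. = FALSE)
  structure(
    list(name = name,
         move_speed_mean = move_speed_mean, move_speed_sd = move_speed_sd,
         p_stop_entry = p_stop_entry, p_stop_exit = p_stop_exit,
         turn_sd = turn_sd, geotaxis_drift = geotaxis_drift,
         slip_rate = slip_rate, slip_depth_mean = slip_depth_mean,
         food_attraction = food_attraction,
         strain = strain, treatment = treatment),
    class = "behavior_preset"
  )
}

#' @export
print.behavior_preset <- function(x, ...) {
  cat(sprintf("<behavior_preset> %s\n", x$name))
  cat(sprintf("  speed %g +/- %g mm/s | stop entry/exit %g/%g | slips %g per 5 s\n",
              x$move_speed_mean, x$move_speed_sd,
              x$p_stop_entry, x$p_stop_exit, x$slip_rate))
  cat(sprintf("  turn sd %g rad | geotaxis drift %g | slip depth %g mm\n",
              x$turn_sd, x$geotaxis_drift, x$slip_depth_mean))
  invisible(x)
}

# stop entry probability implied by a stationary stop-time fraction q and a
# given exit probability: q = pe / (pe + px)
stop_entry_for <- function(q, p_stop_exit) p_stop_exit * q / (1 - q)

#' Default strain-by-treatment preset registry
#'
#' Returns the nine presets (3 strains x 3 treatments) the cohort simulator
#' uses. The nominal per-segment speeds and per-5-s slip counts equal the
#' group statistics reported for walking flies in the vertical arena
#' (wild-type 3.52 mm/s and 0.85 slips per 5 s before treatment, the p38b
#' mutant fastest at 4.22 mm/s, the p53 mutant slowest at 2.72 mm/s;
#' toluene and formaldehyde lower speed and raise slipping, most strongly
#' for p38b under formaldehyde at 4.03 slips per 5 s). Treatment presets
#' additionally encode longer stop bouts, larger heading changes, and a
#' sluggish low-variance gait, so that downstream estimates of speed,
#' acceleration and locomotory rate decrease while stop duration, meander
#' and slipping increase relative to the same strain's control preset.
#' Stop-bout parameters and gait variance are not reported quantities; the
#' choices are documented in the methods vignette.
#'
#' @return Named list of nine [behavior_preset()] objects, keyed
#'   `"<strain>.<treatment>"`.
#' @export
default_presets <- function() {
  spec <- list(
    #            speed  q_stop  p_exit  sd    turn  drift  slips
    wild_type.control      = c(3.52, 0.32, 0.70, 2.4, 0.45, 0.18, 0.85),
    wild_type.toluene      = c(3.12, 0.38, 0.57, 1.2, 0.70, 0.35, 1.23),
    wild_type.formaldehyde = c(2.66, 0.44, 0.30, 0.8, 0.80, 0.30, 2.91),
    p38b.control           = c(4.22, 0.26, 0.70, 2.6, 0.45, 0.18, 0.94),
    p38b.toluene           = c(2.66, 0.44, 0.34, 0.8, 0.75, 0.18, 2.05),
    p38b.formaldehyde      = c(2.18, 0.38, 0.28, 0.25, 0.80, 0.60, 4.03),
    p53.control            = c(2.72, 0.36, 0.65, 1.5, 0.45, 0.15, 1.04),
    p53.toluene            = c(2.10, 0.44, 0.28, 0.5, 0.85, 0.25, 1.83),
    p53.formaldehyde       = c(2.25, 0.40, 0.30, 0.5, 0.85, 0.25, 2.09)
  )
  out <- lapply(names(spec), function(nm) {
    p <- spec[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    behavior_preset(
      name = nm,
      move_speed_mean = p[1], move_speed_sd = p[4],
      p_stop_entry = stop_entry_for(p[2], p[3]), p_stop_exit = p[3],
      turn_sd = p[5], geotaxis_drift = p[6],
      slip_rate = p[7], slip_depth_mean = 2.08, food_attraction = 0,
      strain = parts[1], treatment = parts[2])
  })
  names(out) <- names(spec)
  out
}
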