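#' Box count of a point set
#'
#' Number of cells of a square grid of side `r`, anchored at the arena
#' origin, that contain at least one point.
#'
#' @param points n x 2 matrix of (x, y) positions in mm.
#' @param r Box side length in mm (> 0).
#' @param arena The [arena()] the points live in (defines the grid origin
#'   and bounds).
#' @return Integer count of occupied boxes.
#' @export
box_count <- function(points, r, arena = ethoscreen::arena()) {
  points <- as_xy_matrix(points)
  if (nrow(points) == 0L) stop("empty point set", call. = FALSE)
  if (!(r > 0)) stop("box size must be positive", call. = FALSE)
  if (!all(in_arena(points, arena))) {
    stop("points outside arena bounds", call. = FALSE)
  }
  ix <- floor(points[, 1] / r)
  iy <- floor(points[, 2] / r)
  # points exactly on the far edge belong to the last interior cell
  ix[points[, 1] >= arena$width] <- floor(arena$width / r - 1e-9)
  iy[points[, 2] >= arena$height] <- floor(arena$height / r - 1e-9)
  n_x <- floor(arena$width / r) + 2
  length(unique(iy * n_x + ix))
}

#' Dyadic box-size sequence
#'
#' Halving sequence from `from` (default half the arena height) down to
#' `floor_mm` (default 0.5 mm, about five times the 0.1-mm movement
#' resolution, so tracker noise is not counted as structure).
#'
#' @param arena The [arena()].
#' @param from Largest box size in mm.
#' @param floor_mm Smallest admissible box size in mm.
#' @return Descending numeric vector of box sizes.
#' @export
default_box_sizes <- function(arena = ethoscreen::arena(),
                              from = arena$height / 2, floor_mm = 0.5) {
  sizes <- from / 2^(0:30)
  sizes[sizes >= floor_mm]
}

#' Box-counting fractal dimension
#'
#' Estimates the fractal dimension D of a point set as the least-squares
#' slope of log N(r) against log(1/r), where N(r) is the [box_count()] at
#' box size r. For a dense straight line D is close to 1, for a set
#' filling the arena D is close to 2. When all counts are equal (e.g. a
#' single repeated point) the fit is degenerate and the estimate is
#' flagged with D = 0.
#'
#' @param points n x 2 matrix of positions in mm.
#' @param box_sizes Descending box sizes in mm; at least 4 sizes spanning
#'   at least 2 octaves (default [default_box_sizes()]).
#' @param arena The [arena()].
#' @return An object of class `"fractal_estimate"`: list with `box_sizes`,
#'   `counts`, `dimension`, `fit_r2`, `degenerate`.
#' @export
estimate_dimension <- function(points, box_sizes = default_box_sizes(arena),
                               arena = ethoscreen::arena()) {
  box_sizes <- sort(as.numeric(box_sizes), decreasing = TRUE)
  if (length(box_sizes) < 4L) {
    stop("need at least 4 box sizes", call. = FALSE)
  }
  if (max(box_sizes) / min(box_sizes) < 4) {
    stop("box sizes must span at least 2 octaves", call. = FALSE)
  }
  counts <- vapply(box_sizes, function(r) box_count(points, r, arena),
                   numeric(1))
  if (length(unique(counts)) == 1L) {
    est <- list(box_sizes = box_sizes, counts = counts,
                dimension = 0, fit_r2 = NA_real_, degenerate = TRUE)
  } else {
    fit <- stats::lm(log(counts) ~ log(1 / box_sizes))
    est <- list(box_sizes = box_sizes, counts = counts,
                dimension = unname(stats::coef(fit)[2]),
                fit_r2 = stats::cor(log(counts), log(1 / box_sizes))^2,
                degenerate = FALSE)
  }
  structure(est, class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate> D = %.3f (R^2 = %s, %d box sizes%s)\n",
              x$dimension,
              if (is.na(x$fit_r2)) "NA" else sprintf("%.3f", x$fit_r2),
              length(x$box_sizes),
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Windowed fractal dimensions of a track set
#'
#' Tiles each track into non-overlapping windows (default 30 min, the
#' observation period over which movement-track complexity is assessed)
#' and estimates the box-counting dimension of the positions in each
#' window. A window longer than the track yields a single truncated
#' window, flagged in the output.
#'
#' @param trackset A [track_set()] (or a single [fly_track()]).
#' @param window Window length in seconds (default 1800).
#' @param box_sizes Box sizes passed to [estimate_dimension()].
#' @return A data.frame with one row per track window: labels, `window`,
#'   `n_points`, `dimension`, `fit_r2`, `degenerate`, `truncated`.
#' @export
track_dimensions <- function(trackset, window = 1800,
                             box_sizes = NULL) {
  tracks <- if (inherits(trackset, "fly_track")) {
    a <- ethoscreen::arena()
    list(trackset)
  } else {
    stopifnot(inherits(trackset, "track_set"))
    a <- trackset$arena
    trackset$tracks
  }
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(a)
  rows <- list()
  for (tr in tracks) {
    if (abs(window %% tr$dt) > 1e-9 &&
        abs(window %% tr$dt - tr$dt) > 1e-9) {
      stop("window must be divisible by dt", call. = FALSE)
    }
    per_win <- as.integer(round(window / tr$dt))
    n <- nrow(tr$positions)
    n_win <- max(1L, n %/% per_win)
    for (w in seq_len(n_win)) {
      idx <- ((w - 1L) * per_win + 1L):min(w * per_win, n)
      est <- estimate_dimension(tr$positions[idx, , drop = FALSE],
                                box_sizes, a)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = tr$individual_id, strain = tr$strain,
        treatment = tr$treatment, session = tr$session, window = w,
        n_points = length(idx), dimension = est$dimension,
        fit_r2 = est$fit_r2, degenerate = est$degenerate,
        truncated = length(idx) < per_win)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
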