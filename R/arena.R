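#' Vertical observation arena
#'
#' Describes the rectangular vertical arena the flies walk in, with the
#' origin at the bottom-left corner and y increasing upward (so gravity pulls
#' toward y = 0 and a "slip" is a sharp decrease in y). Besides its outer
#' dimensions the arena carries the zone geometry used for occupancy
#' accounting: a top band, a bottom band, and a food rectangle.
#'
#' The default dimensions (50 mm wide, 150 mm high) match the observation
#' chamber used for negative-geotaxis assays of walking *Drosophila*. The
#' named zones are not standardized anywhere, so their extent is
#' configurable: by default the top and bottom bands each span 20% of the
#' arena height and the food region is a 20 mm x 10 mm rectangle centered on
#' the bottom edge.
#'
#' @param width Arena width in mm (> 0).
#' @param height Arena height in mm (> 0).
#' @param top_zone_fraction Fraction of the height (from the top) forming the
#'   "top" zone, in (0, 1).
#' @param bottom_zone_fraction Fraction of the height (from the bottom)
#'   forming the "bottom" zone, in (0, 1). `top_zone_fraction +
#'   bottom_zone_fraction` must be < 1.
#' @param food_region Numeric vector `c(xmin, xmax, ymin, ymax)` in mm giving
#'   an axis-aligned rectangle inside the arena, or `NULL` for no food region.
#' @return An object of class `"arena"`.
#' @examples
#' a <- arena()
#' zone_of(cbind(25, 149), a)
#' @export
arena <- function(width = 50, height = 150,
                  top_zone_fraction = 0.2, bottom_zone_fraction = 0.2,
                  food_region = c(15, 35, 0, 10)) {
  stopifnot(is.numeric(width), length(width) == 1L,
            is.numeric(height), length(height) == 1L)
  if (!(width > 0) || !(height > 0)) {
    stop("arena width and height must be positive", call. = FALSE)
  }
  if (!(top_zone_fraction > 0 && top_zone_fraction < 1) ||
      !(bottom_zone_fraction > 0 && bottom_zone_fraction < 1) ||
      !(top_zone_fraction + bottom_zone_fraction < 1)) {
    stop("zone fractions must lie in (0,1) and sum to less than 1",
         call. = FALSE)
  }
  if (!is.null(food_region)) {
    food_region <- as.numeric(food_region)
    if (length(food_region) != 4L || anyNA(food_region)) {
      stop("food_region must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
    }
    if (food_region[1] >= food_region[2] || food_region[3] >= food_region[4] ||
        food_region[1] < 0 || food_region[2] > width ||
        food_region[3] < 0 || food_region[4] > height) {
      stop("food_region must be a non-empty rectangle inside the arena",
           call. = FALSE)
    }
  }
  structure(
    list(width = width, height = height,
         top_zone_fraction = top_zone_fraction,
         bottom_zone_fraction = bottom_zone_fraction,
         food_region = food_region),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> %g mm wide x %g mm high (vertical)\n", x$width, x$height))
  cat(sprintf("  top zone: uppermost %g%% | bottom zone: lowest %g%%\n",
              100 * x$top_zone_fraction, 100 * x$bottom_zone_fraction))
  if (is.null(x$food_region)) {
    cat("  food region: none\n")
  } else {
    cat(sprintf("  food region: x [%g, %g], y [%g, %g] mm\n",
                x$food_region[1], x$food_region[2],
                x$food_region[3], x$food_region[4]))
  }
  invisible(x)
}

in_arena <- function(xy, arena, tol = 1e-9) {
  xy[, 1] >= -tol & xy[, 1] <= arena$width + tol &
    xy[, 2] >= -tol & xy[, 2] <= arena$height + tol
}

as_xy_matrix <- function(position) {
  if (is.matrix(position)) {
    stopifnot(ncol(position) == 2L)
    return(position)
  }
  if (is.numeric(position) && length(position) == 2L) {
    return(matrix(position, ncol = 2L))
  }
  stop("position must be a length-2 numeric or an n x 2 matrix", call. = FALSE)
}

#' Zone label of arena positions
#'
#' Maps positions to one of the named arena zones. The food region takes
#' precedence; otherwise a point is `"top"` when `y >= (1 -
#' top_zone_fraction) * height`, `"bottom"` when `y <= bottom_zone_fraction *
#' height`, and `"middle"` elsewhere. Every in-bounds point maps to exactly
#' one zone.
#'
#' @param position Length-2 numeric `c(x, y)` in mm, or an n x 2 matrix of
#'   positions.
#' @param arena An [arena()].
#' @return Character vector of zone labels in
#'   `c("top", "bottom", "food", "middle")`.
#' @export
zone_of <- function(position, arena) {
  xy <- as_xy_matrix(position)
  if (!all(in_arena(xy, arena))) {
    stop("position outside arena bounds", call. = FALSE)
  }
  zone <- rep("middle", nrow(xy))
  top_y <- (1 - arena$top_zone_fraction) * arena$height
  bot_y <- arena$bottom_zone_fraction * arena$height
  zone[xy[, 2] >= top_y] <- "top"
  zone[xy[, 2] <= bot_y] <- "bottom"
  if (!is.null(arena$food_region)) {
    f <- arena$food_region
    in_food <- xy[, 1] >= f[1] & xy[, 1] <= f[2] &
      xy[, 2] >= f[3] & xy[, 2] <= f[4]
    zone[in_food] <- "food"
  }
  zone
}

#' All zone labels
#' @return Character vector of the four zone names.
#' @export
zone_levels <- function() c("top", "bottom", "food", "middle")
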