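#' Min-max normalization of the feature table
#'
#' Rescales each of the six movement parameters to `[0, 1]` and stores the
#' per-parameter bounds so later data can be classified on the same scale.
#' Undefined entries (`NA` locomotory rate or meander on fully stopped
#' segments) are imputed as 0 *after* scaling — a fully stopped segment is
#' legitimately minimal-activity input — and the imputation flags are kept.
#' When `bounds` from a previous normalization are supplied, out-of-range
#' values are clipped to `[0, 1]` and the number of clipped entries is
#' recorded (with a warning).
#'
#' @param table Feature data.frame from [extract_features()], or a numeric
#'   matrix whose columns are the six parameters.
#' @param bounds Optional 2 x P matrix (rows `min`, `max`) from a previous
#'   call; default recomputes bounds from `table`.
#' @return An object of class `"normalized_features"`: list with the
#'   normalized matrix `x`, the `bounds`, the logical `imputed` matrix and
#'   the clip count `n_clipped`.
#' @export
normalize_features <- function(table, bounds = NULL) {
  if (is.data.frame(table)) {
    miss <- setdiff(feature_names(), names(table))
    if (length(miss)) {
      stop(sprintf("feature table lacks column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    m <- as.matrix(table[, feature_names()])
  } else {
    m <- as.matrix(table)
    if (is.null(colnames(m)) && ncol(m) == length(feature_names())) {
      colnames(m) <- feature_names()
    }
  }
  if (is.null(bounds)) {
    lo <- apply(m, 2, min, na.rm = TRUE)
    hi <- apply(m, 2, max, na.rm = TRUE)
    if (any(!(hi > lo))) {
      bad <- colnames(m)[!(hi > lo)]
      stop(sprintf("degenerate scale: constant parameter column(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    bounds <- rbind(min = lo, max = hi)
  } else {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 2L || ncol(bounds) != ncol(m)) {
      stop("bounds must be a 2 x P matrix (rows min, max)", call. = FALSE)
    }
  }
  x <- sweep(m, 2, bounds[1, ], "-")
  x <- sweep(x, 2, bounds[2, ] - bounds[1, ], "/")
  imputed <- is.na(x)
  x[imputed] <- 0
  n_clipped <- sum(x < 0 | x > 1)
  if (n_clipped > 0) {
    warning(sprintf("%d value(s) outside the stored bounds were clipped",
                    n_clipped), call. = FALSE)
    x[x < 0] <- 0
    x[x > 1] <- 1
  }
  structure(list(x = x, bounds = bounds, imputed = imputed,
                 n_clipped = n_clipped),
            class = "normalized_features")
}

norm_matrix <- function(table) {
  if (inherits(table, "normalized_features")) return(table$x)
  as.matrix(table)
}

#' Default two-phase SOM training schedule
#'
#' A rough ordering phase (10 passes, learning rate 0.5 to 0.05,
#' neighborhood radius 5 to 1) followed by a fine-tuning phase (40 passes,
#' 0.05 to 0.01, radius 1 to 0.5), with both the learning rate and the
#' radius decayed linearly within each phase.
#'
#' @return A data.frame with one row per phase.
#' @export
default_som_schedule <- function() {
  data.frame(phase = c("rough", "fine"),
             passes = c(10L, 40L),
             alpha_start = c(0.5, 0.05), alpha_end = c(0.05, 0.01),
             radius_start = c(5, 1), radius_end = c(1, 0.5))
}

som_grid_coords <- function(grid) {
  rows <- grid[1]
  cols <- grid[2]
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

new_som_model <- function(weights, grid, bounds, schedule, seed,
                          trained = FALSE) {
  structure(list(weights = weights, grid = as.integer(grid),
                 coords = som_grid_coords(grid), bounds = bounds,
                 schedule = schedule, seed = seed, trained = trained),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d grid (%d nodes), %d parameters%s\n",
              x$grid[1], x$grid[2], nrow(x$weights), ncol(x$weights),
              if (isTRUE(x$trained)) ", trained" else ", untrained"))
  invisible(x)
}

#' Best matching unit(s)
#'
#' Index of the SOM node whose weight vector has the smallest Euclidean
#' distance to the input (ties broken by the lowest node index). Nodes are
#' numbered row-major on the grid.
#'
#' @param x Normalized input vector of length P, or an n x P matrix.
#' @param model A [som_model] (from [train_som()]).
#' @return Integer node index (or vector of indices).
#' @export
find_bmu <- function(x, model) {
  w <- model$weights
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(xm) != ncol(w)) {
    stop(sprintf("input has %d parameters but the model expects %d",
                 ncol(xm), ncol(w)), call. = FALSE)
  }
  # squared distances via the expansion |x - w|^2 = |x|^2 - 2 x.w + |w|^2
  d2 <- outer(rowSums(xm^2), rep(1, nrow(w))) -
    2 * xm %*% t(w) + outer(rep(1, nrow(xm)), rowSums(w^2))
  idx <- max.col(-d2, ties.method = "first")
  if (single) idx[1L] else idx
}

#' One sequential SOM weight update
#'
#' Moves every node toward the input in proportion to the learning rate and
#' a Gaussian neighborhood centered on the best matching unit:
#' `w_j <- w_j + alpha * h(j) * (x - w_j)` with
#' `h(j) = exp(-d_grid(j, bmu)^2 / (2 radius^2))`; `h = 1` at the BMU, and
#' a vanishing radius updates only the BMU.
#'
#' @param model A [som_model].
#' @param x Normalized input vector.
#' @param bmu Node index of the best matching unit (e.g. [find_bmu()]).
#' @param alpha Learning rate in (0, 1].
#' @param radius Neighborhood radius in grid units (>= 0).
#' @return The updated model.
#' @export
update_weights <- function(model, x, bmu, alpha, radius) {
  stopifnot(alpha >= 0, alpha <= 1, radius >= 0)
  if (alpha == 0) return(model)
  w <- model$weights
  if (radius < 1e-12) {
    w[bmu, ] <- w[bmu, ] + alpha * (x - w[bmu, ])
  } else {
    d2 <- (model$coords[, 1] - model$coords[bmu, 1])^2 +
      (model$coords[, 2] - model$coords[bmu, 2])^2
    h <- exp(-d2 / (2 * radius^2))
    h[h < 1e-12] <- 0
    w <- w + (alpha * h) * sweep(-w, 2, x, "+")
  }
  model$weights <- w
  model
}

som_linear_init <- function(x, grid) {
  n <- nrow(x)
  p <- ncol(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 2)
  sd1 <- sv$d[1] / sqrt(max(n - 1, 1))
  sd2 <- if (length(sv$d) > 1) sv$d[2] / sqrt(max(n - 1, 1)) else 0
  u_r <- seq(-1, 1, length.out = grid[1])
  u_c <- if (grid[2] > 1) seq(-1, 1, length.out = grid[2]) else 0
  coords <- som_grid_coords(grid)
  w <- matrix(rep(ctr, each = prod(grid)), ncol = p)
  w <- w + outer(u_r[coords[, 1]], sd1 * sv$v[, 1])
  if (ncol(sv$v) > 1 && sd2 > 0) {
    w <- w + outer(u_c[coords[, 2]], sd2 * sv$v[, 2])
  }
  colnames(w) <- colnames(x)
  w
}

#' Train a self-organizing map on movement segments
#'
#' Fits a Kohonen map to the normalized 6-parameter segment vectors by
#' random-sample sequential training under the two-phase schedule of
#' [default_som_schedule()]. The codebook is initialized linearly along the
#' first two principal components of the data (spanning the longer grid
#' axis with the larger component), so the dominant activity gradient maps
#' onto the vertical axis of the grid; the seed determines the sample
#' order, and identical seed + data give bit-identical weights.
#'
#' The default 14 x 10 grid follows the `5 * sqrt(n)` sizing heuristic,
#' adjusted so the vertical extent exceeds the horizontal one.
#'
#' @param table A [normalize_features()] result, or a numeric matrix of
#'   normalized rows.
#' @param schedule Training schedule data.frame (see
#'   [default_som_schedule()]).
#' @param seed Integer seed for the presentation order.
#' @param grid `c(rows, cols)` of the map (default `c(14, 10)`).
#' @param init `"linear"` (default) or `"random"` (uniform in the data
#'   range, drawn from the seed).
#' @return A trained [som_model]; normalization bounds are carried over
#'   when `table` is a `normalized_features` object.
#' @export
train_som <- function(table, schedule = default_som_schedule(), seed = 1,
                      grid = c(14L, 10L), init = c("linear", "random")) {
  init <- match.arg(init)
  x <- norm_matrix(table)
  if (nrow(x) == 0L) stop("empty training table", call. = FALSE)
  if (anyNA(x)) stop("normalized input must not contain NA", call. = FALSE)
  bounds <- if (inherits(table, "normalized_features")) table$bounds else NULL
  n <- nrow(x)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  w0 <- if (init == "linear" && n >= 3L) som_linear_init(x, grid)
  else matrix(stats::runif(prod(grid) * ncol(x), min(x), max(x)),
              ncol = ncol(x), dimnames = list(NULL, colnames(x)))

  ord <- integer(0)
  alpha <- numeric(0)
  radius <- numeric(0)
  for (ph in seq_len(nrow(schedule))) {
    passes <- schedule$passes[ph]
    n_it <- passes * n
    ord <- c(ord, unlist(lapply(seq_len(passes),
                                function(i) sample.int(n))) - 1L)
    alpha <- c(alpha, seq(schedule$alpha_start[ph], schedule$alpha_end[ph],
                          length.out = n_it))
    radius <- c(radius, seq(schedule$radius_start[ph],
                            schedule$radius_end[ph], length.out = n_it))
  }
  w <- som_train_c(w0, x, som_grid_coords(grid), ord, alpha, radius)
  colnames(w) <- colnames(x)
  new_som_model(w, grid, bounds, schedule, seed, trained = TRUE)
}

#' Quantization error
#'
#' Mean Euclidean distance between each input row and its best matching
#' unit; the standard goodness-of-fit diagnostic of a SOM codebook.
#'
#' @param table Normalized features (object or matrix).
#' @param model A [som_model].
#' @return Non-negative scalar.
#' @export
quantization_error <- function(table, model) {
  x <- norm_matrix(table)
  if (nrow(x) == 0L) stop("empty table", call. = FALSE)
  bmu <- find_bmu(x, model)
  mean(sqrt(rowSums((x - model$weights[bmu, , drop = FALSE])^2)))
}

#' Write / read a SOM model as portable JSON
#'
#' @param model A [som_model] (for writing).
#' @param path File path.
#' @return `write_som_model` returns `path` invisibly; `read_som_model`
#'   returns the [som_model].
#' @export
write_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  payload <- list(grid = model$grid,
                  feature_names = colnames(model$weights),
                  weights = unname(model$weights),
                  bounds = if (is.null(model$bounds)) NULL
                  else unname(model$bounds),
                  schedule = model$schedule,
                  seed = model$seed, trained = model$trained)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_som_model
#' @export
read_som_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.matrix(payload$weights)
  colnames(w) <- payload$feature_names
  bounds <- if (is.null(payload$bounds)) NULL else {
    b <- as.matrix(payload$bounds)
    dimnames(b) <- list(c("min", "max"), payload$feature_names)
    b
  }
  new_som_model(w, payload$grid, bounds,
                as.data.frame(payload$schedule), payload$seed,
                trained = isTRUE(payload$trained))
}
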