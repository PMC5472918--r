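#' Movement track of one individual
#'
#' A fixed-rate 2-D position series for a single fly, together with its
#' cohort labels. Timestamps are implicit: position `i` was recorded at
#' `(i - 1) * dt` seconds.
#'
#' @param individual_id Character identifier, unique within a [track_set()].
#' @param positions n x 2 numeric matrix of (x, y) positions in mm, n >= 2.
#' @param strain One of `"wild_type"`, `"p38b"`, `"p53"`.
#' @param treatment One of `"control"`, `"toluene"`, `"formaldehyde"`.
#' @param session One of `"pre"`, `"post"`.
#' @param dt Sampling interval in seconds (default 0.25).
#' @param arena Optional [arena()]; when supplied, positions are checked
#'   against its bounds.
#' @return An object of class `"fly_track"`.
#' @export
fly_track <- function(individual_id, positions,
                      strain = c("wild_type", "p38b", "p53"),
                      treatment = c("control", "toluene", "formaldehyde"),
                      session = c("pre", "post"),
                      dt = 0.25, arena = NULL) {
  strain <- match.arg(strain)
  treatment <- match.arg(treatment)
  session <- match.arg(session)
  positions <- as_xy_matrix(positions)
  storage.mode(positions) <- "double"
  if (!(is.numeric(dt) && length(dt) == 1L && dt > 0)) {
    stop("dt must be a positive scalar", call. = FALSE)
  }
  if (nrow(positions) < 2L) {
    stop("a track needs at least 2 positions", call. = FALSE)
  }
  if (anyNA(positions)) stop("positions contain NA", call. = FALSE)
  if (!is.null(arena) && !all(in_arena(positions, arena))) {
    stop(sprintf("track '%s' has positions outside the arena", individual_id),
         call. = FALSE)
  }
  colnames(positions) <- c("x", "y")
  structure(
    list(individual_id = as.character(individual_id),
         strain = strain, treatment = treatment, session = session,
         dt = dt, positions = positions),
    class = "fly_track"
  )
}

#' @export
print.fly_track <- function(x, ...) {
  cat(sprintf("<fly_track> %s [%s / %s / %s], %d positions @ %g s (%.1f s)\n",
              x$individual_id, x$strain, x$treatment, x$session,
              nrow(x$positions), x$dt, (nrow(x$positions) - 1) * x$dt))
  invisible(x)
}

#' Collection of tracks sharing one arena
#'
#' @param tracks List of [fly_track()] objects sharing the same `dt`.
#' @param arena The [arena()] all tracks live in.
#' @return An object of class `"track_set"`.
#' @export
track_set <- function(tracks = list(), arena = ethoscreen::arena()) {
  stopifnot(inherits(arena, "arena"), is.list(tracks))
  for (tr in tracks) {
    if (!inherits(tr, "fly_track")) {
      stop("all elements of tracks must be fly_track objects", call. = FALSE)
    }
    if (!all(in_arena(tr$positions, arena))) {
      stop(sprintf("track '%s' has positions outside the arena",
                   tr$individual_id), call. = FALSE)
    }
  }
  dts <- unique(vapply(tracks, function(t) t$dt, numeric(1)))
  if (length(dts) > 1L) stop("all tracks must share the same dt", call. = FALSE)
  ids <- vapply(tracks, function(t) t$individual_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate individual ids", call. = FALSE)
  structure(list(arena = arena, tracks = tracks), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks\n", length(x$tracks)))
  if (length(x$tracks)) {
    grp <- table(vapply(x$tracks, function(t)
      paste(t$strain, t$treatment, t$session, sep = "/"), character(1)))
    for (g in names(grp)) cat(sprintf("  %s: %d\n", g, grp[[g]]))
  }
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$tracks)

track_columns <- c("individual_id", "strain", "treatment", "session",
                   "frame", "x_mm", "y_mm")

#' Read a trajectory table
#'
#' Reads the delimited (comma-separated) trajectory dialect with header
#' columns `individual_id, strain, treatment, session, frame, x_mm, y_mm`.
#' Frames within an individual must be consecutive integers starting at 0;
#' gaps are reported as errors rather than interpolated, because all
#' kinematic formulas assume uniform 0.25-s sub-segments.
#'
#' @param path Path of the file to read.
#' @param arena The [arena()] the positions are checked against.
#' @param dt Sampling interval in seconds (default 0.25).
#' @return A [track_set()].
#' @seealso [write_tracks()]
#' @export
read_tracks <- function(path, arena = ethoscreen::arena(), dt = 0.25) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(track_columns, names(df))
  if (length(missing)) {
    stop(sprintf("trajectory table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  oob <- which(!in_arena(cbind(df$x_mm, df$y_mm), arena))
  if (length(oob)) {
    stop(sprintf("position outside arena at row %d (and %d more)",
                 oob[1] + 1L, length(oob) - 1L), call. = FALSE)
  }
  tracks <- list()
  for (id in unique(df$individual_id)) {
    sub <- df[df$individual_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (!identical(as.integer(sub$frame), seq_len(nrow(sub)) - 1L)) {
      stop(sprintf("non-consecutive frames for individual '%s'", id),
           call. = FALSE)
    }
    lab <- unique(sub[, c("strain", "treatment", "session")])
    if (nrow(lab) != 1L) {
      stop(sprintf("inconsistent group labels for individual '%s'", id),
           call. = FALSE)
    }
    tracks[[length(tracks) + 1L]] <- fly_track(
      individual_id = id,
      positions = cbind(sub$x_mm, sub$y_mm),
      strain = lab$strain, treatment = lab$treatment, session = lab$session,
      dt = dt, arena = arena)
  }
  track_set(tracks, arena)
}

#' Write a trajectory table
#'
#' Emits the same comma-separated dialect [read_tracks()] accepts, with rows
#' ordered by individual then frame and coordinates printed with six decimal
#' places (so a write/read round trip reproduces positions to 1e-6 mm and a
#' second write is byte-identical).
#'
#' @param trackset A [track_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trackset, path) {
  stopifnot(inherits(trackset, "track_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(track_columns, collapse = ","), con)
  for (tr in trackset$tracks) {
    n <- nrow(tr$positions)
    lines <- sprintf("%s,%s,%s,%s,%d,%.6f,%.6f",
                     tr$individual_id, tr$strain, tr$treatment, tr$session,
                     seq_len(n) - 1L, tr$positions[, 1], tr$positions[, 2])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Flat data.frame view of a track set
#'
#' @param x A [track_set()].
#' @param ... Unused.
#' @return A data.frame in the trajectory-table dialect.
#' @export
as.data.frame.track_set <- function(x, ...) {
  do.call(rbind, lapply(x$tracks, function(tr) {
    data.frame(individual_id = tr$individual_id, strain = tr$strain,
               treatment = tr$treatment, session = tr$session,
               frame = seq_len(nrow(tr$positions)) - 1L,
               x_mm = tr$positions[, 1], y_mm = tr$positions[, 2])
  }))
}
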