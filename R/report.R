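#' Per-group summaries of movement parameters
#'
#' Mean, SD and n of each movement parameter per strain x treatment x
#' session group, optionally joined by the fractal dimension (per track
#' window) and per-zone stay durations. Undefined (`NA`) values are
#' excluded from the mean/SD and counted in `n_excluded`; the SD of a
#' single observation is reported as `NA`.
#'
#' @param features Feature table from [extract_features()].
#' @param dimensions Optional [track_dimensions()] table.
#' @param occupancy Optional per-track occupancy table from
#'   [occupancy_table()].
#' @return Long-format data.frame: `strain`, `treatment`, `session`,
#'   `parameter`, `mean`, `sd`, `n`, `n_excluded`.
#' @export
summarize_groups <- function(features, dimensions = NULL, occupancy = NULL) {
  blocks <- list(features[, c("strain", "treatment", "session",
                              feature_names())])
  if (!is.null(dimensions)) {
    d <- dimensions[, c("strain", "treatment", "session", "dimension")]
    names(d)[4] <- "fractal_dimension"
    blocks <- c(blocks, list(d))
  }
  if (!is.null(occupancy)) {
    o <- occupancy[, c("strain", "treatment", "session", zone_levels())]
    names(o)[4:7] <- paste0("stay_", zone_levels())
    blocks <- c(blocks, list(o))
  }
  rows <- list()
  for (b in blocks) {
    params <- setdiff(names(b), c("strain", "treatment", "session"))
    grp <- interaction(b$strain, b$treatment, b$session, drop = TRUE)
    for (p in params) {
      v <- split(b[[p]], grp)
      keys <- do.call(rbind, strsplit(names(v), ".", fixed = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = keys[, 1], treatment = keys[, 2], session = keys[, 3],
        parameter = p,
        mean = vapply(v, function(x) mean(x, na.rm = TRUE), numeric(1)),
        sd = vapply(v, function(x) {
          x <- x[!is.na(x)]
          if (length(x) < 2L) NA_real_ else stats::sd(x)
        }, numeric(1)),
        n = vapply(v, function(x) sum(!is.na(x)), integer(1)),
        n_excluded = vapply(v, function(x) sum(is.na(x)), integer(1)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-individual mean parameters
#'
#' Collapses the segment-level feature table to one row per individual
#' (mean of each parameter, `NA`s excluded), optionally joined with the
#' individual's mean fractal dimension. This is the unit on which group
#' statistics and correlations are computed: the cohort design observes 15
#' individuals per group, so individual means are the replicates.
#'
#' @param features Feature table from [extract_features()].
#' @param dimensions Optional [track_dimensions()] table.
#' @return One row per individual with labels and mean parameters.
#' @export
individual_means <- function(features, dimensions = NULL) {
  agg <- stats::aggregate(features[, feature_names()],
                          by = features[, c("individual_id", "strain",
                                            "treatment", "session")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  if (!is.null(dimensions)) {
    dim_agg <- stats::aggregate(list(fractal_dimension = dimensions$dimension),
                                by = dimensions["individual_id"],
                                FUN = mean)
    agg <- merge(agg, dim_agg, by = "individual_id", all.x = TRUE)
  }
  agg
}

#' Pearson correlation matrix among movement parameters
#'
#' Pearson correlations computed on per-individual mean parameters pooled
#' across groups (the replicate unit of the cohort design); segment-level
#' correlation is available with `unit = "segment"`. Zero-variance
#' parameters yield `NA` entries and a warning.
#'
#' @param features Feature table from [extract_features()].
#' @param dimensions Optional [track_dimensions()] table; adds a
#'   `fractal_dimension` row/column.
#' @param unit `"individual"` (default) or `"segment"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features, dimensions = NULL,
                               unit = c("individual", "segment")) {
  unit <- match.arg(unit)
  if (unit == "individual") {
    df <- individual_means(features, dimensions)
    if (nrow(df) < 3L) {
      stop("need at least 3 individuals for correlations", call. = FALSE)
    }
    m <- as.matrix(df[, setdiff(names(df), c("individual_id", "strain",
                                             "treatment", "session"))])
  } else {
    m <- as.matrix(features[, feature_names()])
  }
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("zero-variance parameter(s): %s",
                    paste(colnames(m)[which(sds == 0)], collapse = ", ")),
            call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Per-track overall zone occupancy table
#'
#' Applies [zone_occupancy()] to every track and returns one row per track
#' with the overall stay duration (s) per zone.
#'
#' @param trackset A [track_set()].
#' @param window Window length passed to [zone_occupancy()].
#' @return Data.frame with labels and one column per zone.
#' @export
occupancy_table <- function(trackset, window = 30) {
  stopifnot(inherits(trackset, "track_set"))
  rows <- lapply(trackset$tracks, function(tr) {
    ov <- attr(zone_occupancy(tr, trackset$arena, window), "overall")
    cbind(data.frame(individual_id = tr$individual_id, strain = tr$strain,
                     treatment = tr$treatment, session = tr$session),
          as.data.frame(as.list(ov)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
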