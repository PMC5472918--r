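PATTERN_LEVELS <- c("active", "circling", "zigzag", "stop")

#' Ward clustering of the SOM codebook
#'
#' Agglomerative clustering (Ward linkage on the Euclidean distance matrix)
#' of the node weight vectors, cut into `k` clusters. Linkage heights are
#' rescaled to 0-100%. Cluster IDs are dendrogram-ordered: cluster 1 holds
#' the leftmost leaves of the dendrogram.
#'
#' @param model A trained [som_model].
#' @param k Number of clusters, between 1 and the number of nodes
#'   (default 9).
#' @return An object of class `"cluster_model"`: list with the per-node
#'   `assignment`, `k`, rescaled `heights_pct`, the `hclust` tree, and a
#'   `pattern` mapping (filled by [label_patterns()]).
#' @export
cluster_codebook <- function(model, k = 9) {
  stopifnot(inherits(model, "som_model"))
  n_nodes <- nrow(model$weights)
  if (k < 1 || k > n_nodes) {
    stop(sprintf("k must lie in [1, %d]", n_nodes), call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(model$weights), method = "ward.D2")
  heights_pct <- 100 * hc$height / max(hc$height)
  raw <- stats::cutree(hc, k = k)
  # relabel clusters by their order of appearance along the dendrogram
  first_leaf <- vapply(seq_len(k), function(cl) {
    min(match(which(raw == cl), hc$order))
  }, numeric(1))
  relabel <- integer(k)
  relabel[order(first_leaf)] <- seq_len(k)
  assignment <- relabel[raw]
  structure(list(assignment = assignment, k = as.integer(k),
                 heights_pct = heights_pct, hclust = hc, pattern = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d clusters over %d nodes\n",
              x$k, length(x$assignment)))
  if (!is.null(x$pattern)) {
    cat("  patterns:",
        paste(sprintf("%s={%s}", names(x$pattern),
                      vapply(x$pattern, paste, character(1), collapse = ",")),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Group the nine clusters into four movement patterns
#'
#' Maps the `k = 9` codebook clusters onto the four-pattern ethogram
#' (`active`, `circling`, `zigzag`, `stop`) with the fixed 3/1/3/2
#' partition, using the clusters' weight profiles: the 2 lowest-speed
#' clusters become `stop`; among the remaining 7 the 3 highest-meander
#' clusters become `zigzag`; of the remaining 4, the one with the highest
#' meander-to-speed ratio becomes `circling` and the other 3 `active`.
#'
#' @param model The trained [som_model] the clusters came from.
#' @param clusters A [cluster_codebook()] result with `k = 9`.
#' @return The `cluster_model` with its cluster-to-pattern mapping filled
#'   in (`pattern`, a list of cluster IDs per pattern, and the per-node
#'   `node_pattern` factor).
#' @export
label_patterns <- function(model, clusters) {
  stopifnot(inherits(model, "som_model"), inherits(clusters, "cluster_model"))
  if (clusters$k != 9L) {
    stop("pattern labeling expects exactly 9 clusters", call. = FALSE)
  }
  w <- model$weights
  if (!all(c("speed", "meander") %in% colnames(w))) {
    stop("codebook lacks named speed/meander components", call. = FALSE)
  }
  cl <- clusters$assignment
  mean_speed <- tapply(w[, "speed"], cl, mean)
  mean_meander <- tapply(w[, "meander"], cl, mean)
  if (diff(range(mean_speed)) < 1e-8) {
    stop("no activity gradient across clusters: cannot label patterns",
         call. = FALSE)
  }
  ids <- as.integer(names(mean_speed))
  stop_ids <- ids[order(mean_speed)][1:2]
  rest <- setdiff(ids, stop_ids)
  zigzag_ids <- rest[order(mean_meander[as.character(rest)],
                           decreasing = TRUE)][1:3]
  rest <- setdiff(rest, zigzag_ids)
  ratio <- mean_meander[as.character(rest)] /
    pmax(mean_speed[as.character(rest)], 1e-8)
  circling_id <- rest[which.max(ratio)]
  active_ids <- setdiff(rest, circling_id)
  mapping <- list(active = sort(active_ids), circling = circling_id,
                  zigzag = sort(zigzag_ids), stop = sort(stop_ids))
  pattern_of_cluster <- character(9)
  for (p in names(mapping)) pattern_of_cluster[mapping[[p]]] <- p
  clusters$pattern <- mapping
  clusters$cluster_pattern <- factor(pattern_of_cluster,
                                     levels = PATTERN_LEVELS)
  clusters$node_pattern <- clusters$cluster_pattern[cl]
  clusters
}

#' Classify movement segments into the ethogram
#'
#' Normalizes a feature table with the bounds stored in the model, finds
#' each segment's best matching unit, and maps node to cluster to pattern.
#' Per group (strain x treatment x session) the percentage of observation
#' time spent in each of the four patterns is the share of its segments,
#' so the four percentages sum to 100.
#'
#' @param table Feature data.frame from [extract_features()] (raw scale;
#'   it is normalized internally with the model's stored bounds).
#' @param model A trained [som_model] carrying normalization bounds.
#' @param clusters A [label_patterns()]-labeled `cluster_model`.
#' @return An object of class `"ethogram_result"`: list with `segments`
#'   (per-segment node/cluster/pattern) and `group_fractions` (per-group
#'   pattern percentages).
#' @export
classify_segments <- function(table, model, clusters) {
  stopifnot(inherits(model, "som_model"), inherits(clusters, "cluster_model"))
  if (is.null(clusters$node_pattern)) {
    stop("clusters must be labeled with label_patterns() first",
         call. = FALSE)
  }
  if (is.null(model$bounds)) {
    stop("model carries no normalization bounds; train on a ",
         "normalize_features() result", call. = FALSE)
  }
  if (ncol(model$bounds) != length(feature_names())) {
    stop("model bounds do not match the feature set", call. = FALSE)
  }
  nf <- suppressWarnings(normalize_features(table, bounds = model$bounds))
  bmu <- find_bmu(nf$x, model)
  seg <- data.frame(table[, intersect(c("individual_id", "strain",
                                        "treatment", "session", "segment"),
                                      names(table)), drop = FALSE],
                    node = bmu,
                    cluster = clusters$assignment[bmu],
                    pattern = clusters$node_pattern[bmu])
  grp <- interaction(seg$strain, seg$treatment, seg$session, drop = TRUE)
  tab <- table(group = grp, pattern = seg$pattern)
  pct <- 100 * sweep(tab, 1, rowSums(tab), "/")
  keys <- do.call(rbind, strsplit(rownames(pct), ".", fixed = TRUE))
  group_fractions <- data.frame(strain = keys[, 1], treatment = keys[, 2],
                                session = keys[, 3],
                                n_segments = as.integer(rowSums(tab)))
  for (p in PATTERN_LEVELS) group_fractions[[p]] <- as.numeric(pct[, p])
  rownames(group_fractions) <- NULL
  structure(list(segments = seg, group_fractions = group_fractions,
                 n_clipped = nf$n_clipped),
            class = "ethogram_result")
}

#' @export
print.ethogram_result <- function(x, ...) {
  cat(sprintf("<ethogram_result> %d segments, %d groups\n",
              nrow(x$segments), nrow(x$group_fractions)))
  print(x$group_fractions, digits = 3)
  invisible(x)
}

#' Component planes of a trained SOM
#'
#' One panel per movement parameter showing its weight across the grid.
#' @param model A trained [som_model].
#' @param ... Passed to [graphics::image()].
#' @export
plot_component_planes <- function(model, ...) {
  p <- ncol(model$weights)
  old <- graphics::par(mfrow = c(2, ceiling(p / 2)), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(p)) {
    plane <- matrix(model$weights[, k], nrow = model$grid[2])
    graphics::image(seq_len(model$grid[2]), seq_len(model$grid[1]), plane,
                    xlab = "", ylab = "",
                    main = colnames(model$weights)[k], ...)
  }
  invisible(model)
}

#' Dendrogram of the clustered codebook
#' @param clusters A [cluster_codebook()] result.
#' @param ... Passed to `plot.hclust`.
#' @export
plot_codebook_dendrogram <- function(clusters, ...) {
  hc <- clusters$hclust
  hc$height <- 100 * hc$height / max(hc$height)
  plot(hc, labels = FALSE, xlab = "SOM node", sub = "",
       ylab = "linkage distance (%)", ...)
  if (clusters$k > 1 && clusters$k < length(clusters$assignment)) {
    stats::rect.hclust(hc, k = clusters$k)
  }
  invisible(clusters)
}

#' Bar chart of per-group pattern percentages
#' @param ethogram An [classify_segments()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_pattern_fractions <- function(ethogram, ...) {
  gf <- ethogram$group_fractions
  m <- t(as.matrix(gf[, PATTERN_LEVELS]))
  colnames(m) <- paste(gf$strain, gf$treatment, gf$session, sep = "\n")
  graphics::barplot(m, beside = FALSE, legend.text = PATTERN_LEVELS,
                    ylab = "time fraction (%)", las = 2, ...)
  invisible(ethogram)
}
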