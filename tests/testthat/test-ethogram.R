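test_that("Ward clustering handles the degenerate cuts exactly", {
  model <- archetype_model()
  c1 <- cluster_codebook(model, k = 1)
  expect_true(all(c1$assignment == 1L))
  c140 <- cluster_codebook(model, k = 140)
  expect_equal(sort(unique(c140$assignment)), 1:140)
  expect_equal(max(table(c140$assignment)), 1L)
  expect_error(cluster_codebook(model, k = 0), "k must")
  expect_error(cluster_codebook(model, k = 141), "k must")
  # linkage heights are rescaled to 0-100%
  c9 <- cluster_codebook(model, k = 9)
  expect_equal(max(c9$heights_pct), 100)
  expect_true(all(c9$heights_pct >= 0))
})

test_that("clustering recovers planted codebook archetypes", {
  model <- archetype_model(noise = 0.02, seed = 21)
  truth <- attr(model, "truth")
  cl <- cluster_codebook(model, k = 9)
  ari <- mclust::adjustedRandIndex(cl$assignment, truth)
  expect_gte(ari, 0.9)
})

test_that("pattern labeling assigns the 3/1/3/2 partition from profiles", {
  model <- archetype_model(noise = 0.01, seed = 22)
  truth <- attr(model, "truth")
  cl <- label_patterns(model, cluster_codebook(model, k = 9))
  expect_length(cl$pattern$active, 3L)
  expect_length(cl$pattern$circling, 1L)
  expect_length(cl$pattern$zigzag, 3L)
  expect_length(cl$pattern$stop, 2L)
  # every cluster carries exactly one pattern
  expect_setequal(unlist(cl$pattern), 1:9)
  # the recovered semantics match the archetypes that generated each node
  arch_pattern <- rep(c("active", "circling", "zigzag", "stop"),
                      c(3, 1, 3, 2))[truth]
  agreement <- mean(as.character(cl$node_pattern) == arch_pattern)
  expect_gte(agreement, 0.95)
})

test_that("pattern labeling rejects degenerate codebooks", {
  model <- archetype_model()
  model$weights[, "speed"] <- 0
  cl <- cluster_codebook(model, k = 9)
  expect_error(label_patterns(model, cl), "gradient")
  cl8 <- cluster_codebook(archetype_model(), k = 8)
  expect_error(label_patterns(archetype_model(), cl8), "9 clusters")
})

test_that("classification reproduces known pattern fractions", {
  model <- archetype_model(noise = 0.005, seed = 23)
  cl <- label_patterns(model, cluster_codebook(model, k = 9))
  arch <- pattern_archetypes()
  # 10 segments of one group: 4 active, 1 circling, 3 zigzag, 2 stop
  rows <- arch[c(1, 2, 3, 1, 4, 5, 6, 7, 8, 9), ]
  tbl <- as.data.frame(rows)
  names(tbl) <- feature_names()
  tbl <- cbind(data.frame(individual_id = "f1", strain = "wild_type",
                          treatment = "control", session = "pre",
                          segment = 1:10), tbl)
  eth <- classify_segments(tbl, model, cl)
  gf <- eth$group_fractions
  expect_equal(gf$active, 40)
  expect_equal(gf$circling, 10)
  expect_equal(gf$zigzag, 30)
  expect_equal(gf$stop, 20)
  expect_equal(gf$active + gf$circling + gf$zigzag + gf$stop, 100)
})

test_that("a stop-dominated cohort spends most ethogram time stopped", {
  cfg <- simulation_config(duration = 600, n_individuals = 4, seed = 31)
  presets <- list(
    mover = test_preset(name = "mover", move_speed_mean = 4,
                        p_stop_entry = 0.05, p_stop_exit = 0.9,
                        slip_rate = 0.3, strain = "wild_type"),
    sitter = test_preset(name = "sitter", move_speed_mean = 1.2,
                         p_stop_entry = 0.92, p_stop_exit = 0.05,
                         slip_rate = 0, strain = "p53",
                         treatment = "formaldehyde"))
  ts <- generate_cohort(presets, cfg)
  feats <- extract_features(ts)
  model <- train_som(normalize_features(feats), seed = 31)
  cl <- label_patterns(model, cluster_codebook(model, k = 9))
  eth <- classify_segments(feats, model, cl)
  gf <- eth$group_fractions
  sitter <- gf[gf$strain == "p53", ]
  expect_gt(sitter$stop, sitter$active)
  expect_gt(sitter$stop, sitter$circling)
  expect_gt(sitter$stop, sitter$zigzag)
  expect_gt(gf[gf$strain == "wild_type", "active"], sitter$active)
  # fractions sum to 100 per group and every segment is classified once
  expect_equal(rowSums(gf[, c("active", "circling", "zigzag", "stop")]),
               rep(100, nrow(gf)), tolerance = 1e-8)
  expect_equal(nrow(eth$segments), nrow(feats))
  expect_false(anyNA(eth$segments$pattern))
})

test_that("the trained map organizes activity along its vertical axis", {
  cfg <- simulation_config(duration = 600, n_individuals = 3, seed = 32)
  presets <- list(
    fast = test_preset(name = "fast", move_speed_mean = 4.5,
                       p_stop_entry = 0.1, p_stop_exit = 0.8),
    slow = test_preset(name = "slow", move_speed_mean = 1.5,
                       p_stop_entry = 0.6, p_stop_exit = 0.2, slip_rate = 1))
  feats <- extract_features(generate_cohort(presets, cfg))
  model <- train_som(normalize_features(feats), seed = 32)
  rho <- cor(model$coords[, "row"], model$weights[, "speed"],
             method = "spearman")
  expect_gt(abs(rho), 0.6)
})

test_that("classification demands labeled clusters and stored bounds", {
  model <- archetype_model()
  cl <- cluster_codebook(model, k = 9)
  tbl <- data.frame(matrix(runif(12), 2))
  names(tbl) <- feature_names()
  expect_error(classify_segments(tbl, model, cl), "label_patterns")
  cl <- label_patterns(model, cl)
  model$bounds <- NULL
  expect_error(classify_segments(tbl, model, cl), "bounds")
})
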