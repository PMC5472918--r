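make_feature_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- feature_names()
  df
}

test_that("min-max normalization scales, stores bounds and imputes flags", {
  m <- matrix(rep(c(2, 4, 6), 6), nrow = 3)
  nf <- normalize_features(make_feature_df(m))
  expect_equal(unname(nf$x[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nf$bounds["min", 1]), 2)
  # re-applying the stored bounds reproduces the matrix
  nf2 <- normalize_features(make_feature_df(m), bounds = nf$bounds)
  expect_identical(nf2$x, nf$x)
  expect_equal(nf$n_clipped, 0)
})

test_that("undefined entries are imputed as zero after flagging", {
  m <- matrix(runif(30), nrow = 5)
  m[2, 3] <- NA
  m[5, 4] <- NA
  nf <- normalize_features(make_feature_df(m))
  expect_true(nf$imputed[2, 3] && nf$imputed[5, 4])
  expect_equal(sum(nf$imputed), 2L)
  expect_equal(unname(nf$x[2, 3]), 0)
  expect_false(anyNA(nf$x))
})

test_that("later out-of-range data are clipped with a count", {
  train <- matrix(runif(60, 0.2, 0.8), nrow = 10)
  nf <- normalize_features(make_feature_df(train))
  probe <- train[1:3, ]
  probe[1, 1] <- 0.05   # below stored min
  probe[2, 2] <- 0.95   # above stored max
  expect_warning(
    nf2 <- normalize_features(make_feature_df(probe), bounds = nf$bounds),
    "clipped")
  expect_equal(nf2$n_clipped, 2)
  expect_true(all(nf2$x >= 0 & nf2$x <= 1))
})

test_that("constant parameter columns are a degenerate-scale error", {
  m <- matrix(runif(30), nrow = 5)
  m[, 2] <- 7
  expect_error(normalize_features(make_feature_df(m)), "constant")
})

test_that("find_bmu matches trivial cases and the exhaustive scan", {
  set.seed(6)
  w <- matrix(runif(140 * 6), 140)
  colnames(w) <- feature_names()
  model <- ethoscreen:::new_som_model(w, c(14L, 10L), NULL,
                                      default_som_schedule(), 1)
  expect_equal(find_bmu(w[57, ], model), 57L)
  for (i in 1:50) {
    x <- runif(6)
    expect_equal(find_bmu(x, model), bmu_scan(x, w))
  }
  expect_error(find_bmu(runif(4), model), "parameters")
})

test_that("a two-node toy model picks the nearer node", {
  w <- rbind(c(0, 0), c(1, 1))
  model <- ethoscreen:::new_som_model(w, c(2L, 1L), NULL,
                                      default_som_schedule(), 1)
  expect_equal(find_bmu(c(0.1, 0.2), model), 1L)
  expect_equal(find_bmu(c(0.9, 0.9), model), 2L)
})

test_that("the sequential update obeys its limiting cases", {
  set.seed(7)
  w <- matrix(runif(12 * 3), 12)
  model <- ethoscreen:::new_som_model(w, c(4L, 3L), NULL,
                                      default_som_schedule(), 1)
  x <- runif(3)
  bmu <- find_bmu(x, model)
  # alpha = 1 with a vanishing radius copies x into the BMU
  m1 <- update_weights(model, x, bmu, alpha = 1, radius = 0)
  expect_equal(unname(m1$weights[bmu, ]), x)
  off <- setdiff(1:12, bmu)
  expect_identical(m1$weights[off, ], model$weights[off, ])
  # alpha = 0 changes nothing
  expect_identical(update_weights(model, x, bmu, 0, 2)$weights, w)
  # any real update strictly decreases the BMU distance
  m2 <- update_weights(model, x, bmu, alpha = 0.3, radius = 1.5)
  d_before <- sqrt(sum((x - model$weights[bmu, ])^2))
  d_after <- sqrt(sum((x - m2$weights[bmu, ])^2))
  expect_lt(d_after, d_before)
})

test_that("the C++ training core reproduces the R reference update", {
  set.seed(8)
  w <- matrix(runif(20 * 6), 20)
  grid <- c(5L, 4L)
  model <- ethoscreen:::new_som_model(w, grid, NULL,
                                      default_som_schedule(), 1)
  x <- matrix(runif(6), 1)
  for (radius in c(0, 0.8, 3)) {
    ref <- update_weights(model, x[1, ], find_bmu(x[1, ], model),
                          alpha = 0.4, radius = radius)
    got <- ethoscreen:::som_train_c(w, x, ethoscreen:::som_grid_coords(grid),
                                    0L, 0.4, radius)
    expect_equal(got, unname(ref$weights), tolerance = 1e-12)
  }
})

test_that("training separates well-separated clusters and reduces error", {
  set.seed(9)
  blob1 <- matrix(rnorm(300 * 6, 0.2, 0.03), 300)
  blob2 <- matrix(rnorm(300 * 6, 0.8, 0.03), 300)
  x <- pmin(pmax(rbind(blob1, blob2), 0), 1)
  colnames(x) <- feature_names()
  model <- train_som(x, seed = 2)
  bmu1 <- unique(find_bmu(x[1:300, ], model))
  bmu2 <- unique(find_bmu(x[301:600, ], model))
  expect_length(intersect(bmu1, bmu2), 0L)
  q_trained <- quantization_error(x, model)
  init <- ethoscreen:::som_linear_init(x, c(14L, 10L))
  model0 <- ethoscreen:::new_som_model(init, c(14L, 10L), NULL,
                                       default_som_schedule(), 2)
  expect_lt(q_trained, quantization_error(x, model0))
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(10)
  x <- matrix(runif(200 * 6), 200)
  colnames(x) <- feature_names()
  m1 <- train_som(x, seed = 5)
  m2 <- train_som(x, seed = 5)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_som(x, seed = 6)
  expect_false(identical(m3$weights, m1$weights))
})

test_that("quantization error matches its brute-force definition", {
  model <- archetype_model()
  w <- model$weights
  # rows equal to node weights quantize exactly
  expect_equal(quantization_error(w[c(3, 50, 99), ], model), 0)
  set.seed(11)
  x <- matrix(runif(40 * 6), 40)
  brute <- mean(vapply(seq_len(40), function(i) {
    min(sqrt(colSums((t(w) - x[i, ])^2)))
  }, numeric(1)))
  expect_equal(quantization_error(x, model), brute)
  # single row: its own BMU distance
  expect_equal(quantization_error(x[1, , drop = FALSE], model),
               min(sqrt(colSums((t(w) - x[1, ])^2))))
})

test_that("SOM models survive a JSON round trip", {
  set.seed(12)
  x <- matrix(runif(150 * 6), 150)
  colnames(x) <- feature_names()
  nf <- normalize_features(make_feature_df(x))
  model <- train_som(nf, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_som_model(model, path)
  back <- read_som_model(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$bounds, model$bounds)
  expect_equal(back$grid, model$grid)
})
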