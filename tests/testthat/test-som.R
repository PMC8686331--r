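test_that("winner selection uses Euclidean distance with lowest-index ties", {
  layer <- matrix(0, 8, 4)
  layer[5, ] <- c(1, 2, 3, 4)
  wd <- winner_and_distances(c(1, 2, 3, 4), layer)
  expect_equal(wd$winner, 5)
  expect_equal(wd$distances[5], 0)
  # 3-4-5 triangle
  wd2 <- winner_and_distances(c(3, 4, 0, 0), matrix(0, 1, 4))
  expect_equal(wd2$distances, 5)
  # two equidistant units: lowest index wins
  layer3 <- matrix(5, 8, 2)
  layer3[2, ] <- c(1, 0)
  layer3[7, ] <- c(-1, 0)
  expect_equal(winner_and_distances(c(0, 0), layer3)$winner, 2)
  expect_error(winner_and_distances(1, matrix(numeric(0), 0, 1)), "empty")
})

test_that("threshold S sits at the quantile rank, winner counted as rank 1", {
  # units at distances 0, 1, 2, ..., 199 from the winner (unit 1)
  layer <- cbind(0:199, 0)
  # default quantile on a 200-unit layer: rank 40, i.e. distance 39
  expect_equal(threshold_S(layer, winner = 1), 39)
  # generic rank formula: ceiling(quantile * n_units)
  expect_equal(threshold_S(layer, 1, quantile = 0.05), 9)   # rank 10
  layer100 <- cbind(0:99, 0)
  expect_equal(threshold_S(layer100, 1, 0.05), 4)           # rank 5
  # coincident units: S = 0
  expect_equal(threshold_S(matrix(1, 50, 3), 10, 0.05), 0)
})

test_that("the Gaussian decay matches its closed form and is monotone", {
  expect_equal(neighborhood_decay(0, 1), 1)
  expect_equal(neighborhood_decay(1, 1), exp(-1 / (2 * pi)))
  d <- seq(0, 5, by = 0.25)
  vals <- neighborhood_decay(d, 0.7)
  expect_true(all(diff(vals) < 0))
  expect_error(neighborhood_decay(1, 0), "sigma")
})

test_that("a zero learning rate leaves the layer and the inputs unchanged", {
  set.seed(1)
  layer <- matrix(rnorm(40), 10, 4)
  inputs <- matrix(rnorm(12), 3, 4)
  cfg <- som_config(n_units = 10, learning_rate = 0, batch_size = 10)
  res <- som_batch_update(inputs, layer, cfg)
  expect_equal(res$layer, layer)
  expect_equal(res$x_new, inputs)
})

test_that("input feedback equals the per-input delta sum exactly", {
  set.seed(2)
  layer <- matrix(rnorm(80), 20, 4)
  cfg <- som_config(n_units = 20, learning_rate = 0.05, sigma = 0.8,
                    threshold_quantile = 0.2, batch_size = 10)
  inputs <- matrix(rnorm(20), 5, 4)
  res <- som_batch_update(inputs, layer, cfg)
  for (b in 1:5) {
    x <- inputs[b, ]
    winner <- which.min(sqrt(rowSums(sweep(layer, 2, x)^2)))
    d_min <- sqrt(rowSums(sweep(layer, 2, layer[winner, ])^2))
    S <- sort(d_min)[ceiling(0.2 * 20)]
    delta <- (ifelse(d_min <= S, 1, -1) * 0.05 *
                neighborhood_decay(d_min, 0.8)) * sweep(layer, 2, x)
    expect_equal(res$x_new[b, ] - x, colSums(delta), tolerance = 1e-12)
  }
})

test_that("batched update equals the scalar brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    layer <- matrix(rnorm(60), 15, 4)
    inputs <- matrix(rnorm(24), 6, 4)
    cfg <- som_config(n_units = 15, learning_rate = 0.03, sigma = 1.2,
                      threshold_quantile = 0.21, batch_size = 10)
    res <- som_batch_update(inputs, layer, cfg)
    ora <- oracle_som_batch(inputs, layer, 0.03, 1.2, 0.21)
    expect_equal(res$layer, ora$layer, tolerance = 1e-12)
    expect_equal(res$x_new, ora$x_new, tolerance = 1e-12)
  }
})

test_that("gated units approach the input and far units recede", {
  for (seed in 1:100) {
    set.seed(seed)
    layer <- matrix(rnorm(100), 25, 4)
    x <- rnorm(4)
    cfg <- som_config(n_units = 25, learning_rate = 1e-4, sigma = 1,
                      threshold_quantile = 0.2, batch_size = 1)
    res <- som_batch_update(rbind(x), layer, cfg)
    winner <- winner_and_distances(x, layer)$winner
    d_min <- sqrt(rowSums(sweep(layer, 2, layer[winner, ])^2))
    S <- sort(d_min)[ceiling(0.2 * 25)]
    before <- sqrt(rowSums(sweep(layer, 2, x)^2))
    after <- sqrt(rowSums(sweep(res$layer, 2, x)^2))
    near <- d_min <= S & before > 0
    far <- d_min > S & neighborhood_decay(d_min, 1) > 0
    expect_true(all(after[near] < before[near]))
    expect_true(all(after[far] > before[far]))
  }
})

test_that("deltas are computed against the frozen batch-start layer", {
  set.seed(9)
  layer <- matrix(rnorm(48), 12, 4)
  inputs <- matrix(rnorm(32), 8, 4)
  cfg <- som_config(n_units = 12, learning_rate = 0.05, batch_size = 10)
  res1 <- som_batch_update(inputs, layer, cfg)
  perm <- sample(8)
  res2 <- som_batch_update(inputs[perm, ], layer, cfg)
  expect_equal(res1$layer, res2$layer, tolerance = 1e-12)
  expect_equal(res1$x_new[perm, ], res2$x_new, tolerance = 1e-12)
})

test_that("with the threshold wide open the update is a vanilla batch SOM step", {
  set.seed(11)
  layer <- matrix(rnorm(60), 15, 4)
  inputs <- matrix(rnorm(20), 5, 4)
  cfg <- som_config(n_units = 15, learning_rate = 0.02, sigma = 1.5,
                    threshold_quantile = 0.999, batch_size = 10)
  res <- som_batch_update(inputs, layer, cfg)
  expect_equal(res$layer, oracle_vanilla_som(inputs, layer, 0.02, 1.5),
               tolerance = 1e-12)
})

test_that("layer checkpoints round-trip through plain text", {
  set.seed(4)
  layer <- matrix(rnorm(80), 20, 4)
  path <- tempfile()
  save_som_layer(layer, path, config = som_config(n_units = 20))
  back <- load_som_layer(path)
  dimnames(back) <- NULL
  expect_equal(back, layer, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".yaml")))
})
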