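# Modified self-organizing map.  Unlike a classical SOM there is no 2-D
# lattice: the 200 competition units live directly in the feature space,
# and the neighborhood is defined by each unit's Euclidean distance to
# the winning unit.  Units within a rank-based distance threshold S of
# the winner are attracted toward the input; the rest are repelled.  In
# addition each input receives a feedback update x(new) = x + sum_j
# Delta(w_j), moving it opposite to the aggregate unit motion; x(new)
# becomes the regression label for the feature extractor.

#' SOM configuration
#'
#' @param n_units number of competition-layer units (default 200).
#' @param learning_rate the SOM step size L (default 0.005).
#' @param sigma width constant of the Gaussian neighborhood decay
#'   (default 1; the decay is exp(-d^2 / (2 * pi * sigma^2))).
#' @param threshold_quantile fraction of units counted as "near" the
#'   winner (rank = ceiling of quantile * n_units, the winner itself at
#'   rank 1; see [threshold_S()]).  The default 0.2 puts the threshold
#'   S at the distance of the unit at rank 40 when the layer has 200
#'   units.
#' @param batch_size inputs per update batch (default 100); unit
#'   movements are accumulated over the batch against the frozen layer
#'   and applied once at batch end.
#' @param seed integer seed for layer initialization.
#' @return list of class `som_config`.
#' @export
som_config <- function(n_units = 200L, learning_rate = 0.005, sigma = 1,
                       threshold_quantile = 0.2, batch_size = 100L,
                       seed = 1L) {
  stopifnot(n_units >= 1, learning_rate >= 0, sigma > 0,
            threshold_quantile > 0, threshold_quantile < 1, batch_size >= 1)
  structure(list(n_units = as.integer(n_units),
                 learning_rate = learning_rate, sigma = sigma,
                 threshold_quantile = threshold_quantile,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Initialize the competition layer
#'
#' Units are drawn uniformly from the per-dimension bounding box of the
#' supplied feature vectors (normally the first training batch), giving
#' a scale-matched start.
#'
#' @param features numeric matrix of feature vectors (rows).
#' @param config a [som_config()].
#' @return n_units x feature_dim numeric matrix.
#' @export
som_layer_init <- function(features, config = som_config()) {
  features <- as.matrix(features)
  set.seed(config$seed)
  lo <- apply(features, 2, min)
  hi <- apply(features, 2, max)
  span <- ifelse(hi > lo, hi - lo, 1e-3)
  layer <- matrix(stats::runif(config$n_units * ncol(features)),
                  config$n_units, ncol(features))
  sweep(sweep(layer, 2, span, `*`), 2, lo, `+`)
}

#' Distances to all units and the winning unit
#'
#' @param x a feature vector.
#' @param layer competition layer matrix (units in rows).
#' @return list with `distances` (Euclidean distance of `x` to every
#'   unit) and `winner` (index of the nearest unit; ties go to the
#'   lowest index).
#' @export
winner_and_distances <- function(x, layer) {
  if (is.null(dim(layer)) || nrow(layer) == 0)
    stop("empty competition layer", call. = FALSE)
  d2 <- rowSums(sweep(layer, 2, x, `-`)^2)
  dist <- sqrt(d2)
  list(distances = dist, winner = which.min(dist))
}

#' Rank-based distance threshold S
#'
#' Distances from the winning unit to every unit (itself included, at
#' distance 0 and rank 1) are sorted ascending; S is the distance at
#' rank `ceiling(quantile * n_units)`.  With 200 units and the default
#' quantile 0.2 this is the distance of the unit at rank 40.
#'
#' @param layer competition layer matrix.
#' @param winner index of the winning unit.
#' @param quantile fraction of units on the "near" side.
#' @return the threshold distance S.
#' @export
threshold_S <- function(layer, winner, quantile = 0.2) {
  stopifnot(quantile > 0, quantile < 1)
  d <- sqrt(rowSums(sweep(layer, 2, layer[winner, ], `-`)^2))
  rank <- ceiling(quantile * nrow(layer))
  sort(d)[rank]
}

#' Gaussian neighborhood decay
#'
#' D(d) = exp(-d^2 / (2 * pi * sigma^2)).  The denominator includes the
#' factor pi; sigma tunes how quickly a unit's movement decays with its
#' distance from the winning unit.
#'
#' @param d distance(s) from the winning unit, >= 0.
#' @param sigma decay constant, > 0.
#' @return decay value(s) in (0, 1].
#' @export
neighborhood_decay <- function(d, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  exp(-d^2 / (2 * pi * sigma^2))
}

#' One batch update of the competition layer with input feedback
#'
#' For each input x (always against the layer state frozen at batch
#' start): the winner, the threshold S and the per-unit deltas
#' Delta(w_j) = +/- L * D(w_j) * (w_j - x) are computed, with sign `+`
#' for units within S of the winner and `-` beyond.  Units move by
#' -Delta(w_j) — near units approach x, far units recede — with all unit
#' movements accumulated over the batch and applied once at batch end.
#' Each input's feedback is x(new) = x + sum_j Delta(w_j), the opposite
#' direction of the aggregate unit motion.
#'
#' @param inputs numeric matrix of feature vectors (rows), at most
#'   `config$batch_size` of them.
#' @param layer competition layer matrix.
#' @param config a [som_config()].
#' @return list of class `som_batch_result` with `layer` (updated),
#'   `x_new` (matrix of updated inputs), `winners` (integer vector) and
#'   `S` (per-input threshold values).
#' @export
som_batch_update <- function(inputs, layer, config = som_config()) {
  inputs <- as.matrix(inputs)
  if (any(!is.finite(inputs)))
    stop("non-finite input feature vector", call. = FALSE)
  if (nrow(inputs) > config$batch_size)
    stop("batch of ", nrow(inputs), " inputs exceeds batch_size ",
         config$batch_size, call. = FALSE)
  stopifnot(ncol(inputs) == ncol(layer))
  L <- config$learning_rate
  movement <- layer * 0
  x_new <- inputs
  winners <- integer(nrow(inputs))
  S_vals <- numeric(nrow(inputs))
  for (b in seq_len(nrow(inputs))) {
    x <- inputs[b, ]
    wd <- winner_and_distances(x, layer)
    winners[b] <- wd$winner
    d_min <- sqrt(rowSums(sweep(layer, 2, layer[wd$winner, ], `-`)^2))
    S <- sort(d_min)[ceiling(config$threshold_quantile * nrow(layer))]
    S_vals[b] <- S
    decay <- neighborhood_decay(d_min, config$sigma)
    sign <- ifelse(d_min <= S, 1, -1)
    delta <- (sign * L * decay) * sweep(layer, 2, x, `-`)
    movement <- movement - delta
    x_new[b, ] <- x + colSums(delta)
  }
  structure(list(layer = layer + movement, x_new = x_new,
                 winners = winners, S = S_vals),
            class = "som_batch_result")
}

#' Save / load a competition layer
#'
#' The layer is written as a plain whitespace-delimited numeric table,
#' one row per unit; the configuration goes to a YAML side file.
#'
#' @param layer competition layer matrix.
#' @param path file to write / read (config saved as `<path>.yaml`).
#' @param config optional [som_config()] to record alongside.
#' @return `load_som_layer` returns the layer matrix.
#' @export
save_som_layer <- function(layer, path, config = NULL) {
  utils::write.table(layer, path, row.names = FALSE, col.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_som_layer
#' @export
load_som_layer <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
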