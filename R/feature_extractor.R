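# Recurrent feature extractor: a two-layer LSTM, applied with shared
# weights to both directional reads of an encoded mutation (5'->site and
# 3'->site), whose two terminal hidden states are concatenated and mapped
# by one fully connected layer to a low-dimensional feature vector.
#
# Implemented directly on BLAS-backed matrix operations: forward pass,
# full backpropagation through time, and Adam updates.  Gradients are
# verified against numerical differentiation in the test suite.

#' Configuration of the recurrent feature extractor
#'
#' @param hidden_layers number of stacked LSTM layers (default 2).
#' @param hidden_size nodes per hidden layer (default 64).
#' @param feature_dim length of the output feature vector (default 8).
#' @param learning_rate Adam step size for label fitting (default 0.001).
#' @param fit_iterations full-batch gradient passes per call to
#'   [fit_to_labels()] (default 2).
#' @param seed integer seed controlling weight initialization.
#' @return list of class `extractor_config`.
#' @export
extractor_config <- function(hidden_layers = 2L, hidden_size = 64L,
                             feature_dim = 8L, learning_rate = 0.001,
                             fit_iterations = 2L, seed = 1L) {
  stopifnot(feature_dim >= 1, learning_rate >= 0, hidden_layers >= 1,
            hidden_size >= 1, fit_iterations >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_size = as.integer(hidden_size),
                 feature_dim = as.integer(feature_dim),
                 learning_rate = learning_rate,
                 fit_iterations = as.integer(fit_iterations),
                 seed = as.integer(seed)),
            class = "extractor_config")
}

#' Initialize a recurrent feature extractor
#'
#' Weights are drawn uniformly from \[-1/sqrt(H), 1/sqrt(H)\] where H is
#' the hidden size; the forget-gate bias is shifted by +1 to ease
#' gradient flow over the ~50-step reads.  Both directional reads share
#' one set of recurrent weights.
#'
#' @param config an [extractor_config()].
#' @return object of class `lstm_extractor` holding the weights and the
#'   (initially empty) optimizer state.
#' @export
lstm_extractor <- function(config = extractor_config()) {
  set.seed(config$seed)
  H <- config$hidden_size
  k <- 1 / sqrt(H)
  rinit <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  params <- list()
  in_dim <- 4L
  for (l in seq_len(config$hidden_layers)) {
    params[[paste0("Wx", l)]] <- rinit(in_dim, 4L * H)
    params[[paste0("Wh", l)]] <- rinit(H, 4L * H)
    b <- stats::runif(4L * H, -k, k)
    b[(H + 1L):(2L * H)] <- b[(H + 1L):(2L * H)] + 1  # forget gate
    params[[paste0("b", l)]] <- b
    in_dim <- H
  }
  params$Wf <- rinit(2L * H, config$feature_dim)
  params$bf <- stats::runif(config$feature_dim, -k, k)
  structure(list(config = config, params = params, opt = NULL),
            class = "lstm_extractor")
}

#' Stack encoded mutations into directional input arrays
#'
#' Converts a list of `encoded_mutation` objects (all with the same flank
#' length) into two step x sample x 4 arrays, one per reading direction,
#' ready for batched processing.  Idempotent on already-stacked input.
#'
#' @param encs list of `encoded_mutation` objects, or a
#'   `stacked_encodings` object (returned unchanged).
#' @return object of class `stacked_encodings`.
#' @export
stack_encodings <- function(encs) {
  if (inherits(encs, "stacked_encodings")) return(encs)
  stopifnot(length(encs) > 0)
  srows <- vapply(encs, function(e) e$site_row, integer(1))
  nrows <- vapply(encs, function(e) nrow(e$matrix), integer(1))
  if (length(unique(srows)) != 1L || length(unique(nrows)) != 1L)
    stop("ragged batch: all encodings must share the same flank length",
         call. = FALSE)
  steps <- srows[1]
  B <- length(encs)
  x5 <- array(0, c(steps, B, 4L))
  x3 <- array(0, c(steps, B, 4L))
  for (b in seq_len(B)) {
    sp <- split_bidirectional(encs[[b]])
    x5[, b, ] <- sp$five_to_site
    x3[, b, ] <- sp$three_to_site
  }
  structure(list(x5 = x5, x3 = x3, n = B, steps = steps),
            class = "stacked_encodings")
}

#' @export
`[.stacked_encodings` <- function(x, idx) {
  structure(list(x5 = x$x5[, idx, , drop = FALSE],
                 x3 = x$x3[, idx, , drop = FALSE],
                 n = length(seq_len(x$n)[idx]), steps = x$steps),
            class = "stacked_encodings")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass of one directional read through the stacked LSTM.
# X: steps x B x in array.  Returns final hidden state of the top layer
# and, if requested, the per-step cache needed for backpropagation.
.dir_forward <- function(X, params, n_layers, H, want_cache = FALSE) {
  steps <- dim(X)[1]
  B <- dim(X)[2]
  input <- X
  cache <- if (want_cache) vector("list", n_layers) else NULL
  h <- NULL
  for (l in seq_len(n_layers)) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    hs <- array(0, c(steps, B, H))
    layer_cache <- if (want_cache) vector("list", steps) else NULL
    h <- matrix(0, B, H)
    cc <- matrix(0, B, H)
    gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
    for (t in seq_len(steps)) {
      Xt <- matrix(input[t, , ], nrow = B)
      Z <- Xt %*% Wx + h %*% Wh
      Z <- Z + rep(b, each = B)
      i <- .sigmoid(Z[, gi, drop = FALSE])
      f <- .sigmoid(Z[, gf, drop = FALSE])
      g <- tanh(Z[, gg, drop = FALSE])
      o <- .sigmoid(Z[, go, drop = FALSE])
      c_prev <- cc
      h_prev <- h
      cc <- f * cc + i * g
      tanhc <- tanh(cc)
      h <- o * tanhc
      hs[t, , ] <- h
      if (want_cache)
        layer_cache[[t]] <- list(Xt = Xt, h_prev = h_prev, c_prev = c_prev,
                                 i = i, f = f, g = g, o = o, tanhc = tanhc)
    }
    if (want_cache) cache[[l]] <- layer_cache
    input <- hs
  }
  list(h_final = h, cache = cache)
}

# Backpropagation through time for one directional read; accumulates
# parameter gradients into `grads` (shared across directions).
.dir_backward <- function(cache, params, n_layers, H, dH_final, grads) {
  steps <- length(cache[[1]])
  B <- nrow(dH_final)
  zero <- matrix(0, B, H)
  dH_above <- NULL  # per-step gradient handed down from the layer above
  for (l in rev(seq_len(n_layers))) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    dX_seq <- vector("list", steps)
    dh_next <- zero
    dc_next <- zero
    for (t in rev(seq_len(steps))) {
      dh <- dh_next
      if (l == n_layers) {
        if (t == steps) dh <- dh + dH_final
      } else {
        dh <- dh + dH_above[[t]]
      }
      st <- cache[[l]][[t]]
      do_ <- dh * st$tanhc
      dc <- dc_next + dh * st$o * (1 - st$tanhc^2)
      dzi <- (dc * st$g) * st$i * (1 - st$i)
      dzf <- (dc * st$c_prev) * st$f * (1 - st$f)
      dzg <- (dc * st$i) * (1 - st$g^2)
      dzo <- do_ * st$o * (1 - st$o)
      dz <- cbind(dzi, dzf, dzg, dzo)
      grads[[paste0("Wx", l)]] <- grads[[paste0("Wx", l)]] +
        crossprod(st$Xt, dz)
      grads[[paste0("Wh", l)]] <- grads[[paste0("Wh", l)]] +
        crossprod(st$h_prev, dz)
      grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] + colSums(dz)
      dX_seq[[t]] <- dz %*% t(Wx)
      dh_next <- dz %*% t(Wh)
      dc_next <- dc * st$f
    }
    dH_above <- dX_seq
  }
  grads
}

# Full forward pass over both directions plus the output layer.
.extractor_forward <- function(stacked, model, want_cache = FALSE) {
  cfg <- model$config
  f5 <- .dir_forward(stacked$x5, model$params, cfg$hidden_layers,
                     cfg$hidden_size, want_cache)
  f3 <- .dir_forward(stacked$x3, model$params, cfg$hidden_layers,
                     cfg$hidden_size, want_cache)
  concat <- cbind(f5$h_final, f3$h_final)
  Y <- concat %*% model$params$Wf
  Y <- Y + rep(model$params$bf, each = nrow(Y))
  list(Y = Y, concat = concat, c5 = f5$cache, c3 = f3$cache)
}

#' Extract feature vectors from encoded mutations
#'
#' Runs the two directional reads through the shared recurrent core,
#' concatenates the terminal hidden states and applies the fully
#' connected output layer.  Deterministic given fixed weights.
#'
#' @param encs list of `encoded_mutation` objects (all the same flank
#'   length) or a [stack_encodings()] result.
#' @param model an [lstm_extractor()].
#' @return numeric matrix, one row per input, `feature_dim` columns.
#' @export
extract_features <- function(encs, model) {
  stacked <- stack_encodings(encs)
  .extractor_forward(stacked, model)$Y
}

# Gradient of the mean-squared-error objective wrt all parameters.
.extractor_gradients <- function(stacked, labels, model) {
  cfg <- model$config
  fw <- .extractor_forward(stacked, model, want_cache = TRUE)
  B <- nrow(fw$Y)
  resid <- fw$Y - labels
  loss <- mean(resid^2)
  dY <- 2 * resid / length(resid)
  grads <- lapply(model$params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  grads$Wf <- crossprod(fw$concat, dY)
  grads$bf <- colSums(dY)
  dconcat <- dY %*% t(model$params$Wf)
  H <- cfg$hidden_size
  grads <- .dir_backward(fw$c5, model$params, cfg$hidden_layers, H,
                         dconcat[, seq_len(H), drop = FALSE], grads)
  grads <- .dir_backward(fw$c3, model$params, cfg$hidden_layers, H,
                         dconcat[, H + seq_len(H), drop = FALSE], grads)
  list(loss = loss, grads = grads)
}

#' Fit the extractor to label vectors
#'
#' Performs `iterations` full-batch Adam passes minimizing the mean
#' squared error between the extractor output and the given labels.
#' The optimizer state (first/second moments) persists inside the model
#' across calls, so repeated fitting continues one trajectory.
#'
#' @param encs encodings as in [extract_features()].
#' @param labels numeric matrix of target vectors, one row per input.
#' @param model an [lstm_extractor()].
#' @param iterations gradient passes; defaults to the config value (2).
#' @return list with `model` (updated weights) and `loss` (mean squared
#'   error measured at the start of the final pass).
#' @export
fit_to_labels <- function(encs, labels, model,
                          iterations = model$config$fit_iterations) {
  stacked <- stack_encodings(encs)
  labels <- as.matrix(labels)
  if (nrow(labels) != stacked$n)
    stop("labels and batch must have the same length", call. = FALSE)
  if (any(!is.finite(labels)))
    stop("labels contain non-finite values", call. = FALSE)
  lr <- model$config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  if (is.null(model$opt))
    model$opt <- list(m = lapply(model$params, function(p) p * 0),
                      v = lapply(model$params, function(p) p * 0),
                      t = 0L)
  loss <- NA_real_
  for (it in seq_len(iterations)) {
    gr <- .extractor_gradients(stacked, labels, model)
    loss <- gr$loss
    model$opt$t <- model$opt$t + 1L
    tt <- model$opt$t
    for (nm in names(model$params)) {
      g <- gr$grads[[nm]]
      model$opt$m[[nm]] <- beta1 * model$opt$m[[nm]] + (1 - beta1) * g
      model$opt$v[[nm]] <- beta2 * model$opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- model$opt$m[[nm]] / (1 - beta1^tt)
      vhat <- model$opt$v[[nm]] / (1 - beta2^tt)
      model$params[[nm]] <- model$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, loss = loss)
}

#' Save / load extractor weights
#'
#' Weights are written as a plain YAML archive (numeric vectors plus
#' shapes) together with the configuration, so checkpoints are
#' text-only and portable.
#'
#' @param model an [lstm_extractor()].
#' @param path file to write / read.
#' @return `load_extractor` returns the restored model.
#' @export
save_extractor <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = as.numeric(p))))
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) {
  ser <- yaml::read_yaml(path)
  cfg <- do.call(extractor_config, ser$config)
  params <- lapply(ser$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(config = cfg, params = params, opt = NULL),
            class = "lstm_extractor")
}
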