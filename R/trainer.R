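# Orchestration: the alternating extractor/SOM loop that produces one
# binary split, and the recursive splitting schedule that yields the
# final mutation-blot (MB) classes.

#' Configuration of one training round
#'
#' @param extractor an [extractor_config()].
#' @param som a [som_config()].
#' @param max_epochs cap on alternating epochs per round (default 60).
#' @param stability_tol stopping tolerance on the classification: every
#'   `check_every` epochs the monitor subsample is provisionally split
#'   in two, and the round stops once the adjusted Rand index between
#'   consecutive provisional splits reaches 1 - stability_tol for
#'   `stable_checks` checks in a row (default 0.02, i.e. ARI >= 0.98).
#'   This operationalizes training "until a clear, stable
#'   classification" directly on the quantity that matters — the
#'   classification — rather than on raw feature movement.
#' @param batch_size samples per training batch (default 100; shrunk
#'   with a warning when the input is smaller than two batches).
#' @param monitor_size size of the fixed subsample used for the
#'   stability checks (default 400).
#' @param check_every epochs between stability checks (default 5).
#' @param stable_checks consecutive stable checks required (default 2).
#' @param min_epochs epochs to run before stopping is allowed
#'   (default 15).
#' @param readout how the final features are split in two; see
#'   [binary_readout()].  The default `"subclusters"` merges k-means
#'   subclusters by optimal weighted bipartition.
#' @param anchor_readout if `TRUE` (default) the final binary
#'   assignment is smoothed by majority vote inside subclusters of the
#'   raw encoded sequences.  The trained features progressively
#'   collapse fine context detail into the two emerging groups, so
#'   samples near the boundary can drift to the wrong side; snapping
#'   the boundary onto input-space subclusters keeps each locally
#'   coherent context group together while the learned features still
#'   decide which side of the split it belongs to.
#' @param seed integer seed; all extractor/SOM/readout seeds are derived
#'   from it deterministically.
#' @return list of class `train_config`.
#' @export
train_config <- function(extractor = extractor_config(), som = som_config(),
                         max_epochs = 60L, stability_tol = 0.02,
                         batch_size = 100L, monitor_size = 400L,
                         check_every = 5L, stable_checks = 2L,
                         min_epochs = 15L,
                         readout = c("subclusters", "kmeans", "units"),
                         anchor_readout = TRUE, seed = 1L) {
  readout <- match.arg(readout)
  stopifnot(max_epochs >= 1, stability_tol >= 0, batch_size >= 2,
            check_every >= 1, stable_checks >= 1)
  structure(list(extractor = extractor, som = som,
                 max_epochs = as.integer(max_epochs),
                 stability_tol = stability_tol,
                 batch_size = as.integer(batch_size),
                 monitor_size = as.integer(monitor_size),
                 check_every = as.integer(check_every),
                 stable_checks = as.integer(stable_checks),
                 min_epochs = as.integer(min_epochs),
                 readout = readout,
                 anchor_readout = isTRUE(anchor_readout),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split feature vectors into two groups
#'
#' The binary readout used at the end of each training round.  The
#' default `"subclusters"` first over-clusters the feature vectors
#' (seeded k-means into up to 12 subclusters) and then merges the
#' subcluster centroids into the two groups minimizing the
#' size-weighted within-group sum of squares, found by exhaustive
#' bipartition — a split boundary that never cuts through a tight
#' feature cluster.  `"kmeans"` is plain seeded 2-means on the feature
#' vectors; `"units"` assigns each sample to its nearest competition
#' unit and 2-means-clusters the unit vectors.
#'
#' @param features numeric matrix of feature vectors.
#' @param method `"subclusters"`, `"kmeans"` or `"units"`.
#' @param seed integer seed.
#' @param layer competition layer matrix (required for
#'   `method = "units"`).
#' @return integer vector of group labels (1 or 2).
#' @export
binary_readout <- function(features,
                           method = c("subclusters", "kmeans", "units"),
                           seed = 1L, layer = NULL) {
  method <- match.arg(method)
  set.seed(seed)
  features <- as.matrix(features)
  n <- nrow(features)
  if (method == "kmeans" || (method == "subclusters" && n < 8L)) {
    km <- stats::kmeans(features, centers = 2L, nstart = 25L,
                        iter.max = 100L)
    as.integer(km$cluster)
  } else if (method == "subclusters") {
    k <- max(3L, min(12L, n %/% 20L))
    km <- stats::kmeans(features, centers = k, nstart = 25L,
                        iter.max = 100L)
    grouping <- .best_bipartition(km$centers, km$size)
    as.integer(grouping[km$cluster])
  } else {
    if (is.null(layer)) stop("'units' readout needs the layer", call. = FALSE)
    km <- stats::kmeans(layer, centers = 2L, nstart = 25L, iter.max = 100L)
    nearest <- apply(features, 1, function(x)
      which.min(colSums((t(layer) - x)^2)))
    as.integer(km$cluster[nearest])
  }
}

# Exhaustive optimal 2-grouping of <= 16 weighted points: minimizes the
# weighted within-group sum of squares over all bipartitions.
.best_bipartition <- function(centers, sizes) {
  k <- nrow(centers)
  stopifnot(k >= 2, k <= 16)
  best <- NULL
  best_ss <- Inf
  for (mask in seq_len(2^(k - 1L) - 1L)) {
    g <- c(0L, as.integer(intToBits(mask))[seq_len(k - 1L)])
    ss <- 0
    for (side in 0:1) {
      sel <- g == side
      w <- sizes[sel]
      mu <- colSums(centers[sel, , drop = FALSE] * w) / sum(w)
      ss <- ss + sum(w * rowSums(sweep(centers[sel, , drop = FALSE],
                                       2, mu)^2))
    }
    if (ss < best_ss) {
      best_ss <- ss
      best <- g
    }
  }
  best + 1L
}

#' One round of alternating extractor/SOM training
#'
#' Repeats, until the feature vectors stabilize or `max_epochs` is hit:
#' (a) extract features of a random batch, (b) update the competition
#' layer and compute the feedback vectors x(new), (c) fit the extractor
#' to x(new) for two gradient passes.  The competition layer is
#' initialized from the first batch's feature bounding box, and the
#' neighborhood constant sigma of the SOM config is interpreted in
#' units of the initial RMS feature dispersion (so the clustering
#' dynamics do not depend on the arbitrary output scale of the freshly
#' initialized extractor).  Finally the features of all samples are
#' computed and split into exactly two groups.
#'
#' @param encs list of `encoded_mutation` objects or a
#'   [stack_encodings()] result.
#' @param config a [train_config()].
#' @return list of class `train_round_result`: `assignment` (integer 1/2
#'   per sample), `features` (final feature matrix), `model`, `layer`,
#'   `epochs`, `best_epoch` (the snapshot the readout used), `clarity`
#'   (between-group variance fraction of each provisional split),
#'   `stability` (adjusted Rand index between consecutive provisional
#'   monitor-set splits) and `converged`.
#' @export
train_round <- function(encs, config = train_config()) {
  stacked <- stack_encodings(encs)
  n <- stacked$n
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  bs <- config$batch_size
  if (n < 2L * bs) {
    bs <- max(2L, n %/% 2L)
    warning("input smaller than two batches; batch_size shrunk to ", bs,
            call. = FALSE)
  }
  ext_cfg <- config$extractor
  ext_cfg$seed <- derive_seed(config$seed, "extractor")
  som_cfg <- config$som
  som_cfg$seed <- derive_seed(config$seed, "som-layer")
  som_cfg$batch_size <- max(som_cfg$batch_size, bs)
  model <- lstm_extractor(ext_cfg)
  set.seed(derive_seed(config$seed, "epochs"))
  monitor_idx <- sample.int(n, min(config$monitor_size, n))
  batch_plan <- lapply(seq_len(config$max_epochs), function(e)
    sample.int(n, bs))
  stability_seed <- derive_seed(config$seed, "stability")
  layer <- NULL
  prev_assign <- NULL
  stability <- numeric(0)
  clarity <- numeric(0)
  stable_run <- 0L
  converged <- FALSE
  epochs <- 0L
  best <- list(clarity = -Inf, model = model, layer = NULL, epoch = 0L)
  for (e in seq_len(config$max_epochs)) {
    idx <- batch_plan[[e]]
    x <- extract_features(stacked[idx], model)
    if (is.null(layer)) {
      s0 <- sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
      som_cfg$sigma <- som_cfg$sigma * max(s0, 1e-8)
      layer <- som_layer_init(x, som_cfg)
    }
    upd <- som_batch_update(x, layer, som_cfg)
    layer <- upd$layer
    fit <- fit_to_labels(stacked[idx], upd$x_new, model)
    model <- fit$model
    epochs <- e
    if (e %% config$check_every == 0L) {
      mon <- extract_features(stacked[monitor_idx], model)
      assign <- binary_readout(mon, config$readout, seed = stability_seed,
                               layer = layer)
      cl <- .split_clarity(mon, assign)
      clarity <- c(clarity, cl)
      if (cl > best$clarity)
        best <- list(clarity = cl, model = model, layer = layer, epoch = e)
      if (!is.null(prev_assign)) {
        ari <- adjusted_rand_index(assign, prev_assign)
        stability <- c(stability, ari)
        stable_run <- if (ari >= 1 - config$stability_tol)
          stable_run + 1L else 0L
      }
      prev_assign <- assign
      if (e >= config$min_epochs && stable_run >= config$stable_checks) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    message("train_round: classification still moving (last stability ",
            signif(utils::tail(c(NA, stability), 1), 3), ") after ",
            epochs, " epochs; clearest snapshot returned")
  # read out from the snapshot with the clearest provisional split, not
  # necessarily the last epoch: prolonged feedback can blur an already
  # clear classification
  if (!is.null(best$layer)) {
    model <- best$model
    layer <- best$layer
  }
  features <- extract_features(stacked, model)
  assignment <- binary_readout(features, config$readout,
                               seed = derive_seed(config$seed, "readout"),
                               layer = layer)
  if (isTRUE(config$anchor_readout))
    assignment <- .anchor_assignment(.flatten_encodings(stacked), assignment,
                                     derive_seed(config$seed, "anchor"))
  structure(list(assignment = assignment, features = features,
                 model = model, layer = layer, epochs = epochs,
                 best_epoch = best$epoch, clarity = clarity,
                 stability = stability, converged = converged),
            class = "train_round_result")
}

#' Configuration of the recursive splitting schedule
#'
#' @param rounds number of full binary-splitting rounds (default 3,
#'   giving 2^3 = 8 leaves).
#' @param extra_split_count after the full rounds, the largest
#'   `extra_split_count` leaves are each split once more (default 2,
#'   taking 8 leaves to 10).
#' @param train a [train_config()] template used for every split (the
#'   seed of each split is derived from `seed` and the leaf's tree
#'   path).
#' @param min_leaf leaves smaller than this are left intact with a
#'   warning (default 4).
#' @param seed integer master seed.
#' @return list of class `schedule_config`.
#' @export
schedule_config <- function(rounds = 3L, extra_split_count = 2L,
                            train = train_config(), min_leaf = 4L,
                            seed = 1L) {
  stopifnot(rounds >= 0, extra_split_count >= 0, min_leaf >= 2)
  structure(list(rounds = as.integer(rounds),
                 extra_split_count = as.integer(extra_split_count),
                 train = train, min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "schedule_config")
}

# One row per sample: both directional reads, flattened.
.flatten_encodings <- function(stacked) {
  cbind(matrix(aperm(stacked$x5, c(2, 1, 3)), nrow = stacked$n),
        matrix(aperm(stacked$x3, c(2, 1, 3)), nrow = stacked$n))
}

# Majority-vote smoothing of a binary assignment inside subclusters of
# the raw encoding space; falls back to the raw assignment for small
# inputs or degenerate votes.
.anchor_assignment <- function(raw, assignment, seed) {
  n <- nrow(raw)
  k0 <- max(3L, min(24L, n %/% 15L))
  if (n < 60L) return(assignment)
  set.seed(seed)
  km <- stats::kmeans(raw, k0, nstart = 10L, iter.max = 100L)
  out <- assignment
  for (c0 in seq_len(k0)) {
    sel <- km$cluster == c0
    tab <- table(assignment[sel])
    out[sel] <- as.integer(names(tab)[which.max(tab)])
  }
  if (length(unique(out)) < 2L) return(assignment)
  out
}

# Clarity of a provisional binary split: fraction of total feature
# variance explained by the two group means.  Degenerate splits (one
# group under 2% of the samples) score zero.
.split_clarity <- function(features, assign) {
  n <- nrow(features)
  sizes <- table(assign)
  if (length(sizes) < 2L || min(sizes) < max(2, 0.02 * n)) return(0)
  mu <- colMeans(features)
  total <- sum(sweep(features, 2, mu)^2)
  if (total <= 0) return(0)
  between <- 0
  for (g in names(sizes)) {
    mg <- colMeans(features[assign == g, , drop = FALSE])
    between <- between + sizes[[g]] * sum((mg - mu)^2)
  }
  between / total
}

# Split one leaf with a seed derived from the master seed and the
# leaf's tree path; returns the two children (or the leaf itself if it
# is too small to split).
.split_leaf <- function(leaf, stacked, schedule) {
  if (length(leaf$idx) < schedule$min_leaf) {
    warning("leaf ", leaf$path, " has ", length(leaf$idx),
            " samples (< min_leaf); left intact", call. = FALSE)
    return(list(leaf))
  }
  cfg <- schedule$train
  cfg$seed <- derive_seed(schedule$seed, leaf$path)
  res <- train_round(stacked[leaf$idx], cfg)
  list(list(idx = leaf$idx[res$assignment == 1L],
            path = paste0(leaf$path, "0")),
       list(idx = leaf$idx[res$assignment == 2L],
            path = paste0(leaf$path, "1")))
}

#' Run the full recursive splitting schedule
#'
#' Round r applies [train_round()] independently inside each current
#' leaf (fresh extractor and fresh competition layer per leaf, with
#' deterministically derived seeds), so `rounds` rounds give 2^rounds
#' leaves; the `extra_split_count` largest leaves (by sample count) are
#' then each split once more.  Leaves are numbered MB 1, MB 2, ... in
#' decreasing size order (ties broken by tree path).
#'
#' @param encs list of `encoded_mutation` objects or a
#'   [stack_encodings()] result.
#' @param schedule a [schedule_config()].
#' @return object of class `mb_labeling`: list with `labels` (factor of
#'   MB classes, one per input sample, in input order), `k` (leaf
#'   count), and `tree` (data frame recording each final leaf's tree
#'   path and size).
#' @export
run_schedule <- function(encs, schedule = schedule_config()) {
  stacked <- stack_encodings(encs)
  leaves <- list(list(idx = seq_len(stacked$n), path = "r"))
  for (r in seq_len(schedule$rounds)) {
    leaves <- do.call(c, lapply(leaves, .split_leaf, stacked = stacked,
                                schedule = schedule))
    # drop empty children (degenerate split of near-identical samples)
    leaves <- Filter(function(l) length(l$idx) > 0, leaves)
  }
  if (schedule$extra_split_count > 0L && length(leaves) > 0L) {
    sizes <- vapply(leaves, function(l) length(l$idx), integer(1))
    paths <- vapply(leaves, function(l) l$path, character(1))
    ord <- order(-sizes, paths)
    to_split <- ord[seq_len(min(schedule$extra_split_count, length(leaves)))]
    keep <- leaves[setdiff(seq_along(leaves), to_split)]
    extra <- do.call(c, lapply(leaves[to_split], .split_leaf,
                               stacked = stacked, schedule = schedule))
    extra <- Filter(function(l) length(l$idx) > 0, extra)
    leaves <- c(keep, extra)
  }
  sizes <- vapply(leaves, function(l) length(l$idx), integer(1))
  paths <- vapply(leaves, function(l) l$path, character(1))
  ord <- order(-sizes, paths)
  leaves <- leaves[ord]
  k <- length(leaves)
  lvls <- paste("MB", seq_len(k))
  labels <- character(stacked$n)
  for (j in seq_len(k)) labels[leaves[[j]]$idx] <- lvls[j]
  structure(list(labels = factor(labels, levels = lvls), k = k,
                 tree = data.frame(
                   label = lvls,
                   path = vapply(leaves, function(l) l$path, character(1)),
                   n = vapply(leaves, function(l) length(l$idx), integer(1)),
                   stringsAsFactors = FALSE)),
            class = "mb_labeling")
}

#' Write a run manifest
#'
#' Echoes every seed and configuration value of a schedule run, plus
#' the resulting leaf table, into a YAML file so a labeling can be
#' reproduced exactly.
#'
#' @param schedule the [schedule_config()] that was run.
#' @param labeling the resulting `mb_labeling` (optional).
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(schedule, labeling = NULL, path) {
  manifest <- list(
    schedule = list(rounds = schedule$rounds,
                    extra_split_count = schedule$extra_split_count,
                    min_leaf = schedule$min_leaf,
                    seed = schedule$seed),
    train = unclass(schedule$train)[c("max_epochs", "stability_tol",
                                      "batch_size", "monitor_size",
                                      "check_every", "stable_checks",
                                      "min_epochs", "readout",
                                      "anchor_readout", "seed")],
    extractor = unclass(schedule$train$extractor),
    som = unclass(schedule$train$som))
  if (!is.null(labeling))
    manifest$leaves <- lapply(seq_len(nrow(labeling$tree)), function(i)
      as.list(labeling$tree[i, ]))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Write MB labels alongside their source records
#'
#' @param labeling an `mb_labeling` from [run_schedule()].
#' @param records the SBS record data frame the labeling was computed
#'   from (same row order).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_mb_labels <- function(labeling, records, path) {
  stopifnot(nrow(records) == length(labeling$labels))
  out <- data.frame(
    sample_barcode = records$sample_barcode,
    chromosome = records$chromosome,
    position = records$position,
    ref_allele = records$ref_allele,
    alt_allele = records$alt_allele,
    gene_symbol = records$gene_symbol %||% "",
    mb_label = as.character(labeling$labels),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
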