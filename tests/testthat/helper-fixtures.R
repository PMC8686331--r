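# Shared fixtures, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full fixture bundle (micro, two_class, ten_class, survival).
fixture_bundle <- function() {
  with_cache("bundle", {
    dir <- file.path(tempdir(), "mutblot-fixtures")
    write_fixtures(dir, seed = 1)
  })
}

# Encoded two-class recovery set plus its hidden truth.
two_class_data <- function() {
  with_cache("two_class", {
    fx <- fixture_bundle()$two_class
    maf <- read_maf(fx$maf)
    genome <- genome_source(fx$genome)
    seqs <- extract_flanks(maf, genome, flank = 10)
    truth <- utils::read.delim(fx$truth_sbs)
    stopifnot(all(truth$position == maf$position))
    list(maf = maf, seqs = seqs,
         stacked = stack_encodings(encode_sequences(seqs)),
         truth = truth)
  })
}

# Encoded ten-class schedule set plus truth.
ten_class_data <- function() {
  with_cache("ten_class", {
    fx <- fixture_bundle()$ten_class
    maf <- read_maf(fx$maf)
    genome <- genome_source(fx$genome)
    seqs <- extract_flanks(maf, genome, flank = 10)
    truth <- utils::read.delim(fx$truth_sbs)
    list(maf = maf, seqs = seqs,
         stacked = stack_encodings(encode_sequences(seqs)),
         truth = truth)
  })
}

# Planted-truth recovery of one training round, cached per seed.
two_class_round <- function(seed) {
  with_cache(paste0("round", seed), {
    dat <- two_class_data()
    res <- train_round(dat$stacked, train_config(seed = seed))
    list(assignment = res$assignment,
         ari = adjusted_rand_index(res$assignment, dat$truth$class),
         converged = res$converged)
  })
}

# Full splitting schedule on the ten-class set, cached per seed.
ten_class_schedule <- function(seed) {
  with_cache(paste0("schedule", seed), {
    dat <- ten_class_data()
    lab <- suppressWarnings(
      run_schedule(dat$stacked, schedule_config(seed = seed)))
    list(labeling = lab,
         ari = adjusted_rand_index(lab$labels, dat$truth$class))
  })
}

# Tiny random encodings for fast structural tests.
tiny_encodings <- function(n, f = 2, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    encode_mutation_sequence(random_mutation_sequence(f)))
}

# Small configs that keep structural trainer tests fast.
tiny_train_config <- function(seed = 1, ...) {
  train_config(
    extractor = extractor_config(hidden_size = 8L, seed = seed),
    som = som_config(n_units = 40L, seed = seed),
    max_epochs = 3L, batch_size = 10L, monitor_size = 50L,
    seed = seed, ...)
}
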