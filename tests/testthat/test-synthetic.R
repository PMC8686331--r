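test_that("generated references honor GC content and determinism", {
  p1 <- tempfile(fileext = ".fa")
  g1 <- generate_reference(1e5, gc = 0.5, seed = 3, path = p1)
  seq <- genome_subseq(g1, "chr1", 1, 1e5)
  gc <- mean(strsplit(seq, "")[[1]] %in% c("G", "C"))
  expect_true(gc >= 0.49 && gc <= 0.51)
  p2 <- tempfile(fileext = ".fa")
  g2 <- generate_reference(1e5, gc = 0.5, seed = 3, path = p2)
  expect_identical(readLines(p1)[-1], readLines(p2)[-1])
  expect_error(generate_reference(1e4, gc = 1, seed = 1), "gc")
  expect_error(generate_reference(50, seed = 1, flank = 50), "below")
})

test_that("context profiles decay toward uniform away from the site", {
  prof <- context_profile(1, "C>T", five_base = "T", p_max = 0.9,
                          tau = 3, flank = 20)
  expect_equal(rowSums(prof$five_probs), rep(1, 20), tolerance = 1e-12)
  expect_equal(rowSums(prof$three_probs), rep(1, 20), tolerance = 1e-12)
  expect_equal(unname(prof$five_probs[20, "T"]), 0.9)        # position -1
  expect_lt(unname(prof$five_probs[1, "T"]), 0.3)            # position -20
  expect_equal(unname(prof$sub_probs["C>T"]), 1)
  expect_error(context_profile(1, "C>X", "T"), "sub_type")
})

test_that("hidden classes follow the patient mixtures exactly and in frequency", {
  dir <- file.path(tempdir(), "mix-cohort")
  spec <- synthetic_spec(n_patients = 4, sbs_per_patient = 30,
                         archetype_mixtures = list(c(1, 0), c(0, 1)),
                         hazards = c(0.001, 0.001), flank = 2, seed = 5)
  profiles <- list(context_profile(1, "C>T", "T", flank = 2),
                   context_profile(2, "T>G", "A", flank = 2))
  genome <- generate_reference(5000, seed = 6, flank = 2,
                               path = tempfile(fileext = ".fa"))
  out <- generate_cohort(spec, profiles, genome, dir)
  truth <- out$truth_sbs_df
  arch <- out$truth_patients_df
  for (p in arch$sample_barcode) {
    cls <- truth$class[truth$sample_barcode == p]
    expect_length(unique(cls), 1)  # pure mixtures: one hidden class
    expect_equal(unique(cls), arch$archetype[arch$sample_barcode == p])
  }
  # planted 0.3/0.7 mixture converges at n ~ 10^4
  spec2 <- synthetic_spec(n_patients = 200, sbs_per_patient = 50,
                          archetype_mixtures = list(c(0.3, 0.7)),
                          hazards = 0.001, flank = 2, seed = 7)
  genome2 <- generate_reference(7e5, seed = 8, flank = 2,
                                path = tempfile(fileext = ".fa"))
  out2 <- generate_cohort(spec2, profiles, genome2,
                          file.path(tempdir(), "mix-cohort2"))
  n <- nrow(out2$truth_sbs_df)
  phat <- mean(out2$truth_sbs_df$class == 1)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_patients = 3, sbs_per_patient = 10,
                         archetype_mixtures = list(c(0.5, 0.5)),
                         hazards = 0.002, flank = 2, seed = 11)
  profiles <- list(context_profile(1, "C>A", "T", flank = 2),
                   context_profile(2, "T>C", "G", flank = 2))
  genome <- generate_reference(2000, seed = 12, flank = 2,
                               path = tempfile(fileext = ".fa"))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  o1 <- generate_cohort(spec, profiles, genome, d1)
  o2 <- generate_cohort(spec, profiles, genome, d2)
  for (f in c("maf", "clinical", "genome", "truth_sbs"))
    expect_identical(readLines(o1[[f]]), readLines(o2[[f]]))
})

test_that("generated files parse with the package readers and validate", {
  fx <- fixture_bundle()$survival
  maf <- read_maf(fx$maf)
  clin <- read_clinical(fx$clinical)
  expect_gt(nrow(maf), 0)
  expect_equal(nrow(clin), 200)
  expect_true(all(clin$event %in% 0:1))
  expect_true(all(clin$survival_time >= 0))
  # truth labels live in a separate file with a different schema
  truth_cols <- names(utils::read.delim(fx$truth_sbs, nrows = 1))
  expect_true("class" %in% truth_cols)
  expect_false("class" %in% names(maf))
  genome <- genome_source(fx$genome)
  seqs <- extract_flanks(maf[1:50, ], genome, flank = 10)
  expect_true(all(nchar(seqs$five_prime_flank) == 10))
  expect_false(any(seqs$ref_mismatch))
})

test_that("degenerate generation requests are rejected", {
  spec <- synthetic_spec(n_patients = 50, sbs_per_patient = 100,
                         archetype_mixtures = list(1), hazards = 0.001,
                         flank = 10, seed = 1)
  prof <- list(context_profile(1, "C>T", "T", flank = 10))
  small_genome <- generate_reference(500, seed = 2, flank = 10,
                                     path = tempfile(fileext = ".fa"))
  expect_error(generate_cohort(spec, prof, small_genome,
                               file.path(tempdir(), "short")),
               "too short")
  near_identical <- list(
    context_profile(1, "C>T", "T", p_max = 0.26, flank = 10),
    context_profile(2, "C>T", "T", p_max = 0.27, flank = 10))
  spec2 <- synthetic_spec(n_patients = 2, sbs_per_patient = 5,
                          archetype_mixtures = list(c(1, 0), c(0, 1)),
                          hazards = c(0.001, 0.001), flank = 10, seed = 1)
  big_genome <- generate_reference(5000, seed = 3, flank = 10,
                                   path = tempfile(fileext = ".fa"))
  expect_error(generate_cohort(spec2, near_identical, big_genome,
                               file.path(tempdir(), "close")),
               "separated")
  expect_error(synthetic_spec(2, 5, list(c(0.5, 0.6)), hazards = 1),
               "sum to 1")
})

test_that("the fixture bundle reproduces the worked example and is checksum-stable", {
  fx <- fixture_bundle()
  maf <- read_maf(fx$micro$maf)
  genome <- genome_source(fx$micro$genome)
  seqs <- extract_flanks(maf, genome, flank = 2)
  enc <- encode_sequences(seqs)[[1]]
  expect_identical(enc$matrix, rbind(c(1, 0, 1, 0),
                                     c(0, 0, 0, 0),
                                     c(1, 0, 0, 1),
                                     c(0, 1, 0, 1),
                                     c(1, 1, 1, 1)))
  two <- read_maf(fx$two_class$maf)
  expect_equal(nrow(two), 2000)
  # regeneration with the same seed leaves every checksum unchanged
  dir2 <- file.path(tempdir(), "fixture-rerun")
  write_fixtures(dir2, seed = 1)
  base_dir <- file.path(tempdir(), "mutblot-fixtures")
  c1 <- readLines(file.path(base_dir, "checksums.txt"))
  c2 <- readLines(file.path(dir2, "checksums.txt"))
  expect_identical(sort(c1), sort(c2))
})
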