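test_that("MB composition rows are proportions summing to one", {
  labels <- c("MB 1", "MB 1", "MB 2", "MB 2",
              "MB 1", "MB 3", "MB 3", "MB 3")
  barcodes <- c(rep("P1", 4), rep("P2", 4))
  comp <- mb_composition(labels, barcodes)
  expect_equal(unname(comp$proportions["P1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(comp$proportions["P2", ]), c(0.25, 0, 0.75))
  expect_equal(unname(comp$n_sbs), c(4L, 4L))
  set.seed(1)
  rnd <- mb_composition(sample(paste("MB", 1:5), 300, replace = TRUE),
                        sample(paste0("P", 1:20), 300, replace = TRUE))
  expect_equal(unname(rowSums(rnd$proportions)),
               rep(1, nrow(rnd$proportions)), tolerance = 1e-9)
})

test_that("composition of a synthetic cohort matches the planted mixture", {
  # 500 SBS per patient drawn from a fixed two-class mixture
  set.seed(42)
  mix <- c(0.7, 0.3)
  n_per <- 500
  labels <- unlist(lapply(1:12, function(p)
    sample(c("MB 1", "MB 2"), n_per, replace = TRUE, prob = mix)))
  barcodes <- rep(paste0("P", sprintf("%02d", 1:12)), each = n_per)
  comp <- mb_composition(labels, barcodes)
  se <- sqrt(mix[1] * (1 - mix[1]) / n_per)
  expect_true(all(abs(comp$proportions[, "MB 1"] - mix[1]) < 4 * se))
})

test_that("spectrum summary reports type fractions and per-position base fractions", {
  seqs <- data.frame(
    five_prime_flank = c("AT", "GG", "CC", "TA"),
    ref_allele = c("C", "C", "G", "T"),
    alt_allele = c("A", "A", "T", "G"),
    three_prime_flank = c("GG", "AA", "TT", "CC"),
    stringsAsFactors = FALSE)
  labels <- c("MB 1", "MB 1", "MB 1", "MB 2")
  sp <- spectrum_summary(labels, seqs)
  # MB 1: C>A, C>A and G>T (which collapses to C>A) -> pure C>A
  expect_equal(unname(sp$type_fractions["MB 1", ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(rownames(sp$base_fractions[["MB 1"]]),
               c("-2", "-1", "+1", "+2"))
  for (lv in names(sp$base_fractions))
    expect_equal(unname(rowSums(sp$base_fractions[[lv]])),
                 rep(1, 4), tolerance = 1e-12)
})

test_that("planted near-site enrichment is recovered by the spectrum", {
  # class with an 80% T preference at position -1, n = 2000
  prof <- context_profile(1, "C>T", five_base = "T", p_max = 0.8,
                          tau = 2, flank = 3)
  spec <- synthetic_spec(n_patients = 20, sbs_per_patient = 100,
                         archetype_mixtures = list(1), hazards = 0.001,
                         flank = 3, seed = 77)
  genome <- generate_reference(20000, seed = 78, flank = 3,
                               path = tempfile(fileext = ".fa"))
  out <- generate_cohort(spec, list(prof), genome,
                         file.path(tempdir(), "spectrum-cohort"))
  maf <- read_maf(out$maf)
  seqs <- extract_flanks(maf, genome_source(out$genome), flank = 3)
  sp <- spectrum_summary(rep("MB 1", nrow(seqs)), seqs)
  expect_equal(unname(sp$base_fractions[["MB 1"]]["-1", "T"]), 0.8,
               tolerance = 0.03)
  expect_equal(unname(sp$type_fractions["MB 1", "C>T"]), 1)
})

test_that("the elbow rule finds the sharpest knee of the dispersion curve", {
  k_range <- 2:10
  wss <- c(100, 60, 20, 18, 16.5, 15, 14, 13.2, 12.5)
  expect_equal(choose_k_elbow(wss, k_range), 4)
  expect_error(choose_k_elbow(c(1, 2), 1:2), "length")
})

test_that("patient clustering defaults to K = 7 and honors K = 1", {
  set.seed(5)
  labels <- sample(paste("MB", 1:8), 4000, replace = TRUE)
  barcodes <- rep(sprintf("P%03d", 1:40), each = 100)
  comp <- mb_composition(labels, barcodes)
  pc <- cluster_patients(comp)
  expect_equal(pc$K, 7L)
  expect_equal(nlevels(pc$classes), 7L)
  expect_equal(length(pc$classes), 40)
  one <- cluster_patients(comp, K = 1)
  expect_equal(nlevels(droplevels(one$classes)), 1L)
  expect_error(cluster_patients(comp, K = 41), "exceeds")
})

test_that("the elbow scan recovers three planted composition archetypes", {
  set.seed(9)
  archetypes <- list(c(0.7, 0.1, 0.1, 0.05, 0.05),
                     c(0.05, 0.7, 0.1, 0.1, 0.05),
                     c(0.05, 0.1, 0.1, 0.05, 0.7))
  labels <- character(0); barcodes <- character(0)
  for (p in 1:60) {
    arch <- archetypes[[(p - 1) %% 3 + 1]]
    labels <- c(labels, sample(paste("MB", 1:5), 500, replace = TRUE,
                               prob = arch))
    barcodes <- c(barcodes, rep(sprintf("P%03d", p), 500))
  }
  comp <- mb_composition(labels, barcodes)
  pc <- cluster_patients(comp, K = "auto", k_range = 2:10, seed = 3)
  expect_equal(pc$K, 3L)
  truth <- rep(1:3, 20)[order(rep(1:20, each = 3))]  # archetype per patient
  truth <- ((seq_len(60) - 1) %% 3) + 1
  expect_gt(adjusted_rand_index(pc$classes, truth), 0.95)
  # permutation invariance up to label renaming
  perm <- sample(nrow(comp$proportions))
  comp2 <- comp
  comp2$proportions <- comp$proportions[perm, ]
  comp2$n_sbs <- comp$n_sbs[perm]
  pc2 <- cluster_patients(comp2, K = 3, seed = 3)
  expect_equal(adjusted_rand_index(pc2$classes,
                                   pc$classes[rownames(comp2$proportions)]), 1)
})

test_that("group comparison dispatches on outcome type and group count", {
  g2 <- rep(c("a", "b"), each = 10)
  same <- rep(seq_len(10), 2)
  res <- group_compare(same, g2)
  expect_equal(res$test_name, "t")
  expect_equal(res$statistic, 0)
  g3 <- rep(c("a", "b", "c"), each = 10)
  res3 <- group_compare(rnorm(30), g3)
  expect_equal(res3$test_name, "anova")
  cat_res <- group_compare(rep(c("x", "y"), 15), g3)
  expect_equal(cat_res$test_name, "chi-square")
  expect_true(res3$p_value >= 0 && res3$p_value <= 1)
})

test_that("the 2x2 chi-square statistic matches the hand-computed value", {
  # contingency table [[10, 20], [20, 10]]
  values <- rep(rep(c("x", "y"), 2), c(10, 20, 20, 10))
  groups <- rep(c("g1", "g2"), each = 30)
  res <- group_compare(values, groups)
  n <- 60
  ad_bc <- abs(10 * 10 - 20 * 20)
  hand <- n * (ad_bc - n / 2)^2 / (30 * 30 * 30 * 30)  # Yates-corrected
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(hand, 5.4)
})

test_that("missing rows are removed per analysis and emptied groups are an error", {
  vals <- c(1, 2, NA, 4, 5, NA)
  grp <- c("a", "a", "a", "b", "b", "b")
  res <- group_compare(vals, grp)
  expect_equal(res$dropped, 2)
  expect_equal(unname(res$group_sizes), c(2L, 2L))
  vals2 <- c(NA, NA, NA, 1, 2, 3)
  expect_error(group_compare(vals2, grp), "a")
})

test_that("the log-rank statistic agrees with risk-set tabulation to 1e-10", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:20, 1)
    time <- round(rexp(n, 0.01), 1)
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("g1", "g2"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    res <- logrank(time, event, group)
    expect_equal(res$statistic, oracle_logrank_2group(time, event, group),
                 tolerance = 1e-10)
  }
})

test_that("log-rank handles all-censored groups and rejects event-free input", {
  time <- c(10, 20, 30, 40, 50, 60)
  event <- c(1, 1, 1, 0, 0, 0)
  group <- rep(c("a", "b"), each = 3)
  res <- logrank(time, event, group)     # group b has zero events
  expect_true(is.finite(res$statistic))
  expect_equal(unname(res$group_sizes), c(3L, 3L))
  expect_error(logrank(time, rep(0, 6), group), "no events")
})

test_that("per-gene survival groups honor the multi-MB patient modes", {
  labeled <- data.frame(
    sample_barcode = c("P1", "P1", "P1", "P2", "P3"),
    gene_symbol = "GENE01",
    mb_label = c("MB 2", "MB 2", "MB 1", "MB 1", "MB 2"),
    stringsAsFactors = FALSE)
  clinical <- data.frame(sample_barcode = c("P1", "P2", "P3"),
                         survival_time = c(100, 200, 300),
                         event = c(1L, 0L, 1L),
                         stringsAsFactors = FALSE)
  any_mode <- mb_gene_groups(labeled, clinical, "GENE01")
  expect_equal(sum(any_mode$patient == "P1"), 2)  # P1 in both groups
  excl <- mb_gene_groups(labeled, clinical, "GENE01", mode = "exclusive")
  expect_equal(excl$group[excl$patient == "P1"], "MB 2")  # majority class
  dropped <- mb_gene_groups(labeled, clinical, "GENE01", mode = "drop")
  expect_false("P1" %in% dropped$patient)
  expect_error(mb_gene_groups(labeled, clinical, "GENE99"), "GENE99")
})

test_that("survival curves export as valid step functions", {
  set.seed(12)
  time <- rexp(40, 0.01)
  event <- rbinom(40, 1, 0.6)
  group <- rep(c("a", "b"), 20)
  curves <- survival_curves(time, event, group)
  expect_setequal(unique(curves$group), c("a", "b"))
  for (g in c("a", "b")) {
    s <- curves$surv[curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})
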