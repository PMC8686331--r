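# Synthetic-data generator: a toy reference genome, MAF-format SBS
# records with planted per-class flank-context signatures, and clinical
# tables with class-dependent exponential hazards, so the whole pipeline
# runs end to end with no external downloads.

#' A planted flank-context profile for one SBS class
#'
#' Defines the substitution-type distribution (over the six canonical
#' pyrimidine-represented types) and, at every flank position, the base
#' probabilities.  The preference for the class's favored base is
#' strongest next to the mutated site and decays exponentially toward
#' the uniform 0.25 with distance, mirroring how real flank composition
#' balances out away from the site.
#'
#' @param class_id integer id of the class.
#' @param sub_type either one of the six canonical types (point mass) or
#'   a named probability vector over them.
#' @param five_base,three_base the favored base of each flank.
#' @param p_max probability of the favored base immediately next to the
#'   site (default 0.85).
#' @param tau exponential decay length, in bases, of the preference
#'   (default 4).
#' @param flank flank length F (default 50).
#' @return list of class `context_profile` with `sub_probs`,
#'   `five_probs` (F x 4, rows ordered -F..-1) and `three_probs`
#'   (F x 4, rows ordered +1..+F).
#' @export
context_profile <- function(class_id, sub_type, five_base,
                            three_base = five_base, p_max = 0.85,
                            tau = 4, flank = 50) {
  stopifnot(p_max > 0.25, p_max < 1, tau > 0, flank >= 0)
  bases <- c("A", "C", "G", "T")
  if (length(sub_type) == 1L && is.character(sub_type)) {
    stopifnot(sub_type %in% CANONICAL_SUBSTITUTIONS)
    sub_probs <- stats::setNames(as.numeric(
      CANONICAL_SUBSTITUTIONS == sub_type), CANONICAL_SUBSTITUTIONS)
  } else {
    stopifnot(all(names(sub_type) %in% CANONICAL_SUBSTITUTIONS),
              abs(sum(sub_type) - 1) < 1e-9)
    sub_probs <- stats::setNames(rep(0, 6), CANONICAL_SUBSTITUTIONS)
    sub_probs[names(sub_type)] <- sub_type
  }
  pref_curve <- function(dist) 0.25 + (p_max - 0.25) * exp(-(dist - 1) / tau)
  build <- function(pref, dists) {
    probs <- matrix(0, length(dists), 4, dimnames = list(NULL, bases))
    for (i in seq_along(dists)) {
      p <- pref_curve(dists[i])
      probs[i, ] <- (1 - p) / 3
      probs[i, pref] <- p
    }
    probs
  }
  structure(list(class_id = class_id, sub_probs = sub_probs,
                 five_probs = build(five_base,
                                    if (flank) rev(seq_len(flank)) else integer(0)),
                 three_probs = build(three_base,
                                     if (flank) seq_len(flank) else integer(0)),
                 flank = as.integer(flank)),
            class = "context_profile")
}

#' A default family of well-separated context profiles
#'
#' Produces `k` (up to 16) mutually distinct profiles.  The favored 5'
#' base cycles fast and the favored 3' base cycles slowly over A/T/C/G,
#' so every pair of profiles differs in at least one flank preference
#' (not merely in the substituted base); the substitution type cycles
#' through the six canonical classes on top.
#'
#' @param k number of classes (<= 16).
#' @param flank flank length F.
#' @param p_max,tau passed to [context_profile()].
#' @return list of `k` context profiles.
#' @export
default_profiles <- function(k, flank = 50, p_max = 0.85, tau = 4) {
  stopifnot(k <= 16)
  bases <- c("A", "T", "C", "G")
  lapply(seq_len(k), function(i)
    context_profile(
      class_id = i,
      sub_type = CANONICAL_SUBSTITUTIONS[(i - 1L) %% 6L + 1L],
      five_base = bases[(i - 1L) %% 4L + 1L],
      three_base = bases[((i - 1L) %/% 4L) %% 4L + 1L],
      p_max = p_max, tau = tau, flank = flank))
}

# Minimum pairwise separation between profiles: the larger of the
# total-variation distances of the substitution distributions and of
# the base distributions at the nearest flank position.
profile_separation <- function(profiles) {
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  pair_sep <- function(a, b) {
    near <- if (a$flank > 0)
      max(tv(a$five_probs[a$flank, ], b$five_probs[b$flank, ]),
          tv(a$three_probs[1, ], b$three_probs[1, ]))
    else 0
    max(tv(a$sub_probs, b$sub_probs), near)
  }
  k <- length(profiles)
  if (k < 2) return(Inf)
  min(unlist(lapply(seq_len(k - 1), function(i)
    vapply((i + 1):k, function(j) pair_sep(profiles[[i]], profiles[[j]]),
           numeric(1)))))
}

#' Generate a random reference genome
#'
#' I.i.d. bases with the requested GC content, written as an uppercase
#' single-record FASTA.
#'
#' @param length genome length in bases.
#' @param gc GC content in (0, 1) exclusive (default 0.41, human-like).
#' @param seed integer seed.
#' @param path output FASTA path.
#' @param name chromosome name (default "chr1").
#' @param flank flank length the genome must accommodate; lengths below
#'   2*flank + 1 are rejected.
#' @return a [genome_source()] for the written file.
#' @export
generate_reference <- function(length, gc = 0.41, seed = 1L,
                               path = tempfile(fileext = ".fa"),
                               name = "chr1", flank = 50) {
  if (gc <= 0 || gc >= 1)
    stop("gc must be strictly between 0 and 1", call. = FALSE)
  if (length < 2 * flank + 1)
    stop("genome length ", length, " is below 2*flank+1 = ",
         2 * flank + 1, call. = FALSE)
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- name
  Biostrings::writeXStringSet(seq, path, width = 80L)
  genome_source(path)
}

#' Specification of a synthetic cohort
#'
#' @param n_patients number of patients.
#' @param sbs_per_patient mean SBS count per patient.
#' @param count_model `"poisson"` (default; counts Poisson-distributed,
#'   floored at 1) or `"fixed"` (every patient gets exactly
#'   `sbs_per_patient` SBSs, giving cohorts of exact total size).
#' @param archetype_mixtures list of per-archetype mixture vectors over
#'   the SBS classes (each summing to 1); every patient belongs to one
#'   archetype and draws each SBS's hidden class from its mixture.
#' @param archetype_probs archetype frequencies (default uniform).
#' @param hazards per-archetype exponential death hazard, in events per
#'   day (> 0).
#' @param censor_horizon independent uniform censoring horizon, days.
#' @param flank flank length F.
#' @param n_genes size of the gene-symbol pool SBSs are assigned to.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients, sbs_per_patient, archetype_mixtures,
                           archetype_probs = NULL, hazards,
                           censor_horizon = 2000, flank = 50,
                           n_genes = 20L, count_model = c("poisson", "fixed"),
                           seed = 1L) {
  count_model <- match.arg(count_model)
  k_arch <- length(archetype_mixtures)
  stopifnot(k_arch >= 1, length(hazards) == k_arch, all(hazards > 0),
            censor_horizon > 0)
  for (mix in archetype_mixtures)
    if (abs(sum(mix) - 1) > 1e-9)
      stop("archetype mixtures must sum to 1", call. = FALSE)
  archetype_probs <- archetype_probs %||% rep(1 / k_arch, k_arch)
  structure(list(n_patients = as.integer(n_patients),
                 sbs_per_patient = sbs_per_patient,
                 archetype_mixtures = archetype_mixtures,
                 archetype_probs = archetype_probs,
                 hazards = hazards, censor_horizon = censor_horizon,
                 flank = as.integer(flank), n_genes = as.integer(n_genes),
                 count_model = count_model, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort with planted context classes
#'
#' Each SBS receives a hidden class drawn from its patient's archetype
#' mixture; its site is placed on a non-overlapping window of the
#' genome, and the flanks around the site are overwritten in a scratch
#' copy of the genome to follow the class's context profile — so
#' [extract_flanks()] on the written files reproduces the planted
#' context exactly.  Survival times are exponential with the
#' archetype's hazard under independent uniform censoring.  The hidden
#' truth is written separately and never enters the MAF or clinical
#' files.
#'
#' @param spec a [synthetic_spec()].
#' @param profiles list of [context_profile()]s, one per SBS class.
#' @param genome a [genome_source()] (e.g. from [generate_reference()]);
#'   a modified copy is written, the input file is untouched.
#' @param dir output directory (created if needed).
#' @param min_separation reject profile families whose minimum pairwise
#'   separation (total-variation distance of substitution or near-flank
#'   base distributions) is below this floor (default 0.1).
#' @return list with paths (`genome`, `maf`, `clinical`, `truth_sbs`,
#'   `truth_patients`) and the corresponding data frames, invisibly
#'   usable in memory.
#' @export
generate_cohort <- function(spec, profiles, genome, dir,
                            min_separation = 0.1) {
  k <- length(profiles)
  for (mix in spec$archetype_mixtures)
    stopifnot(length(mix) == k)
  sep <- profile_separation(profiles)
  if (sep < min_separation)
    stop("profiles are not separated enough (", signif(sep, 3), " < ",
         min_separation, ")", call. = FALSE)
  F <- spec$flank
  stopifnot(all(vapply(profiles, function(p) p$flank, integer(1)) == F))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  chrom_name <- names(genome$seqs)[1]
  genome_chars <- strsplit(toupper(as.character(genome$seqs[[1]])), "")[[1]]
  glen <- length(genome_chars)

  patients <- sprintf("P%04d", seq_len(spec$n_patients))
  archetype <- sample.int(length(spec$archetype_mixtures),
                          spec$n_patients, replace = TRUE,
                          prob = spec$archetype_probs)
  counts <- if (identical(spec$count_model, "fixed"))
    rep(as.integer(round(spec$sbs_per_patient)), spec$n_patients)
  else pmax(1L, stats::rpois(spec$n_patients, spec$sbs_per_patient))
  n_sbs <- sum(counts)

  window <- 2L * F + 2L
  needed <- F + 1L + (n_sbs - 1L) * window + F
  if (needed > glen)
    stop("genome too short: need ", needed, " bases for ", n_sbs,
         " non-overlapping SBS windows, have ", glen, call. = FALSE)
  sites <- F + 1L + (seq_len(n_sbs) - 1L) * window
  sites <- sites[sample.int(n_sbs)]

  barcode <- rep(patients, counts)
  patient_arch <- rep(archetype, counts)
  class <- vapply(patient_arch, function(a)
    sample.int(k, 1L, prob = spec$archetype_mixtures[[a]]), integer(1))
  genes <- sprintf("GENE%02d", sample.int(spec$n_genes, n_sbs,
                                          replace = TRUE))

  bases <- c("A", "C", "G", "T")
  ref <- character(n_sbs)
  alt <- character(n_sbs)
  for (i in seq_len(n_sbs)) {
    prof <- profiles[[class[i]]]
    st <- sample(CANONICAL_SUBSTITUTIONS, 1L, prob = prof$sub_probs)
    ref[i] <- substr(st, 1L, 1L)
    alt[i] <- substr(st, 3L, 3L)
    s <- sites[i]
    if (F > 0) {
      for (j in seq_len(F)) {
        genome_chars[s - F + j - 1L] <-
          sample(bases, 1L, prob = prof$five_probs[j, ])
        genome_chars[s + j] <- sample(bases, 1L, prob = prof$three_probs[j, ])
      }
    }
    genome_chars[s] <- ref[i]
  }

  genome_path <- file.path(dir, "genome.fa")
  seq <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(seq) <- chrom_name
  Biostrings::writeXStringSet(seq, genome_path, width = 80L)

  maf <- data.frame(
    Hugo_Symbol = genes,
    Chromosome = chrom_name,
    Start_Position = sites,
    Reference_Allele = ref,
    Tumor_Seq_Allele2 = alt,
    Tumor_Sample_Barcode = barcode,
    Variant_Type = "SNP",
    stringsAsFactors = FALSE)
  maf_path <- file.path(dir, "cohort.maf")
  utils::write.table(maf, maf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  death_time <- stats::rexp(spec$n_patients, rate = spec$hazards[archetype])
  censor_time <- stats::runif(spec$n_patients, 0, spec$censor_horizon)
  clinical <- data.frame(
    sample_barcode = patients,
    age = round(stats::rnorm(spec$n_patients, 65, 10)),
    sex = sample(c("male", "female"), spec$n_patients, replace = TRUE),
    weight = round(stats::rnorm(spec$n_patients, 75, 12), 1),
    t_stage = sample(paste0("T", 1:4), spec$n_patients, replace = TRUE),
    n_stage = sample(paste0("N", 0:3), spec$n_patients, replace = TRUE),
    m_stage = sample(paste0("M", 0:1), spec$n_patients, replace = TRUE),
    ajcc_stage = sample(c("I", "II", "III", "IV"), spec$n_patients,
                        replace = TRUE),
    survival_time = round(pmin(death_time, censor_time), 2),
    event = as.integer(death_time <= censor_time),
    stringsAsFactors = FALSE)
  clinical_path <- file.path(dir, "clinical.csv")
  utils::write.csv(clinical, clinical_path, row.names = FALSE,
                   quote = FALSE)

  truth_sbs <- data.frame(
    sample_barcode = barcode, chromosome = chrom_name,
    position = sites, class = class, stringsAsFactors = FALSE)
  truth_sbs_path <- file.path(dir, "truth_sbs.tsv")
  utils::write.table(truth_sbs, truth_sbs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_patients <- data.frame(
    sample_barcode = patients, archetype = archetype,
    stringsAsFactors = FALSE)
  truth_patients_path <- file.path(dir, "truth_patients.tsv")
  utils::write.table(truth_patients, truth_patients_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(n_patients = spec$n_patients,
                        sbs_per_patient = spec$sbs_per_patient,
                        hazards = spec$hazards,
                        censor_horizon = spec$censor_horizon,
                        flank = spec$flank, seed = spec$seed,
                        n_sbs = n_sbs, n_classes = k),
                   file.path(dir, "spec.yaml"))

  list(genome = genome_path, maf = maf_path, clinical = clinical_path,
       truth_sbs = truth_sbs_path, truth_patients = truth_patients_path,
       maf_df = maf, clinical_df = clinical, truth_sbs_df = truth_sbs,
       truth_patients_df = truth_patients)
}

#' Write the canned fixture bundles
#'
#' Emits four small datasets under `outdir`: `micro/` (the five-base
#' CATTG > CACTG worked example as a one-row MAF plus reference),
#' `two_class/` (a two-class planted-context recovery set, n = 2000,
#' flank 10), `ten_class/` (a ten-class set at reduced size for the
#' full splitting schedule) and `survival/` (a two-archetype cohort
#' with a planted hazard ratio of 3).  MD5 checksums of every written
#' file go to `checksums.txt`.
#'
#' @param outdir output directory.
#' @param seed integer master seed.
#' @return named list of per-bundle path lists, invisibly.
#' @export
write_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # (i) micro worked example: CATTG with the middle T substituted to C
  micro_dir <- file.path(outdir, "micro")
  dir.create(micro_dir, showWarnings = FALSE)
  ref <- Biostrings::DNAStringSet("CATTG")
  names(ref) <- "chr1"
  micro_fa <- file.path(micro_dir, "reference.fa")
  Biostrings::writeXStringSet(ref, micro_fa)
  micro_maf <- file.path(micro_dir, "micro.maf")
  utils::write.table(
    data.frame(Hugo_Symbol = "GENE01", Chromosome = "chr1",
               Start_Position = 3L, Reference_Allele = "T",
               Tumor_Seq_Allele2 = "C",
               Tumor_Sample_Barcode = "SAMPLE-0001",
               stringsAsFactors = FALSE),
    micro_maf, sep = "\t", quote = FALSE, row.names = FALSE)

  two_profiles <- list(
    context_profile(1, "C>T", five_base = "T", p_max = 0.9, tau = 6,
                    flank = 10),
    context_profile(2, "C>A", five_base = "A", p_max = 0.9, tau = 6,
                    flank = 10))
  two_spec <- synthetic_spec(
    n_patients = 40, sbs_per_patient = 50,
    archetype_mixtures = list(c(1, 0), c(0, 1)),
    archetype_probs = c(0.5, 0.5),
    hazards = c(0.001, 0.001), flank = 10, count_model = "fixed",
    seed = derive_seed(seed, "two_class"))
  two_genome <- generate_reference(60000, seed = derive_seed(seed, "ref2"),
                                   flank = 10)
  two <- generate_cohort(two_spec, two_profiles, two_genome,
                         file.path(outdir, "two_class"))

  ten_profiles <- default_profiles(10, flank = 10, p_max = 0.9, tau = 6)
  ten_mix <- lapply(seq_len(10), function(i) as.numeric(seq_len(10) == i))
  ten_spec <- synthetic_spec(
    n_patients = 30, sbs_per_patient = 50,
    archetype_mixtures = ten_mix,
    hazards = rep(0.001, 10), flank = 10, count_model = "fixed",
    seed = derive_seed(seed, "ten_class"))
  ten_genome <- generate_reference(45000, seed = derive_seed(seed, "ref10"),
                                   flank = 10)
  ten <- generate_cohort(ten_spec, ten_profiles, ten_genome,
                         file.path(outdir, "ten_class"))

  surv_profiles <- list(
    context_profile(1, "C>T", five_base = "T", p_max = 0.9, tau = 6,
                    flank = 10),
    context_profile(2, "T>C", five_base = "G", p_max = 0.9, tau = 6,
                    flank = 10))
  surv_spec <- synthetic_spec(
    n_patients = 200, sbs_per_patient = 5,
    archetype_mixtures = list(c(1, 0), c(0, 1)),
    hazards = c(0.001, 0.003), censor_horizon = 2000, flank = 10,
    count_model = "fixed",
    seed = derive_seed(seed, "survival"))
  surv_genome <- generate_reference(30000, seed = derive_seed(seed, "refs"),
                                    flank = 10)
  surv <- generate_cohort(surv_spec, surv_profiles, surv_genome,
                          file.path(outdir, "survival"))

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "checksums.txt"))
  sums <- tools::md5sum(files)
  writeLines(paste(unname(sums), sub(paste0("^", outdir, "/?"), "",
                                     names(sums))),
             file.path(outdir, "checksums.txt"))

  invisible(list(micro = list(genome = micro_fa, maf = micro_maf),
                 two_class = two, ten_class = ten, survival = surv))
}
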