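# Per-patient MB composition, patient K-means classes with elbow
# selection, flank-composition spectra, group-comparison statistics and
# log-rank survival tests.

#' Per-patient MB composition
#'
#' Each MB class is expressed as its proportion of all labeled SBSs in
#' one patient.  Sample barcodes are collapsed to patient level with
#' [barcode_to_patient()]; patients with zero SBSs simply have no row.
#'
#' @param labels factor/character of MB labels, one per SBS.
#' @param barcodes sample barcodes aligned with `labels`.
#' @return list of class `mb_composition` with `proportions` (patients
#'   x classes matrix, rows summing to 1) and `n_sbs` (per-patient SBS
#'   count).
#' @export
mb_composition <- function(labels, barcodes) {
  stopifnot(length(labels) == length(barcodes), length(labels) > 0)
  patient <- barcode_to_patient(as.character(barcodes))
  tab <- table(patient, factor(labels))
  counts <- unclass(tab)
  n_sbs <- rowSums(counts)
  structure(list(proportions = counts / n_sbs, n_sbs = n_sbs),
            class = "mb_composition")
}

#' Substitution-type and flank-composition spectrum per MB
#'
#' Sequences are first collapsed to their pyrimidine representation,
#' then summarized per MB class: the fraction of each of the six
#' canonical substitution types, and at every flank position (-F..-1,
#' +1..+F relative to the site) the fraction of A/C/G/T/N.
#'
#' @param labels factor/character of MB labels, one per sequence.
#' @param sequences data frame with columns `five_prime_flank`,
#'   `ref_allele`, `alt_allele`, `three_prime_flank`.
#' @return list of class `mb_spectrum` with `type_fractions` (classes x
#'   6 matrix) and `base_fractions` (named list: per class a positions x
#'   5 matrix with rownames like "-2", "-1", "+1", "+2").
#' @export
spectrum_summary <- function(labels, sequences) {
  stopifnot(length(labels) == nrow(sequences))
  collapsed <- lapply(seq_len(nrow(sequences)), function(i)
    pyrimidine_collapse(list(
      five_prime_flank = sequences$five_prime_flank[i],
      ref_allele = sequences$ref_allele[i],
      alt_allele = sequences$alt_allele[i],
      three_prime_flank = sequences$three_prime_flank[i])))
  sub_types <- vapply(collapsed, function(x) x$sub_type, character(1))
  flank <- nchar(collapsed[[1]]$five_prime_flank)
  labels <- factor(labels)
  bases <- c("A", "C", "G", "T", "N")
  pos_names <- c(paste0("-", rev(seq_len(flank))),
                 paste0("+", seq_len(flank)))
  type_fractions <- matrix(0, nlevels(labels),
                           length(CANONICAL_SUBSTITUTIONS),
                           dimnames = list(levels(labels),
                                           CANONICAL_SUBSTITUTIONS))
  base_fractions <- stats::setNames(vector("list", nlevels(labels)),
                                    levels(labels))
  for (lv in levels(labels)) {
    sel <- which(labels == lv)
    tf <- table(factor(sub_types[sel], levels = CANONICAL_SUBSTITUTIONS))
    type_fractions[lv, ] <- as.numeric(tf) / length(sel)
    if (flank > 0) {
      charmat <- t(vapply(collapsed[sel], function(x)
        strsplit(paste0(x$five_prime_flank, x$three_prime_flank),
                 "")[[1]],
        character(2 * flank)))
      bf <- t(apply(charmat, 2, function(col)
        table(factor(col, levels = bases)) / length(col)))
      rownames(bf) <- pos_names
      base_fractions[[lv]] <- bf
    } else {
      base_fractions[[lv]] <- matrix(numeric(0), 0, length(bases),
                                     dimnames = list(NULL, bases))
    }
  }
  structure(list(type_fractions = type_fractions,
                 base_fractions = base_fractions),
            class = "mb_spectrum")
}

#' Pick the elbow of a dispersion curve
#'
#' The knee is operationalized as the k with the maximum second
#' difference of the within-cluster sum-of-squares curve (only interior
#' points of `k_range` are eligible).
#'
#' @param wss within-cluster sum of squares, one value per k.
#' @param k_range the k values the curve was computed over.
#' @return the selected k.
#' @export
choose_k_elbow <- function(wss, k_range) {
  stopifnot(length(wss) == length(k_range), length(wss) >= 3)
  d2 <- wss[-c(length(wss) - 1, length(wss))] -
    2 * wss[-c(1, length(wss))] + wss[-c(1, 2)]
  k_range[1 + which.max(d2)]
}

#' Cluster patients by MB composition
#'
#' Seeded Lloyd K-means (multiple restarts) on the per-patient MB
#' proportion rows.  With `K = "auto"` the within-cluster sum of
#' squares is computed over `k_range` and the elbow is selected via
#' [choose_k_elbow()]; the default is the fixed K = 7.
#'
#' @param comp an [mb_composition()].
#' @param K number of classes, or `"auto"`.
#' @param k_range candidate k values for the elbow scan.
#' @param nstart K-means restarts (default 10).
#' @param seed integer seed.
#' @return list of class `patient_classing` with `classes` (factor
#'   "Class 1"... named by patient, classes ordered by decreasing
#'   size), `K`, `wss` and `k_range` (the latter two NULL unless the
#'   elbow scan ran).
#' @export
cluster_patients <- function(comp, K = 7, k_range = 2:10, nstart = 10L,
                             seed = 1L) {
  x <- comp$proportions
  wss <- NULL
  if (identical(K, "auto")) {
    set.seed(derive_seed(seed, "elbow"))
    wss <- vapply(k_range, function(k)
      stats::kmeans(x, centers = k, nstart = nstart,
                    iter.max = 100L)$tot.withinss, numeric(1))
    K <- choose_k_elbow(wss, k_range)
  }
  K <- as.integer(K)
  if (K > nrow(x))
    stop("K = ", K, " exceeds the number of patients (", nrow(x), ")",
         call. = FALSE)
  set.seed(derive_seed(seed, "kmeans"))
  km <- stats::kmeans(x, centers = K, nstart = nstart, iter.max = 100L)
  # relabel classes by decreasing size for a deterministic presentation
  size_order <- order(-km$size, seq_len(K))
  remap <- integer(K)
  remap[size_order] <- seq_len(K)
  lvls <- paste("Class", seq_len(K))
  classes <- factor(lvls[remap[km$cluster]], levels = lvls)
  names(classes) <- rownames(x)
  structure(list(classes = classes, K = K, wss = wss,
                 k_range = if (is.null(wss)) NULL else k_range),
            class = "patient_classing")
}

#' Compare a clinical variable between groups
#'
#' Dispatches on the outcome type and group count: numeric outcome with
#' two groups gets an independent-samples t test (pooled variance),
#' numeric with more than two groups a one-way ANOVA F test, and a
#' categorical outcome a chi-square test on the contingency table.
#' Rows missing the outcome or the group are removed first and counted.
#'
#' @param values the outcome: numeric, or character/factor for
#'   categorical data.
#' @param grouping group membership, coerced to factor.
#' @return list of class `mb_test_result`: `statistic`, `p_value`,
#'   `test_name`, `group_sizes`, `dropped`.
#' @export
group_compare <- function(values, grouping) {
  stopifnot(length(values) == length(grouping))
  grouping <- factor(grouping)
  keep <- !is.na(values) & !is.na(grouping)
  dropped <- sum(!keep)
  lost <- setdiff(levels(grouping),
                  unique(as.character(grouping[keep])))
  if (length(lost))
    stop("group(s) emptied by missing-data removal: ",
         paste(lost, collapse = ", "), call. = FALSE)
  values <- values[keep]
  grouping <- droplevels(grouping[keep])
  if (nlevels(grouping) < 2)
    stop("need at least 2 non-empty groups, got ", nlevels(grouping),
         call. = FALSE)
  if (is.numeric(values)) {
    if (nlevels(grouping) == 2) {
      tt <- stats::t.test(values ~ grouping, var.equal = TRUE)
      res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                  test_name = "t")
    } else {
      ow <- stats::oneway.test(values ~ grouping, var.equal = TRUE)
      res <- list(statistic = unname(ow$statistic), p_value = ow$p.value,
                  test_name = "anova")
    }
  } else {
    ct <- suppressWarnings(stats::chisq.test(table(values, grouping)))
    res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                test_name = "chi-square")
  }
  res$group_sizes <- as.integer(table(grouping))
  names(res$group_sizes) <- levels(grouping)
  res$dropped <- dropped
  structure(res, class = "mb_test_result")
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square over the pooled event times, via
#' `survival::survdiff`.  Rows with missing time, event or group are
#' removed and counted; a group consisting only of censored times still
#' contributes valid risk sets.
#'
#' @param time survival / follow-up times (days), >= 0.
#' @param event 1 = death, 0 = censored.
#' @param group group membership, coerced to factor.
#' @return list of class `mb_test_result` with `statistic` (chi-square),
#'   `p_value`, `df`, `test_name`, `group_sizes`, `dropped`.
#' @export
logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  dropped <- sum(!keep)
  time <- time[keep]; event <- event[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2)
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (sum(event) == 0)
    stop("no events in any group; log-rank test undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 df = df, test_name = "log-rank",
                 group_sizes = as.integer(sd$n),
                 dropped = dropped),
            class = "mb_test_result")
}

#' Group patients by the MB class of their mutations in one gene
#'
#' For survival analysis of a single gene: every patient carrying an
#' SBS in `gene` is grouped by that SBS's MB class.  A patient whose
#' mutations in the gene span several MB classes enters every one of
#' those groups (`mode = "any"`, the default), is assigned to its most
#' frequent class with ties to the lowest MB number
#' (`mode = "exclusive"`), or is excluded (`mode = "drop"`).
#'
#' @param labeled_records SBS record data frame carrying `gene_symbol`,
#'   `sample_barcode` and an `mb_label` column.
#' @param clinical clinical table as from [read_clinical()].
#' @param gene gene symbol to analyze.
#' @param mode multi-class patient handling; see above.
#' @return data frame with `patient`, `group` (MB label),
#'   `survival_time`, `event` — ready for [logrank()].
#' @export
mb_gene_groups <- function(labeled_records, clinical, gene,
                           mode = c("any", "exclusive", "drop")) {
  mode <- match.arg(mode)
  sel <- labeled_records[labeled_records$gene_symbol == gene, , drop = FALSE]
  if (!nrow(sel)) stop("no labeled SBS in gene ", gene, call. = FALSE)
  patient <- barcode_to_patient(sel$sample_barcode)
  mb <- as.character(sel$mb_label)
  per_patient <- split(mb, patient)
  pick <- switch(mode,
    any = lapply(per_patient, unique),
    exclusive = lapply(per_patient, function(m) {
      tab <- sort(table(m), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      # ties resolved to the lowest MB number
      top[order(as.integer(sub("^MB ", "", top)))][1]
    }),
    drop = lapply(per_patient, function(m) {
      u <- unique(m)
      if (length(u) == 1L) u else character(0)
    }))
  out <- data.frame(
    patient = rep(names(pick), lengths(pick)),
    group = unlist(pick, use.names = FALSE),
    stringsAsFactors = FALSE)
  clin_patient <- barcode_to_patient(clinical$sample_barcode)
  m <- match(out$patient, clin_patient)
  out$survival_time <- clinical$survival_time[m]
  out$event <- clinical$event[m]
  out
}

#' Kaplan-Meier survival curves as a step-function table
#'
#' @param time,event,group as in [logrank()].
#' @return data frame with columns `group`, `time`, `n_risk`,
#'   `n_event`, `surv` suitable for plotting or CSV export.
#' @export
survival_curves <- function(time, event, group) {
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  data.frame(group = sub("^group=", "", strata),
             time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}
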