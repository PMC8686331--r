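# Readers for MAF and clinical tables, and flank extraction from a
# reference genome.

.MAF_DEFAULT_COLUMNS <- c(
  sample_barcode = "Tumor_Sample_Barcode",
  chromosome     = "Chromosome",
  position       = "Start_Position",
  ref_allele     = "Reference_Allele",
  alt_allele     = "Tumor_Seq_Allele2",
  gene_symbol    = "Hugo_Symbol"
)

#' Read somatic single-base substitutions from a MAF file
#'
#' Reads a tab-separated MAF (TCGA dialect, header row, `#` comment lines
#' allowed) and keeps only true single-base substitutions: rows whose
#' reference and tumor alleles are single, distinct A/C/G/T bases.
#' Indels, multi-base variants and ref==alt rows are dropped and the
#' dropped count is reported via `message()`.
#'
#' @param path path to a MAF file.
#' @param columns optional named character vector remapping any of
#'   `sample_barcode`, `chromosome`, `position`, `ref_allele`,
#'   `alt_allele`, `gene_symbol`, `cancer_type` to column names in the
#'   file.  Defaults follow the TCGA MAF layout.
#' @return data frame with columns `sample_barcode`, `chromosome`,
#'   `position` (integer, 1-based), `ref_allele`, `alt_allele`,
#'   `gene_symbol`, `cancer_type` (empty string when absent).
#' @export
read_maf <- function(path, columns = NULL) {
  cols <- .MAF_DEFAULT_COLUMNS
  if (!is.null(columns)) cols[names(columns)] <- columns
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", colClasses = "character",
                           check.names = FALSE, quote = "")
  required <- cols[c("sample_barcode", "chromosome", "position",
                     "ref_allele", "alt_allele")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols))
    stop("MAF file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pos <- suppressWarnings(as.integer(raw[[cols[["position"]]]]))
  bad_pos <- which(is.na(pos) | pos < 1L)
  if (length(bad_pos))
    stop("unparseable or non-positive position at MAF data line(s): ",
         paste(utils::head(bad_pos, 10), collapse = ", "), call. = FALSE)
  gene <- if (cols[["gene_symbol"]] %in% names(raw))
    raw[[cols[["gene_symbol"]]]] else ""
  ctype_col <- if ("cancer_type" %in% names(cols)) cols[["cancer_type"]] else "Project_ID"
  ctype <- if (ctype_col %in% names(raw)) raw[[ctype_col]] else ""
  out <- data.frame(
    sample_barcode = raw[[cols[["sample_barcode"]]]],
    chromosome     = raw[[cols[["chromosome"]]]],
    position       = pos,
    ref_allele     = toupper(raw[[cols[["ref_allele"]]]]),
    alt_allele     = toupper(raw[[cols[["alt_allele"]]]]),
    gene_symbol    = gene,
    cancer_type    = ctype,
    stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  keep <- out$ref_allele %in% bases & out$alt_allele %in% bases &
    out$ref_allele != out$alt_allele
  dropped <- sum(!keep)
  if (dropped > 0)
    message("read_maf: dropped ", dropped,
            " non-SBS row(s) (indels, multi-base or ref==alt)")
  out[keep, , drop = FALSE]
}

#' Read a clinical table
#'
#' Reads a CSV or TSV clinical table keyed by sample barcode.  Fields
#' absent from the file are set to `NA`; rows with missing values are
#' kept — each downstream analysis removes the rows missing the items it
#' needs.
#'
#' @param path path to a delimited file with a header.  Tab or comma
#'   separation is detected from the header line.
#' @return data frame with columns `sample_barcode`, `age`, `sex`,
#'   `weight`, `t_stage`, `n_stage`, `m_stage`, `ajcc_stage`,
#'   `survival_time`, `event`.
#' @export
read_clinical <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(raw) <- tolower(names(raw))
  bc_col <- intersect(c("sample_barcode", "barcode", "bcr_patient_barcode"),
                      names(raw))
  if (!length(bc_col))
    stop("clinical table ", path, " has no barcode column", call. = FALSE)
  barcodes <- as.character(raw[[bc_col[1]]])
  dup <- unique(barcodes[duplicated(barcodes)])
  if (length(dup))
    stop("duplicate barcode(s) in clinical table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  grab <- function(col, as = as.character) {
    if (col %in% names(raw)) as(raw[[col]]) else rep(as(NA), length(barcodes))
  }
  out <- data.frame(
    sample_barcode = barcodes,
    age            = grab("age", as.numeric),
    sex            = tolower(grab("sex")),
    weight         = grab("weight", as.numeric),
    t_stage        = grab("t_stage"),
    n_stage        = grab("n_stage"),
    m_stage        = grab("m_stage"),
    ajcc_stage     = grab("ajcc_stage"),
    survival_time  = grab("survival_time", as.numeric),
    event          = grab("event", as.integer),
    stringsAsFactors = FALSE)
  bad_t <- which(!is.na(out$survival_time) & out$survival_time < 0)
  if (length(bad_t))
    stop("negative survival_time for barcode(s): ",
         paste(out$sample_barcode[bad_t], collapse = ", "), call. = FALSE)
  bad_e <- which(!is.na(out$event) & !out$event %in% c(0L, 1L))
  if (length(bad_e))
    stop("event must be 0 or 1; offending barcode(s): ",
         paste(out$sample_barcode[bad_e], collapse = ", "), call. = FALSE)
  out
}

#' Open a reference genome from a FASTA file
#'
#' Loads the sequences into memory (the intended genomes here are small)
#' and builds a chromosome-name map that tolerates the presence or
#' absence of a `chr` prefix.
#'
#' @param path FASTA file.
#' @return object of class `genome_source`.
#' @export
genome_source <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  name_map <- stats::setNames(names(seqs), names(seqs))
  bare <- sub("^chr", "", names(seqs))
  name_map[bare] <- names(seqs)
  name_map[paste0("chr", bare)] <- names(seqs)
  structure(list(seqs = seqs, name_map = name_map, path = path),
            class = "genome_source")
}

# Resolve a user-facing chromosome name to the FASTA record name.
resolve_chrom <- function(genome, chrom) {
  hit <- genome$name_map[chrom]
  if (is.na(hit))
    stop("chromosome '", chrom, "' not found in genome ", genome$path,
         call. = FALSE)
  unname(hit)
}

#' Fetch a genome subsequence with N padding outside chromosome bounds
#'
#' @param genome a [genome_source()].
#' @param chrom chromosome name (with or without `chr` prefix).
#' @param start,end 1-based inclusive coordinates; may extend beyond the
#'   chromosome, in which case the out-of-bounds part is filled with `N`.
#' @return uppercase character string of length `end - start + 1`.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  stopifnot(end >= start - 1)
  key <- resolve_chrom(genome, chrom)
  len <- Biostrings::width(genome$seqs[key])
  lo <- max(start, 1L)
  hi <- min(end, len)
  core <- if (hi >= lo)
    toupper(as.character(Biostrings::subseq(genome$seqs[[key]], lo, hi)))
  else ""
  paste0(strrep("N", max(0L, lo - start)), core, strrep("N", max(0L, end - hi)))
}

#' Extract flanking sequences for SBS records
#'
#' For each record the 5' flank is the reference sequence at positions
#' \[position - F, position - 1\] and the 3' flank at
#' \[position + 1, position + F\] (1-based inclusive, plus strand);
#' positions beyond the chromosome ends are padded with N so flanks
#' always have exactly F bases.  The genome base at the mutated position
#' is checked against the record's reference allele.
#'
#' @param records data frame of SBS records as returned by [read_maf()]
#'   (a single record as a one-row data frame works too).
#' @param genome a [genome_source()].
#' @param flank number of flanking bases on each side (default 50, for a
#'   total represented length of 2*flank + 1 = 101).
#' @param on_mismatch what to do when the genome base differs from the
#'   reference allele: `"error"` (default), `"drop"` the record with a
#'   message, or `"keep"` it flagged.
#' @return `records` with added columns `five_prime_flank`,
#'   `three_prime_flank` and logical `ref_mismatch`.
#' @export
extract_flanks <- function(records, genome, flank = 50,
                           on_mismatch = c("error", "drop", "keep")) {
  on_mismatch <- match.arg(on_mismatch)
  stopifnot(flank >= 0, nrow(records) > 0)
  five <- character(nrow(records))
  three <- character(nrow(records))
  at_site <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- records$position[i]
    chrom <- records$chromosome[i]
    five[i] <- genome_subseq(genome, chrom, p - flank, p - 1L)
    at_site[i] <- genome_subseq(genome, chrom, p, p)
    three[i] <- genome_subseq(genome, chrom, p + 1L, p + flank)
  }
  mismatch <- at_site != records$ref_allele
  if (any(mismatch)) {
    where <- paste0(records$chromosome[mismatch], ":",
                    records$position[mismatch], collapse = ", ")
    if (on_mismatch == "error")
      stop("reference allele disagrees with the genome at: ", where,
           call. = FALSE)
    if (on_mismatch == "drop")
      message("extract_flanks: dropping ", sum(mismatch),
              " record(s) with reference mismatch")
  }
  out <- records
  out$five_prime_flank <- five
  out$three_prime_flank <- three
  out$ref_mismatch <- mismatch
  if (on_mismatch == "drop") out <- out[!mismatch, , drop = FALSE]
  out
}

#' Collapse sample barcodes to patient identifiers
#'
#' TCGA-style barcodes (`TCGA-XX-YYYY-...`) are truncated to the
#' patient-level prefix (first 12 characters); any other barcode is
#' returned unchanged.
#'
#' @param barcodes character vector.
#' @return character vector of patient identifiers.
#' @export
barcode_to_patient <- function(barcodes) {
  ifelse(grepl("^TCGA-", barcodes), substr(barcodes, 1L, 12L), barcodes)
}
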