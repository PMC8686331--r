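# Numeric encoding of mutated sequences and the pyrimidine-collapsed
# 6-type substitution representation used in reporting.

# Two-bit base codes.  N (unknown/padded base) gets its own code so that
# chromosome-end padding survives encoding.
.BASE_CODE <- list(
  A = c(0, 0),
  T = c(0, 1),
  C = c(1, 0),
  G = c(1, 1),
  N = c(-1, -1)
)

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C", N = "N")

#' The six canonical substitution types
#'
#' Substitutions represented by the pyrimidine member of the base pair.
#' @export
CANONICAL_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

base_code <- function(b) {
  code <- .BASE_CODE[[b]]
  if (is.null(code)) stop("cannot encode base '", b, "'", call. = FALSE)
  code
}

#' Construct a mutation sequence
#'
#' Bundles a single-base substitution with its 5' and 3' flanking
#' sequences (as read on the reference plus strand).  Flanks may contain
#' N; the substituted alleles may not.
#'
#' @param five_prime_flank,three_prime_flank strings over \{A,C,G,T,N\};
#'   must have equal length.
#' @param ref_allele,alt_allele single distinct bases in \{A,C,G,T\}.
#' @return an object of class `mutation_sequence`.
#' @export
mutation_sequence <- function(five_prime_flank, ref_allele, alt_allele,
                              three_prime_flank) {
  five_prime_flank <- toupper(five_prime_flank)
  three_prime_flank <- toupper(three_prime_flank)
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  if (nchar(five_prime_flank) != nchar(three_prime_flank))
    stop("flanks must have equal length", call. = FALSE)
  if (!ref_allele %in% c("A", "C", "G", "T") ||
      !alt_allele %in% c("A", "C", "G", "T"))
    stop("ref and alt alleles must be single A/C/G/T bases", call. = FALSE)
  if (ref_allele == alt_allele)
    stop("ref and alt alleles must differ", call. = FALSE)
  bad <- setdiff(strsplit(paste0(five_prime_flank, three_prime_flank), "")[[1]],
                 names(.BASE_CODE))
  if (length(bad))
    stop("invalid flank base(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  structure(
    list(five_prime_flank = five_prime_flank,
         ref_allele = ref_allele,
         alt_allele = alt_allele,
         three_prime_flank = three_prime_flank),
    class = "mutation_sequence")
}

#' Encode a mutation sequence as an n x 4 matrix
#'
#' Each flank base b becomes the row \[b | b\] (its two-bit code repeated);
#' the mutation row is \[alt | ref\] — mutant code in columns 1-2,
#' reference code in columns 3-4.  Base codes: A = (0,0), T = (0,1),
#' C = (1,0), G = (1,1), N = (-1,-1).  For flanks of length F the matrix
#' has n = 2F + 1 rows and the mutation row is row F + 1 (`site_row`).
#'
#' The mutant-first column order in the mutation row is deliberate and
#' load-bearing: it is what makes e.g. CATTG > CACTG encode with third
#' row (1, 0, 0, 1), i.e. the C code followed by the T code.
#'
#' @param seq a [mutation_sequence()] (or a list with the same fields).
#' @return an object of class `encoded_mutation`: a list with `matrix`
#'   (n x 4, entries in \{-1, 0, 1\}) and `site_row` (1-based row index of
#'   the mutation row).
#' @export
encode_mutation_sequence <- function(seq) {
  five <- strsplit(toupper(seq$five_prime_flank), "")[[1]]
  three <- strsplit(toupper(seq$three_prime_flank), "")[[1]]
  ref <- toupper(seq$ref_allele)
  alt <- toupper(seq$alt_allele)
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stop("ref/alt must be A/C/G/T, got ", ref, ">", alt, call. = FALSE)
  rows <- vector("list", length(five) + 1L + length(three))
  for (i in seq_along(five)) rows[[i]] <- rep(base_code(five[i]), 2)
  rows[[length(five) + 1L]] <- c(base_code(alt), base_code(ref))
  for (i in seq_along(three))
    rows[[length(five) + 1L + i]] <- rep(base_code(three[i]), 2)
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  structure(list(matrix = m, site_row = length(five) + 1L),
            class = "encoded_mutation")
}

#' Split an encoded mutation into its two directional reads
#'
#' The recurrent extractor reads the matrix from both ends toward the
#' mutation site, so that the mutation row sits at the end of both reads
#' where its influence on the recurrent state is largest.
#'
#' @param enc an `encoded_mutation`.
#' @return list with `five_to_site` (rows 1..site_row in natural order)
#'   and `three_to_site` (rows n..site_row, reversed); both are
#'   (F+1) x 4 matrices sharing the mutation row as their last row.
#' @export
split_bidirectional <- function(enc) {
  m <- enc$matrix
  s <- enc$site_row
  n <- nrow(m)
  list(five_to_site = m[seq_len(s), , drop = FALSE],
       three_to_site = m[seq(n, s), , drop = FALSE])
}

#' Collapse a substitution to its pyrimidine representation
#'
#' The four bases form six substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G) once each substitution is represented by the strand whose
#' reference base is a pyrimidine.  If the reference allele is already C
#' or T the sequence is returned unchanged; otherwise both alleles are
#' complemented and the whole flanked sequence is reverse-complemented,
#' so the original 3' flank (reverse-complemented) becomes the new 5'
#' flank.  complement(N) = N.  The operation is idempotent.
#'
#' @param seq a [mutation_sequence()].
#' @return list with `sub_type` (one of the six canonical types),
#'   `five_prime_flank`, `three_prime_flank`, `ref_allele`, `alt_allele`.
#' @export
pyrimidine_collapse <- function(seq) {
  ref <- toupper(seq$ref_allele)
  alt <- toupper(seq$alt_allele)
  five <- toupper(seq$five_prime_flank)
  three <- toupper(seq$three_prime_flank)
  if (!ref %in% c("C", "T")) {
    new_ref <- .COMPLEMENT[[ref]]
    new_alt <- .COMPLEMENT[[alt]]
    rc <- function(s) {
      if (!nchar(s)) return(s)
      paste(rev(.COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
    }
    new_five <- rc(three)
    new_three <- rc(five)
    ref <- new_ref; alt <- new_alt; five <- new_five; three <- new_three
  }
  structure(
    list(sub_type = paste0(ref, ">", alt),
         five_prime_flank = five,
         ref_allele = ref,
         alt_allele = alt,
         three_prime_flank = three),
    class = c("canonical_substitution"))
}

#' Encode a table of mutation sequences
#'
#' Vectorized convenience wrapper around [encode_mutation_sequence()] for
#' the data frame produced by [extract_flanks()].
#'
#' @param seqs data frame with columns `five_prime_flank`, `ref_allele`,
#'   `alt_allele`, `three_prime_flank`.
#' @return list of `encoded_mutation` objects.
#' @export
encode_sequences <- function(seqs) {
  lapply(seq_len(nrow(seqs)), function(i)
    encode_mutation_sequence(list(
      five_prime_flank = seqs$five_prime_flank[i],
      ref_allele = seqs$ref_allele[i],
      alt_allele = seqs$alt_allele[i],
      three_prime_flank = seqs$three_prime_flank[i])))
}
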