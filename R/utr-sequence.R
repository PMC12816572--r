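#' 5'UTR sequence with a CDS prefix
#'
#' Holds the 5'UTR in transcript (5'->3' mRNA) orientation together with a
#' short prefix of the coding sequence beginning at the main-ORF ATG. The CDS
#' prefix supplies the +4 Kozak base of the main AUG and the downstream
#' sequence needed to locate where an overlapping ORF terminates.
#'
#' Only `A`, `C`, `G`, `T` are accepted; degenerate bases (including `N`) are
#' rejected so that ORF-architecture calls are deterministic.
#'
#' @param seq 5'UTR nucleotide string.
#' @param cds_prefix CDS prefix; must start with `ATG`.
#' @return An object of class `utr_sequence`.
#' @examples
#' utr_sequence("GGGATGCCCTAACCC", "ATGGTTGTTGTT")
#' @export
utr_sequence <- function(seq, cds_prefix) {
  seq <- toupper(as.character(seq))
  cds_prefix <- toupper(as.character(cds_prefix))
  bad <- function(s) grepl("[^ACGT]", s)
  if (bad(seq) || bad(cds_prefix)) {
    stop(
      "sequence contains characters outside {A,C,G,T}; degenerate bases are not supported",
      call. = FALSE
    )
  }
  if (!startsWith(cds_prefix, "ATG")) {
    stop("cds_prefix must begin with ATG (the main-ORF start codon)", call. = FALSE)
  }
  if (nchar(cds_prefix) < 4) {
    stop("cds_prefix must supply at least the +4 Kozak base (>= 4 nt)", call. = FALSE)
  }
  structure(list(seq = seq, cds_prefix = cds_prefix), class = "utr_sequence")
}

#' @export
print.utr_sequence <- function(x, ...) {
  cat(sprintf(
    "<utr_sequence> 5'UTR %d nt + CDS prefix %d nt\n",
    nchar(x$seq), nchar(x$cds_prefix)
  ))
  cat(" UTR: ", abbreviate_seq(x$seq), "\n", sep = "")
  cat(" CDS: ", abbreviate_seq(x$cds_prefix), "\n", sep = "")
  invisible(x)
}

abbreviate_seq <- function(s, n = 60) {
  if (nchar(s) <= n) s else paste0(substr(s, 1, n - 3), "...")
}

#' UTR length in nucleotides
#' @param utr A [utr_sequence()].
#' @return Integer length of the 5'UTR (excluding the CDS prefix).
#' @export
utr_length <- function(utr) {
  stopifnot(inherits(utr, "utr_sequence"))
  nchar(utr$seq)
}

# full scanned sequence: UTR followed by CDS prefix (internal)
full_seq <- function(utr) paste0(utr$seq, utr$cds_prefix)

#' Read a 5'UTR + CDS prefix from FASTA
#'
#' Two layouts are supported: two records (first the UTR, second the CDS
#' prefix), or a single record with `cds_offset` giving the 0-based offset of
#' the main-ORF A within the record.
#'
#' @param path FASTA file.
#' @param cds_offset Optional 0-based offset of the main AUG in a one-record
#'   file.
#' @return A [utr_sequence()].
#' @export
read_utr_fasta <- function(path, cds_offset = NULL) {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) >= 2 && is.null(cds_offset)) {
    utr_sequence(as.character(recs[[1]]), as.character(recs[[2]]))
  } else if (length(recs) >= 1 && !is.null(cds_offset)) {
    s <- as.character(recs[[1]])
    utr_sequence(substr(s, 1, cds_offset), substr(s, cds_offset + 1, nchar(s)))
  } else {
    stop(sprintf(
      "FASTA '%s': expected a UTR record plus a CDS-prefix record, or one record with cds_offset",
      path
    ), call. = FALSE)
  }
}

#' Write a 5'UTR + CDS prefix to FASTA
#'
#' @param utr A [utr_sequence()].
#' @param path Output file.
#' @param names Record names (UTR record, CDS-prefix record).
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utr, path, names = c("5UTR", "CDS_prefix")) {
  stopifnot(inherits(utr, "utr_sequence"))
  x <- Biostrings::DNAStringSet(c(utr$seq, utr$cds_prefix))
  names(x) <- names
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

complement_base <- function(s) {
  chartr("ACGT", "TGCA", s)
}
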