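#' Per-base conservation track for a 5'UTR
#'
#' Bundles up to two per-base conservation channels keyed by 0-based cap
#' offset: a basewise score (e.g. PhyloP, where values above the threshold
#' indicate purifying selection) and an elementwise score (e.g. PhastCons,
#' a conserved-element probability). Channels are independent and either may
#' be absent.
#'
#' @param basewise,elementwise Data frames with columns `cap_offset` and
#'   `score`, or `NULL`.
#' @param basewise_min Threshold a basewise score must exceed (default 2.0).
#' @param elementwise_min Threshold an elementwise score must exceed
#'   (default 0.8).
#' @return An object of class `conservation_track`.
#' @export
conservation_track <- function(basewise = NULL, elementwise = NULL,
                               basewise_min = 2.0, elementwise_min = 0.8) {
  check_channel <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- tibble::as_tibble(x)
    if (!all(c("cap_offset", "score") %in% names(x))) {
      stop(sprintf("%s channel needs columns cap_offset and score", nm), call. = FALSE)
    }
    x[c("cap_offset", "score")]
  }
  structure(
    list(
      basewise = check_channel(basewise, "basewise"),
      elementwise = check_channel(elementwise, "elementwise"),
      basewise_min = basewise_min, elementwise_min = elementwise_min
    ),
    class = "conservation_track"
  )
}

#' Read a 2-column conservation TSV (cap_offset, score)
#' @param path TSV file with columns `cap_offset` and `score` (header
#'   optional).
#' @return A tibble suitable for [conservation_track()].
#' @export
read_conservation_tsv <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("cap_offset", first)
  x <- utils::read.delim(path, header = header,
                         col.names = if (header) NULL else c("cap_offset", "score"))
  tibble::as_tibble(x)
}

channel_scores <- function(channel, offsets) {
  if (is.null(channel)) return(NULL)
  channel$score[match(offsets, channel$cap_offset)]
}

# is a codon (3 cap offsets) conserved under either channel? NA when no
# channel fully covers it (internal)
codon_conserved <- function(track, offsets) {
  bw <- channel_scores(track$basewise, offsets)
  ew <- channel_scores(track$elementwise, offsets)
  verdicts <- c(
    if (!is.null(bw) && !anyNA(bw)) all(bw > track$basewise_min),
    if (!is.null(ew) && !anyNA(ew)) all(ew > track$elementwise_min)
  )
  partial <- (!is.null(bw) && anyNA(bw)) || (!is.null(ew) && anyNA(ew))
  if (!length(verdicts)) {
    return(list(flag = NA, partial = partial))
  }
  list(flag = any(verdicts), partial = FALSE)
}

#' Gate uORF start/stop codons through conservation thresholds
#'
#' A codon is called conserved when all three of its bases exceed the
#' basewise threshold, or when the elementwise score exceeds its threshold at
#' all three bases. Flags are set independently for the start and stop codon
#' of each uORF. With no track coverage the flags stay `NA`; partial coverage
#' of a codon leaves its flag `NA` with a warning.
#'
#' @param uorfs Tibble from [scan_uorfs()].
#' @param track A [conservation_track()].
#' @return `uorfs` with `conserved_start` / `conserved_stop` filled.
#' @export
conservation_gate <- function(uorfs, track) {
  stopifnot(inherits(track, "conservation_track"))
  if (nrow(uorfs) == 0) return(uorfs)
  partial_seen <- FALSE
  res <- purrr::pmap(
    list(uorfs$start_offset, uorfs$end_offset),
    function(s, e) {
      st <- codon_conserved(track, s + 0:2)
      sp <- codon_conserved(track, e - 2:0)
      partial_seen <<- partial_seen || st$partial || sp$partial
      c(start = st$flag, stop = sp$flag)
    }
  )
  if (partial_seen) {
    warning("conservation track only partially covers some uORF codons; flags left NA",
            call. = FALSE)
  }
  uorfs$conserved_start <- purrr::map_lgl(res, "start")
  uorfs$conserved_stop <- purrr::map_lgl(res, "stop")
  uorfs
}

#' Mean pairwise percent identity of aligned peptides
#'
#' For every unordered pair of aligned (equal-length, gapped) peptide
#' sequences, identity is the number of identical columns where the residues
#' are not both gaps, divided by the number of columns where at least one
#' sequence has a residue. The mean over all pairs is classified as `high`
#' (>= 80), `moderate` (50-80) or `weak` (< 50); values exactly on a boundary
#' take the higher class.
#'
#' @param aligned_peptides Character vector of >= 2 equal-length gapped
#'   sequences (`-` for gaps).
#' @return A list with `mean_identity` (percent) and `class`.
#' @examples
#' peptide_identity_class(c("MRALP", "MRTLP"))
#' @export
peptide_identity_class <- function(aligned_peptides) {
  if (length(aligned_peptides) < 2) {
    stop("need at least two aligned peptide sequences", call. = FALSE)
  }
  if (length(unique(nchar(aligned_peptides))) != 1) {
    stop("aligned peptides must all have the same length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(aligned_peptides), ""))
  pairs <- utils::combn(nrow(mat), 2)
  ident <- apply(pairs, 2, function(ij) {
    a <- mat[ij[1], ]
    b <- mat[ij[2], ]
    informative <- !(a == "-" & b == "-")
    if (!any(informative)) return(NA_real_)
    100 * sum(a == b & informative) / sum(informative)
  })
  mi <- mean(ident)
  cls <- if (mi >= 80) "high" else if (mi >= 50) "moderate" else "weak"
  list(mean_identity = mi, class = cls)
}
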