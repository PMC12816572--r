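STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 0-based offsets of ATG within a character sequence (internal)
find_atg_offsets <- function(seq) {
  m <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# 0-based start offset of the first in-frame stop whose codon lies entirely
# within seq[from..limit_end], or NA (internal)
first_inframe_stop <- function(seq, from, limit_end = nchar(seq) - 1L) {
  starts <- seq.int(from, limit_end - 2L, by = 3L)
  if (from > limit_end - 2L) return(NA_integer_)
  codons <- substring(seq, starts + 1L, starts + 3L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) starts[hit[1]] else NA_integer_
}

translate_codons <- function(seq, from, to) {
  starts <- seq.int(from, to - 2L, by = 3L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# extent of the reading frame opened at an ATG (internal workhorse).
# Returns list(extent, stop_offset, stop_end, frame_vs_morf, peptide,
# readthrough) where stop offsets are 0-based in the UTR (contained) or the
# full UTR+prefix sequence (overlapping), NA when no stop is reached.
orf_extent_info <- function(utr, atg_offset) {
  L <- utr_length(utr)
  fs <- full_seq(utr)
  if (substr(utr$seq, atg_offset + 1L, atg_offset + 3L) != "ATG") {
    stop(sprintf("no ATG at cap offset %d", atg_offset), call. = FALSE)
  }
  in_frame <- (L - atg_offset) %% 3L == 0L
  # a contained uORF's stop codon must lie entirely within the UTR: a stop
  # whose last base is at c.-1 counts, one overlapping the mAUG does not
  stop_in_utr <- first_inframe_stop(utr$seq, atg_offset, L - 1L)
  if (!is.na(stop_in_utr)) {
    return(list(
      extent = "contained_uorf",
      stop_offset = stop_in_utr, stop_end = stop_in_utr + 2L,
      frame_vs_morf = if (in_frame) "in_frame" else "out_of_frame",
      peptide = translate_codons(utr$seq, atg_offset, stop_in_utr - 1L),
      readthrough = NA_character_
    ))
  }
  if (in_frame) {
    return(list(
      extent = "n_terminal_extension",
      stop_offset = NA_integer_, stop_end = NA_integer_,
      frame_vs_morf = "in_frame", peptide = NA_character_,
      readthrough = "in_frame_with_morf"
    ))
  }
  stop_full <- first_inframe_stop(fs, atg_offset, nchar(fs) - 1L)
  list(
    extent = "overlapping_oorf",
    stop_offset = stop_full, stop_end = if (is.na(stop_full)) NA_integer_ else stop_full + 2L,
    frame_vs_morf = "out_of_frame", peptide = NA_character_,
    readthrough = if (is.na(stop_full)) "beyond_cds_prefix" else "within_cds_prefix"
  )
}

#' Classify the extent of the reading frame opened at an upstream ATG
#'
#' An ATG in the 5'UTR opens one of three architectures: a `contained_uorf`
#' whose first in-frame stop codon lies entirely within the UTR; an
#' `n_terminal_extension` when the ATG is in frame with the main ORF and no
#' in-frame stop intervenes; or an `overlapping_oorf` that reads past the main
#' AUG out of frame, terminating wherever the UTR + CDS prefix next supplies a
#' stop (or beyond the supplied prefix).
#'
#' @param utr A [utr_sequence()].
#' @param atg_offset 0-based cap offset of the A of an ATG in the UTR.
#' @return One of `"contained_uorf"`, `"overlapping_oorf"`,
#'   `"n_terminal_extension"`.
#' @export
classify_orf_extent <- function(utr, atg_offset) {
  orf_extent_info(utr, atg_offset)$extent
}

#' Score the Kozak context of an AUG
#'
#' Matches the -3 and +4 positions around an AUG against the core motif
#' `A/GXXATGG`: the -3 base matches if it is a purine (`A`/`G`), the +4 base
#' if it is `G`. Both matching gives `strong`, exactly one `moderate`, neither
#' `weak`. When the context is truncated the missing position counts as a
#' non-match and the result carries an `incomplete` attribute instead of
#' failing.
#'
#' @param x A [utr_sequence()] (scored on UTR + CDS prefix so the main AUG's
#'   +4 base is available) or a plain character sequence.
#' @param atg_offset 0-based offset(s) of the A of the AUG within `x`.
#' @return Character vector of classes with attribute `incomplete` (logical).
#' @examples
#' kozak_class("GCCATGG", 3)  # strong
#' kozak_class("TTTATGC", 3)  # weak
#' @export
kozak_class <- function(x, atg_offset) {
  seq <- if (inherits(x, "utr_sequence")) full_seq(x) else toupper(as.character(x))
  n <- nchar(seq)
  res <- character(length(atg_offset))
  inc <- logical(length(atg_offset))
  for (i in seq_along(atg_offset)) {
    off <- atg_offset[i]
    if (substr(seq, off + 1L, off + 3L) != "ATG") {
      stop(sprintf("no ATG at offset %d", off), call. = FALSE)
    }
    has_m3 <- off - 3L >= 0L
    has_p4 <- off + 3L <= n - 1L
    m3 <- has_m3 && substr(seq, off - 2L, off - 2L) %in% c("A", "G")
    p4 <- has_p4 && substr(seq, off + 4L, off + 4L) == "G"
    res[i] <- c("weak", "moderate", "strong")[m3 + p4 + 1L]
    inc[i] <- !(has_m3 && has_p4)
  }
  attr(res, "incomplete") <- inc
  res
}

#' Scan a 5'UTR for AUG-initiated upstream ORFs
#'
#' Every ATG in the UTR whose first in-frame stop codon lies entirely within
#' the UTR yields one uORF row, ordered 5'->3'. Only ATG starts are
#' considered (no near-cognate starts such as CTG). ATGs whose reading frame
#' continues to or past the main AUG are not uORFs; see
#' [classify_orf_extent()]. Nested and overlapping ATGs each produce their own
#' record.
#'
#' @param utr A [utr_sequence()].
#' @param track Optional [conservation_track()]; when supplied, start/stop
#'   codon conservation flags are filled via [conservation_gate()].
#' @return A tibble with one row per uORF: `uorf` (index 5'->3'),
#'   `start_offset` / `end_offset` (0-based cap offsets of the first ATG base
#'   and last stop-codon base), `width`, `peptide` (excluding the stop),
#'   `n_aa`, `frame_vs_morf`, `cap_to_uaug`, `stop_to_maug_gap`, `kozak`,
#'   `kozak_incomplete`, `conserved_start`, `conserved_stop`.
#' @examples
#' utr <- utr_sequence("AAGATGCCCTAAGGG", "ATGGCTGCTGCT")
#' scan_uorfs(utr)
#' @export
scan_uorfs <- function(utr, track = NULL) {
  stopifnot(inherits(utr, "utr_sequence"))
  L <- utr_length(utr)
  offs <- find_atg_offsets(utr$seq)
  rows <- purrr::map(offs, function(o) {
    info <- orf_extent_info(utr, o)
    if (info$extent != "contained_uorf") return(NULL)
    tibble::tibble(
      start_offset = o,
      end_offset = info$stop_end,
      peptide = info$peptide,
      frame_vs_morf = info$frame_vs_morf
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      uorf = integer(), start_offset = integer(), end_offset = integer(),
      width = integer(), peptide = character(), n_aa = integer(),
      frame_vs_morf = character(), cap_to_uaug = integer(),
      stop_to_maug_gap = integer(), kozak = character(),
      kozak_incomplete = logical(), conserved_start = logical(),
      conserved_stop = logical()
    )
    return(out)
  }
  kz <- kozak_class(utr, out$start_offset)
  out <- out |>
    dplyr::mutate(
      uorf = dplyr::row_number(),
      width = .data$end_offset - .data$start_offset + 1L,
      n_aa = .data$width %/% 3L - 1L,
      cap_to_uaug = .data$start_offset,
      stop_to_maug_gap = L - 1L - .data$end_offset,
      kozak = as.character(kz),
      kozak_incomplete = attr(kz, "incomplete"),
      conserved_start = NA,
      conserved_stop = NA
    ) |>
    dplyr::select(
      "uorf", "start_offset", "end_offset", "width", "peptide", "n_aa",
      "frame_vs_morf", "cap_to_uaug", "stop_to_maug_gap", "kozak",
      "kozak_incomplete", "conserved_start", "conserved_stop"
    )
  if (!is.null(track)) out <- conservation_gate(out, track)
  out
}
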