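#' Strand-aware transcript coordinate model for a 5'UTR
#'
#' A `transcript_model` ties together the genomic span of a contiguous 5'UTR,
#' the genomic position of the first base of the main-ORF AUG, and HGVS-style
#' `c.` coordinates. UTR bases are numbered `c.-L` (the cap base, `L` = UTR
#' length) through `c.-1` (the base adjacent to the A of the main AUG); `c.1`
#' is the A of the main AUG and there is no `c.0`. Internally all interval
#' arithmetic uses 0-based cap offsets; `c.` values appear only at the API
#' boundary.
#'
#' On the minus strand the 5' cap base is the *maximum* genomic coordinate of
#' the UTR span and the CDS starts one base below its minimum; mirrored on the
#' plus strand. The modelled region is the UTR plus the first CDS codon (the
#' CDS itself is supplied as a sequence suffix, not as coordinates).
#'
#' @param chrom Chromosome name.
#' @param strand `"plus"`/`"+"` or `"minus"`/`"-"`.
#' @param utr5_start,utr5_end 1-based inclusive genomic interval of the 5'UTR.
#' @param cds_start Genomic position of the first base of the main-ORF AUG.
#'   Must be adjacent to the UTR span on the strand-appropriate side.
#' @param transcript_id Free-text label.
#' @return An object of class `transcript_model`.
#' @examples
#' m <- transcript_model("chr16", "minus", 2135690, 2135898, 2135689)
#' genomic_to_tx(m, 2135898)
#' @export
transcript_model <- function(chrom, strand, utr5_start, utr5_end, cds_start,
                             transcript_id = "") {
  strand <- switch(as.character(strand),
    "+" = , "plus" = "plus",
    "-" = , "minus" = "minus",
    stop("`strand` must be 'plus'/'+' or 'minus'/'-'", call. = FALSE)
  )
  utr5_start <- as.integer(utr5_start)
  utr5_end <- as.integer(utr5_end)
  cds_start <- as.integer(cds_start)
  if (is.na(utr5_start) || is.na(utr5_end) || utr5_start > utr5_end) {
    stop("invalid UTR interval: utr5_start must be <= utr5_end", call. = FALSE)
  }
  expected_cds <- if (strand == "minus") utr5_start - 1L else utr5_end + 1L
  if (cds_start != expected_cds) {
    stop(sprintf(
      "cds_start (%d) must be adjacent to the UTR span on the %s strand (expected %d)",
      cds_start, strand, expected_cds
    ), call. = FALSE)
  }
  structure(
    list(
      chrom = as.character(chrom), strand = strand,
      utr5_start = utr5_start, utr5_end = utr5_end,
      cds_start = cds_start,
      utr_length = utr5_end - utr5_start + 1L,
      transcript_id = as.character(transcript_id)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s %s:%s-%s (%s strand), 5'UTR %d nt, CDS start %s\n",
    x$transcript_id, x$chrom,
    format(x$utr5_start, big.mark = ","), format(x$utr5_end, big.mark = ","),
    x$strand, x$utr_length, format(x$cds_start, big.mark = ",")
  ))
  invisible(x)
}

#' Build a transcript model from a key-value config block
#'
#' Accepts either a named list/vector or the path of a plain-text file of
#' `key = value` (or `key: value`) lines with keys `chrom`, `strand`,
#' `utr5_start`, `utr5_end`, `cds_start` and optionally `transcript_id`.
#'
#' @param config Named list/character vector, or a file path.
#' @return A [transcript_model()].
#' @export
transcript_model_from_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    lines <- readLines(config, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "[=:]", fixed = FALSE)
    config <- stats::setNames(
      trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), "")),
      trimws(vapply(kv, `[[`, "", 1))
    )
  }
  config <- as.list(config)
  needed <- c("chrom", "strand", "utr5_start", "utr5_end", "cds_start")
  missing <- setdiff(needed, names(config))
  if (length(missing)) {
    stop("config is missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  transcript_model(
    config$chrom, config$strand,
    as.integer(config$utr5_start), as.integer(config$utr5_end),
    as.integer(config$cds_start),
    transcript_id = config$transcript_id %||% ""
  )
}

#' Build a transcript model from a BED-like line
#'
#' Five whitespace-separated columns: chrom, 0-based start, end, name, strand.
#' The interval is the 5'UTR; the CDS start is placed on the adjacent base
#' dictated by the strand.
#'
#' @param line A single character string.
#' @return A [transcript_model()].
#' @export
transcript_model_from_bed <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 5) stop("BED-like line needs 5 columns (chrom start end name strand)", call. = FALSE)
  start1 <- as.integer(f[2]) + 1L
  end1 <- as.integer(f[3])
  strand <- if (f[5] %in% c("-", "minus")) "minus" else "plus"
  cds <- if (strand == "minus") start1 - 1L else end1 + 1L
  transcript_model(f[1], strand, start1, end1, cds, transcript_id = f[4])
}

genomic_in_model <- function(model, gpos) {
  in_utr <- gpos >= model$utr5_start & gpos <= model$utr5_end
  cds3 <- if (model$strand == "minus") {
    gpos <= model$cds_start & gpos >= model$cds_start - 2L
  } else {
    gpos >= model$cds_start & gpos <= model$cds_start + 2L
  }
  in_utr | cds3
}

#' Map genomic positions to transcript coordinates
#'
#' Converts genomic positions inside the modelled region (the 5'UTR plus the
#' first three CDS bases) to HGVS-like `c.` values and 0-based cap offsets.
#' On the minus strand increasing genomic position maps to decreasing cap
#' offset.
#'
#' @param model A [transcript_model()].
#' @param gpos Integer vector of 1-based genomic positions.
#' @return A tibble with columns `genomic`, `cap_offset` (0-based distance
#'   from the cap; `NA` for CDS bases) and `c_position`.
#' @examples
#' m <- transcript_model("chr16", "minus", 2135690, 2135898, 2135689)
#' genomic_to_tx(m, c(2135898, 2135776, 2135758, 2135689))
#' @export
genomic_to_tx <- function(model, gpos) {
  stopifnot(inherits(model, "transcript_model"))
  gpos <- as.integer(gpos)
  ok <- genomic_in_model(model, gpos)
  if (!all(ok)) {
    stop(sprintf(
      "genomic position %s outside modelled region %s:%d-%d (+ first 3 CDS bases)",
      paste(gpos[!ok], collapse = ", "), model$chrom, model$utr5_start, model$utr5_end
    ), call. = FALSE)
  }
  L <- model$utr_length
  if (model$strand == "minus") {
    in_utr <- gpos >= model$utr5_start
    offset <- ifelse(in_utr, model$utr5_end - gpos, NA_integer_)
    c_pos <- ifelse(in_utr, offset - L, model$cds_start - gpos + 1L)
  } else {
    in_utr <- gpos <= model$utr5_end
    offset <- ifelse(in_utr, gpos - model$utr5_start, NA_integer_)
    c_pos <- ifelse(in_utr, offset - L, gpos - model$cds_start + 1L)
  }
  tibble::tibble(
    genomic = gpos,
    cap_offset = as.integer(offset),
    c_position = as.integer(c_pos)
  )
}

#' Map transcript coordinates to genomic positions
#'
#' Exact inverse of [genomic_to_tx()] over the modelled region. `c.` values
#' must lie in `[-utr_length, 3]` and cannot be 0 (there is no `c.0`).
#'
#' @param model A [transcript_model()].
#' @param c_position Integer vector of signed `c.` coordinates.
#' @return Integer vector of genomic positions.
#' @export
tx_to_genomic <- function(model, c_position) {
  stopifnot(inherits(model, "transcript_model"))
  c_position <- as.integer(c_position)
  if (any(c_position == 0L, na.rm = TRUE)) {
    stop("invalid coordinate: there is no c.0", call. = FALSE)
  }
  L <- model$utr_length
  if (any(c_position < -L | c_position > 3L)) {
    stop(sprintf("c. position outside modelled range [-%d, 3]", L), call. = FALSE)
  }
  if (model$strand == "minus") {
    ifelse(c_position < 0L,
      model$utr5_end - (L + c_position),
      model$cds_start - (c_position - 1L)
    )
  } else {
    ifelse(c_position < 0L,
      model$utr5_start + (L + c_position),
      model$cds_start + (c_position - 1L)
    )
  }
}

# cap offset <-> c. value for UTR bases (internal; L = UTR length)
offset_to_c <- function(offset, L) as.integer(offset - L)
c_to_offset <- function(c_position, L) {
  if (any(c_position == 0L)) stop("invalid coordinate: there is no c.0", call. = FALSE)
  ifelse(c_position < 0L, as.integer(L + c_position), as.integer(L + c_position - 1L))
}
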