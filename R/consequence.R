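#' @title Consequence taxonomy
#' @description Severity ranking used to pick the primary consequence code
#'   when a variant triggers several. Stop disruption and AUG creation head
#'   the ranking, mirroring the tiering used for 5'UTR variant triage in
#'   haploinsufficient disease genes.
#' @format Character vector, most severe first.
#' @export
CONSEQUENCE_SEVERITY <- c(
  "uStop_lost_oORF", "uAUG_created_oORF", "uStop_lost_extension",
  "uAUG_created_uORF", "uAUG_created_NTE", "uStart_lost", "uFrameshift",
  "uAA_substitution", "kozak_changed_uORF", "kozak_changed_mORF",
  "uSynonymous", "no_uorf_change"
)

# architecture of every ATG-opened frame in a UTR (internal)
utr_architecture <- function(utr) {
  offs <- find_atg_offsets(utr$seq)
  purrr::map(offs, function(o) c(list(offset = o), orf_extent_info(utr, o)))
}

#' Classify the translational consequence of 5'UTR variants
#'
#' Applies the variant set to the reference UTR, re-derives the ORF
#' architecture of both sequences, matches ORFs across the edit by their
#' variant-adjusted start coordinate, and emits a structural-diff code:
#'
#' * `uStop_lost_oORF` - a uORF's stop is disrupted and reading continues
#'   past the main AUG (overlapping ORF read-through).
#' * `uStop_lost_extension` - the stop is disrupted but a new in-frame stop
#'   is reached within the UTR; the new stop-to-mAUG gap is reported.
#' * `uAUG_created_uORF` / `uAUG_created_oORF` / `uAUG_created_NTE` - a new
#'   upstream ATG appears, classified by the extent of the frame it opens.
#' * `uStart_lost` - a uORF's ATG is destroyed.
#' * `uFrameshift` - an indel of non-multiple-of-3 length inside a uORF
#'   (always accompanied by a stop-change code, hence secondary).
#' * `uAA_substitution` / `uSynonymous` - coding change inside a uORF with
#'   the stop intact (a premature stop inside the uORF is reported as
#'   `uAA_substitution` with a `premature_stop` detail flag).
#' * `kozak_changed_uORF` / `kozak_changed_mORF` - the Kozak strength class
#'   (not merely a context base) of a uORF or the main ORF changes.
#' * `no_uorf_change` - none of the above.
#'
#' At most one primary code is assigned, ordered by [CONSEQUENCE_SEVERITY];
#' everything else triggered lands in `secondary_codes`.
#'
#' @param ref_utr Reference [utr_sequence()].
#' @param variants Character vector of HGVS-like `c.` strings (or parsed
#'   tibble); may be empty for a no-op.
#' @param splice_score Optional splice-disruption score for the variant
#'   (e.g. a SpliceAI delta); at or above `splice_threshold` the call gains a
#'   possible-splice-effect flag.
#' @param splice_threshold Splice flag threshold (default 0.05).
#' @param af Optional population allele frequency annotation, carried
#'   through to prioritisation.
#' @return A `consequence_call` object; see [tidy.consequence_call()].
#' @examples
#' utr <- utr_sequence("AAGATGCCCTAAGGG", "ATGGCTGCTGCT")
#' classify_consequence(utr, "c.-6T>C")$primary_code  # destroys the uORF stop
#' @export
classify_consequence <- function(ref_utr, variants = character(),
                                 splice_score = NA_real_,
                                 splice_threshold = 0.05,
                                 af = NA_real_) {
  stopifnot(inherits(ref_utr, "utr_sequence"))
  rv <- resolve_variants(ref_utr, variants)
  alt_utr <- apply_variant(ref_utr, rv)
  L_ref <- utr_length(ref_utr)
  L_alt <- utr_length(alt_utr)
  map <- offset_map(rv)

  ref_arch <- utr_architecture(ref_utr)
  alt_arch <- utr_architecture(alt_utr)
  alt_by_offset <- stats::setNames(alt_arch, vapply(alt_arch, `[[`, 0L, "offset"))
  ref_contained <- ref_arch[vapply(ref_arch, function(x) x$extent == "contained_uorf", TRUE)]

  codes <- character()
  details <- list()
  affected <- NA_integer_
  matched_alt_offsets <- integer()

  edit_anchors <- rv$offset
  edit_in_span <- function(from, to) {
    any(vapply(seq_len(nrow(rv)), function(i) {
      a <- rv$offset[i]; b <- rv$end_offset[i]
      b >= from && a <= to
    }, TRUE))
  }
  indel_shift_in_span <- function(from, to) {
    sel <- vapply(seq_len(nrow(rv)), function(i) {
      rv$shift[i] != 0L && rv$end_offset[i] >= from && rv$offset[i] <= to
    }, TRUE)
    sum(rv$shift[sel])
  }

  add_code <- function(code, uorf_idx = NA_integer_, det = list()) {
    codes <<- c(codes, code)
    if (is.na(affected) && !is.na(uorf_idx) &&
        code %in% CONSEQUENCE_SEVERITY[1:8]) {
      affected <<- uorf_idx
    }
    details <<- utils::modifyList(details, det)
  }

  alt_contained_spans <- purrr::keep(alt_arch, ~ .x$extent == "contained_uorf")

  for (i in seq_along(ref_contained)) {
    ro <- ref_contained[[i]]
    a <- map(ro$offset)
    alt_has_atg <- !is.na(a) && a <= L_alt - 3L &&
      substr(alt_utr$seq, a + 1L, a + 3L) == "ATG"
    if (!alt_has_atg) {
      add_code("uStart_lost", i)
      next
    }
    matched_alt_offsets <- c(matched_alt_offsets, a)
    ai <- alt_by_offset[[as.character(a)]]
    shift_inside <- indel_shift_in_span(ro$offset, ro$stop_end)
    frameshifted <- shift_inside %% 3L != 0L
    old_stop_mapped <- map(ro$stop_end)
    if (ai$extent == "contained_uorf") {
      stop_same <- !is.na(old_stop_mapped) && ai$stop_end == old_stop_mapped &&
        !frameshifted
      if (stop_same) {
        if (!identical(ai$peptide, ro$peptide)) {
          premature <- grepl("\\*", ai$peptide) # never true: stop excluded; keep for clarity
          add_code("uAA_substitution", i, list(premature_stop = premature))
        } else if (edit_in_span(ro$offset, ro$stop_end)) {
          add_code("uSynonymous", i)
        }
      } else if (is.na(old_stop_mapped) ||
                 ai$stop_end > old_stop_mapped || frameshifted) {
        stop_span <- ai$stop_offset:ai$stop_end
        in_other <- any(vapply(alt_contained_spans, function(x) {
          x$offset != ai$offset &&
            any(stop_span >= x$offset & stop_span <= x$stop_end)
        }, TRUE))
        add_code("uStop_lost_extension", i, list(
          old_stop_end = ro$stop_end,
          new_stop_end = ai$stop_end,
          new_stop_to_maug_gap = L_alt - 1L - ai$stop_end,
          stop_in_other_uorf = in_other
        ))
        if (frameshifted) add_code("uFrameshift", i)
      } else {
        # a new stop upstream of the (intact) old one truncates the peptide
        add_code("uAA_substitution", i, list(
          premature_stop = TRUE,
          old_stop_end = ro$stop_end, new_stop_end = ai$stop_end
        ))
      }
    } else {
      # contained uORF now reads to/past the main AUG
      add_code("uStop_lost_oORF", i, list(
        old_stop_end = ro$stop_end,
        new_stop_end = ai$stop_end,
        readthrough = if (ai$extent == "n_terminal_extension") {
          "in_frame_with_morf"
        } else {
          ai$readthrough
        },
        in_frame_readthrough = ai$extent == "n_terminal_extension"
      ))
      if (frameshifted) add_code("uFrameshift", i)
    }
    kz_ref <- as.character(kozak_class(ref_utr, ro$offset))
    kz_alt <- as.character(kozak_class(alt_utr, a))
    if (kz_ref != kz_alt) {
      add_code("kozak_changed_uORF", i,
               stats::setNames(list(c(kz_ref, kz_alt)),
                               paste0("kozak_uorf", i)))
    }
  }

  # ref ATGs that are not contained uORFs still occupy alt positions; exclude
  # them from "created" calls when they persist
  ref_noncontained <- ref_arch[vapply(ref_arch, function(x) x$extent != "contained_uorf", TRUE)]
  for (ro in ref_noncontained) {
    a <- map(ro$offset)
    if (!is.na(a) && a <= L_alt - 3L &&
        substr(alt_utr$seq, a + 1L, a + 3L) == "ATG") {
      matched_alt_offsets <- c(matched_alt_offsets, a)
    }
  }

  for (ai in alt_arch) {
    if (ai$offset %in% matched_alt_offsets) next
    code <- switch(ai$extent,
      contained_uorf = "uAUG_created_uORF",
      overlapping_oorf = "uAUG_created_oORF",
      n_terminal_extension = "uAUG_created_NTE"
    )
    add_code(code, NA_integer_, list(
      created_atg_offset = ai$offset,
      created_stop_end = ai$stop_end
    ))
  }

  kz_m_ref <- as.character(kozak_class(ref_utr, L_ref))
  kz_m_alt <- as.character(kozak_class(alt_utr, L_alt))
  if (kz_m_ref != kz_m_alt) {
    add_code("kozak_changed_mORF", NA_integer_,
             list(kozak_morf = c(kz_m_ref, kz_m_alt)))
  }

  if (!length(codes)) codes <- "no_uorf_change"
  ord <- order(match(codes, CONSEQUENCE_SEVERITY))
  codes <- codes[ord]
  structure(
    list(
      variants = if (nrow(rv)) rv$label else character(),
      primary_code = codes[1],
      secondary_codes = unique(codes[-1]),
      affected_uorf = affected,
      details = details,
      splice_flagged = !is.na(splice_score) && splice_score >= splice_threshold,
      splice_score = splice_score,
      af = af
    ),
    class = "consequence_call"
  )
}

#' @export
print.consequence_call <- function(x, ...) {
  v <- if (length(x$variants)) paste(x$variants, collapse = " + ") else "(no variant)"
  cat(sprintf("<consequence_call> %s -> %s", v, x$primary_code))
  if (length(x$secondary_codes)) {
    cat(" [", paste(x$secondary_codes, collapse = ", "), "]", sep = "")
  }
  cat("\n")
  if (!is.null(x$details$new_stop_to_maug_gap)) {
    cat(sprintf("  new stop ends %d nt upstream of the main AUG\n",
                x$details$new_stop_to_maug_gap))
  }
  if (isTRUE(x$splice_flagged)) cat("  flagged: possible splice effect\n")
  invisible(x)
}

#' Tidy a consequence call into a one-row tibble
#'
#' @param x A `consequence_call`.
#' @param ... Unused.
#' @return A one-row tibble with the call's variants, primary and secondary
#'   codes, affected uORF, stop-gap detail, read-through and flag columns.
#' @export
tidy.consequence_call <- function(x, ...) {
  d <- x$details
  tibble::tibble(
    variants = paste(x$variants, collapse = ";"),
    primary_code = x$primary_code,
    secondary_codes = paste(x$secondary_codes, collapse = ";"),
    affected_uorf = x$affected_uorf,
    new_stop_to_maug_gap = d$new_stop_to_maug_gap %||% NA_integer_,
    readthrough = d$readthrough %||% NA_character_,
    stop_in_other_uorf = d$stop_in_other_uorf %||% NA,
    premature_stop = d$premature_stop %||% NA,
    splice_flagged = x$splice_flagged,
    af = x$af
  )
}

#' Classify a panel of variants or variant combinations
#'
#' Maps [classify_consequence()] over a construct panel. Each panel row may
#' combine several simple variants (separated by `;` or `+` in `hgvs`); an
#' empty/NA `hgvs` is a wildtype no-op.
#'
#' @param utr Reference [utr_sequence()].
#' @param panel Tibble with columns `hgvs` and optionally `construct`, `af`,
#'   `splice_score`.
#' @param splice_threshold Splice flag threshold.
#' @return A tibble: one row per panel entry with the tidy consequence-call
#'   columns.
#' @export
classify_variants <- function(utr, panel, splice_threshold = 0.05) {
  panel <- tibble::as_tibble(panel)
  stopifnot("hgvs" %in% names(panel))
  if (!"construct" %in% names(panel)) panel$construct <- panel$hgvs
  if (!"af" %in% names(panel)) panel$af <- NA_real_
  if (!"splice_score" %in% names(panel)) panel$splice_score <- NA_real_
  rows <- purrr::pmap(
    panel[c("construct", "hgvs", "af", "splice_score")],
    function(construct, hgvs, af, splice_score) {
      vars <- if (is.na(hgvs) || !nzchar(hgvs)) {
        character()
      } else {
        strsplit(hgvs, "[;+]")[[1]] |> trimws()
      }
      call <- classify_consequence(utr, vars, splice_score = splice_score,
                                   splice_threshold = splice_threshold, af = af)
      dplyr::bind_cols(tibble::tibble(construct = construct), tidy(call))
    }
  )
  dplyr::bind_rows(rows)
}
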