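#' Configuration for the dual-reporter assay simulator
#'
#' Encodes the replicate structure of the emulated experiment - 12
#' transfections per construct split over 2 independent experiments, with 2
#' technical duplicate wells assayed per transfection - together with the
#' true mean relative activities to plant and a two-level noise model: a
#' lognormal per-transfection efficiency factor (shared by both reporters,
#' cancelled by SeAP normalisation) and independent lognormal measurement
#' noise per well.
#'
#' The preset construct panels carry the true relative activities implied by
#' the characterised PKD1 5'UTR constructs (wildtype-minus-construct mean
#' differences 0.8678, -0.097, 0.4465, 0.008, 0.06369 for the variant panel
#' and -0.09, -0.34, -1.31 for the uORF start-loss knockouts). The default
#' measurement noise (sdlog 0.075) reproduces the within-group dispersion
#' implied by the assay's reported Tukey p-values at n = 12.
#'
#' @param panel `"variant"`, `"knockout"`, or `"combined"`; ignored when
#'   `constructs` is given.
#' @param constructs Named numeric vector of true mean relative activities
#'   (wildtype must be 1 and present).
#' @param n_transfections Transfections per construct (total across
#'   experiments).
#' @param n_experiments Independent experiments.
#' @param n_duplicates Technical duplicate wells per transfection.
#' @param transfection_sdlog Lognormal sdlog of the per-transfection
#'   efficiency factor.
#' @param measurement_sdlog Lognormal sdlog of per-well measurement noise.
#' @param base_signal Baseline SeAP luminescence (arbitrary units).
#' @return A list of class `assay_sim_config`.
#' @export
assay_sim_config <- function(panel = c("variant", "knockout", "combined"),
                             constructs = NULL,
                             n_transfections = 12L, n_experiments = 2L,
                             n_duplicates = 2L,
                             transfection_sdlog = 0.25,
                             measurement_sdlog = 0.075,
                             base_signal = 1000) {
  variant_means <- c(
    wildtype = 1, "c.-69dupG" = 1 - 0.8678, rescue1 = 1 + 0.097,
    rescue2 = 1 - 0.4465, benign = 1 - 0.008, nhs1 = 1 - 0.06369
  )
  knockout_means <- c(
    wildtype = 1, uorf1_ko = 1 + 0.09, uorf2_ko = 1 + 0.34,
    double_ko = 1 + 1.31
  )
  if (is.null(constructs)) {
    panel <- match.arg(panel)
    constructs <- switch(panel,
      variant = variant_means,
      knockout = knockout_means,
      combined = c(variant_means, knockout_means[-1])
    )
  }
  if (is.null(names(constructs)) || !"wildtype" %in% names(constructs)) {
    stop("constructs must be a named vector including 'wildtype'", call. = FALSE)
  }
  if (any(constructs <= 0)) stop("true mean activities must be > 0", call. = FALSE)
  if (n_transfections %% n_experiments != 0) {
    stop("n_transfections must divide evenly across experiments", call. = FALSE)
  }
  structure(
    list(
      constructs = constructs, n_transfections = as.integer(n_transfections),
      n_experiments = as.integer(n_experiments),
      n_duplicates = as.integer(n_duplicates),
      transfection_sdlog = transfection_sdlog,
      measurement_sdlog = measurement_sdlog, base_signal = base_signal
    ),
    class = "assay_sim_config"
  )
}

#' Simulate a dual-reporter assay table
#'
#' For every transfection replicate a lognormal transfection-efficiency
#' factor is drawn; each duplicate well then receives
#' `seap = base * factor * noise` and
#' `gluc = base * factor * true_mean * noise` with independent measurement
#' noise, so [normalize_assay()] recovers the planted construct means up to
#' measurement noise (exactly, when both noise terms are zero).
#'
#' @param config An [assay_sim_config()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return Tibble with columns `construct`, `experiment`, `replicate`,
#'   `duplicate`, `gluc`, `seap`.
#' @export
simulate_assay <- function(config = assay_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "assay_sim_config"))
  reps_per_exp <- config$n_transfections %/% config$n_experiments
  grid <- tidyr::expand_grid(
    construct = names(config$constructs),
    experiment = seq_len(config$n_experiments),
    replicate = seq_len(reps_per_exp)
  )
  withr::with_seed(seed, {
    grid$factor <- stats::rlnorm(nrow(grid), 0, config$transfection_sdlog)
    wells <- tidyr::expand_grid(
      grid,
      duplicate = seq_len(config$n_duplicates)
    )
    mu <- config$constructs[wells$construct]
    wells$seap <- config$base_signal * wells$factor *
      stats::rlnorm(nrow(wells), 0, config$measurement_sdlog)
    wells$gluc <- config$base_signal * wells$factor * mu *
      stats::rlnorm(nrow(wells), 0, config$measurement_sdlog)
  })
  wells |>
    dplyr::select("construct", "experiment", "replicate", "duplicate",
                  "gluc", "seap")
}

#' Simulate a conservation track with conserved uORF boundary codons
#'
#' Background positions get basewise/elementwise scores below the gate
#' thresholds; the start and stop codons of the supplied uORFs are planted
#' above them, emulating strong species conservation of uORF boundaries.
#'
#' @param uorfs Tibble from [scan_uorfs()].
#' @param utr_len UTR length in nucleotides.
#' @param basewise_min,elementwise_min Gate thresholds the planted scores
#'   must exceed (defaults 2.0 and 0.8).
#' @param seed Integer seed.
#' @return A [conservation_track()].
#' @export
simulate_conservation <- function(uorfs, utr_len,
                                  basewise_min = 2.0, elementwise_min = 0.8,
                                  seed = 1L) {
  offs <- 0:(utr_len - 1L)
  planted <- unique(unlist(purrr::map2(
    uorfs$start_offset, uorfs$end_offset,
    function(s, e) c(s + 0:2, e - 2:0)
  )))
  withr::with_seed(seed, {
    bw <- stats::runif(utr_len, -1.5, 0.75 * basewise_min)
    ew <- stats::runif(utr_len, 0, 0.5 * elementwise_min)
    bw[offs %in% planted] <- stats::runif(length(planted),
                                          basewise_min + 0.5, basewise_min + 2)
    ew[offs %in% planted] <- stats::runif(length(planted),
                                          (1 + elementwise_min) / 2, 1)
  })
  conservation_track(
    basewise = tibble::tibble(cap_offset = offs, score = bw),
    elementwise = tibble::tibble(cap_offset = offs, score = ew),
    basewise_min = basewise_min, elementwise_min = elementwise_min
  )
}

#' The nine-construct variant panel of the reporter experiment
#'
#' Wildtype no-op; the patient duplication; the two in-phase rescue
#' substitutions on the duplication background; a benign high-frequency
#' control; a rare cohort substitution at the cap; and the three uORF
#' start-loss knockouts (ATG -> ACG at the second AUG base, configurable).
#' Allele-frequency and splice-score annotations are synthetic stand-ins
#' consistent with the characterised variants (the duplication is absent
#' from the population database and below the splice threshold; the benign
#' control is common).
#'
#' @param uorf1_ko,uorf2_ko HGVS `c.` strings used as start-loss knockouts.
#' @param benign_af Synthetic population allele frequency of the benign
#'   control.
#' @return Tibble with columns `construct`, `hgvs`, `af`, `splice_score`.
#' @export
variant_panel <- function(uorf1_ko = "c.-86T>C", uorf2_ko = "c.-19T>C",
                          benign_af = 0.01) {
  tibble::tibble(
    construct = c("wildtype", "c.-69dupG", "rescue1", "rescue2", "benign",
                  "nhs1", "uorf1_ko", "uorf2_ko", "double_ko"),
    hgvs = c(
      NA_character_,
      "c.-69dupG",
      "c.-69dupG;c.-59C>A",
      "c.-69dupG;c.-8C>A",
      "c.-52C>T",
      "c.-209G>A",
      uorf1_ko,
      uorf2_ko,
      paste(uorf1_ko, uorf2_ko, sep = ";")
    ),
    af = c(NA, NA, NA, NA, benign_af, NA, NA, NA, NA),
    splice_score = c(NA, 0.01, 0.01, 0.01, 0.01, 0.02, NA, NA, NA)
  )
}

#' Write a variant panel as a c.-notation TSV
#' @param panel Tibble from [variant_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# one simple c. variant -> plus-strand VCF fields (internal)
variant_to_vcf <- function(spec_row, utr, model) {
  L <- utr_length(utr)
  rv <- resolve_variants(utr, spec_row)
  minus <- model$strand == "minus"
  g_of <- function(off) tx_to_genomic(model, offset_to_c(off, L))
  if (rv$kind == "substitution") {
    pos <- g_of(rv$offset)
    ref <- if (minus) complement_base(rv$ref) else rv$ref
    alt <- if (minus) complement_base(rv$alt) else rv$alt
  } else if (rv$kind %in% c("duplication", "insertion")) {
    # inserted after transcript offset q; on the minus strand that is the
    # plus-strand position just 5' (lower coordinate), so anchor at g(q+1)
    q <- rv$offset
    anchor_off <- if (minus) q + 1L else q
    pos <- g_of(anchor_off)
    anchor_base <- substr(utr$seq, anchor_off + 1L, anchor_off + 1L)
    ref <- if (minus) complement_base(anchor_base) else anchor_base
    ins <- if (minus) revcomp(rv$seq) else rv$seq
    alt <- paste0(ref, ins)
  } else {
    # deletion of offsets [a, b]: anchor one base 5' on the plus strand
    a <- rv$offset; b <- rv$end_offset
    anchor_off <- if (minus) b + 1L else a - 1L
    pos <- g_of(anchor_off)
    deleted <- substr(utr$seq, a + 1L, b + 1L)
    anchor_base <- substr(utr$seq, anchor_off + 1L, anchor_off + 1L)
    anchor_plus <- if (minus) complement_base(anchor_base) else anchor_base
    ref <- paste0(anchor_plus, if (minus) revcomp(deleted) else deleted)
    alt <- anchor_plus
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Write a variant panel as a plus-strand VCF
#'
#' Each unique simple variant becomes one record; transcript-orientation
#' duplications are emitted as plus-strand insertions after the appropriate
#' anchor base (on a minus-strand transcript the record position therefore
#' differs from the `c.` position, matching paired `c.`/`g.` notation).
#'
#' @param panel Tibble from [variant_panel()].
#' @param utr The reference [utr_sequence()].
#' @param model The anchoring [transcript_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, utr, model, path) {
  simple <- unique(unlist(strsplit(stats::na.omit(panel$hgvs), "[;+]")))
  simple <- trimws(simple[nzchar(simple)])
  parsed <- parse_hgvs_c(simple)
  recs <- purrr::map_chr(seq_len(nrow(parsed)), function(i) {
    v <- variant_to_vcf(parsed[i, ], utr, model)
    paste(model$chrom, v$pos, parsed$label[i], v$ref, v$alt, ".", "PASS", ".",
          sep = "\t")
  })
  ord <- order(purrr::map_int(seq_len(nrow(parsed)), function(i) {
    variant_to_vcf(parsed[i, ], utr, model)$pos
  }))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", model$chrom),
    sprintf("##reference=%s", model$transcript_id),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  writeLines(c(header, recs[ord]), path)
  invisible(path)
}

#' Read plus-strand VCF variants and express them in transcript c. notation
#'
#' Substitutions and simple insertions are converted through the transcript
#' model (complemented and re-anchored on minus-strand transcripts);
#' insertions that duplicate the adjacent transcript base are normalised to
#' `dup` notation at the 3'-most equivalent transcript position.
#'
#' @param path VCF file.
#' @param model The anchoring [transcript_model()].
#' @param utr Reference [utr_sequence()] (needed for dup normalisation).
#' @return Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `hgvs`.
#' @export
read_variants_vcf <- function(path, model, utr) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  L <- utr_length(utr)
  minus <- model$strand == "minus"
  hgvs <- purrr::pmap_chr(fix[c("POS", "REF", "ALT")], function(POS, REF, ALT) {
    pos <- as.integer(POS)
    if (nchar(REF) == 1 && nchar(ALT) == 1) {
      cpos <- genomic_to_tx(model, pos)$c_position
      ref_t <- if (minus) complement_base(REF) else REF
      alt_t <- if (minus) complement_base(ALT) else ALT
      return(sprintf("c.%d%s>%s", cpos, ref_t, alt_t))
    }
    if (nchar(ALT) > nchar(REF) && startsWith(ALT, REF) && nchar(REF) == 1) {
      ins_plus <- substr(ALT, 2, nchar(ALT))
      if (minus) {
        ins_t <- revcomp(ins_plus)
        after_off <- genomic_to_tx(model, pos)$cap_offset - 1L
      } else {
        ins_t <- ins_plus
        after_off <- genomic_to_tx(model, pos)$cap_offset
      }
      # duplication when the inserted bases repeat the preceding transcript
      # base(s); normalise 3'-most
      if (nchar(ins_t) == 1 &&
          substr(utr$seq, after_off + 1L, after_off + 1L) == ins_t) {
        q <- after_off
        while (q + 1L <= L - 1L &&
               substr(utr$seq, q + 2L, q + 2L) == ins_t) q <- q + 1L
        return(sprintf("c.%ddup%s", offset_to_c(q, L), ins_t))
      }
      return(sprintf("c.%d_%dins%s", offset_to_c(after_off, L),
                     offset_to_c(after_off + 1L, L), ins_t))
    }
    if (nchar(REF) > nchar(ALT) && startsWith(REF, ALT) && nchar(ALT) == 1) {
      del_plus <- substr(REF, 2, nchar(REF))
      k <- nchar(del_plus)
      if (minus) {
        hi <- genomic_to_tx(model, pos)$cap_offset # anchor offset (3' side on tx)
        a <- hi - k; b <- hi - 1L
      } else {
        a <- genomic_to_tx(model, pos)$cap_offset + 1L; b <- a + k - 1L
      }
      if (a == b) return(sprintf("c.%ddel", offset_to_c(a, L)))
      return(sprintf("c.%d_%ddel", offset_to_c(a, L), offset_to_c(b, L)))
    }
    NA_character_
  })
  tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT, hgvs = hgvs
  )
}
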