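#' Transcript model of the PKD1-like synthetic 5'UTR
#'
#' Genomic anchoring of the synthetic fixture: a 209-nt 5'UTR on the minus
#' strand of chr16 spanning 2,135,690-2,135,898 (GRCh38 numbering), with the
#' main-ORF ATG beginning at 2,135,689. The coordinates are real; the
#' sequence produced by [generate_fixture()] is synthetic.
#'
#' @return A [transcript_model()].
#' @export
pkd1_transcript_model <- function() {
  transcript_model(
    chrom = "chr16", strand = "minus",
    utr5_start = 2135690L, utr5_end = 2135898L, cds_start = 2135689L,
    transcript_id = "PKD1-like-synthetic"
  )
}

#' Structural constraints satisfied by the synthetic PKD1-like fixture
#'
#' The fixture must carry exactly two AUG-initiated contained uORFs: uORF1 at
#' cap offsets 122-145 encoding MPSAGPA (in frame with the main ORF, stop 63
#' nt upstream of the main AUG) and uORF2 at offsets 189-206 encoding MRALP
#' (out of frame, stop 2 nt upstream); both upstream AUGs have a moderate
#' Kozak context with G at -3 and C at +4. Behaviourally, `c.-69dupG` must
#' frameshift uORF1 into an overlapping ORF with no new in-frame stop before
#' the main AUG; `c.-59C>A` and `c.-8C>A` on that background must create
#' stops ending 58 and 7 nt upstream of the main AUG respectively; and
#' `c.-52C>T` / `c.-209G>A` must leave the ORF architecture unchanged.
#'
#' @return A named list of constraint parameters consumed by
#'   [generate_fixture()] and [validate_fixture()].
#' @export
pkd1_fixture_constraints <- function() {
  list(
    utr_length = 209L,
    uorf1 = list(start = 122L, end = 145L, peptide = "MPSAGPA",
                 frame = "in_frame", gap = 63L,
                 genomic = c(2135753L, 2135776L)),
    uorf2 = list(start = 189L, end = 206L, peptide = "MRALP",
                 frame = "out_of_frame", gap = 2L,
                 genomic = c(2135692L, 2135709L)),
    reference_bases = c("-209" = "G", "-69" = "G", "-59" = "C",
                        "-52" = "C", "-8" = "C"),
    rescue1_gap = 58L, rescue2_gap = 7L,
    cds_prefix_length = 30L
  )
}

SYN_CODONS <- list(
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  A = c("GCT", "GCC", "GCA", "GCG"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  R_C = c("CGT", "CGC", "CGA", "CGG"),          # Arg codons with C at +4
  L_TA = c("TTA", "CTA", "TTG", "CTG"),         # Leu codons with purine 3rd base
  STOP = c("TAA", "TAG", "TGA")
)

pick <- function(x, n = 1) x[sample.int(length(x), n, replace = TRUE)]

# one random candidate satisfying the fixed placements (internal)
fixture_candidate <- function(constraints) {
  L <- constraints$utr_length
  u <- pick(c("A", "C", "G", "T"), L)
  set_codons <- function(u, start_offset, codons) {
    u[(start_offset + 1L):(start_offset + 3L * length(codons))] <-
      unlist(strsplit(codons, ""))
    u
  }
  # uORF1: M P S A G P A stop, offsets 122-145
  u <- set_codons(u, 122L, c(
    "ATG", pick(SYN_CODONS$P), pick(SYN_CODONS$S), pick(SYN_CODONS$A),
    pick(SYN_CODONS$G), pick(SYN_CODONS$P), pick(SYN_CODONS$A),
    pick(SYN_CODONS$STOP)
  ))
  # uORF2: M R A L P stop, offsets 189-206; Arg must start with C (+4 Kozak),
  # Leu's 3rd base must be a purine so c.-8C>A can complete a stop codon
  u <- set_codons(u, 189L, c(
    "ATG", pick(SYN_CODONS$R_C), pick(SYN_CODONS$A), pick(SYN_CODONS$L_TA),
    pick(SYN_CODONS$P), pick(SYN_CODONS$STOP)
  ))
  # fixed single bases (R index = cap offset + 1):
  u[1] <- "G"     # c.-209 reference base
  u[120] <- "G"   # uAUG1 Kozak -3
  u[187] <- "G"   # uAUG2 Kozak -3
  u[149] <- "T"   # with u[150] these let c.-59C>A complete a stop on the dup background
  u[150] <- pick(c("A", "G"))
  u[151] <- "C"   # c.-59 reference base
  u[158] <- "C"   # c.-52 reference base
  seq <- paste(u, collapse = "")
  # CDS prefix: ATG, +4 base not G (moderate main-AUG Kozak assumption)
  n_cds <- constraints$cds_prefix_length
  cds <- c("A", "T", "G", pick(c("A", "C", "T")), pick(c("A", "C", "G", "T"), n_cds - 4L))
  list(seq = seq, cds = paste(cds, collapse = ""))
}

# cheap structural screen before running the full validator (internal)
fixture_prescreen <- function(seq, cds, constraints) {
  atg <- find_atg_offsets(seq)
  if (!identical(atg, c(122L, 189L))) return(FALSE)
  # duplication-shifted frame (codons at ref offsets 148, 151, ..., 205) must
  # be stop-free so c.-69dupG reads through the whole UTR remainder
  starts <- seq.int(148L, 205L, by = 3L)
  if (any(substring(seq, starts + 1L, starts + 3L) %in% STOP_CODONS)) return(FALSE)
  # CDS prefix: stop-free in both the main frame and the +1-shifted frame the
  # read-through enters, and no internal ATG
  n <- nchar(cds)
  main <- seq.int(3L, n - 3L, by = 3L)
  shifted <- seq.int(2L, n - 3L, by = 3L)
  if (any(substring(cds, main + 1L, main + 3L) %in% STOP_CODONS)) return(FALSE)
  if (any(substring(cds, shifted + 1L, shifted + 3L) %in% STOP_CODONS)) return(FALSE)
  if (length(find_atg_offsets(cds)) != 1L) return(FALSE)
  TRUE
}

#' Generate a constraint-satisfying PKD1-like 5'UTR fixture
#'
#' Builds a synthetic 209-nt 5'UTR (plus a 30-nt CDS prefix) that reproduces
#' every structural constraint in [pkd1_fixture_constraints()]: the two uORF
#' placements are laid down from randomly chosen synonymous codons, required
#' single bases (reference alleles, Kozak -3 positions, the bases that let
#' the rescue substitutions complete stop codons) are pinned, the remaining
#' positions are filled by seeded randomised search, and candidates are
#' accepted only when the independent [validate_fixture()] passes. The
#' generator is deterministic for a fixed seed; different seeds may give
#' different (all valid) sequences.
#'
#' @param seed Integer seed.
#' @param max_attempts Bounded search budget; exceeding it is an error (the
#'   constraints are never silently relaxed).
#' @param constraints See [pkd1_fixture_constraints()].
#' @return A list of class `pkd1_fixture` with elements `utr`
#'   (a [utr_sequence()]), `model` (a [transcript_model()]), `seed`,
#'   `attempts`.
#' @examples
#' fx <- generate_fixture(seed = 1)
#' scan_uorfs(fx$utr)
#' @export
generate_fixture <- function(seed = 1L, max_attempts = 10000L,
                             constraints = pkd1_fixture_constraints()) {
  model <- pkd1_transcript_model()
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      cand <- fixture_candidate(constraints)
      if (!fixture_prescreen(cand$seq, cand$cds, constraints)) next
      utr <- utr_sequence(cand$seq, cand$cds)
      report <- validate_fixture(utr, model, constraints)
      if (all(report$pass)) {
        return(structure(
          list(utr = utr, model = model, seed = seed, attempts = attempt),
          class = "pkd1_fixture"
        ))
      }
    }
  })
  stop(sprintf(
    "no constraint-satisfying fixture found in %d attempts; try a different seed",
    max_attempts
  ), call. = FALSE)
}

#' @export
print.pkd1_fixture <- function(x, ...) {
  cat(sprintf("<pkd1_fixture> seed %d (accepted on attempt %d)\n", x$seed, x$attempts))
  print(x$model)
  print(x$utr)
  invisible(x)
}

check_row <- function(constraint, pass, detail = "") {
  tibble::tibble(constraint = constraint, pass = isTRUE(pass), detail = detail)
}

#' Independently validate a fixture against its constraints
#'
#' Re-checks every structural and behavioural constraint using only the
#' scanner, coordinate and variant-classification primitives - the generator
#' is never trusted. Returns a per-constraint report; the fixture passes when
#' every row does.
#'
#' @param utr A [utr_sequence()] (or a `pkd1_fixture`, whose model is then
#'   used).
#' @param model The anchoring [transcript_model()].
#' @param constraints See [pkd1_fixture_constraints()].
#' @return A tibble with columns `constraint`, `pass`, `detail`.
#' @export
validate_fixture <- function(utr, model = pkd1_transcript_model(),
                             constraints = pkd1_fixture_constraints()) {
  if (inherits(utr, "pkd1_fixture")) {
    model <- utr$model
    utr <- utr$utr
  }
  cs <- constraints
  L <- utr_length(utr)
  rows <- list()
  rows <- c(rows, list(check_row(
    "utr_length",
    L == cs$utr_length && L == model$utr_length,
    sprintf("length %d", L)
  )))
  uorfs <- scan_uorfs(utr)
  rows <- c(rows, list(check_row(
    "exactly_two_uorfs", nrow(uorfs) == 2, sprintf("found %d", nrow(uorfs))
  )))
  check_uorf <- function(name, spec, row) {
    ok <- !is.null(row) &&
      row$start_offset == spec$start && row$end_offset == spec$end &&
      row$peptide == spec$peptide && row$frame_vs_morf == spec$frame &&
      row$stop_to_maug_gap == spec$gap
    check_row(name, ok, if (is.null(row)) "missing" else
      sprintf("%d-%d %s %s gap %d", row$start_offset, row$end_offset,
              row$peptide, row$frame_vs_morf, row$stop_to_maug_gap))
  }
  u1 <- if (nrow(uorfs) >= 1) uorfs[1, ] else NULL
  u2 <- if (nrow(uorfs) >= 2) uorfs[2, ] else NULL
  rows <- c(rows, list(
    check_uorf("uorf1_structure", cs$uorf1, u1),
    check_uorf("uorf2_structure", cs$uorf2, u2)
  ))
  span_ok <- function(spec, row) {
    if (is.null(row)) return(FALSE)
    g <- sort(tx_to_genomic(model, offset_to_c(c(row$start_offset, row$end_offset), L)))
    identical(as.integer(g), as.integer(spec$genomic))
  }
  rows <- c(rows, list(
    check_row("uorf1_genomic_span", span_ok(cs$uorf1, u1),
              paste(cs$uorf1$genomic, collapse = "-")),
    check_row("uorf2_genomic_span", span_ok(cs$uorf2, u2),
              paste(cs$uorf2$genomic, collapse = "-"))
  ))
  kozak_ok <- if (nrow(uorfs) == 2) {
    all(uorfs$kozak == "moderate") &&
      all(substring(utr$seq, uorfs$start_offset - 2L, uorfs$start_offset - 2L) %in% c("A", "G")) &&
      all(substring(utr$seq, uorfs$start_offset + 4L, uorfs$start_offset + 4L) == "C")
  } else FALSE
  rows <- c(rows, list(check_row("uaug_kozak_moderate_G3_C4", kozak_ok)))
  ref_ok <- all(vapply(names(cs$reference_bases), function(cpos) {
    off <- c_to_offset(as.integer(cpos), L)
    substr(utr$seq, off + 1L, off + 1L) == cs$reference_bases[[cpos]]
  }, TRUE))
  rows <- c(rows, list(check_row("reference_bases", ref_ok,
                                 paste(names(cs$reference_bases), collapse = ","))))
  safe_call <- function(vars) {
    tryCatch(classify_consequence(utr, vars), error = function(e) NULL)
  }
  dup <- safe_call("c.-69dupG")
  rows <- c(rows, list(check_row(
    "dup_creates_oorf_readthrough",
    !is.null(dup) && dup$primary_code == "uStop_lost_oORF" &&
      "uFrameshift" %in% dup$secondary_codes,
    if (is.null(dup)) "error" else dup$primary_code
  )))
  r1 <- safe_call(c("c.-69dupG", "c.-59C>A"))
  rows <- c(rows, list(check_row(
    "rescue1_extension_gap",
    !is.null(r1) && r1$primary_code == "uStop_lost_extension" &&
      identical(r1$details$new_stop_to_maug_gap, cs$rescue1_gap),
    if (is.null(r1)) "error" else
      sprintf("%s gap %s", r1$primary_code, r1$details$new_stop_to_maug_gap %||% NA)
  )))
  r2 <- safe_call(c("c.-69dupG", "c.-8C>A"))
  rows <- c(rows, list(check_row(
    "rescue2_extension_gap",
    !is.null(r2) && r2$primary_code == "uStop_lost_extension" &&
      identical(r2$details$new_stop_to_maug_gap, cs$rescue2_gap),
    if (is.null(r2)) "error" else
      sprintf("%s gap %s", r2$primary_code, r2$details$new_stop_to_maug_gap %||% NA)
  )))
  nochange <- c(benign_no_change = "c.-52C>T", nhs1_no_change = "c.-209G>A")
  for (nm in names(nochange)) {
    cc <- safe_call(nochange[[nm]])
    rows <- c(rows, list(check_row(
      nm,
      !is.null(cc) && cc$primary_code == "no_uorf_change" &&
        length(cc$secondary_codes) == 0,
      if (is.null(cc)) "error" else cc$primary_code
    )))
  }
  rows <- c(rows, list(check_row(
    "cds_prefix",
    startsWith(utr$cds_prefix, "ATG") && nchar(utr$cds_prefix) >= cs$cds_prefix_length
  )))
  dplyr::bind_rows(rows)
}
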