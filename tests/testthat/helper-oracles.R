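# Independent brute-force oracles used to cross-check the scanner and the
# consequence classifier. These deliberately share no code with the package:
# plain loops over substrings, an independent codon table via seqinr.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

random_utr_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_cds_prefix <- function(len = 30) {
  paste0("ATG", paste(sample(c("A", "C", "G", "T"), len - 3, replace = TRUE),
                      collapse = ""))
}

oracle_translate <- function(seq, from, to) {
  codons <- substring(seq, seq(from + 1, to - 1, by = 3),
                      seq(from + 3, to + 1, by = 3))
  paste(seqinr::translate(unlist(strsplit(paste(codons, collapse = ""), ""))),
        collapse = "")
}

# enumerate every (ATG, first in-frame stop fully inside the UTR) pair
oracle_scan <- function(seq) {
  L <- nchar(seq)
  out <- list()
  for (i in 0:(L - 3)) {
    if (substr(seq, i + 1, i + 3) != "ATG") next
    j <- i + 3
    stop_at <- NA
    while (j + 2 <= L - 1) {
      if (substr(seq, j + 1, j + 3) %in% ORACLE_STOPS) {
        stop_at <- j
        break
      }
      j <- j + 3
    }
    if (!is.na(stop_at)) {
      out[[length(out) + 1]] <- data.frame(
        start_offset = i, end_offset = stop_at + 2,
        peptide = oracle_translate(seq, i, stop_at - 1),
        in_frame = (L - i) %% 3 == 0,
        gap = L - 1 - (stop_at + 2)
      )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_offset = integer(), end_offset = integer(),
               peptide = character(), in_frame = logical(), gap = integer())
}

oracle_extent <- function(seq, cds, i) {
  L <- nchar(seq)
  sc <- oracle_scan(seq)
  if (i %in% sc$start_offset) return("contained_uorf")
  if ((L - i) %% 3 == 0) return("n_terminal_extension")
  "overlapping_oorf"
}

oracle_kozak <- function(ctx_seq, i) {
  m3 <- if (i - 3 >= 0) substr(ctx_seq, i - 2, i - 2) else ""
  p4 <- if (i + 3 <= nchar(ctx_seq) - 1) substr(ctx_seq, i + 4, i + 4) else ""
  n <- (m3 %in% c("A", "G")) + (p4 == "G")
  c("weak", "moderate", "strong")[n + 1]
}

# consequence of one single-base substitution, re-derived from scratch by
# diffing the two oracle-scanned architectures (no indels, so coordinates
# map by identity)
oracle_classify_sub <- function(seq, cds, off, alt_base) {
  L <- nchar(seq)
  alt_seq <- paste0(substr(seq, 1, off), alt_base, substr(seq, off + 2, L))
  ref_sc <- oracle_scan(seq)
  alt_sc <- oracle_scan(alt_seq)
  atg_at <- function(s, i) i <= nchar(s) - 3 && substr(s, i + 1, i + 3) == "ATG"
  codes <- character()
  for (k in seq_len(nrow(ref_sc))) {
    r <- ref_sc[k, ]
    if (!atg_at(alt_seq, r$start_offset)) {
      codes <- c(codes, "uStart_lost")
      next
    }
    a <- alt_sc[alt_sc$start_offset == r$start_offset, ]
    if (nrow(a) == 1) {
      if (a$end_offset == r$end_offset) {
        if (a$peptide != r$peptide) {
          codes <- c(codes, "uAA_substitution")
        } else if (off >= r$start_offset && off <= r$end_offset) {
          codes <- c(codes, "uSynonymous")
        }
      } else if (a$end_offset > r$end_offset) {
        codes <- c(codes, "uStop_lost_extension")
      } else {
        codes <- c(codes, "uAA_substitution") # premature internal stop
      }
    } else {
      codes <- c(codes, "uStop_lost_oORF")
    }
    full_ref <- paste0(seq, cds)
    full_alt <- paste0(alt_seq, cds)
    if (oracle_kozak(full_ref, r$start_offset) !=
        oracle_kozak(full_alt, r$start_offset)) {
      codes <- c(codes, "kozak_changed_uORF")
    }
  }
  for (i in 0:(L - 3)) {
    if (atg_at(alt_seq, i) && !atg_at(seq, i)) {
      ext <- oracle_extent(alt_seq, cds, i)
      codes <- c(codes, switch(ext,
        contained_uorf = "uAUG_created_uORF",
        overlapping_oorf = "uAUG_created_oORF",
        n_terminal_extension = "uAUG_created_NTE"
      ))
    }
  }
  if (oracle_kozak(paste0(seq, cds), L) != oracle_kozak(paste0(alt_seq, cds), L)) {
    codes <- c(codes, "kozak_changed_mORF")
  }
  if (!length(codes)) return("no_uorf_change")
  codes[which.min(match(codes, uorfkit::CONSEQUENCE_SEVERITY))]
}

oracle_pair_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  num <- 0
  den <- 0
  for (i in seq_along(av)) {
    if (av[i] == "-" && bv[i] == "-") next
    den <- den + 1
    if (av[i] == bv[i]) num <- num + 1
  }
  100 * num / den
}

oracle_mean_identity <- function(peps) {
  pr <- combn(length(peps), 2)
  mean(apply(pr, 2, function(ij) oracle_pair_identity(peps[ij[1]], peps[ij[2]])))
}
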