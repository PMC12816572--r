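#' Parse HGVS-like c. variant notation
#'
#' Supports the subset of HGVS `c.` syntax needed for 5'UTR work:
#' substitutions (`c.-52C>T`), single-position duplications (`c.-69dupG`),
#' insertions between adjacent bases (`c.-10_-9insTT`), and deletions
#' (`c.-20del`, `c.-20_-18del`). A Unicode minus sign is accepted. All
#' affected positions must be UTR positions (negative `c.` values); `c.0`
#' does not exist and is rejected.
#'
#' Duplications are later normalised to the 3'-most equivalent position on
#' the transcript strand when resolved against a sequence (see
#' [apply_variant()]).
#'
#' @param text Character vector of variant strings.
#' @return A tibble with columns `label`, `kind` (`substitution`,
#'   `duplication`, `insertion`, `deletion`), `c_start`, `c_end`, `ref`,
#'   `alt`, `seq` (inserted/duplicated bases).
#' @examples
#' parse_hgvs_c(c("c.-69dupG", "c.-52C>T"))
#' @export
parse_hgvs_c <- function(text) {
  text <- as.character(text)
  norm <- gsub("−|–", "-", text)
  one <- function(tok, label) {
    chk_pos <- function(p) {
      p <- as.integer(p)
      if (any(p == 0L)) stop(sprintf("'%s': there is no c.0", label), call. = FALSE)
      p
    }
    m <- regmatches(tok, regexec("^c\\.(-?[0-9]+)([ACGT])>([ACGT])$", tok))[[1]]
    if (length(m)) {
      p <- chk_pos(m[2])
      return(tibble::tibble(label = label, kind = "substitution",
                            c_start = p, c_end = p, ref = m[3], alt = m[4],
                            seq = NA_character_))
    }
    m <- regmatches(tok, regexec("^c\\.(-?[0-9]+)dup([ACGT]+)$", tok))[[1]]
    if (length(m)) {
      p <- chk_pos(m[2])
      if (nchar(m[3]) != 1) {
        stop(sprintf("'%s': only single-base duplications are supported", label),
             call. = FALSE)
      }
      return(tibble::tibble(label = label, kind = "duplication",
                            c_start = p, c_end = p, ref = m[3],
                            alt = NA_character_, seq = m[3]))
    }
    m <- regmatches(tok, regexec("^c\\.(-?[0-9]+)_(-?[0-9]+)ins([ACGT]+)$", tok))[[1]]
    if (length(m)) {
      p1 <- chk_pos(m[2]); p2 <- chk_pos(m[3])
      if (p2 != p1 + 1L) {
        stop(sprintf("'%s': insertion positions must be adjacent", label), call. = FALSE)
      }
      return(tibble::tibble(label = label, kind = "insertion",
                            c_start = p1, c_end = p2, ref = NA_character_,
                            alt = NA_character_, seq = m[4]))
    }
    m <- regmatches(tok, regexec("^c\\.(-?[0-9]+)(?:_(-?[0-9]+))?del([ACGT]*)$", tok))[[1]]
    if (length(m)) {
      p1 <- chk_pos(m[2])
      p2 <- if (nzchar(m[3])) chk_pos(m[3]) else p1
      if (p2 < p1) stop(sprintf("'%s': deletion end before start", label), call. = FALSE)
      return(tibble::tibble(label = label, kind = "deletion",
                            c_start = p1, c_end = p2,
                            ref = if (nzchar(m[4])) m[4] else NA_character_,
                            alt = NA_character_, seq = NA_character_))
    }
    stop(sprintf("cannot parse variant token '%s'", label), call. = FALSE)
  }
  dplyr::bind_rows(purrr::map2(norm, text, one))
}

# coerce character vector or parsed tibble to a parsed tibble (internal)
as_variant_tbl <- function(variants) {
  if (is.character(variants)) return(parse_hgvs_c(variants))
  stopifnot(is.data.frame(variants))
  tibble::as_tibble(variants)
}

# resolve parsed variants against a sequence: verify ref alleles, 3'-normalise
# duplications, attach 0-based offsets, and check for overlap (internal)
resolve_variants <- function(utr, variants) {
  if (is.data.frame(variants) && all(c("offset", "shift") %in% names(variants))) {
    return(tibble::as_tibble(variants)) # already resolved
  }
  v <- as_variant_tbl(variants)
  if (nrow(v) == 0) return(cbind(v, tibble::tibble(offset = integer(), end_offset = integer(), shift = integer())))
  L <- utr_length(utr)
  base_at <- function(off) substr(utr$seq, off + 1L, off + 1L)
  rows <- purrr::pmap(v, function(label, kind, c_start, c_end, ref, alt, seq, ...) {
    if (c_start < -L || c_start > -1L || c_end < -L || c_end > -1L) {
      stop(sprintf("'%s': positions must lie within the UTR [c.-%d, c.-1]", label, L),
           call. = FALSE)
    }
    off <- c_to_offset(c_start, L)
    if (kind == "substitution") {
      found <- base_at(off)
      if (found != ref) {
        stop(sprintf("'%s': reference mismatch at c.%d (expected %s, found %s)",
                     label, c_start, ref, found), call. = FALSE)
      }
      return(tibble::tibble(label = label, kind = kind, offset = off,
                            end_offset = off, ref = ref, alt = alt,
                            seq = NA_character_, shift = 0L))
    }
    if (kind == "duplication") {
      found <- base_at(off)
      if (found != seq) {
        stop(sprintf("'%s': reference mismatch at c.%d (expected %s, found %s)",
                     label, c_start, seq, found), call. = FALSE)
      }
      # 3'-most equivalent position: slide across an identical run
      while (off + 1L <= L - 1L && base_at(off + 1L) == seq) off <- off + 1L
      return(tibble::tibble(label = label, kind = kind, offset = off,
                            end_offset = off, ref = seq, alt = NA_character_,
                            seq = seq, shift = 1L))
    }
    if (kind == "insertion") {
      return(tibble::tibble(label = label, kind = kind, offset = off,
                            end_offset = off, ref = NA_character_,
                            alt = NA_character_, seq = seq,
                            shift = nchar(seq)))
    }
    # deletion
    off2 <- c_to_offset(c_end, L)
    if (!is.na(ref)) {
      found <- substr(utr$seq, off + 1L, off2 + 1L)
      if (found != ref) {
        stop(sprintf("'%s': reference mismatch at c.%d_%d (expected %s, found %s)",
                     label, c_start, c_end, ref, found), call. = FALSE)
      }
    }
    tibble::tibble(label = label, kind = kind, offset = off, end_offset = off2,
                   ref = ref, alt = NA_character_, seq = NA_character_,
                   shift = -(off2 - off + 1L))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 1) {
    o <- out[order(out$offset), ]
    for (i in seq_len(nrow(o) - 1)) {
      if (o$end_offset[i] >= o$offset[i + 1]) {
        stop(sprintf("variants '%s' and '%s' overlap", o$label[i], o$label[i + 1]),
             call. = FALSE)
      }
    }
  }
  out
}

#' Apply 5'UTR variants to a sequence
#'
#' Edits the UTR with one or more non-overlapping variants. Reference alleles
#' are verified against the sequence before editing; multiple variants are
#' applied 3'->5' so that upstream length changes never invalidate downstream
#' coordinates (supporting "in phase" combinations such as a duplication plus
#' a downstream substitution).
#'
#' @param utr A [utr_sequence()].
#' @param variants Character vector of HGVS-like `c.` strings or a tibble
#'   from [parse_hgvs_c()].
#' @return The edited [utr_sequence()] (CDS prefix unchanged).
#' @examples
#' utr <- utr_sequence("AAGATGCCCTAAGGG", "ATGGCTGCTGCT")
#' utr_length(apply_variant(utr, "c.-10dupC"))
#' @export
apply_variant <- function(utr, variants) {
  stopifnot(inherits(utr, "utr_sequence"))
  rv <- resolve_variants(utr, variants)
  if (nrow(rv) == 0) return(utr)
  s <- utr$seq
  rv <- rv[order(rv$offset, decreasing = TRUE), ]
  for (i in seq_len(nrow(rv))) {
    off <- rv$offset[i]
    s <- switch(rv$kind[i],
      substitution = paste0(substr(s, 1, off), rv$alt[i], substr(s, off + 2, nchar(s))),
      duplication = paste0(substr(s, 1, off + 1), rv$seq[i], substr(s, off + 2, nchar(s))),
      insertion = paste0(substr(s, 1, off + 1), rv$seq[i], substr(s, off + 2, nchar(s))),
      deletion = paste0(substr(s, 1, off), substr(s, rv$end_offset[i] + 2, nchar(s)))
    )
  }
  utr_sequence(s, utr$cds_prefix)
}

# reference -> alternate 0-based offset map for a resolved variant set
# (internal). Returns a vectorised function; deleted positions map to NA.
offset_map <- function(resolved) {
  function(ref_off) {
    vapply(ref_off, function(r) {
      if (is.na(r)) return(NA_integer_)
      shift <- 0L
      for (i in seq_len(nrow(resolved))) {
        k <- resolved$kind[i]
        if (k %in% c("duplication", "insertion")) {
          if (r > resolved$offset[i]) shift <- shift + resolved$shift[i]
        } else if (k == "deletion") {
          if (r >= resolved$offset[i] && r <= resolved$end_offset[i]) return(NA_integer_)
          if (r > resolved$end_offset[i]) shift <- shift + resolved$shift[i]
        }
      }
      r + shift
    }, integer(1))
  }
}
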