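test_that("the HGVS c. subset parses and rejects what it should", {
  v <- parse_hgvs_c(c("c.-69dupG", "c.-52C>T", "c.-10_-9insTT", "c.-20_-18del"))
  expect_equal(v$kind, c("duplication", "substitution", "insertion", "deletion"))
  expect_equal(v$c_start, c(-69L, -52L, -10L, -20L))
  expect_equal(v$ref[2], "C")
  expect_equal(v$alt[2], "T")
  expect_equal(v$seq[3], "TT")
  # the Unicode minus used in printed notation is accepted
  expect_equal(parse_hgvs_c("c.−69dupG")$kind, "duplication")
  expect_error(parse_hgvs_c("c.0A>T"), "no c\\.0")
  expect_error(parse_hgvs_c("c.-5inv"), "cannot parse")
  expect_error(parse_hgvs_c("c.-10_-8insAA"), "adjacent")
})

test_that("variants apply 3'->5' with reference checking", {
  expect_equal(utr_length(apply_variant(FX$utr, "c.-69dupG")), 210L)
  both <- apply_variant(FX$utr, c("c.-69dupG", "c.-59C>A"))
  expect_equal(utr_length(both), 210L)
  # the downstream substitution lands at its original base despite the
  # upstream length change (c.-59 is offset 150 in reference coordinates,
  # 151 after the duplication)
  expect_equal(substr(both$seq, 152, 152), "A")
  expect_error(apply_variant(FX$utr, "c.-52G>A"), "reference mismatch")
  expect_error(apply_variant(FX$utr, c("c.-69dupG", "c.-69G>A")), "overlap")
  # applying a variant then its exact inverse restores the reference
  fwd <- apply_variant(FX$utr, "c.-52C>T")
  back <- apply_variant(fwd, "c.-52T>C")
  expect_identical(back$seq, FX$utr$seq)
  expect_equal(classify_consequence(back, character())$primary_code,
               "no_uorf_change")
})

test_that("duplications normalise to the 3'-most equivalent position", {
  utr <- utr_sequence("AACGGGTAACC", "ATGG")
  # c.-8dupG sits at the start of a GGG run; all equivalent representations
  # must produce the same edited sequence
  a <- apply_variant(utr, "c.-8dupG")$seq
  b <- apply_variant(utr, "c.-6dupG")$seq
  expect_identical(a, b)
  expect_equal(a, "AACGGGGTAACC")
})

test_that("the characterised construct panel reproduces its consequence codes", {
  cc <- classify_consequence(FX$utr, "c.-69dupG")
  expect_equal(cc$primary_code, "uStop_lost_oORF")
  expect_true("uFrameshift" %in% cc$secondary_codes)
  expect_equal(cc$affected_uorf, 1L)
  expect_equal(cc$details$readthrough, "beyond_cds_prefix")

  r1 <- classify_consequence(FX$utr, c("c.-69dupG", "c.-59C>A"))
  expect_equal(r1$primary_code, "uStop_lost_extension")
  expect_equal(r1$details$new_stop_to_maug_gap, 58L)
  expect_false(r1$details$stop_in_other_uorf)

  r2 <- classify_consequence(FX$utr, c("c.-69dupG", "c.-8C>A"))
  expect_equal(r2$primary_code, "uStop_lost_extension")
  expect_equal(r2$details$new_stop_to_maug_gap, 7L)
  expect_true(r2$details$stop_in_other_uorf) # the new stop lies inside uORF2

  expect_equal(classify_consequence(FX$utr, "c.-52C>T")$primary_code,
               "no_uorf_change")
  expect_equal(classify_consequence(FX$utr, "c.-209G>A")$primary_code,
               "no_uorf_change")

  ko1 <- classify_consequence(FX$utr, "c.-86T>C")
  expect_equal(ko1$primary_code, "uStart_lost")
  expect_equal(ko1$affected_uorf, 1L)
  ko2 <- classify_consequence(FX$utr, "c.-19T>C")
  expect_equal(ko2$primary_code, "uStart_lost")
  expect_equal(ko2$affected_uorf, 2L)
  both <- classify_consequence(FX$utr, c("c.-86T>C", "c.-19T>C"))
  expect_equal(both$primary_code, "uStart_lost") # both uORFs knocked out
})

test_that("an empty variant list is a no-op call", {
  expect_equal(classify_consequence(FX$utr, character())$primary_code,
               "no_uorf_change")
  set.seed(12)
  for (i in 1:10) {
    expect_equal(classify_consequence(random_utr(60), character())$primary_code,
                 "no_uorf_change")
  }
})

test_that("stop-loss extensions report plausible gaps", {
  # for every uStop_lost_extension found among random edits, the new gap is
  # non-negative and smaller than the reference gap plus the indel length
  set.seed(77)
  found <- 0
  while (found < 10) {
    utr <- random_utr(150)
    sc <- scan_uorfs(utr)
    if (!nrow(sc)) next
    # disrupt the first uORF's stop codon
    stop_off <- sc$end_offset[1] - 2
    base <- substr(utr$seq, stop_off + 1, stop_off + 1)
    cc <- classify_consequence(
      utr, sprintf("c.%d%s>C", stop_off - 150, base)
    )
    if (cc$primary_code != "uStop_lost_extension") next
    found <- found + 1
    gap <- cc$details$new_stop_to_maug_gap
    expect_gte(gap, 0)
    expect_lt(gap, sc$stop_to_maug_gap[1])
  }
})

test_that("classifier agrees with the independent diff oracle on random edits", {
  set.seed(501)
  n_checked <- 0
  while (n_checked < 200) {
    utr <- random_utr(sample(60:200, 1))
    L <- utr_length(utr)
    off <- sample(0:(L - 1), 1)
    ref_base <- substr(utr$seq, off + 1, off + 1)
    alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    hgvs <- sprintf("c.%d%s>%s", off - L, ref_base, alt_base)
    got <- classify_consequence(utr, hgvs)$primary_code
    want <- oracle_classify_sub(utr$seq, utr$cds_prefix, off, alt_base)
    expect_equal(got, want, label = sprintf("%s on %s", hgvs, utr$seq))
    n_checked <- n_checked + 1
  }
})

test_that("tidy() and classify_variants() present calls as tidy rows", {
  tt <- tidy(classify_consequence(FX$utr, c("c.-69dupG", "c.-59C>A")))
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$new_stop_to_maug_gap, 58L)
  tbl <- classify_variants(FX$utr, variant_panel())
  expect_equal(nrow(tbl), 9L)
  expect_equal(
    tbl$primary_code,
    c("no_uorf_change", "uStop_lost_oORF", "uStop_lost_extension",
      "uStop_lost_extension", "no_uorf_change", "no_uorf_change",
      "uStart_lost", "uStart_lost", "uStart_lost")
  )
})
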