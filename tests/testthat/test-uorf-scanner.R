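test_that("the PKD1-like fixture carries the two characterised uORFs", {
  sc <- scan_uorfs(FX$utr)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$peptide, c("MPSAGPA", "MRALP"))
  expect_equal(sc$cap_to_uaug, c(122L, 189L))
  expect_equal(sc$stop_to_maug_gap, c(63L, 2L))
  expect_equal(sc$frame_vs_morf, c("in_frame", "out_of_frame"))
  expect_equal(sc$n_aa, c(7L, 5L))
  expect_equal(sc$kozak, c("moderate", "moderate"))
})

test_that("a UTR without ATG yields an empty scan", {
  sc <- scan_uorfs(utr_sequence("AAATTTCCC", "ATGGAAGAA"))
  expect_equal(nrow(sc), 0L)
  expect_true(all(c("start_offset", "peptide", "stop_to_maug_gap") %in% names(sc)))
})

test_that("scanner agrees with the brute-force oracle on random UTRs", {
  set.seed(401)
  for (i in 1:150) {
    utr <- random_utr(sample(50:400, 1))
    sc <- scan_uorfs(utr)
    orc <- oracle_scan(utr$seq)
    expect_equal(sc$start_offset, orc$start_offset)
    expect_equal(sc$end_offset, orc$end_offset)
    expect_equal(sc$peptide, orc$peptide)
    expect_equal(sc$frame_vs_morf == "in_frame", orc$in_frame)
    expect_equal(sc$stop_to_maug_gap, orc$gap)
    # in-frame call is divisibility of the uAUG->mAUG distance by 3
    expect_equal(sc$frame_vs_morf == "in_frame",
                 (utr_length(utr) - sc$start_offset) %% 3 == 0)
  }
})

test_that("ORF extent distinguishes contained, overlapping and N-terminal cases", {
  expect_equal(classify_orf_extent(FX$utr, 122), "contained_uorf")
  expect_equal(classify_orf_extent(FX$utr, 189), "contained_uorf")
  # after the patient duplication the former uORF1 reads through the main AUG
  dup <- apply_variant(FX$utr, "c.-69dupG")
  expect_equal(classify_orf_extent(dup, 122), "overlapping_oorf")
  # constructed: ATG in frame with the main ORF, stopless tail
  nte <- utr_sequence("CCCATGGCCGCC", "ATGGAAGAAGAA")
  expect_equal(classify_orf_extent(nte, 3), "n_terminal_extension")
  expect_error(classify_orf_extent(FX$utr, 10), "no ATG")
})

test_that("Kozak strength depends on exactly the -3 and +4 bases", {
  expect_equal(as.character(kozak_class("GCCATGG", 3)), "strong")
  expect_equal(as.character(kozak_class("TTTATGC", 3)), "weak")
  expect_equal(as.character(kozak_class("GGGATGC", 3)), "moderate")
  expect_equal(as.character(kozak_class("TTTATGG", 3)), "moderate")
  # permuting every other context base never changes the class
  set.seed(42)
  for (i in 1:25) {
    pre <- random_utr_seq(5)
    post <- random_utr_seq(4)
    for (m3 in c("A", "C")) {
      ctx1 <- paste0(pre, m3, "AA", "ATG", "G", post)
      ctx2 <- paste0(random_utr_seq(5), m3, random_utr_seq(2), "ATG", "G",
                     random_utr_seq(4))
      expect_equal(as.character(kozak_class(ctx1, 8)),
                   as.character(kozak_class(ctx2, 8)))
    }
  }
  # truncated context is flagged, not fatal
  kz <- kozak_class("ATGG", 0)
  expect_true(attr(kz, "incomplete"))
  expect_equal(as.character(kz), "moderate")
})

test_that("kozak class of both fixture uAUGs reflects G at -3 and C at +4", {
  sc <- scan_uorfs(FX$utr)
  for (s in sc$start_offset) {
    expect_equal(substr(FX$utr$seq, s - 2, s - 2), "G")
    expect_equal(substr(FX$utr$seq, s + 4, s + 4), "C")
  }
})
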