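test_that("conservation gate calls codons by basewise-OR-elementwise rule", {
  uorfs <- tibble::tibble(start_offset = 10L, end_offset = 21L)
  mk_track <- function(bw_vals, ew_vals = NULL) {
    offs <- c(10:12, 19:21)
    conservation_track(
      basewise = tibble::tibble(cap_offset = offs, score = bw_vals),
      elementwise = if (!is.null(ew_vals)) {
        tibble::tibble(cap_offset = offs, score = ew_vals)
      }
    )
  }
  # all three start-codon bases above 2.0 -> conserved
  g <- conservation_gate(uorfs, mk_track(c(3.1, 2.5, 4.0, 5, 5, 5)))
  expect_true(g$conserved_start)
  expect_true(g$conserved_stop)
  # one base below the basewise threshold and weak elementwise -> not conserved
  g <- conservation_gate(uorfs, mk_track(c(1.9, 3.0, 3.0, 5, 5, 5),
                                         c(0.5, 0.5, 0.5, 0.9, 0.9, 0.9)))
  expect_false(g$conserved_start)
  expect_true(g$conserved_stop)
  # elementwise channel can rescue a failing basewise call
  g <- conservation_gate(uorfs, mk_track(c(1.9, 3.0, 3.0, 5, 5, 5),
                                         c(0.9, 0.95, 0.9, 0.9, 0.9, 0.9)))
  expect_true(g$conserved_start)
})

test_that("partial coverage warns and leaves flags NA; no track leaves them NA", {
  uorfs <- tibble::tibble(start_offset = 10L, end_offset = 21L)
  partial <- conservation_track(
    basewise = tibble::tibble(cap_offset = c(10, 11), score = c(5, 5))
  )
  expect_warning(g <- conservation_gate(uorfs, partial), "partially covers")
  expect_true(is.na(g$conserved_start))
  sc <- scan_uorfs(FX$utr)
  expect_true(all(is.na(sc$conserved_start)))
})

test_that("simulated conservation plants recoverable boundary codons", {
  sc <- scan_uorfs(FX$utr)
  track <- simulate_conservation(sc, utr_length(FX$utr), seed = 7)
  gated <- conservation_gate(sc, track)
  expect_true(all(gated$conserved_start))
  expect_true(all(gated$conserved_stop))
  # raising the thresholds above the planted scores turns the flags off
  strict <- track
  strict$basewise_min <- 10
  strict$elementwise_min <- 1.5
  gated2 <- conservation_gate(sc, strict)
  expect_false(any(gated2$conserved_start))
  expect_false(any(gated2$conserved_stop))
  # seeded reproducibility
  track_b <- simulate_conservation(sc, utr_length(FX$utr), seed = 7)
  expect_identical(track$basewise, track_b$basewise)
})

test_that("mean percent identity matches the pairwise counting oracle", {
  expect_equal(peptide_identity_class(c("MPSAGPA", "MPSAGPA")),
               list(mean_identity = 100, class = "high"))
  r <- peptide_identity_class(c("MRALP", "MRTLP"))
  expect_equal(r$mean_identity, 80)
  expect_equal(r$class, "high")      # exactly 80 -> high
  r <- peptide_identity_class(c("MAAAAA", "MAA---"))
  expect_equal(r$mean_identity, 50)
  expect_equal(r$class, "moderate")  # exactly 50 -> moderate
  expect_equal(peptide_identity_class(c("MKLV", "AAAA"))$class, "weak")
  expect_error(peptide_identity_class("MRALP"), "at least two")
  expect_error(peptide_identity_class(c("MR", "MRA")), "same length")

  set.seed(11)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  for (i in 1:40) {
    n <- sample(2:5, 1)
    len <- sample(4:12, 1)
    peps <- vapply(seq_len(n), function(j) {
      paste(sample(aa, len, replace = TRUE), collapse = "")
    }, "")
    expect_equal(peptide_identity_class(peps)$mean_identity,
                 oracle_mean_identity(peps))
  }
})
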