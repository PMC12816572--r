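test_that("fixture generation is deterministic per seed and always validates", {
  fx_a <- generate_fixture(seed = 1)
  expect_identical(fx_a$utr$seq, FX$utr$seq)
  expect_identical(fx_a$utr$cds_prefix, FX$utr$cds_prefix)
  for (s in c(2, 3, 11, 123)) {
    fx <- generate_fixture(seed = s)
    expect_true(all(validate_fixture(fx)$pass), label = sprintf("seed %d", s))
  }
})

test_that("the validator catches broken fixtures", {
  rep0 <- validate_fixture(FX)
  expect_true(all(rep0$pass))
  # destroy uAUG1
  broken <- FX$utr
  broken$seq <- paste0(substr(broken$seq, 1, 122), "C",
                       substr(broken$seq, 124, 209))
  rep1 <- validate_fixture(utr_sequence(broken$seq, broken$cds_prefix))
  expect_false(rep1$pass[rep1$constraint == "exactly_two_uorfs"])
  # plant an extra uORF (ATG...TAA) in the inter-uORF spacer
  extra <- FX$utr$seq
  substr(extra, 161, 166) <- "ATGTAA"
  rep2 <- validate_fixture(utr_sequence(extra, FX$utr$cds_prefix))
  expect_false(rep2$pass[rep2$constraint == "exactly_two_uorfs"])
})

test_that("zero-noise assay simulation recovers the planted means exactly", {
  cfg <- assay_sim_config("combined", transfection_sdlog = 0,
                          measurement_sdlog = 0)
  norm <- normalize_assay(simulate_assay(cfg, seed = 5))
  means <- tapply(norm$relative_activity, norm$construct, mean)
  expect_equal(means[names(cfg$constructs)], cfg$constructs,
               tolerance = 1e-12, ignore_attr = TRUE)
  # transfection noise alone is cancelled by SeAP normalisation
  cfg2 <- assay_sim_config("combined", transfection_sdlog = 0.5,
                           measurement_sdlog = 0)
  norm2 <- normalize_assay(simulate_assay(cfg2, seed = 5))
  means2 <- tapply(norm2$relative_activity, norm2$construct, mean)
  expect_equal(means2[names(cfg2$constructs)], cfg2$constructs,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("assay simulation is reproducible per seed and has the stated shape", {
  a <- simulate_assay(seed = 9)
  b <- simulate_assay(seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 6 * 12 * 2) # constructs x transfections x duplicates
  counts <- dplyr::count(a, construct, experiment)
  expect_true(all(counts$n == 12)) # 6 transfections x 2 duplicates per experiment
})

test_that("the variant panel round-trips through plus-strand VCF", {
  panel <- variant_panel()
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(panel, FX$utr, FX$model, vcf_path)
  back <- read_variants_vcf(vcf_path, FX$model, FX$utr)
  simple <- sort(unique(trimws(unlist(strsplit(na.omit(panel$hgvs), "[;+]")))))
  expect_equal(sort(back$hgvs), simple)

  # the duplication is written as an insertion after the plus-strand anchor,
  # one base away from the transcript-orientation position
  dup <- back[grepl("dup", back$hgvs), ]
  expect_equal(dup$hgvs, "c.-69dupG")
  expect_equal(dup$pos, 2135757L)
  expect_equal(nchar(dup$alt) - nchar(dup$ref), 1L)
  expect_equal(substr(dup$alt, 2, 2), "C")

  # VCF REF bases match the plus-strand rendering of the fixture
  plus_strand <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(FX$utr$seq))
  )
  for (i in which(nchar(back$ref) == 1)) {
    off_plus <- back$pos[i] - FX$model$utr5_start
    expect_equal(back$ref[i], substr(plus_strand, off_plus + 1, off_plus + 1))
  }

  # applying the round-tripped variants reproduces the panel's codes
  codes <- classify_variants(FX$utr, tibble::tibble(hgvs = back$hgvs))
  expect_true("uStop_lost_oORF" %in% codes$primary_code)
})

test_that("panel TSV writer emits a readable table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(variant_panel(), path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$hgvs[2], "c.-69dupG")
})

test_that("the generator refuses rather than relaxes unsatisfiable budgets", {
  expect_error(generate_fixture(seed = 1, max_attempts = 1),
               "try a different seed")
})
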