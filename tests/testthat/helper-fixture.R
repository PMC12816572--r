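# one shared fixture for the whole suite (deterministic; seed 1)
FX <- uorfkit::generate_fixture(seed = 1)

random_utr <- function(len, cds_len = 30) {
  uorfkit::utr_sequence(random_utr_seq(len), random_cds_prefix(cds_len))
}
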