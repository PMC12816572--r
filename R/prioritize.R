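#' Maximum credible population allele frequency
#'
#' For a heterozygous (dominant) disease, the highest population allele
#' frequency a pathogenic variant could plausibly reach is
#' `prevalence * genetic_heterogeneity * allelic_heterogeneity /
#' (2 * penetrance)`: the prevalence is apportioned to the gene (genetic
#' heterogeneity) and to the single most common pathogenic allele (allelic
#' heterogeneity), halved to convert a genotype frequency to an allele
#' frequency in heterozygotes, and inflated by incomplete penetrance.
#'
#' With the defaults (prevalence 1/1000, allelic heterogeneity 0.1, genetic
#' heterogeneity 0.9, penetrance 0.75) the threshold is 6e-05.
#'
#' @param prevalence Disease prevalence (proportion, in (0, 1]).
#' @param allelic_heterogeneity Maximum share of disease alleles attributable
#'   to one variant.
#' @param genetic_heterogeneity Share of cases attributable to the gene.
#' @param penetrance Penetrance (in (0, 1]); 0 is an error.
#' @param inheritance Currently only `"heterozygous"`.
#' @return Allele frequency (numeric scalar).
#' @examples
#' max_credible_af(0.001, 0.1, 0.9, 0.75)
#' @export
max_credible_af <- function(prevalence = 0.001, allelic_heterogeneity = 0.1,
                            genetic_heterogeneity = 0.9, penetrance = 0.75,
                            inheritance = "heterozygous") {
  inheritance <- match.arg(inheritance)
  vals <- c(
    prevalence = prevalence, allelic_heterogeneity = allelic_heterogeneity,
    genetic_heterogeneity = genetic_heterogeneity, penetrance = penetrance
  )
  if (penetrance <= 0) stop("penetrance must be > 0", call. = FALSE)
  if (any(vals <= 0 | vals > 1)) {
    stop("all parameters must lie in (0, 1]", call. = FALSE)
  }
  prevalence * genetic_heterogeneity * allelic_heterogeneity / (2 * penetrance)
}

#' Rarity filter on a population allele frequency
#'
#' A variant passes when its allele frequency annotation is absent (never
#' observed in the population database, hence rare) or strictly below the
#' threshold.
#'
#' @param af Allele frequency vector (NA = unobserved).
#' @param threshold Review threshold (default 0.001).
#' @return Logical vector.
#' @export
rarity_filter <- function(af, threshold = 0.001) {
  if (any(!is.na(af) & af < 0)) stop("allele frequency cannot be negative", call. = FALSE)
  is.na(af) | af < threshold
}

PDC_CODES <- c("uAUG_created_uORF", "uAUG_created_oORF",
               "uStop_lost_extension", "uStop_lost_oORF")

criteria_for_codes <- function(codes) {
  crit <- character()
  if (any(codes %in% c("uAUG_created_uORF", "uAUG_created_oORF"))) {
    crit <- c(crit, "AUG_creating")
  }
  if (any(codes %in% c("uStop_lost_extension", "uStop_lost_oORF"))) {
    crit <- c(crit, "stop_disrupting")
  }
  if ("uAUG_created_NTE" %in% codes) crit <- c(crit, "NTE")
  if ("uAA_substitution" %in% codes) crit <- c(crit, "uorf_missense")
  if (any(codes %in% c("kozak_changed_uORF", "kozak_changed_mORF"))) {
    crit <- c(crit, "kozak_alteration")
  }
  if ("uStart_lost" %in% codes) crit <- c(crit, "uorf_start_loss")
  crit
}

#' Assign a prioritisation tier to a classified variant
#'
#' Rare variants whose consequence codes include AUG creation (uORF or
#' overlapping ORF) or uORF stop disruption are tiered
#' `potentially_disease_causing`. Rare variants meeting any of the
#' uncertain-significance criteria - N-terminal extension, amino-acid change
#' within a uORF, Kozak-class alteration of a uORF or the main ORF, uORF
#' start loss - or any other rare 5'UTR variant (catch-all) are
#' `uncertain_significance`. Variants failing the rarity filter are
#' `not_prioritised`.
#'
#' @param primary_code,secondary_codes Consequence codes (see
#'   [classify_consequence()]).
#' @param af Population allele frequency (NA = unobserved).
#' @param splice_score Optional splice-prediction score.
#' @param rarity_threshold Review threshold (default 0.001).
#' @param credible_af Maximum credible allele frequency for the
#'   population-database screen (default [max_credible_af()] with the
#'   package defaults, 6e-05).
#' @param splice_threshold Splice flag threshold (default 0.05).
#' @return One-row tibble: `tier`, `criteria_met`, `passed_rarity`,
#'   `passed_credible_af`, `splice_flagged`.
#' @export
assign_tier <- function(primary_code, secondary_codes = character(),
                        af = NA_real_, splice_score = NA_real_,
                        rarity_threshold = 0.001,
                        credible_af = max_credible_af(),
                        splice_threshold = 0.05) {
  if (is.character(secondary_codes) && length(secondary_codes) == 1 &&
      grepl(";", secondary_codes)) {
    secondary_codes <- strsplit(secondary_codes, ";")[[1]]
  }
  codes <- c(primary_code, secondary_codes)
  codes <- codes[nzchar(codes)]
  passed_rarity <- rarity_filter(af, rarity_threshold)
  passed_credible <- rarity_filter(af, credible_af)
  crit <- criteria_for_codes(codes)
  tier <- if (!passed_rarity) {
    "not_prioritised"
  } else if (any(codes %in% PDC_CODES)) {
    "potentially_disease_causing"
  } else {
    "uncertain_significance"
  }
  vus_criteria <- c("NTE", "uorf_missense", "kozak_alteration", "uorf_start_loss")
  if (tier == "uncertain_significance" && !any(crit %in% vus_criteria)) {
    crit <- c(crit, "other_rare_5utr")
  }
  tibble::tibble(
    tier = tier,
    criteria_met = paste(crit, collapse = ";"),
    passed_rarity = passed_rarity,
    passed_credible_af = passed_credible,
    splice_flagged = !is.na(splice_score) && splice_score >= splice_threshold
  )
}

#' Prioritise a table of classified variants
#'
#' Joins [assign_tier()] results onto a [classify_variants()] table.
#'
#' @param consequences Tibble from [classify_variants()] (needs
#'   `primary_code`, `secondary_codes`, and optionally `af`,
#'   `splice_flagged` columns; a `splice_score` column is used if present).
#' @param rarity_threshold,credible_af,splice_threshold Thresholds; see
#'   [assign_tier()].
#' @return The input tibble with tier columns appended.
#' @export
prioritize_variants <- function(consequences, rarity_threshold = 0.001,
                                credible_af = max_credible_af(),
                                splice_threshold = 0.05) {
  consequences <- tibble::as_tibble(consequences)
  if (!"af" %in% names(consequences)) consequences$af <- NA_real_
  splice <- consequences[["splice_score"]]
  if (is.null(splice)) {
    flagged <- consequences[["splice_flagged"]] %||% rep(FALSE, nrow(consequences))
    splice <- ifelse(flagged %in% TRUE, splice_threshold, NA_real_)
  }
  tiers <- purrr::pmap(
    list(consequences$primary_code, consequences$secondary_codes,
         consequences$af, splice),
    function(p, s, af, sp) {
      assign_tier(p, s, af = af, splice_score = sp,
                  rarity_threshold = rarity_threshold,
                  credible_af = credible_af,
                  splice_threshold = splice_threshold)
    }
  )
  dplyr::bind_cols(
    consequences,
    dplyr::bind_rows(tiers) |>
      dplyr::select(-"splice_flagged")
  )
}
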