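#' Run the full 5'UTR variant-analysis pipeline
#'
#' Orchestrates the analysis stages in order: uORF scan (with optional
#' conservation gating), variant-consequence classification, rarity and
#' credible-allele-frequency prioritisation, and (when assay data are given)
#' reporter-assay statistics. Deterministic given inputs; every output table
#' carries the package version and a configuration hash.
#'
#' @param utr A [utr_sequence()] or the path of a FASTA file (UTR record +
#'   CDS-prefix record).
#' @param model A [transcript_model()] (default the PKD1-like anchoring).
#' @param variants A panel tibble (columns `hgvs`, optionally `construct`,
#'   `af`, `splice_score`), the path of such a TSV, or the path of a
#'   plus-strand VCF; `NULL` for a scan-only run.
#' @param conservation Optional [conservation_track()].
#' @param assay Optional assay table (see [normalize_assay()]) or CSV path.
#' @param af_params Named list passed to [max_credible_af()].
#' @param rarity_threshold,splice_threshold,alpha Thresholds for
#'   prioritisation and assay significance.
#' @param reference_construct Wildtype label in the assay table.
#' @return A list of class `uorf_pipeline`: `uorfs`, `consequences`,
#'   `prioritization`, `assay` (an `assay_fit` or `NULL`), `config`.
#' @export
run_pipeline <- function(utr, model = pkd1_transcript_model(),
                         variants = NULL, conservation = NULL, assay = NULL,
                         af_params = list(), rarity_threshold = 0.001,
                         splice_threshold = 0.05, alpha = 0.05,
                         reference_construct = "wildtype") {
  if (is.character(utr)) utr <- read_utr_fasta(utr)
  stopifnot(inherits(utr, "utr_sequence"))
  if (utr_length(utr) != model$utr_length) {
    stop(sprintf("UTR sequence length (%d) does not match the transcript model (%d)",
                 utr_length(utr), model$utr_length), call. = FALSE)
  }
  credible <- do.call(max_credible_af, af_params)

  uorfs <- scan_uorfs(utr, track = conservation)

  panel <- NULL
  if (!is.null(variants)) {
    if (is.character(variants) && length(variants) == 1) {
      panel <- if (grepl("\\.vcf$", variants, ignore.case = TRUE)) {
        vcf <- read_variants_vcf(variants, model, utr)
        tibble::tibble(construct = vcf$id, hgvs = vcf$hgvs)
      } else {
        tibble::as_tibble(utils::read.delim(variants,
                                            stringsAsFactors = FALSE,
                                            na.strings = c("NA", "")))
      }
    } else {
      panel <- tibble::as_tibble(variants)
    }
  }
  consequences <- if (is.null(panel) || nrow(panel) == 0) {
    classify_variants(utr, tibble::tibble(hgvs = character()),
                      splice_threshold = splice_threshold)
  } else {
    classify_variants(utr, panel, splice_threshold = splice_threshold)
  }
  prioritization <- if (nrow(consequences)) {
    prioritize_variants(consequences, rarity_threshold = rarity_threshold,
                        credible_af = credible,
                        splice_threshold = splice_threshold)
  } else {
    consequences
  }

  assay_fit <- NULL
  if (!is.null(assay)) {
    if (is.character(assay) && length(assay) == 1) {
      assay <- utils::read.csv(assay, stringsAsFactors = FALSE)
    }
    assay_fit <- assay_anova(
      normalize_assay(assay, wildtype = reference_construct),
      reference = reference_construct, alpha = alpha
    )
  }

  config <- list(
    version = as.character(utils::packageVersion("uorfkit")),
    transcript = model$transcript_id,
    rarity_threshold = rarity_threshold,
    credible_af = credible,
    splice_threshold = splice_threshold,
    alpha = alpha
  )
  config$hash <- rlang::hash(list(config, utr$seq, panel))
  structure(
    list(uorfs = uorfs, consequences = consequences,
         prioritization = prioritization, assay = assay_fit,
         config = config),
    class = "uorf_pipeline"
  )
}

#' @export
print.uorf_pipeline <- function(x, ...) {
  cat(sprintf("<uorf_pipeline> uorfkit %s, config %s\n",
              x$config$version, x$config$hash))
  cat(sprintf("  %d uORF(s); %d variant(s) classified\n",
              nrow(x$uorfs), nrow(x$consequences)))
  if (nrow(x$prioritization) && "tier" %in% names(x$prioritization)) {
    tab <- table(x$prioritization$tier)
    cat("  tiers: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$assay)) print(x$assay)
  invisible(x)
}

#' Write pipeline report tables
#'
#' Emits TSV tables (uORF report, per-variant consequences + tiers, Tukey
#' comparisons when assay data were analysed) and a JSON summary. Every table
#' starts with a comment header naming the tool version and configuration
#' hash.
#'
#' @param x A `uorf_pipeline` result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_pipeline_reports <- function(x, dir) {
  stopifnot(inherits(x, "uorf_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# uorfkit %s config_hash=%s", x$config$version, x$config$hash)
  write_tsv_stamped <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    write_tsv_stamped(x$uorfs, file.path(dir, "uorfs.tsv")),
    write_tsv_stamped(x$prioritization, file.path(dir, "variants.tsv"))
  )
  summary <- list(
    version = x$config$version, config = x$config[setdiff(names(x$config), "hash")],
    config_hash = x$config$hash,
    n_uorfs = nrow(x$uorfs),
    tiers = if ("tier" %in% names(x$prioritization)) {
      as.list(table(x$prioritization$tier))
    }
  )
  if (!is.null(x$assay)) {
    paths <- c(paths, write_tsv_stamped(tidy(x$assay), file.path(dir, "tukey.tsv")))
    summary$anova <- as.list(glance(x$assay))
  }
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, json_path))
}
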