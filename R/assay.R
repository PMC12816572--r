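#' Normalise a dual-reporter assay table
#'
#' Per-well Gaussia luciferase (GLuc) signals are normalised for transfection
#' efficiency by secreted alkaline phosphatase (SeAP) expressed from the same
#' construct: technical duplicates are averaged, the GLuc/SeAP ratio is
#' formed per transfection replicate, and each ratio is divided by the mean
#' wildtype ratio of the same experiment, so batch effects cancel and the
#' wildtype experiment-mean is 1 by construction. Analysis then proceeds on
#' this linear relative-activity scale with n = number of transfections (not
#' wells), avoiding pseudo-replication.
#'
#' @param table Data frame with columns `construct`, `experiment`,
#'   `replicate`, `duplicate`, `gluc`, `seap` (signals > 0).
#' @param wildtype Label of the wildtype construct (default `"wildtype"`).
#' @return Tibble with one row per (construct, experiment, replicate):
#'   `ratio` and `relative_activity`.
#' @export
normalize_assay <- function(table, wildtype = "wildtype") {
  table <- tibble::as_tibble(table)
  needed <- c("construct", "experiment", "replicate", "gluc", "seap")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("assay table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$gluc <= 0 | table$seap <= 0)) {
    stop("GLuc/SeAP signals must be positive", call. = FALSE)
  }
  per_exp <- unique(table$experiment)
  wt_present <- vapply(per_exp, function(e) {
    any(table$construct == wildtype & table$experiment == e)
  }, TRUE)
  if (!all(wt_present)) {
    stop(sprintf("wildtype construct '%s' missing from experiment(s): %s",
                 wildtype, paste(per_exp[!wt_present], collapse = ", ")),
         call. = FALSE)
  }
  ratios <- table |>
    dplyr::group_by(.data$construct, .data$experiment, .data$replicate) |>
    dplyr::summarise(
      ratio = mean(.data$gluc) / mean(.data$seap), .groups = "drop"
    )
  wt_means <- ratios |>
    dplyr::filter(.data$construct == wildtype) |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(wt_mean = mean(.data$ratio), .groups = "drop")
  ratios |>
    dplyr::left_join(wt_means, by = "experiment") |>
    dplyr::mutate(relative_activity = .data$ratio / .data$wt_mean) |>
    dplyr::select(-"wt_mean")
}

#' One-way ANOVA with Tukey HSD on relative activities
#'
#' Fits `relative_activity ~ construct` by ordinary one-way ANOVA and
#' computes all pairwise Tukey honestly-significant-difference comparisons
#' from the studentized-range distribution with the pooled within-group
#' variance. Mean differences are reported with the reference (wildtype)
#' first: `reference - other`, so a variant that reduces activity has a
#' positive difference against wildtype.
#'
#' @param normalized Tibble from [normalize_assay()] (needs `construct` and
#'   `relative_activity`).
#' @param reference Reference construct placed first in each contrast.
#' @param conf_level Confidence level for Tukey intervals.
#' @param alpha Significance level for the `significant` flag.
#' @return An `assay_fit` object; use [tidy.assay_fit()] for the pairwise
#'   table, [glance.assay_fit()] for the ANOVA summary,
#'   [autoplot.assay_fit()] for a mean +/- SEM bar chart.
#' @export
assay_anova <- function(normalized, reference = "wildtype",
                        conf_level = 0.95, alpha = 0.05) {
  normalized <- tibble::as_tibble(normalized)
  stopifnot(all(c("construct", "relative_activity") %in% names(normalized)))
  counts <- table(normalized$construct)
  if (length(counts) < 2) stop("need at least two constructs", call. = FALSE)
  if (any(counts < 2)) stop("need at least two observations per construct", call. = FALSE)
  vars <- tapply(normalized$relative_activity, normalized$construct, stats::var)
  if (all(vars == 0)) {
    stop("degenerate input: zero within-group variance in every construct",
         call. = FALSE)
  }
  lv <- unique(c(intersect(reference, normalized$construct),
                 sort(setdiff(unique(normalized$construct), reference))))
  dat <- data.frame(
    construct = factor(normalized$construct, levels = lv),
    relative_activity = normalized$relative_activity
  )
  fit <- stats::aov(relative_activity ~ construct, data = dat)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$construct
  # TukeyHSD rows follow combn(levels, 2) with difference = second - first;
  # rebuild the pairs from that ordering rather than parsing row labels
  pairs <- utils::combn(lv, 2)
  means <- tapply(dat$relative_activity, dat$construct, mean)
  tukey <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff_2_minus_1 = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
    adjusted_p = unname(tk[, "p adj"])
  ) |>
    dplyr::mutate(
      # orient as group1 - group2 with the reference always group1
      mean_difference = -.data$diff_2_minus_1,
      conf_low = -.data$upr, conf_high = -.data$lwr,
      contrast = paste(.data$group1, "-", .data$group2),
      significant = .data$adjusted_p < alpha,
      p_label = format_pvalue(.data$adjusted_p)
    ) |>
    dplyr::select("contrast", "group1", "group2", "mean_difference",
                  "conf_low", "conf_high", "adjusted_p", "p_label",
                  "significant")
  structure(
    list(
      fit = fit,
      tukey = tukey,
      reference = reference,
      alpha = alpha,
      f_statistic = sm[["F value"]][1],
      p_value = sm[["Pr(>F)"]][1],
      df = c(between = sm[["Df"]][1], within = sm[["Df"]][2]),
      group_means = tibble::tibble(
        construct = names(means),
        mean = unname(means),
        sem = unname(tapply(dat$relative_activity, dat$construct,
                            function(x) stats::sd(x) / sqrt(length(x)))),
        n = as.integer(counts[names(means)])
      )
    ),
    class = "assay_fit"
  )
}

#' Format p-values the way reporter-assay results are reported
#'
#' Values below `floor` print as `"<0.0001"`.
#'
#' @param p Numeric p-values.
#' @param floor Reporting floor (default 1e-4).
#' @return Character vector.
#' @export
format_pvalue <- function(p, floor = 1e-4) {
  ifelse(p < floor, paste0("<", format(floor, scientific = FALSE)),
         formatC(p, digits = 4, format = "fg"))
}

#' Signed percent change in activity relative to wildtype
#'
#' On the relative-activity scale (wildtype mean = 1), a mean difference
#' `d = wildtype - variant` corresponds to a `-100 * d` percent change:
#' reductions are negative, increases positive.
#'
#' @param mean_difference Wildtype-minus-variant mean difference(s).
#' @return Signed percent change.
#' @examples
#' percent_change(0.8678)  # ~ -87%
#' percent_change(-1.31)   # ~ +131%
#' @export
percent_change <- function(mean_difference) {
  -100 * mean_difference
}

#' @export
print.assay_fit <- function(x, ...) {
  cat(sprintf("<assay_fit> one-way ANOVA: F(%d, %d) = %.4g, p %s\n",
              x$df[["between"]], x$df[["within"]], x$f_statistic,
              format_pvalue(x$p_value)))
  ref_rows <- dplyr::filter(x$tukey, .data$group1 == x$reference |
                              .data$group2 == x$reference)
  cat(sprintf("Tukey HSD (vs %s):\n", x$reference))
  print(as.data.frame(ref_rows[c("contrast", "mean_difference", "p_label",
                                 "significant")]), row.names = FALSE)
  invisible(x)
}

#' Tidy the Tukey pairwise comparisons of an assay fit
#' @param x An `assay_fit`.
#' @param ... Unused.
#' @return Tibble of pairwise contrasts (reference-first orientation).
#' @export
tidy.assay_fit <- function(x, ...) x$tukey

#' One-row ANOVA summary of an assay fit
#' @param x An `assay_fit`.
#' @param ... Unused.
#' @return One-row tibble: F statistic, degrees of freedom, p-value, group
#'   and observation counts.
#' @export
glance.assay_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_statistic,
    df_between = x$df[["between"]],
    df_within = x$df[["within"]],
    p_value = x$p_value,
    n_groups = nrow(x$group_means),
    n_obs = sum(x$group_means$n)
  )
}

#' Bar chart of relative activities with SEM error bars
#' @param object An `assay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assay_fit <- function(object, ...) {
  gm <- object$group_means
  gm$construct <- factor(gm$construct,
                         levels = unique(c(object$reference, gm$construct)))
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$construct, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Relative luciferase activity (GLuc/SeAP, wildtype = 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
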