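make_table <- function(gluc_fun) {
  tidyr::expand_grid(
    construct = c("wildtype", "mut"),
    experiment = 1:2, replicate = 1:3, duplicate = 1:2
  ) |>
    dplyr::mutate(seap = 1000, gluc = gluc_fun(construct))
}

test_that("normalisation pins the wildtype experiment-mean to 1", {
  tab <- make_table(function(con) 500)
  norm <- normalize_assay(tab)
  expect_true(all(norm$relative_activity == 1))

  tab2 <- make_table(function(con) ifelse(con == "wildtype", 500, 250))
  norm2 <- normalize_assay(tab2)
  expect_equal(unique(norm2$relative_activity[norm2$construct == "mut"]), 0.5)
  expect_error(normalize_assay(dplyr::filter(tab, construct != "wildtype")),
               "wildtype construct")
  expect_error(normalize_assay(dplyr::mutate(tab, gluc = 0)), "positive")
})

test_that("normalisation is invariant to per-experiment rescaling", {
  set.seed(8)
  tab <- simulate_assay(assay_sim_config("variant"), seed = 8)
  scaled <- tab |>
    dplyr::mutate(
      gluc = gluc * ifelse(experiment == 2, 7.3, 1),
      seap = seap * ifelse(experiment == 2, 7.3, 1)
    )
  expect_equal(normalize_assay(scaled)$relative_activity,
               normalize_assay(tab)$relative_activity)
})

test_that("Tukey significance flips exactly at tabulated studentized-range quantiles", {
  # frozen published upper-5% studentized range quantiles
  # q(k = 3, df = 12) = 3.77 ; q(k = 4, df = 20) = 3.96
  run_groups <- function(means, n, pattern) {
    df <- purrr::imap(means, function(m, nm) {
      tibble::tibble(construct = nm, relative_activity = m + pattern)
    }) |> dplyr::bind_rows()
    assay_anova(df, reference = names(means)[1])
  }
  pattern5 <- c(-1, 1, 0, 0, 0)  # var = 0.5, so MSE = 0.5, se = sqrt(0.1)
  crit3_12 <- 3.77 * sqrt(0.5 / 5)
  fit_hi <- run_groups(c(wildtype = 0, mid = 0.5, far = crit3_12 + 0.06),
                       5, pattern5)
  fit_lo <- run_groups(c(wildtype = 0, mid = 0.5, far = crit3_12 - 0.06),
                       5, pattern5)
  get_p <- function(fit, g2) {
    tt <- tidy(fit)
    tt$adjusted_p[tt$group1 == "wildtype" & tt$group2 == g2]
  }
  expect_lt(get_p(fit_hi, "far"), 0.05)
  expect_gt(get_p(fit_lo, "far"), 0.05)

  pattern6 <- c(-1, 1, 0, 0, 0, 0) # var = 0.4, k = 4 -> df = 20
  crit4_20 <- 3.96 * sqrt(0.4 / 6)
  fit_hi <- run_groups(c(wildtype = 0, a = 0.3, b = 0.6, far = crit4_20 + 0.06),
                       6, pattern6)
  fit_lo <- run_groups(c(wildtype = 0, a = 0.3, b = 0.6, far = crit4_20 - 0.06),
                       6, pattern6)
  expect_lt(get_p(fit_hi, "far"), 0.05)
  expect_gt(get_p(fit_lo, "far"), 0.05)
})

test_that("Tukey adjusted p is never smaller than the unadjusted pairwise p", {
  # the unadjusted comparison uses the same pooled within-group variance and
  # error degrees of freedom as the Tukey procedure
  set.seed(21)
  for (i in 1:10) {
    tab <- simulate_assay(assay_sim_config("variant"), seed = 100 + i)
    norm <- normalize_assay(tab)
    fit <- assay_anova(norm)
    tt <- tidy(fit)
    mse <- sum(stats::residuals(fit$fit)^2) / fit$df[["within"]]
    for (j in seq_len(nrow(tt))) {
      n1 <- sum(norm$construct == tt$group1[j])
      n2 <- sum(norm$construct == tt$group2[j])
      se <- sqrt(mse * (1 / n1 + 1 / n2))
      p_unadj <- 2 * stats::pt(-abs(tt$mean_difference[j]) / se,
                               fit$df[["within"]])
      expect_gte(tt$adjusted_p[j] + 1e-12, p_unadj)
    }
  }
})

test_that("identical groups give zero difference; degenerate input errors", {
  df <- tibble::tibble(
    construct = rep(c("wildtype", "mut"), each = 4),
    relative_activity = rep(c(1, 1.1, 0.9, 1), 2)
  )
  fit <- assay_anova(df)
  tt <- tidy(fit)
  expect_equal(tt$mean_difference, 0)
  expect_false(tt$significant)

  flat <- tibble::tibble(construct = rep(c("a", "b"), each = 3),
                         relative_activity = rep(c(1, 2), each = 3))
  expect_error(assay_anova(flat), "zero within-group variance")
  expect_error(assay_anova(df[df$construct == "mut", ]), "at least two constructs")
})

test_that("a planted ~87% knockdown is recovered with the reported sign", {
  tab <- simulate_assay(assay_sim_config("variant"), seed = 42)
  fit <- assay_anova(normalize_assay(tab))
  tt <- tidy(fit)
  row <- tt[tt$group1 == "wildtype" & tt$group2 == "c.-69dupG", ]
  mse <- sum(stats::residuals(fit$fit)^2) / fit$df[["within"]]
  se <- sqrt(mse * 2 / 12)
  expect_lt(abs(row$mean_difference - 0.8678), 3 * se)
  expect_true(row$significant)
  expect_equal(row$p_label, "<0.0001")
  # wildtype-minus-variant is positive for a knockdown
  expect_gt(row$mean_difference, 0)
  expect_lt(percent_change(row$mean_difference), -70)
})

test_that("percent change converts mean differences with the right sign", {
  expect_equal(percent_change(0.8678), -86.78)
  expect_equal(percent_change(-1.31), 131)
  expect_equal(percent_change(0), 0)
})

test_that("tidy/glance/autoplot expose the fit", {
  fit <- assay_anova(normalize_assay(simulate_assay(seed = 3)))
  g <- glance(fit)
  expect_equal(g$n_groups, 6L)
  expect_equal(g$n_obs, 72L)
  expect_s3_class(autoplot(fit), "ggplot")
})
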