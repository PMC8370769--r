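# Two-condition and multi-timepoint comparisons plus categorical
# phenotype tests.

#' Welch's t-test (unequal-variance two-sample t)
#'
#' Two-tailed Student's t assuming unequal variances, with the
#' Welch-Satterthwaite degrees of freedom. Groups where both are constant
#' are handled explicitly: equal constants give `t = 0, p = 1`; unequal
#' constants give `p = 0` with an infinite statistic of the appropriate
#' sign (the noiseless limit).
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return Tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`, `direction`
#'   (`"up"` if mean_a > mean_b, `"down"` if below, `"none"`).
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    d <- mean(a) - mean(b)
    return(tibble(
      t = if (d == 0) 0 else sign(d) * Inf,
      df = NA_real_,
      p_value = if (d == 0) 1 else 0,
      mean_a = mean(a), mean_b = mean(b),
      direction = if (d > 0) "up" else if (d < 0) "down" else "none"
    ))
  }
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  d <- mean(a) - mean(b)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
    direction = if (d > 0) "up" else if (d < 0) "down" else "none"
  )
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p using the probability-based definition: the sum of
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one.
#'
#' @param counts A 2x2 matrix (or length-4 vector, filled by column) of
#'   nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(counts) {
  m <- matrix(as.numeric(counts), nrow = 2)
  if (any(m < 0) || any(m != round(m))) {
    abort("Counts must be nonnegative integers.")
  }
  fisher.test(m, alternative = "two.sided")$p.value
}

#' Fisher's exact test on a 2x3 contingency table
#'
#' Exact two-sided p over all margin-preserving 2x3 tables whose
#' hypergeometric probability does not exceed the observed table's.
#'
#' @param counts A 2x3 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x3 <- function(counts) {
  m <- matrix(as.numeric(counts), nrow = 2)
  if (ncol(m) != 3) abort("Expected a 2x3 table.")
  if (any(m < 0) || any(m != round(m))) {
    abort("Counts must be nonnegative integers.")
  }
  fisher.test(m)$p.value
}

#' Classify phosphosite responses over a treatment time axis
#'
#' Per site: the replicate-mean trajectory over the ordered treatment
#' timepoints is unit-scaled; a Welch t-test across replicate multiplexes
#' compares the first (baseline) and last (final) timepoints. A site is
#' `increased_high` when its scaled final value is at or above
#' `high_threshold` and significantly above baseline; `decreased` when
#' significantly below; else `unchanged`. With a single replicate the
#' significance test is skipped and thresholds alone decide (flagged in
#' the output).
#'
#' @param tbl Normalized phospho table over treatment timepoints.
#' @param design A [stage_design()] whose stages are the ordered
#'   timepoints.
#' @param high_threshold Scaled-value cut for `increased_high`
#'   (default 0.5).
#' @param alpha Significance level for the Welch test.
#' @return An object of class `treatment_response`: list with `sites`
#'   (per-site class, scaled values, test results), `fractions` (class
#'   fractions), and `threshold_only` (TRUE when significance was
#'   unavailable).
#' @export
classify_treatment_response <- function(tbl, design, high_threshold = 0.5,
                                        alpha = 0.05) {
  if (high_threshold <= 0 || high_threshold >= 1) {
    abort("high_threshold must lie in (0, 1).")
  }
  stages <- design_stages(design)
  if (length(stages) < 2) abort("Need at least two timepoints.")
  baseline <- stages[1]
  final <- stages[length(stages)]
  per_mux <- stage_values_by_multiplex(tbl, design)
  means <- stage_means(tbl, design)
  scaled <- scale_unit_interval(means, min_stages = 2)
  threshold_only <- length(unique(tbl$multiplex_id)) < 2

  tests <- per_mux |>
    group_by(.data$feature_id) |>
    summarise(
      base_vals = list(.data[[baseline]][!is.na(.data[[baseline]])]),
      final_vals = list(.data[[final]][!is.na(.data[[final]])]),
      .groups = "drop"
    )
  test_res <- purrr::map2(tests$final_vals, tests$base_vals, function(f, b) {
    if (length(f) < 2 || length(b) < 2) {
      return(tibble(t = NA_real_, p_value = NA_real_,
                    direction = NA_character_))
    }
    select(welch_t(f, b), "t", "p_value", "direction")
  })
  tests <- bind_cols(select(tests, "feature_id"), bind_rows(test_res))

  out <- scaled |>
    select("feature_id", all_of(c(baseline, final)), "degenerate") |>
    rename(scaled_baseline = all_of(baseline), scaled_final = all_of(final)) |>
    left_join(tests, by = "feature_id")
  sig_avail <- !threshold_only & !is.na(out$p_value)
  up <- ifelse(sig_avail,
               out$p_value <= alpha & out$direction == "up",
               out$scaled_final > out$scaled_baseline & !out$degenerate)
  down <- ifelse(sig_avail,
                 out$p_value <= alpha & out$direction == "down",
                 out$scaled_final < out$scaled_baseline & !out$degenerate)
  out$class <- dplyr::case_when(
    !out$degenerate & out$scaled_final >= high_threshold & up ~ "increased_high",
    !out$degenerate & down ~ "decreased",
    TRUE ~ "unchanged"
  )
  fractions <- out |>
    group_by(.data$class) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    mutate(fraction = .data$n / sum(.data$n))
  structure(
    list(sites = out, fractions = fractions, threshold_only = threshold_only,
         baseline = baseline, final = final),
    class = "treatment_response"
  )
}

#' @export
print.treatment_response <- function(x, ...) {
  cat("<treatment_response> ", nrow(x$sites), " sites (",
      x$baseline, " -> ", x$final, ")\n", sep = "")
  print(as.data.frame(x$fractions), digits = 3)
  invisible(x)
}
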