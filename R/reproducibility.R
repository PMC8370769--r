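# Localization and cross-replicate correlation filters defining the
# analyzable site set.

#' Pearson correlation of two trajectories
#'
#' Product-moment correlation; returns `NA` (with an attribute flag) when
#' either trajectory has zero variance over the jointly observed stages.
#'
#' @param x,y Equal-length numeric trajectories (>= 3 shared finite values).
#' @return The correlation coefficient, or `NA_real_` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("Trajectories must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("Need at least 3 jointly observed stages.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `n - 2` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations (stages).
#' @return Two-sided p-value.
#' @export
r_to_p <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(tstat), df = n - 2)
}

#' Cross-replicate correlation of feature trajectories
#'
#' For every feature observed in at least two multiplexes over at least
#' `min_common_stages` shared stages, computes all pairwise Pearson
#' correlations between per-multiplex trajectories. With two replicates the
#' combined r is the single pairwise r; with three or more it is the mean
#' of the pairwise r values (`method = "mean_pairwise"`, the default) or
#' the multiple correlation coefficient of the first replicate on the
#' others (`method = "multiple"`). The p-value uses the t transform with
#' n equal to the smallest common-stage count among the pairs used.
#'
#' @param tbl Normalized phospho or protein quant table.
#' @param design A [stage_design()].
#' @param method Combination rule for three or more replicates.
#' @param min_common_stages Minimum jointly observed stages per pair.
#' @return A tibble: `feature_id`, `n_multiplexes`, `r_pairs` (list),
#'   `r_combined`, `n_stages`, `p_value`, `evaluable`.
#' @export
replicate_correlation <- function(tbl, design,
                                  method = c("mean_pairwise", "multiple"),
                                  min_common_stages = 3) {
  method <- match.arg(method)
  stages <- design_stages(design)
  per_mux <- stage_values_by_multiplex(tbl, design)
  vals <- as.matrix(per_mux[, stages, drop = FALSE])
  split_rows <- split(seq_len(nrow(per_mux)), per_mux$feature_id)
  fids <- names(split_rows)
  nf <- length(fids)
  n_multiplexes <- integer(nf)
  r_pairs <- vector("list", nf)
  r_combined <- rep(NA_real_, nf)
  n_stages_out <- rep(NA_integer_, nf)
  for (fi in seq_len(nf)) {
    m <- vals[split_rows[[fi]], , drop = FALSE]
    n_mux <- nrow(m)
    n_multiplexes[fi] <- n_mux
    r_pairs[fi] <- list(numeric())
    if (n_mux < 2) next
    rs <- numeric(0)
    ns <- integer(0)
    for (i in seq_len(n_mux - 1)) {
      for (j in seq(i + 1, n_mux)) {
        ok <- is.finite(m[i, ]) & is.finite(m[j, ])
        if (sum(ok) < min_common_stages) next
        if (sd(m[i, ok]) == 0 || sd(m[j, ok]) == 0) next
        rs <- c(rs, cor(m[i, ok], m[j, ok]))
        ns <- c(ns, sum(ok))
      }
    }
    if (!length(rs)) next
    r_pairs[[fi]] <- rs
    r_combined[fi] <- if (method == "mean_pairwise" || n_mux == 2) {
      mean(rs)
    } else {
      # Multiple correlation of replicate 1 on the others, over the stages
      # jointly observed by all replicates.
      ok <- apply(is.finite(m), 2, all)
      if (sum(ok) >= min_common_stages &&
          all(apply(m[, ok, drop = FALSE], 1, sd) > 0)) {
        fit <- stats::lm(m[1, ok] ~ t(m[-1, ok, drop = FALSE]))
        sqrt(max(0, summary(fit)$r.squared))
      } else {
        mean(rs)
      }
    }
    n_stages_out[fi] <- min(ns)
  }
  tibble(
    feature_id = fids,
    n_multiplexes = n_multiplexes,
    r_pairs = r_pairs,
    r_combined = r_combined,
    n_stages = n_stages_out,
    p_value = purrr::map2_dbl(r_combined, n_stages_out, function(r, n) {
      if (is.na(r) || is.na(n)) NA_real_ else r_to_p(r, n)
    }),
    evaluable = !is.na(r_combined)
  )
}

#' Apply localization and reproducibility filters
#'
#' Retains records meeting all enabled criteria (conjunction, so filter
#' order is immaterial): every listed site localized with probability at or
#' above `loc_threshold`, and a combined replicate correlation at or above
#' `r_threshold` (thresholds inclusive, matching the "or higher / or less"
#' convention). Gating on the correlation p-value instead is available via
#' `p_threshold`.
#'
#' @param records Phospho quant table.
#' @param correlations Output of [replicate_correlation()] on the same
#'   table (computed if omitted, in which case `design` is required).
#' @param design A [stage_design()]; only needed to compute correlations.
#' @param loc_threshold Localization probability cut (default 0.9); `NULL`
#'   disables.
#' @param r_threshold Combined correlation cut (default 0.8); `NULL`
#'   disables.
#' @param p_threshold Optional p-value cut used instead of `r_threshold`.
#' @return A list with `records` (retained rows) and `attrition`
#'   (row counts after each criterion).
#' @export
apply_site_filters <- function(records, correlations = NULL, design = NULL,
                               loc_threshold = 0.9, r_threshold = 0.8,
                               p_threshold = NULL) {
  n_input <- nrow(records)
  out <- records
  if (!is.null(loc_threshold)) {
    keep <- vapply(out$localization_probs,
                   function(p) all(p >= loc_threshold), logical(1))
    out <- out[keep, , drop = FALSE]
  }
  n_loc <- nrow(out)
  if (!is.null(r_threshold) || !is.null(p_threshold)) {
    if (is.null(correlations)) {
      if (is.null(design)) abort("Supply `correlations` or `design`.")
      correlations <- replicate_correlation(records, design)
    }
    if (!is.null(p_threshold)) {
      ok_ids <- correlations$feature_id[
        correlations$evaluable & !is.na(correlations$p_value) &
          correlations$p_value <= p_threshold
      ]
    } else {
      ok_ids <- correlations$feature_id[
        correlations$evaluable & !is.na(correlations$r_combined) &
          correlations$r_combined >= r_threshold
      ]
    }
    out <- out[out$peptide_id %in% ok_ids, , drop = FALSE]
  }
  n_corr <- nrow(out)
  list(
    records = out,
    attrition = tibble(
      step = c("input", "localization", "correlation"),
      n_records = c(n_input, n_loc, n_corr)
    )
  )
}
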