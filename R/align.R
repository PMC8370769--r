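# Cross-dataset stage alignment via conserved marker phosphosites, and
# motif enrichment among decreasing sites.

#' Align timepoints between two datasets via conserved marker sites
#'
#' Each marker trajectory is unit-scaled within its own dataset (so the
#' alignment is invariant to per-dataset affine rescaling); every query
#' timepoint is then assigned a reference stage by a monotone
#' dynamic-programming alignment over the ordered axes, minimizing the
#' total Euclidean distance over the shared marker vector. Ties break to
#' the earliest reference stage. The mapping never inverts the stage order.
#'
#' @param query,reference Tibbles with a `timepoint` column (ordered as
#'   given) and one numeric column per marker site; marker columns shared
#'   by both tables are used (at least one required).
#' @return An object of class `stage_alignment`: tibble with
#'   `query_timepoint`, `ref_stage`, `distance`, `score` (Pearson r of the
#'   marker vectors; `NA` with a single marker), and the markers used in
#'   `attr(, "markers")`.
#' @export
align_timepoints <- function(query, reference) {
  markers <- intersect(setdiff(names(query), "timepoint"),
                       setdiff(names(reference), "timepoint"))
  markers <- markers[vapply(query[markers], is.numeric, logical(1))]
  if (!length(markers)) abort("No shared marker sites between the datasets.")
  scale01 <- function(m) {
    apply(m, 2, function(x) {
      rng <- range(x, na.rm = TRUE)
      if (diff(rng) == 0) return(rep(0, length(x)))
      (x - rng[1]) / diff(rng)
    })
  }
  q <- scale01(as.matrix(query[, markers, drop = FALSE]))
  r <- scale01(as.matrix(reference[, markers, drop = FALSE]))
  nq <- nrow(q)
  nr <- nrow(r)
  cost <- matrix(NA_real_, nq, nr)
  for (i in seq_len(nq)) {
    for (j in seq_len(nr)) cost[i, j] <- sqrt(sum((q[i, ] - r[j, ])^2))
  }
  # DP over monotone (nondecreasing) assignments of query rows to
  # reference rows.
  best <- matrix(Inf, nq, nr)
  back <- matrix(NA_integer_, nq, nr)
  best[1, ] <- cost[1, ]
  for (i in seq(2, length.out = nq - 1)) {
    run_min <- Inf
    run_arg <- NA_integer_
    for (j in seq_len(nr)) {
      if (best[i - 1, j] < run_min) {  # strict: earliest argmin wins ties
        run_min <- best[i - 1, j]
        run_arg <- j
      }
      best[i, j] <- cost[i, j] + run_min
      back[i, j] <- run_arg
    }
  }
  j <- which.min(best[nq, ])  # which.min takes the earliest minimum
  path <- integer(nq)
  path[nq] <- j
  if (nq >= 2) {
    for (i in nq:2) path[i - 1] <- back[i, path[i]]
  }
  score <- vapply(seq_len(nq), function(i) {
    if (length(markers) < 2) return(NA_real_)
    if (sd(q[i, ]) == 0 || sd(r[path[i], ]) == 0) return(NA_real_)
    cor(q[i, ], r[path[i], ])
  }, numeric(1))
  out <- tibble(
    query_timepoint = as.character(query$timepoint),
    ref_stage = as.character(reference$timepoint[path]),
    distance = cost[cbind(seq_len(nq), path)],
    score = score
  )
  attr(out, "markers") <- markers
  class(out) <- c("stage_alignment", class(out))
  out
}

#' Sites decreasing between two aligned stages
#'
#' @param traj Scaled trajectory tibble.
#' @param from,to Aligned stage labels (e.g. the MI-like and MII-like
#'   points from [align_timepoints()]).
#' @param drop_threshold Minimum scaled decrease (default 0.3).
#' @return The subset of `traj` rows with
#'   `value(from) - value(to) >= drop_threshold`.
#' @export
decreasing_sites <- function(traj, from, to, drop_threshold = 0.3) {
  dd <- dephos_delta(traj, from, to)
  keep <- !is.na(dd$delta) & dd$delta >= drop_threshold
  out <- traj[keep, , drop = FALSE]
  attr(out, "stages") <- attr(traj, "stages")
  out
}

#' Motif composition of decreasing sites against a background
#'
#' Tests whether the sites that lose phosphorylation across the aligned
#' transition carry the TP-basic signature (threonine, +1 proline,
#' +2 basic) and are depleted of SP-acidic sites, relative to a background
#' set — the conserved-dephosphorylation readout. Delegates to
#' [logo_enrichment()] for the positional logo; class-level enrichment uses
#' the same one-sample binomial z. When per-site deltas are supplied, a KS
#' comparison of TP-basic against SP-acidic deltas is added.
#'
#' @param decreasing,background Classified site tibbles with `window`,
#'   `acceptor`, `plus1_proline`, `plus2_class` columns (see
#'   [classify_sites()]); `decreasing` must be nonempty.
#' @param deltas Optional tibble (`peptide_id`, `delta`) for the KS
#'   comparison.
#' @param alpha Significance level.
#' @return A list: `logo` ([logo_enrichment()] result), `class_tests`
#'   (per-class frequency, z, p), `ks` (or `NULL`).
#' @export
conserved_motif_test <- function(decreasing, background, deltas = NULL,
                                 alpha = 0.05) {
  if (!nrow(decreasing)) abort("Decreasing site set is empty.")
  if (!nrow(background)) abort("Background site set is empty.")
  site_class <- function(df) {
    dplyr::case_when(
      df$acceptor == "T" & df$plus1_proline & df$plus2_class == "basic" ~ "TP_basic",
      df$acceptor == "S" & df$plus1_proline & df$plus2_class == "acidic" ~ "SP_acidic",
      TRUE ~ "other"
    )
  }
  dec_cl <- site_class(decreasing)
  bg_cl <- site_class(background)
  n_dec <- length(dec_cl)
  class_tests <- bind_rows(lapply(c("TP_basic", "SP_acidic"), function(cl) {
    p_e <- mean(dec_cl == cl)
    p_r <- mean(bg_cl == cl)
    se <- sqrt(p_r * (1 - p_r) / n_dec)
    z <- if (se > 0) (p_e - p_r) / se else if (p_e == p_r) 0 else sign(p_e - p_r) * Inf
    tibble(class = cl, freq_decreasing = p_e, freq_background = p_r,
           z = z, p_value = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)),
           call = dplyr::case_when(
             is.finite(z) && 2 * pnorm(-abs(z)) <= alpha && z > 0 ~ "enriched",
             is.finite(z) && 2 * pnorm(-abs(z)) <= alpha && z < 0 ~ "depleted",
             is.infinite(z) ~ if (z > 0) "enriched" else "depleted",
             TRUE ~ "none"
           ))
  }))
  ks <- NULL
  if (!is.null(deltas)) {
    dd <- deltas$delta[match(decreasing$peptide_id, deltas$peptide_id)]
    a <- dd[dec_cl == "TP_basic" & !is.na(dd)]
    b <- dd[dec_cl == "SP_acidic" & !is.na(dd)]
    if (length(a) >= 2 && length(b) >= 2) ks <- ks_compare(a, b)
  }
  list(
    logo = logo_enrichment(decreasing$window, background$window, alpha = alpha),
    class_tests = class_tests,
    ks = ks
  )
}
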