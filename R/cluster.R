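# Hierarchical clustering of scaled trajectories, peak-stage assignment,
# cluster/stage summaries.

#' Hierarchical clustering of scaled trajectories
#'
#' Agglomerative clustering with Euclidean distance and average (UPGMA)
#' linkage, cut into exactly `k` flat clusters. Rows with any missing stage
#' or a degenerate flag are excluded (no imputation) and reported.
#' Deterministic given the input row order; duplicate rows merge at height
#' zero.
#'
#' With `min_cluster_size = 1` (the default) the tree is cut into exactly
#' `k` flat clusters. With a larger value the cut is deepened until at
#' least `k` clusters reach that size; the `k` largest become the main
#' clusters and members of smaller branches (isolated outlier
#' trajectories, which an exact-`k` cut of an average-linkage tree would
#' otherwise promote to their own clusters) are left unassigned (`NA`).
#' This mirrors reading the `k` substantive branches off a dendrogram.
#'
#' @param traj Scaled trajectory tibble ([scale_unit_interval()] output).
#' @param k Number of flat clusters (1 <= k <= number of clustered rows).
#' @param stages Stage columns.
#' @param min_cluster_size Minimum size for a cluster to count as one of
#'   the `k` main clusters (default 1: exact-`k` cut).
#' @return An object of class `phos_clusters`: list with `assignments`
#'   (`feature_id`, `cluster`; `NA` for unassigned outliers), the `hclust`
#'   tree, `k`, `stages`, the clustered trajectory tibble, and `excluded`
#'   feature ids.
#' @export
hierarchical_cluster <- function(traj, k, stages = NULL, min_cluster_size = 1) {
  stages <- traj_stages(traj, stages)
  m <- traj_matrix(traj, stages)
  complete <- rowSums(is.na(m)) == 0
  if ("degenerate" %in% names(traj)) complete <- complete & !traj$degenerate
  excluded <- traj$feature_id[!complete]
  if (length(excluded)) {
    inform(paste0("Excluding ", length(excluded),
                  " feature(s) with missing stages or degenerate scaling from clustering."))
  }
  m <- m[complete, , drop = FALSE]
  if (k > nrow(m)) abort("k exceeds the number of clusterable rows.")
  if (k < 1) abort("k must be at least 1.")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  if (min_cluster_size <= 1) {
    cl <- stats::cutree(hc, k = k)
  } else {
    n <- nrow(m)
    cl <- NULL
    for (m_cut in seq(k, n)) {
      cand <- stats::cutree(hc, k = m_cut)
      sizes <- table(cand)
      big <- names(sizes)[sizes >= min_cluster_size]
      if (length(big) >= k) {
        big <- names(sort(sizes[big], decreasing = TRUE))[seq_len(k)]
        cl <- rep(NA_integer_, n)
        for (ci in seq_along(big)) cl[cand == as.integer(big[ci])] <- ci
        names(cl) <- names(cand)
        break
      }
    }
    if (is.null(cl)) abort("No cut yields k clusters of the requested minimum size.")
  }
  structure(
    list(
      assignments = tibble(feature_id = rownames(m), cluster = unname(cl)),
      hclust = hc,
      k = as.integer(k),
      stages = stages,
      trajectories = traj[complete, , drop = FALSE],
      excluded = excluded
    ),
    class = "phos_clusters"
  )
}

#' @export
print.phos_clusters <- function(x, ...) {
  cat("<phos_clusters> ", nrow(x$assignments), " features in ", x$k,
      " clusters (Euclidean / average linkage)\n", sep = "")
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Assign the peak stage of each trajectory
#'
#' The peak stage is the stage of the maximum replicate-mean scaled value;
#' ties break to the earliest stage. Degenerate trajectories get `NA`.
#'
#' @param traj Scaled trajectory tibble.
#' @param stages Stage columns.
#' @return `traj` with a `peak_stage` column.
#' @export
assign_peak_stage <- function(traj, stages = NULL) {
  stages <- traj_stages(traj, stages)
  m <- traj_matrix(traj, stages)
  peak <- apply(m, 1, function(x) {
    if (all(is.na(x))) return(NA_character_)
    stages[which.max(x)]
  })
  if ("degenerate" %in% names(traj)) peak[traj$degenerate] <- NA_character_
  out <- traj
  out$peak_stage <- unname(peak)
  attr(out, "stages") <- stages
  out
}

#' Per-stage peak fractions and mean abundance
#'
#' @param traj Scaled trajectory tibble with a `peak_stage` column (see
#'   [assign_peak_stage()]).
#' @param stages Stage columns.
#' @return Tibble per stage: `peak_fraction` (fractions over non-degenerate
#'   features, summing to 1), `mean_abundance`, `sd_abundance`.
#' @export
stage_summaries <- function(traj, stages = NULL) {
  stages <- traj_stages(traj, stages)
  if (!"peak_stage" %in% names(traj)) traj <- assign_peak_stage(traj, stages)
  peaked <- traj$peak_stage[!is.na(traj$peak_stage)]
  n <- length(peaked)
  m <- traj_matrix(traj, stages)
  tibble(
    stage = stages,
    peak_fraction = if (n) as.numeric(table(factor(peaked, levels = stages))) / n
                    else rep(NA_real_, length(stages)),
    mean_abundance = apply(m, 2, mean_keep_na),
    sd_abundance = apply(m, 2, sd_keep_na)
  )
}

#' Select singly phosphorylated sites peaking at a stage
#'
#' Retains records with exactly one phosphosite, localized at or above
#' `loc_threshold`, whose replicate-mean scaled trajectory peaks at
#' `stage` (default MI) — the site universe for the motif analyses.
#'
#' @param records Phospho quant table (one row per record-multiplex; rows
#'   are deduplicated to one per peptide).
#' @param traj Scaled trajectory tibble with peak stages.
#' @param stage Target peak stage.
#' @param loc_threshold Localization cut (inclusive).
#' @return Tibble of selected sites: `peptide_id`, `protein_id`,
#'   `position`, `acceptor`, `localization_prob`, `peak_stage`.
#' @export
select_mi_peak_singletons <- function(records, traj, stage = "MI",
                                      loc_threshold = 0.9) {
  if (!"peak_stage" %in% names(traj)) {
    abort("`traj` must carry a peak_stage column (see assign_peak_stage()).")
  }
  sites <- records |>
    distinct(.data$peptide_id, .keep_all = TRUE) |>
    filter(lengths(.data$site_positions) == 1) |>
    mutate(
      position = purrr::map_int(.data$site_positions, 1),
      acceptor = purrr::map_chr(.data$acceptor_residues, 1),
      localization_prob = purrr::map_dbl(.data$localization_probs, 1)
    ) |>
    filter(.data$localization_prob >= loc_threshold) |>
    select("peptide_id", "protein_id", "position", "acceptor", "localization_prob")
  peaks <- traj |> select(feature_id = "feature_id", "peak_stage")
  sites |>
    inner_join(peaks, by = c(peptide_id = "feature_id")) |>
    filter(.data$peak_stage == stage)
}
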