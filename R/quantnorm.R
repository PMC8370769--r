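# Peptide-to-protein rollup, internal-standard and loading normalization,
# unit-interval scaling, fold-change statistics.
#
# Pipeline order for protein-level analyses:
#   rollup -> multiplex normalization -> channel loading adjustment ->
#   replicate mean -> unit-interval scaling.
# Phospho tables skip the rollup and use the protein-input loading mode.

#' Sum peptide intensities to protein level
#'
#' Per (protein, multiplex, channel), the protein intensity is the sum of
#' that protein's peptide intensities. Missing cells are skipped; a cell
#' where every contributing peptide is missing stays missing (never zero).
#'
#' @param peptides Tibble with `peptide_id`, `protein_id`, `multiplex_id`
#'   and one numeric column per channel.
#' @return A protein table: one row per (protein, multiplex).
#' @export
rollup_proteins <- function(peptides) {
  chans <- intensity_cols(peptides)
  peptides |>
    group_by(.data$protein_id, .data$multiplex_id) |>
    summarise(across(all_of(chans), sum_keep_na), .groups = "drop")
}

#' Normalize multiplexes to each other via the internal-standard channel
#'
#' For each feature, every multiplex's channels are rescaled so that its
#' reference-channel (pooled internal standard) value equals the mean
#' reference value of that feature across multiplexes. This is feature-wise:
#' the internal standard is a pooled mixture intended to be comparable per
#' feature. A per-multiplex global-median variant is available via
#' `method = "global_median"`.
#'
#' Features missing (or zero in) the reference channel in a multiplex are
#' flagged in a `ref_missing` column and left unscaled.
#'
#' @param tbl Protein or phospho quant table.
#' @param design A [stage_design()]; every multiplex present in `tbl` must
#'   declare a reference channel.
#' @param method `"feature_reference"` (default) or `"global_median"`.
#' @return `tbl` with rescaled intensity columns and a `ref_missing` flag.
#' @export
normalize_multiplexes <- function(tbl, design,
                                  method = c("feature_reference", "global_median")) {
  method <- match.arg(method)
  feature_col <- if ("peptide_id" %in% names(tbl)) "peptide_id" else "protein_id"
  chans <- intensity_cols(tbl)
  muxes <- unique(tbl$multiplex_id)
  refs <- vapply(muxes, function(m) {
    r <- tryCatch(design_reference(design, m), error = function(e) NA_character_)
    if (is.na(r) || !r %in% chans) {
      abort(paste0("Multiplex ", m, " has no reference channel in the design/table."))
    }
    r
  }, character(1))

  ref_val <- vapply(seq_len(nrow(tbl)), function(i) {
    tbl[[refs[[tbl$multiplex_id[i]]]]][i]
  }, numeric(1))
  usable <- !is.na(ref_val) & ref_val > 0

  if (method == "global_median") {
    med <- tapply(ref_val[usable], tbl$multiplex_id[usable], median)
    target <- mean(med)
    factor <- ifelse(usable, target / unname(med[tbl$multiplex_id]), 1)
  } else {
    key <- tbl[[feature_col]]
    target <- tapply(ifelse(usable, ref_val, NA_real_), key, mean_keep_na)
    factor <- ifelse(usable, unname(target[key]) / ref_val, 1)
  }
  out <- tbl
  for (ch in chans) out[[ch]] <- out[[ch]] * factor
  out$ref_missing <- !usable
  out
}

#' Adjust channel loading
#'
#' `mode = "protein_total"` (protein tables): within each multiplex, every
#' channel is divided by its column total and rescaled to the across-channel
#' mean total, so column totals are equal afterwards.
#' `mode = "phospho_protein_input"` (phospho tables): each channel is
#' divided by the matched protein table's channel total for that multiplex
#' (the protein input in that channel) and rescaled by the median protein
#' channel total, so differences in protein input do not masquerade as
#' phosphorylation changes.
#'
#' @param tbl Quant table (after [normalize_multiplexes()]).
#' @param design A [stage_design()].
#' @param mode `"protein_total"` or `"phospho_protein_input"`.
#' @param protein_table Companion protein table (required for the phospho
#'   mode); totals are taken per matched multiplex and channel.
#' @return The adjusted table.
#' @export
adjust_channel_loading <- function(tbl, design,
                                   mode = c("protein_total", "phospho_protein_input"),
                                   protein_table = NULL) {
  mode <- match.arg(mode)
  chans <- intensity_cols(tbl)
  chans <- setdiff(chans, character(0))
  if (mode == "phospho_protein_input" && is.null(protein_table)) {
    abort("phospho_protein_input mode requires `protein_table`.")
  }
  out <- tbl
  for (m in unique(tbl$multiplex_id)) {
    rows <- tbl$multiplex_id == m
    if (mode == "protein_total") {
      totals <- vapply(chans, function(ch) sum(tbl[[ch]][rows], na.rm = TRUE), numeric(1))
    } else {
      prows <- protein_table$multiplex_id == m
      pchans <- intersect(chans, intensity_cols(protein_table))
      if (!setequal(pchans, chans)) {
        abort("Protein table lacks channel(s) present in the phospho table.")
      }
      totals <- vapply(chans, function(ch) sum(protein_table[[ch]][prows], na.rm = TRUE),
                       numeric(1))
    }
    zero <- totals == 0 | is.na(totals)
    if (any(zero)) {
      abort(paste0("Zero channel total in multiplex ", m, ", channel(s): ",
                   paste(chans[zero], collapse = ", ")))
    }
    scale_to <- if (mode == "protein_total") mean(totals) else median(totals)
    for (ch in chans) {
      out[[ch]][rows] <- tbl[[ch]][rows] / totals[[ch]] * scale_to
    }
  }
  out
}

#' Per-feature stage trajectories averaged across multiplexes
#'
#' Maps each multiplex's channels onto stage labels via the design and
#' averages across multiplexes (arithmetic mean of normalized values;
#' standard deviation retained). The reference channel is dropped.
#'
#' @param tbl Quant table after normalization.
#' @param design A [stage_design()].
#' @return A wide tibble: `feature_id`, one column per stage (replicate
#'   mean), `n_observed` (stages with at least one value), with the stage
#'   order in `attr(, "stages")` and per-stage standard deviations in
#'   `attr(, "sd")`.
#' @export
stage_means <- function(tbl, design) {
  feature_col <- if ("peptide_id" %in% names(tbl)) "peptide_id" else "protein_id"
  stages <- design_stages(design)
  long <- lapply(unique(tbl$multiplex_id), function(m) {
    cmap <- design_channel_map(design, m)
    rows <- tbl[tbl$multiplex_id == m, , drop = FALSE]
    present <- intersect(names(cmap), names(rows))
    sub <- rows[, c(feature_col, present)]
    names(sub) <- c("feature_id", unname(cmap[present]))
    tidyr::pivot_longer(sub, -"feature_id", names_to = "stage", values_to = "value")
  })
  long <- bind_rows(long) |> filter(!is.na(.data$value))
  agg <- long |>
    group_by(.data$feature_id, .data$stage) |>
    summarise(mean = mean(.data$value), sd = sd_keep_na(.data$value), .groups = "drop")
  wide <- agg |>
    select("feature_id", "stage", "mean") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "mean")
  missing_stage <- setdiff(stages, names(wide))
  for (s in missing_stage) wide[[s]] <- NA_real_
  wide <- wide[, c("feature_id", stages)]
  wide$n_observed <- rowSums(!is.na(wide[, stages]))
  sd_wide <- agg |>
    select("feature_id", "stage", "sd") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "sd")
  attr(wide, "stages") <- stages
  attr(wide, "sd") <- sd_wide
  wide
}

#' Per-multiplex stage trajectories (no replicate averaging)
#'
#' Like [stage_means()] but keeps one trajectory per (feature, multiplex);
#' used by the replicate-correlation filter.
#'
#' @inheritParams stage_means
#' @return A wide tibble: `feature_id`, `multiplex_id`, one column per stage.
#' @export
stage_values_by_multiplex <- function(tbl, design) {
  feature_col <- if ("peptide_id" %in% names(tbl)) "peptide_id" else "protein_id"
  stages <- design_stages(design)
  out <- lapply(unique(tbl$multiplex_id), function(m) {
    cmap <- design_channel_map(design, m)
    rows <- tbl[tbl$multiplex_id == m, , drop = FALSE]
    present <- intersect(names(cmap), names(rows))
    sub <- rows[, c(feature_col, present)]
    names(sub) <- c("feature_id", unname(cmap[present]))
    sub$multiplex_id <- m
    for (s in setdiff(stages, names(sub))) sub[[s]] <- NA_real_
    sub[, c("feature_id", "multiplex_id", stages)]
  })
  out <- bind_rows(out)
  attr(out, "stages") <- stages
  out
}

#' Scale trajectories to the unit interval
#'
#' Elementwise `(x - min) / (max - min)` per feature so the minimum maps to
#' 0 and the maximum to 1. Missing stages are excluded from min/max.
#' Degenerate trajectories (`max == min`, or fewer than `min_stages`
#' observed stages) are flagged in a `degenerate` column with their values
#' set to 0; they are excluded from clustering by default.
#'
#' Scaling is idempotent and invariant to positive affine transforms of the
#' input.
#'
#' @param traj Wide trajectory tibble from [stage_means()].
#' @param stages Stage columns (defaults to the attribute set by
#'   [stage_means()]).
#' @param min_stages Minimum observed stages required to scale (default 4).
#' @return The scaled trajectory tibble with a `degenerate` flag.
#' @export
scale_unit_interval <- function(traj, stages = NULL, min_stages = 4) {
  stages <- traj_stages(traj, stages)
  m <- traj_matrix(traj, stages)
  lo <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  hi <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  n_obs <- rowSums(!is.na(m))
  degenerate <- is.na(lo) | hi == lo | n_obs < min_stages
  scaled <- (m - lo) / (hi - lo)
  scaled[degenerate, ] <- 0
  out <- traj
  out[, stages] <- as_tibble(scaled)
  out$degenerate <- unname(degenerate)
  attr(out, "stages") <- stages
  out
}

#' Maximum fold change of a positive trajectory
#'
#' `max(values) / min(values)` per feature over observed stages, on
#' replicate-mean (unscaled) trajectories.
#'
#' @param traj Wide trajectory tibble (strictly positive values).
#' @param stages Stage columns.
#' @return Tibble with `feature_id` and `max_fold_change` (>= 1).
#' @export
max_fold_change <- function(traj, stages = NULL) {
  stages <- traj_stages(traj, stages)
  m <- traj_matrix(traj, stages)
  if (any(m <= 0, na.rm = TRUE)) {
    abort("max_fold_change requires strictly positive values (cannot form ratios).")
  }
  tibble(
    feature_id = traj$feature_id,
    max_fold_change = unname(apply(m, 1, function(x) {
      x <- x[!is.na(x)]
      max(x) / min(x)
    }))
  )
}

#' Summarise a fold-change distribution
#'
#' @param fc Output of [max_fold_change()].
#' @param thresholds Fold-change thresholds to report fractions below.
#' @param binwidth Histogram bin width on the fold-change axis.
#' @return A list with `histogram` (bin edges/counts summing to the feature
#'   count) and `fraction_below` (one row per threshold).
#' @export
fold_change_summary <- function(fc, thresholds = 2, binwidth = 0.25) {
  x <- fc$max_fold_change
  edges <- seq(1, max(x) + binwidth, by = binwidth)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  list(
    histogram = tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       count = counts),
    fraction_below = tibble(
      threshold = thresholds,
      fraction = vapply(thresholds, function(t) mean(x < t), numeric(1))
    )
  )
}

#' Protein abundance distribution
#'
#' Histogram and moment summary of log10 total intensity per protein
#' (summed over channels and multiplexes); used to confirm the roughly
#' log-normal abundance spread expected of deep proteome coverage.
#'
#' @param proteins Protein quant table.
#' @return An object of class `abundance_dist`: list with `data`
#'   (per-protein log10 intensity), `histogram`, `skewness`, `kurtosis`
#'   (excess).
#' @export
abundance_distribution <- function(proteins) {
  chans <- intensity_cols(proteins)
  per_protein <- proteins |>
    group_by(.data$protein_id) |>
    summarise(total = sum_keep_na(unlist(across(all_of(chans)))), .groups = "drop") |>
    filter(!is.na(.data$total))
  if (nrow(per_protein) && any(per_protein$total <= 0)) {
    abort("abundance_distribution requires positive intensities.")
  }
  lx <- log10(per_protein$total)
  h <- if (length(lx)) graphics::hist(lx, breaks = "Sturges", plot = FALSE) else NULL
  structure(
    list(
      data = tibble(protein_id = per_protein$protein_id, log10_intensity = lx),
      histogram = if (is.null(h)) {
        tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer())
      } else {
        tibble(bin_lo = h$breaks[-length(h$breaks)], bin_hi = h$breaks[-1],
               count = h$counts)
      },
      skewness = if (length(lx)) moment_skewness(lx) else NA_real_,
      kurtosis = if (length(lx)) moment_kurtosis(lx) else NA_real_
    ),
    class = "abundance_dist"
  )
}

#' @export
print.abundance_dist <- function(x, ...) {
  cat("<abundance_dist> ", nrow(x$data), " proteins; skewness ",
      signif(x$skewness, 3), ", excess kurtosis ", signif(x$kurtosis, 3), "\n",
      sep = "")
  invisible(x)
}
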