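# End-to-end orchestration: normalize -> filter -> cluster -> motifs,
# with a reproducibility manifest and a markdown report.

#' Run the phosphoproteomics time-course pipeline
#'
#' Orchestrates the full analysis on in-memory tables (typically a
#' [simulate_phospho_timecourse()] result or tables read with the
#' `tables-io` functions): peptide-to-protein rollup, internal-standard
#' normalization, channel loading adjustment (protein-total mode for
#' proteins, protein-input mode for phospho), replicate-mean trajectories,
#' unit scaling, localization/correlation filtering, peak-stage assignment,
#' MI-peak singleton selection, k-cluster hierarchical clustering, and the
#' SP/TP motif analysis. Deterministic given its inputs; stages are also
#' runnable individually through the exported functions with identical
#' results.
#'
#' @param phospho Phosphopeptide quant table.
#' @param peptides Phospho-free peptide quant table (for the protein
#'   rollup); pass `NULL` to skip protein-level steps (loading adjustment
#'   then falls back to `protein_total` mode on the phospho table).
#' @param design A [stage_design()].
#' @param sequences Named character vector of protein sequences (for the
#'   motif analyses); `NULL` skips them.
#' @param loc_threshold,r_threshold Site filter cuts (defaults 0.9, 0.8).
#' @param k Number of flat clusters for the MI-peak analysis (default 3).
#' @param min_cluster_frac Minimum fraction of clustered sites a branch
#'   must hold to count as a main cluster (default 0.01); isolated outlier
#'   trajectories below this stay unassigned. Set to 0 for an exact-`k`
#'   cut.
#' @param peak_stage_label Stage whose peaking singletons feed the motif
#'   analysis (default `"MI"`).
#' @param min_stages Minimum observed stages for scaling (default 4).
#' @return An object of class `phos_pipeline`: list with `proteins`,
#'   `phospho_normalized`, `trajectories`, `scaled`, `filter`,
#'   `stage_summary`, `mi_sites`, `clusters`, `sp_tp`, `manifest`.
#' @export
run_phospho_pipeline <- function(phospho, peptides = NULL, design,
                                 sequences = NULL,
                                 loc_threshold = 0.9, r_threshold = 0.8,
                                 k = 3, peak_stage_label = "MI",
                                 min_stages = 4, min_cluster_frac = 0.01) {
  manifest <- list()
  tick <- function(stage, n_in, n_out, t0) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out,
      seconds = round(as.numeric(Sys.time()) - t0, 3)
    )
  }

  t0 <- as.numeric(Sys.time())
  proteins <- NULL
  proteins_raw <- NULL
  if (!is.null(peptides)) {
    # Raw rollup carries the per-channel protein input used to adjust the
    # phospho table; the adjusted copy is for protein-level analyses.
    proteins_raw <- rollup_proteins(peptides)
    proteins <- normalize_multiplexes(proteins_raw, design)
    proteins <- adjust_channel_loading(proteins, design, mode = "protein_total")
    tick("proteins", nrow(peptides), nrow(proteins), t0)
  }

  t0 <- as.numeric(Sys.time())
  phos <- normalize_multiplexes(phospho, design)
  phos <- if (!is.null(proteins_raw)) {
    adjust_channel_loading(phos, design, mode = "phospho_protein_input",
                           protein_table = proteins_raw)
  } else {
    adjust_channel_loading(phos, design, mode = "protein_total")
  }
  tick("normalize_phospho", nrow(phospho), nrow(phos), t0)

  t0 <- as.numeric(Sys.time())
  corr <- replicate_correlation(phos, design)
  filt <- apply_site_filters(phos, correlations = corr,
                             loc_threshold = loc_threshold,
                             r_threshold = r_threshold)
  tick("filter", nrow(phos), nrow(filt$records), t0)

  t0 <- as.numeric(Sys.time())
  traj <- stage_means(filt$records, design)
  scaled <- scale_unit_interval(traj, min_stages = min_stages)
  scaled <- assign_peak_stage(scaled)
  summary_tbl <- stage_summaries(scaled)
  tick("trajectories", nrow(filt$records), nrow(scaled), t0)

  t0 <- as.numeric(Sys.time())
  mi_sites <- select_mi_peak_singletons(filt$records, scaled,
                                        stage = peak_stage_label,
                                        loc_threshold = loc_threshold)
  mi_traj <- scaled[scaled$feature_id %in% mi_sites$peptide_id, , drop = FALSE]
  attr(mi_traj, "stages") <- design_stages(design)
  clusters <- if (nrow(mi_traj) >= k && k >= 1) {
    hierarchical_cluster(mi_traj, k = k,
                         min_cluster_size = max(1, ceiling(min_cluster_frac * nrow(mi_traj))))
  } else {
    NULL
  }
  tick("cluster", nrow(scaled), if (is.null(clusters)) 0L else nrow(clusters$assignments), t0)

  sp_tp <- NULL
  if (!is.null(sequences) && nrow(mi_sites)) {
    t0 <- as.numeric(Sys.time())
    classified <- mi_sites |>
      extract_windows(sequences) |>
      classify_sites()
    if (!is.null(clusters)) {
      classified <- left_join(classified, clusters$assignments,
                              by = c(peptide_id = "feature_id")) |>
        rename(cluster = "cluster")
    }
    sp_tp <- tryCatch(
      sp_tp_analysis(classified, scaled),
      error = function(e) {
        inform(paste0("SP/TP analysis skipped: ", conditionMessage(e)))
        NULL
      }
    )
    tick("motifs", nrow(mi_sites), if (is.null(sp_tp)) 0L else nrow(sp_tp$deltas), t0)
  }

  structure(
    list(
      proteins = proteins,
      phospho_normalized = phos,
      trajectories = traj,
      scaled = scaled,
      filter = filt,
      stage_summary = summary_tbl,
      mi_sites = mi_sites,
      clusters = clusters,
      sp_tp = sp_tp,
      manifest = bind_rows(manifest)
    ),
    class = "phos_pipeline"
  )
}

#' @export
print.phos_pipeline <- function(x, ...) {
  cat("<phos_pipeline>\n")
  print(as.data.frame(x$manifest))
  invisible(x)
}

#' Render a markdown summary of pipeline outputs
#'
#' Writes a plain-markdown report embedding the attrition table, per-stage
#' peak fractions, cluster sizes, and the SP/TP KS contrasts. Sections
#' whose artifact is missing are skipped with a warning.
#'
#' @param result A [run_phospho_pipeline()] result.
#' @param path Output file path (`.md`).
#' @return `path`, invisibly.
#' @export
render_report <- function(result, path) {
  lines <- c("# Phosphoproteomics time-course report", "")
  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(format(r), collapse = " | "), "|"))
    c(header, sep, body, "")
  }
  if (!is.null(result$filter)) {
    lines <- c(lines, "## Filter attrition", "", fmt_tbl(result$filter$attrition))
  } else {
    warn("No filter results; attrition section skipped.")
  }
  if (!is.null(result$stage_summary)) {
    lines <- c(lines, "## Peak-stage fractions and mean abundance", "",
               fmt_tbl(mutate(result$stage_summary,
                              across(where(is.numeric), ~ signif(.x, 4)))))
  } else {
    warn("No stage summary; section skipped.")
  }
  if (!is.null(result$clusters)) {
    sizes <- result$clusters$assignments |>
      group_by(.data$cluster) |>
      summarise(n = dplyr::n(), .groups = "drop")
    lines <- c(lines, "## MI-peak clusters", "", fmt_tbl(sizes))
  } else {
    warn("No clustering results; cluster section skipped.")
  }
  if (!is.null(result$sp_tp) && nrow(result$sp_tp$ks %||% tibble())) {
    lines <- c(lines, "## SP vs TP dephosphorylation contrasts", "",
               fmt_tbl(mutate(result$sp_tp$ks,
                              across(where(is.numeric), ~ signif(.x, 4)))))
  } else {
    warn("No SP/TP results; section skipped.")
  }
  writeLines(lines, path)
  invisible(path)
}
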