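# broom-style tidy()/glance() methods for fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a clustering result
#'
#' @param x A `phos_clusters` object.
#' @param ... Unused.
#' @return One row per feature: `feature_id`, `cluster`.
#' @export
tidy.phos_clusters <- function(x, ...) x$assignments

#' @rdname tidy.phos_clusters
#' @return `glance()`: one row with `k`, `n_features`, `n_excluded`,
#'   `max_height`.
#' @export
glance.phos_clusters <- function(x, ...) {
  tibble(
    k = x$k,
    n_features = nrow(x$assignments),
    n_excluded = length(x$excluded),
    max_height = max(x$hclust$height)
  )
}

#' Tidy an SP/TP dephosphorylation result
#'
#' @param x An `sp_tp_result`.
#' @param ... Unused.
#' @return The KS contrast table (one row per contrast).
#' @export
tidy.sp_tp_result <- function(x, ...) x$ks

#' @rdname tidy.sp_tp_result
#' @export
glance.sp_tp_result <- function(x, ...) {
  by_acc <- split(x$deltas$delta, x$deltas$acceptor)
  tibble(
    n_sites = nrow(x$deltas),
    n_sp = length(by_acc$S %||% numeric()),
    n_tp = length(by_acc$T %||% numeric()),
    mean_delta_sp = mean(by_acc$S %||% NA_real_),
    mean_delta_tp = mean(by_acc$T %||% NA_real_)
  )
}

#' Tidy a motif enrichment result
#'
#' @param x A `motif_enrichment` result.
#' @param ... Unused.
#' @return A plain tibble of per-(offset, residue) statistics.
#' @export
tidy.motif_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "motif_enrichment")
  out
}

#' @rdname tidy.motif_enrichment
#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble(
    n_exp = attr(x, "n_exp"),
    n_ref = attr(x, "n_ref"),
    n_selected = sum(x$call == "selected"),
    n_deselected = sum(x$call == "deselected"),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a stage alignment
#'
#' @param x A `stage_alignment`.
#' @param ... Unused.
#' @return One row per query timepoint with its mapped reference stage.
#' @export
tidy.stage_alignment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stage_alignment")
  out
}

#' @rdname tidy.stage_alignment
#' @export
glance.stage_alignment <- function(x, ...) {
  tibble(
    n_timepoints = nrow(x),
    n_markers = length(attr(x, "markers")),
    mean_distance = mean(x$distance),
    mean_score = mean(x$score, na.rm = TRUE)
  )
}

#' Tidy a treatment-response classification
#'
#' @param x A `treatment_response`.
#' @param ... Unused.
#' @return One row per site with its class and test results.
#' @export
tidy.treatment_response <- function(x, ...) x$sites

#' @rdname tidy.treatment_response
#' @export
glance.treatment_response <- function(x, ...) {
  wide <- tidyr::pivot_wider(select(x$fractions, "class", "fraction"),
                             names_from = "class", values_from = "fraction")
  mutate(wide, n_sites = nrow(x$sites), threshold_only = x$threshold_only)
}
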