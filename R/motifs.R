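# Sequence-window extraction and classification, motif enrichment logos,
# SP/TP dephosphorylation analysis, RVxF and kinase-consensus scanning.

WINDOW_GAP <- "-"

#' Extract a phosphosite-centred sequence window
#'
#' Returns the +/- `half_width` residue window centred on `position`
#' (1-based within the protein). Positions beyond the termini are filled
#' with the gap symbol `-`. When `acceptor` is given, a mismatch with the
#' sequence raises an error naming the protein and position.
#'
#' @param sequences Named character vector of protein sequences
#'   ([read_fasta()] output).
#' @param protein_id Protein identifier.
#' @param position 1-based site position.
#' @param half_width Window half width (default 7).
#' @param acceptor Optional declared phosphoacceptor residue to verify.
#' @return A window string of length `2 * half_width + 1`.
#' @export
extract_window <- function(sequences, protein_id, position, half_width = 7,
                           acceptor = NULL) {
  seqs <- sequences[[protein_id]]
  if (is.null(seqs)) abort(paste0("Unknown protein: ", protein_id))
  len <- nchar(seqs)
  if (position < 1 || position > len) {
    abort(paste0("Position ", position, " out of range for ", protein_id,
                 " (length ", len, ")."))
  }
  centre <- substr(seqs, position, position)
  if (!is.null(acceptor) && centre != acceptor) {
    abort(paste0("Acceptor mismatch at ", protein_id, ":", position,
                 " — declared ", acceptor, ", sequence has ", centre, "."))
  }
  offs <- (position - half_width):(position + half_width)
  chars <- ifelse(offs < 1 | offs > len, WINDOW_GAP,
                  vapply(offs, function(i) substr(seqs, i, i), character(1)))
  paste(chars, collapse = "")
}

#' @rdname extract_window
#' @param sites Tibble with `protein_id`, `position` and optionally
#'   `acceptor` columns.
#' @return `extract_windows()`: `sites` with a `window` column appended.
#' @export
extract_windows <- function(sites, sequences, half_width = 7) {
  acc <- if ("acceptor" %in% names(sites)) sites$acceptor else NULL
  sites$window <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(sequences, sites$protein_id[i], sites$position[i],
                   half_width = half_width,
                   acceptor = if (is.null(acc)) NULL else acc[i])
  }, character(1))
  sites
}

window_char <- function(windows, offset) {
  half <- (nchar(windows[1]) - 1) / 2
  substr(windows, half + 1 + offset, half + 1 + offset)
}

#' Classify phosphosite sequence windows
#'
#' Adds the site-class fields the dephosphorylation analyses use:
#' the phosphoacceptor (offset 0), whether the +1 residue is proline
#' (proline-directed SP/TP sites), the +2 residue class (`basic` K/R/H,
#' `acidic` D/E, `small_nonpolar` A/G, `proline`, `other` — exhaustive and
#' exclusive), and a downstream basic patch flag (at least two of offsets
#' +2..+6 in K/R). Windows with a gap at +1 or +2 are classed `other` with
#' an `edge` flag.
#'
#' @param sites Tibble with a `window` column (see [extract_windows()]).
#' @return `sites` with `acceptor`, `plus1_proline`, `plus2_class`,
#'   `downstream_basic_patch`, `edge` columns.
#' @export
classify_sites <- function(sites) {
  w <- sites$window
  plus1 <- window_char(w, 1)
  plus2 <- window_char(w, 2)
  edge <- plus1 == WINDOW_GAP | plus2 == WINDOW_GAP
  plus2_class <- dplyr::case_when(
    edge ~ "other",
    plus2 %in% AA_BASIC ~ "basic",
    plus2 %in% AA_ACIDIC ~ "acidic",
    plus2 %in% AA_SMALL_NONPOLAR ~ "small_nonpolar",
    plus2 == "P" ~ "proline",
    TRUE ~ "other"
  )
  patch <- vapply(w, function(win) {
    res <- vapply(2:6, function(o) window_char(win, o), character(1))
    sum(res %in% c("K", "R")) >= 2
  }, logical(1), USE.NAMES = FALSE)
  sites |>
    mutate(
      acceptor = window_char(w, 0),
      plus1_proline = plus1 == "P",
      plus2_class = plus2_class,
      downstream_basic_patch = patch,
      edge = edge
    )
}

#' Position-resolved residue enrichment between two window sets
#'
#' For every (offset, residue) pair, compares the experimental frequency
#' against the reference frequency: percent difference
#' `100 * (p_exp - p_ref)`, a one-sample binomial z score treating the
#' reference frequency as fixed
#' (`z = (p_exp - p_ref) / sqrt(p_ref (1 - p_ref) / n_exp)`), a two-sided
#' normal p-value, and a `selected` / `deselected` call at `alpha`. Gap
#' symbols are excluded from the denominators. A two-proportion z variant
#' is available via `method = "two_proportion"`.
#'
#' @param exp_windows,ref_windows Character vectors of equal-width windows.
#' @param alpha Significance level for the calls (default 0.05).
#' @param method `"binomial"` (reference fixed; default) or
#'   `"two_proportion"`.
#' @return A tibble of class `motif_enrichment`: `offset`, `residue`,
#'   `freq_exp`, `freq_ref`, `pct_diff`, `z`, `p_value`, `call`.
#' @export
logo_enrichment <- function(exp_windows, ref_windows, alpha = 0.05,
                            method = c("binomial", "two_proportion")) {
  method <- match.arg(method)
  if (!length(exp_windows) || !length(ref_windows)) {
    abort("Both window sets must be nonempty.")
  }
  half <- (nchar(exp_windows[1]) - 1) / 2
  offsets <- -half:half
  rows <- purrr::map(offsets, function(o) {
    e <- window_char(exp_windows, o)
    r <- window_char(ref_windows, o)
    e <- e[e != WINDOW_GAP]
    r <- r[r != WINDOW_GAP]
    n_e <- length(e)
    n_r <- length(r)
    if (n_e == 0 || n_r == 0) return(NULL)
    p_e <- as.numeric(table(factor(e, levels = AA20))) / n_e
    p_r <- as.numeric(table(factor(r, levels = AA20))) / n_r
    if (method == "binomial") {
      se <- sqrt(p_r * (1 - p_r) / n_e)
    } else {
      pool <- (p_e * n_e + p_r * n_r) / (n_e + n_r)
      se <- sqrt(pool * (1 - pool) * (1 / n_e + 1 / n_r))
    }
    z <- ifelse(se > 0, (p_e - p_r) / se,
                ifelse(p_e == p_r, 0, sign(p_e - p_r) * Inf))
    p <- ifelse(is.infinite(z), 0, 2 * pnorm(-abs(z)))
    p[se == 0 & p_e == p_r] <- 1
    tibble(
      offset = o, residue = AA20,
      freq_exp = p_e, freq_ref = p_r,
      pct_diff = 100 * (p_e - p_r),
      z = z, p_value = p,
      call = dplyr::case_when(
        p <= alpha & z > 0 ~ "selected",
        p <= alpha & z < 0 ~ "deselected",
        TRUE ~ "none"
      )
    )
  })
  out <- bind_rows(rows)
  attr(out, "n_exp") <- length(exp_windows)
  attr(out, "n_ref") <- length(ref_windows)
  attr(out, "alpha") <- alpha
  class(out) <- c("motif_enrichment", class(out))
  out
}

#' Dephosphorylation delta between two stages
#'
#' `delta = scaled(from) - scaled(to)` per feature on unit-scaled
#' replicate-mean trajectories; positive values are net dephosphorylation
#' across the transition (MI to MII by default). Features missing either
#' stage get `NA`.
#'
#' @param traj Scaled trajectory tibble.
#' @param from,to Stage labels (defaults MI, MII).
#' @return Tibble: `feature_id`, `delta` in `[-1, 1]`.
#' @export
dephos_delta <- function(traj, from = "MI", to = "MII") {
  if (!all(c(from, to) %in% names(traj))) {
    abort("Both stages must be columns of the trajectory table.")
  }
  tibble(feature_id = traj$feature_id, delta = traj[[from]] - traj[[to]])
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test: `D = sup |ECDF_A - ECDF_B|` with the exact
#' small-sample p-value where available (otherwise the asymptotic
#' Kolmogorov distribution), via [stats::ks.test()].
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param exact Passed to [stats::ks.test()] (`NULL` lets it decide).
#' @return Tibble: `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each sample needs at least 2 observations.")
  }
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided", exact = exact))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(a), n_b = length(b))
}

#' Empirical CDF table of dephosphorylation deltas
#'
#' @param deltas Numeric vector of per-site deltas.
#' @param label Group label.
#' @return Tibble: `group`, `delta` (sorted), `cdf` (nondecreasing 0 to 1).
#' @export
dephos_cdf <- function(deltas, label = "all") {
  d <- sort(deltas[!is.na(deltas)])
  tibble(group = label, delta = d, cdf = seq_along(d) / length(d))
}

#' SP vs TP dephosphorylation analysis
#'
#' The core contrast: among proline-directed (+1 P) single phosphosites,
#' compares MI-to-MII dephosphorylation (unit-scaled deltas) between serine
#' (SP) and threonine (TP) acceptors, and between +2 residue classes within
#' TP sites; optionally per temporal cluster. All pairwise contrasts use
#' the two-sample KS test with Bonferroni adjustment within each family
#' (acceptor contrasts; +2-class contrasts). Also reports mean +/- sd
#' scaled stage traces per acceptor.
#'
#' @param sites Classified site tibble ([classify_sites()] output) with
#'   `peptide_id`; optionally a `cluster` column.
#' @param traj Scaled trajectory tibble keyed by `feature_id`.
#' @param stages Stage columns.
#' @param from,to Transition stages (default MI to MII).
#' @param restrict_proline_directed Drop sites without +1 proline
#'   (default TRUE).
#' @param alpha Significance level.
#' @param min_group Minimum group size for a contrast (default 2; smaller
#'   groups are skipped with a message).
#' @return An object of class `sp_tp_result`: list with `deltas` (per-site
#'   group labels and deltas), `cdf` (ECDF tables), `ks` (contrast table
#'   with `p_adj`), and `stage_means` (per-acceptor traces).
#' @export
sp_tp_analysis <- function(sites, traj, stages = NULL, from = "MI", to = "MII",
                           restrict_proline_directed = TRUE, alpha = 0.05,
                           min_group = 2) {
  stages <- traj_stages(traj, stages)
  if (restrict_proline_directed) sites <- filter(sites, .data$plus1_proline)
  dd <- dephos_delta(traj, from, to)
  dat <- sites |>
    inner_join(dd, by = c(peptide_id = "feature_id")) |>
    filter(!is.na(.data$delta), .data$acceptor %in% c("S", "T"))
  if (!nrow(dat)) abort("No proline-directed sites with evaluable deltas.")

  run_family <- function(df, group_col, family) {
    groups <- split(df$delta, df[[group_col]])
    groups <- groups[lengths(groups) >= min_group]
    if (length(groups) < 2) {
      if (length(groups) < 2) {
        inform(paste0("Family '", family, "': fewer than two groups with >= ",
                      min_group, " members; contrasts skipped."))
      }
      return(NULL)
    }
    combos <- utils::combn(names(groups), 2, simplify = FALSE)
    res <- bind_rows(purrr::map(combos, function(pr) {
      ks <- ks_compare(groups[[pr[1]]], groups[[pr[2]]])
      mutate(ks, family = family, group_a = pr[1], group_b = pr[2],
             .before = 1)
    }))
    res$p_adj <- pmin(1, res$p_value * nrow(res))
    res
  }

  fam <- list(run_family(dat, "acceptor", "SP_vs_TP"))
  tp <- filter(dat, .data$acceptor == "T")
  fam <- c(fam, list(run_family(tp, "plus2_class", "TP_plus2_class")))
  if ("cluster" %in% names(dat)) {
    for (cl in sort(unique(dat$cluster))) {
      fam <- c(fam, list(run_family(filter(dat, .data$cluster == cl),
                                    "acceptor", paste0("SP_vs_TP_cluster", cl))))
    }
  }
  ks_tbl <- bind_rows(fam)

  cdf_tbl <- bind_rows(
    dephos_cdf(dat$delta[dat$acceptor == "S"], "SP"),
    dephos_cdf(dat$delta[dat$acceptor == "T"], "TP"),
    bind_rows(lapply(split(dat, dat$plus2_class), function(df) {
      dephos_cdf(df$delta, paste0("plus2_", df$plus2_class[1]))
    }))
  )

  tr <- traj |>
    inner_join(select(dat, "peptide_id", "acceptor"),
               by = c(feature_id = "peptide_id"))
  stage_tr <- tr |>
    tidyr::pivot_longer(all_of(stages), names_to = "stage", values_to = "value") |>
    group_by(.data$acceptor, .data$stage) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd_keep_na(.data$value), n = dplyr::n(), .groups = "drop") |>
    mutate(stage = factor(.data$stage, levels = stages)) |>
    arrange(.data$acceptor, .data$stage)

  structure(
    list(deltas = select(dat, "peptide_id", "acceptor", "plus2_class",
                         any_of("cluster"), "delta"),
         cdf = cdf_tbl, ks = ks_tbl, stage_means = stage_tr,
         alpha = alpha, from = from, to = to),
    class = "sp_tp_result"
  )
}

#' @export
print.sp_tp_result <- function(x, ...) {
  cat("<sp_tp_result> ", nrow(x$deltas), " proline-directed sites; ",
      x$from, " -> ", x$to, " deltas\n", sep = "")
  if (!is.null(x$ks) && nrow(x$ks)) print(as.data.frame(x$ks), digits = 3)
  invisible(x)
}

# The RVxF docking motif: 5 pattern positions; the canonical 'x' is the 4th
# (offset +3 from the motif start).
RVXF_PATTERN <- "[KRL][KRSTAMVHN][VI][^FIMYDP][FW]"

#' Scan sequences for RVxF docking motifs
#'
#' Reports every 5-mer matching `[KRL][KRSTAMVHN][VI][^FIMYDP][FW]`
#' (overlapping matches included). A hit's phospho flag is true when a
#' phosphorylated S/T lies at the x position (4th pattern position) or
#' within two residues of either motif boundary.
#'
#' @param sequences Named character vector of protein sequences.
#' @param phospho_sites Optional tibble with `protein_id`, `position`, and
#'   (optionally) `acceptor` and `peptide_id`, listing quantified
#'   phosphosites; only S/T sites can set the flag.
#' @return Tibble: `protein_id`, `start`, `end` (1-based inclusive),
#'   `match`, `x_position`, `phospho` flag, `site_ids` (list of linked
#'   phosphosite peptide ids).
#' @export
scan_rvxf <- function(sequences, phospho_sites = NULL) {
  hits <- purrr::imap(sequences, function(seqs, pid) {
    m <- gregexpr(paste0("(?=(", RVXF_PATTERN, "))"), seqs, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m)
    tibble(
      protein_id = pid,
      start = starts,
      end = starts + 4L,
      match = substring(seqs, starts, starts + 4L),
      x_position = starts + 3L
    )
  })
  out <- bind_rows(hits)
  if (!nrow(out)) {
    return(tibble(protein_id = character(), start = integer(), end = integer(),
                  match = character(), x_position = integer(),
                  phospho = logical(), site_ids = list()))
  }
  if (is.null(phospho_sites) || !nrow(phospho_sites)) {
    out$phospho <- FALSE
    out$site_ids <- replicate(nrow(out), character(), simplify = FALSE)
    return(out)
  }
  ps <- phospho_sites
  if (!"acceptor" %in% names(ps)) {
    ps$acceptor <- vapply(seq_len(nrow(ps)), function(i) {
      substr(sequences[[ps$protein_id[i]]], ps$position[i], ps$position[i])
    }, character(1))
  }
  ps <- filter(ps, .data$acceptor %in% c("S", "T"))
  if (!"peptide_id" %in% names(ps)) {
    ps$peptide_id <- paste0(ps$protein_id, ":", ps$position)
  }
  linked <- purrr::map(seq_len(nrow(out)), function(i) {
    cand <- ps[ps$protein_id == out$protein_id[i], , drop = FALSE]
    if (!nrow(cand)) return(character())
    in_span <- cand$position == out$x_position[i] |
      (cand$position >= out$start[i] - 2L & cand$position <= out$end[i] + 2L)
    unique(cand$peptide_id[in_span])
  })
  out$phospho <- lengths(linked) > 0
  out$site_ids <- linked
  out
}

#' RVxF phosphorylation occupancy trajectory
#'
#' Mean +/- sd scaled phosphorylation per stage over the phosphosites
#' linked to phospho-flagged RVxF hits.
#'
#' @param hits [scan_rvxf()] output.
#' @param traj Scaled trajectory tibble keyed by `feature_id`.
#' @param stages Stage columns.
#' @return Tibble per stage: `mean`, `sd`, `n_sites` (empty when no hit is
#'   flagged).
#' @export
rvxf_occupancy <- function(hits, traj, stages = NULL) {
  stages <- traj_stages(traj, stages)
  ids <- unique(unlist(hits$site_ids[hits$phospho]))
  sub <- traj[traj$feature_id %in% ids, , drop = FALSE]
  if (!nrow(sub)) {
    return(tibble(stage = character(), mean = numeric(), sd = numeric(),
                  n_sites = integer()))
  }
  m <- traj_matrix(sub, stages)
  tibble(
    stage = stages,
    mean = unname(apply(m, 2, mean_keep_na)),
    sd = unname(apply(m, 2, sd_keep_na)),
    n_sites = unname(apply(m, 2, function(x) sum(!is.na(x))))
  )
}

#' Split RxRxxS/T consensus sites by early phosphorylation increase
#'
#' Identifies basophilic kinase consensus sites (R at -5 and R at -3
#' relative to the S/T acceptor, so the motif reads R-x-R-x-x-[S/T] ending
#' at the phosphosite) among localized singletons, and splits them by
#' whether phosphorylation increases at least `fold_threshold`-fold from
#' `from_stage` to `to_stage` on normalized (unscaled) intensities. Reports
#' the frequency of basophilic residues (K/R/H) at the -4 position in each
#' partition — the discriminator between AKT-like (basophilic -4) and
#' SGK-like consensus — plus a full positional enrichment of the increasing
#' against the non-increasing set.
#'
#' @param sites Tibble with `peptide_id` and `window` columns.
#' @param traj Normalized (unscaled) trajectory tibble keyed by
#'   `feature_id` containing `from_stage` and `to_stage` columns.
#' @param from_stage,to_stage Ratio stages (defaults Pro, GVBD).
#' @param fold_threshold Ratio cut (default 3).
#' @param alpha Significance level for the logo calls.
#' @return A list: `sites` (consensus sites with `ratio` and `increased`),
#'   `minus4` (per-partition basophilic -4 frequency), `logo`
#'   (increasing vs non-increasing enrichment), `n_excluded_zero_baseline`.
#' @export
kinase_consensus_split <- function(sites, traj, from_stage = "Pro",
                                   to_stage = "GVBD", fold_threshold = 3,
                                   alpha = 0.05) {
  acc <- window_char(sites$window, 0)
  cons <- window_char(sites$window, -5) == "R" &
    window_char(sites$window, -3) == "R" & acc %in% c("S", "T")
  cs <- sites[cons, , drop = FALSE]
  vals <- traj |> select("feature_id", all_of(c(from_stage, to_stage)))
  cs <- inner_join(cs, vals, by = c(peptide_id = "feature_id"))
  zero <- is.na(cs[[from_stage]]) | cs[[from_stage]] <= 0 | is.na(cs[[to_stage]])
  if (any(zero)) {
    inform(paste0("Excluding ", sum(zero),
                  " consensus site(s) with missing or zero baseline."))
  }
  cs <- cs[!zero, , drop = FALSE]
  cs$ratio <- cs[[to_stage]] / cs[[from_stage]]
  cs$increased <- cs$ratio >= fold_threshold
  minus4 <- window_char(cs$window, -4)
  minus4_tbl <- cs |>
    mutate(minus4_basophilic = minus4 %in% AA_BASIC) |>
    group_by(.data$increased) |>
    summarise(n = dplyr::n(),
              minus4_basophilic_freq = mean(.data$minus4_basophilic),
              .groups = "drop")
  logo <- if (sum(cs$increased) > 0 && sum(!cs$increased) > 0) {
    logo_enrichment(cs$window[cs$increased], cs$window[!cs$increased],
                    alpha = alpha)
  } else {
    NULL
  }
  list(sites = cs, minus4 = minus4_tbl, logo = logo,
       n_excluded_zero_baseline = sum(zero))
}
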