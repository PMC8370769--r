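# Synthetic multiplexed phospho/proteome time courses with planted structure.
#
# The generator emulates the study design the analysis targets: replicate
# TMT multiplexes covering ordered meiotic stages plus a pooled
# internal-standard channel, phosphosites drawn from temporal classes with
# known noiseless trajectories, class-conditional sequence context
# (+1 proline, +2 basic/acidic), planted kinase-consensus and RVxF context,
# multiplicative lognormal noise, and per-multiplex dropout. Ground truth is
# returned alongside the tables so recovery is testable.

SIM_CLASSES <- c("stable", "MI_peak_fast", "MI_peak_intermediate",
                 "MI_peak_stable", "prophase_peak", "FC_peak")

#' Configuration for the synthetic time-course generator
#'
#' Defaults encode the study conditions the generator emulates: six ordered
#' meiotic stages in three replicate multiplexes with one internal-standard
#' channel each; S/T/Y phosphoacceptor proportions 79.3/19.6/1.1;
#' a temporal class mix dominated by MI-peaking sites; a fast-class
#' MI-to-MII drop of 0.6 scaled units against 0.1 for the stable class;
#' 99% of proteins with a maximum fold change below 2; localization
#' probabilities massed near 1 with a tail below 0.9.
#'
#' @param n_proteins,n_phosphosites Numbers of proteins and phosphosite
#'   records to simulate.
#' @param stages Ordered stage labels (length >= 3).
#' @param n_multiplexes Number of replicate multiplexes.
#' @param acceptor_props Named S/T/Y probabilities summing to 1.
#' @param class_mix Named proportions over the temporal classes
#'   `r paste(SIM_CLASSES, collapse = ", ")`, summing to 1.
#' @param dephos_delta Named scaled-unit MI-to-MII drops for the
#'   `fast`, `intermediate` and `stable` MI-peak classes.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise (0 disables noise).
#' @param loc_below_frac Fraction of sites with localization
#'   probability below 0.9.
#' @param missing_rate Per-(site, multiplex) dropout probability.
#' @param frac_stable_proteins Fraction of proteins whose noiseless maximum
#'   fold change is below 2 (the rest get a cyclin-like regulated profile).
#' @param multi_site_frac Fraction of records carrying a second
#'   phosphosite (excluded by single-site analyses).
#' @param consensus_frac Fraction of S/T sites planted with an RxRxxS/T
#'   kinase consensus (R at -5 and -3); among these the -4 residue is
#'   basophilic with probability 0.1 for stage-increasing classes (SGK-like)
#'   and 0.6 otherwise (AKT-like).
#' @param rvxf_frac Fraction of sites planted with an RVxF docking motif
#'   whose x position is the phosphosite (drawn from the intermediate
#'   MI-peak class so occupancy rises into MI).
#' @param baseline_occupancy Occupancy floor added to every noiseless
#'   trajectory before intensity conversion; keeps intensities positive
#'   while leaving unit-interval scaling (an affine map) unaffected.
#' @param channel_loading_cv,multiplex_scale_cv CVs of the planted
#'   per-channel loading and per-multiplex scale factors that the
#'   normalization chain is expected to remove.
#' @param seed Integer master seed; each table draws from its own derived
#'   stream so resizing one table does not perturb the others.
#' @return A validated object of class `phos_sim_config`.
#' @export
sim_config <- function(n_proteins = 500,
                       n_phosphosites = 2000,
                       stages = PHOS_STAGES,
                       n_multiplexes = 3,
                       acceptor_props = c(S = 0.793, T = 0.196, Y = 0.011),
                       class_mix = c(stable = 0.25, MI_peak_fast = 0.20,
                                     MI_peak_intermediate = 0.15,
                                     MI_peak_stable = 0.15,
                                     prophase_peak = 0.10, FC_peak = 0.15),
                       dephos_delta = c(fast = 0.6, intermediate = 0.35,
                                        stable = 0.1),
                       noise_cv = 0.1,
                       loc_below_frac = 0.15,
                       missing_rate = 0.1,
                       frac_stable_proteins = 0.99,
                       multi_site_frac = 0.05,
                       consensus_frac = 0.08,
                       rvxf_frac = 0.02,
                       baseline_occupancy = 0.05,
                       channel_loading_cv = 0.05,
                       multiplex_scale_cv = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_phosphosites = as.integer(n_phosphosites),
    stages = as.character(stages),
    n_multiplexes = as.integer(n_multiplexes),
    acceptor_props = acceptor_props,
    class_mix = class_mix,
    dephos_delta = dephos_delta,
    noise_cv = noise_cv,
    loc_below_frac = loc_below_frac,
    missing_rate = missing_rate,
    frac_stable_proteins = frac_stable_proteins,
    multi_site_frac = multi_site_frac,
    consensus_frac = consensus_frac,
    rvxf_frac = rvxf_frac,
    baseline_occupancy = baseline_occupancy,
    channel_loading_cv = channel_loading_cv,
    multiplex_scale_cv = multiplex_scale_cv,
    seed = as.integer(seed)
  )
  class(cfg) <- "phos_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$stages) < 3) abort("Config error: need at least 3 stages.")
  if (!setequal(names(cfg$acceptor_props), c("S", "T", "Y"))) {
    abort("Config error: acceptor_props must be named S, T, Y.")
  }
  if (abs(sum(cfg$acceptor_props) - 1) > 1e-9) {
    abort("Config error: acceptor_props must sum to 1.")
  }
  if (!all(names(cfg$class_mix) %in% SIM_CLASSES) ||
      !setequal(names(cfg$class_mix), SIM_CLASSES)) {
    abort(paste0("Config error: class_mix must be named over: ",
                 paste(SIM_CLASSES, collapse = ", ")))
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-9) {
    abort("Config error: class_mix must sum to 1.")
  }
  props <- c(cfg$acceptor_props, cfg$class_mix, cfg$loc_below_frac,
             cfg$missing_rate, cfg$frac_stable_proteins, cfg$multi_site_frac,
             cfg$consensus_frac, cfg$rvxf_frac, cfg$baseline_occupancy)
  if (any(props < 0 | props > 1)) {
    abort("Config error: all proportions must lie in [0, 1].")
  }
  if (cfg$n_phosphosites < length(cfg$class_mix)) {
    abort("Config error: n_phosphosites must be at least the number of classes.")
  }
  if (any(cfg$dephos_delta < 0 | cfg$dephos_delta > 1)) {
    abort("Config error: dephos_delta values must lie in [0, 1].")
  }
  invisible(cfg)
}

# Map a canonical six-point template onto an arbitrary number of stages.
template_on_stages <- function(canonical, n_stages) {
  if (n_stages == length(canonical)) return(canonical)
  stats::approx(seq(0, 1, length.out = length(canonical)), canonical,
                xout = seq(0, 1, length.out = n_stages))$y
}

#' Noiseless class trajectory templates
#'
#' Scaled (0-1) per-stage occupancies for each temporal class. The three
#' MI-peak classes are anchored at 0 in prophase and 1 at MI so that
#' unit-interval scaling is the identity on the noiseless truth and the
#' MI-to-MII drop equals `dephos_delta` exactly.
#'
#' @param cfg A [sim_config()].
#' @return A matrix with one row per class and one column per stage.
#' @export
class_templates <- function(cfg) {
  d <- cfg$dephos_delta
  canon <- rbind(
    stable               = c(0.55, 0.62, 0.66, 0.70, 0.72, 0.68),
    MI_peak_fast         = c(0, 0.60, 1, 1 - d[["fast"]], 0.15, 0.05),
    MI_peak_intermediate = c(0, 0.55, 1, 1 - d[["intermediate"]], 0.50, 0.35),
    MI_peak_stable       = c(0, 0.60, 1, 1 - d[["stable"]], 0.88, 0.85),
    prophase_peak        = c(1, 0.65, 0.40, 0.25, 0.15, 0.10),
    FC_peak              = c(0.05, 0.10, 0.20, 0.30, 0.60, 1)
  )
  out <- t(apply(canon, 1, template_on_stages, n_stages = length(cfg$stages)))
  colnames(out) <- cfg$stages
  out
}

# Classes whose occupancy rises at least threefold from the first to the
# second stage (hormonal-stimulation responders in the consensus analysis).
.increasing_classes <- c("MI_peak_fast", "MI_peak_intermediate", "MI_peak_stable")

# Class-conditional acceptor probabilities that preserve the configured
# S/T/Y marginal exactly: the fast MI-peak class is tilted toward threonine
# (TP sites) and the stable MI-peak class toward serine (SP sites); the
# remaining classes absorb the residual mass. Falls back to the marginal for
# every class when the configured mix cannot support the tilt.
acceptor_class_probs <- function(cfg) {
  props <- cfg$acceptor_props[c("S", "T", "Y")]
  mix <- cfg$class_mix[SIM_CLASSES]
  flat <- matrix(rep(props, length(SIM_CLASSES)), nrow = length(SIM_CLASSES),
                 byrow = TRUE, dimnames = list(SIM_CLASSES, c("S", "T", "Y")))
  w_f <- mix[["MI_peak_fast"]]
  w_s <- mix[["MI_peak_stable"]]
  w_r <- 1 - w_f - w_s
  if (w_r <= 0) return(flat)
  y <- props[["Y"]]
  t_f <- if (w_f > 0) min(0.8, 0.95 * props[["T"]] / w_f) else props[["T"]]
  fast <- c(S = 1 - t_f - y, T = t_f, Y = y)
  t_s <- min(0.01, props[["T"]])
  sp <- c(S = 1 - t_s - y, T = t_s, Y = y)
  resid <- (props - w_f * fast - w_s * sp) / w_r
  out <- flat
  out["MI_peak_fast", ] <- fast
  out["MI_peak_stable", ] <- sp
  for (cl in setdiff(SIM_CLASSES, c("MI_peak_fast", "MI_peak_stable"))) {
    out[cl, ] <- resid
  }
  if (any(out < -1e-12 | out > 1 + 1e-12)) {
    inform("Configured class mix cannot support acceptor tilts; using the marginal for all classes.")
    return(flat)
  }
  pmin(pmax(out, 0), 1)
}

# Multiplicative lognormal noise factors with unit mean and the given CV.
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic integer allocation of n items to proportions (largest
# remainder), so noiseless class fractions are exact.
allocate_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(left)]] <- counts[order_idx[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

#' Simulate a multiplexed phospho and proteome time course
#'
#' Generates a peptide-level proteome table, a phosphopeptide table, the
#' protein sequences carrying the planted site windows, the stage design,
#' and the ground truth (class labels, noiseless trajectories, sequence
#' context, planted motif flags). Identical configurations give identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `phos_simulation` with elements `peptides`,
#'   `phospho`, `sequences`, `design`, and `truth`.
#' @examples
#' sim <- simulate_phospho_timecourse(sim_config(n_proteins = 20,
#'                                               n_phosphosites = 50))
#' dplyr::count(sim$truth$sites, class)
#' @export
simulate_phospho_timecourse <- function(cfg) {
  validate_sim_config(cfg)
  stages <- cfg$stages
  L <- length(stages)
  design <- stage_design(stages, n_multiplexes = cfg$n_multiplexes)
  muxes <- design_multiplexes(design)
  chans <- names(design_channel_map(design, muxes[1]))
  refch <- design_reference(design, muxes[1])
  all_ch <- c(chans, refch)

  ## --- protein stream -----------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  protein_ids <- sprintf("P%05d", seq_len(cfg$n_proteins))
  n_reg <- round((1 - cfg$frac_stable_proteins) * cfg$n_proteins)
  regulated <- sample(cfg$n_proteins, n_reg)
  prot_class <- rep("stable", cfg$n_proteins)
  prot_class[regulated] <- "regulated"
  reg_template <- template_on_stages(c(1, 1, 0.9, 0.45, 0.25, 0.8), L)
  prot_templates <- matrix(1, nrow = cfg$n_proteins, ncol = L)
  if (n_reg > 0) {
    prot_templates[regulated, ] <- matrix(reg_template, nrow = n_reg, ncol = L,
                                          byrow = TRUE)
  }
  prot_base <- rlnorm(cfg$n_proteins, meanlog = log(1e7), sdlog = 0.8)
  n_pep <- 1L + stats::rpois(cfg$n_proteins, 2)
  pep_weights <- lapply(n_pep, function(k) {
    w <- runif(k, 0.2, 1)
    w / sum(w)
  })

  ## --- technical factor stream --------------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  loading <- matrix(lnoise(cfg$n_multiplexes * length(all_ch), cfg$channel_loading_cv),
                    nrow = cfg$n_multiplexes,
                    dimnames = list(muxes, all_ch))
  mux_scale_prot <- lnoise(cfg$n_multiplexes, cfg$multiplex_scale_cv)
  mux_scale_phos <- lnoise(cfg$n_multiplexes, cfg$multiplex_scale_cv)

  ## --- peptide (proteome) table -------------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  pep_protein <- rep(seq_len(cfg$n_proteins), n_pep)
  pep_share <- unlist(pep_weights)
  n_pep_total <- length(pep_protein)
  pep_rows <- vector("list", cfg$n_multiplexes)
  for (mi in seq_len(cfg$n_multiplexes)) {
    occ <- cbind(prot_templates, rowMeans(prot_templates))[pep_protein, , drop = FALSE]
    base <- prot_base[pep_protein] * pep_share
    cells <- base * occ
    cells <- sweep(cells, 2, loading[mi, all_ch], `*`) * mux_scale_prot[mi]
    cells <- cells * matrix(lnoise(length(cells), cfg$noise_cv), nrow = nrow(cells))
    colnames(cells) <- all_ch
    pep_rows[[mi]] <- bind_cols(
      tibble(
        peptide_id = sprintf("prpep%06d", seq_len(n_pep_total)),
        protein_id = protein_ids[pep_protein],
        multiplex_id = muxes[mi]
      ),
      as_tibble(cells)
    )
  }
  peptides <- bind_rows(pep_rows)

  ## --- phosphosite stream --------------------------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  n <- cfg$n_phosphosites
  site_protein <- sample(cfg$n_proteins, n, replace = TRUE)
  site_class <- sample(SIM_CLASSES, n, replace = TRUE, prob = cfg$class_mix[SIM_CLASSES])
  acc_probs <- acceptor_class_probs(cfg)
  acceptor <- vapply(seq_len(n), function(i) {
    sample(c("S", "T", "Y"), 1, prob = acc_probs[site_class[i], ])
  }, character(1))
  loc_low <- runif(n) < cfg$loc_below_frac
  loc_prob <- ifelse(loc_low, runif(n, 0.3, 0.9 - 1e-6), 1 - 0.1 * rbeta(n, 1, 9))

  half <- 7L
  width <- 2L * half + 1L
  win <- matrix(sample(AA20, n * width, replace = TRUE), nrow = n)
  centre <- half + 1L
  win[, centre] <- acceptor
  is_mi_peak <- site_class %in% .increasing_classes
  # +1 proline: always for MI-peak (proline-directed) classes, occasional
  # elsewhere; +2 class-conditional context for the fast (basic) and stable
  # (acidic) MI-peak classes.
  plus1_p <- is_mi_peak | runif(n) < 0.1
  win[plus1_p, centre + 1L] <- "P"
  fast <- site_class == "MI_peak_fast"
  win[fast, centre + 2L] <- sample(AA_BASIC, sum(fast), replace = TRUE)
  spc <- site_class == "MI_peak_stable"
  win[spc, centre + 2L] <- sample(AA_ACIDIC, sum(spc), replace = TRUE)

  # Planted RxRxxS/T consensus with class-dependent -4 basophilicity.
  consensus <- runif(n) < cfg$consensus_frac & acceptor %in% c("S", "T")
  win[consensus, centre - 5L] <- "R"
  win[consensus, centre - 3L] <- "R"
  minus4_basic_p <- ifelse(is_mi_peak, 0.1, 0.6)
  m4_basic <- consensus & runif(n) < minus4_basic_p
  win[m4_basic, centre - 4L] <- sample(AA_BASIC, sum(m4_basic), replace = TRUE)
  m4_other <- consensus & !m4_basic
  win[m4_other, centre - 4L] <- sample(setdiff(AA20, AA_BASIC), sum(m4_other),
                                       replace = TRUE)

  # Planted RVxF motifs, drawn from intermediate-class S/T sites that carry
  # no consensus plant; the x position is the phosphosite.
  w_int <- cfg$class_mix[["MI_peak_intermediate"]]
  rvxf_p <- if (w_int > 0) min(1, cfg$rvxf_frac / w_int) else 0
  rvxf <- site_class == "MI_peak_intermediate" & acceptor %in% c("S", "T") &
    !consensus & runif(n) < rvxf_p
  win[rvxf, centre - 3L] <- "K"
  win[rvxf, centre - 2L] <- "V"
  win[rvxf, centre - 1L] <- "V"
  win[rvxf, centre + 1L] <- "F"

  multi <- runif(n) < cfg$multi_site_frac
  sec_acceptor <- ifelse(multi,
                         vapply(seq_len(n), function(i) {
                           sample(c("S", "T", "Y"), 1, prob = cfg$acceptor_props)
                         }, character(1)),
                         NA_character_)
  sec_loc <- ifelse(multi, 1 - 0.1 * rbeta(n, 1, 9), NA_real_)
  sec_win <- matrix(sample(AA20, n * width, replace = TRUE), nrow = n)
  sec_win[, centre] <- ifelse(is.na(sec_acceptor), "S", sec_acceptor)

  ## --- sequences: embed windows at allocated positions --------------------
  set.seed(derive_seed(cfg$seed, 5L))
  # Slots per protein: each primary site takes one slot, each secondary site
  # the next; positions are spaced so windows never overlap.
  slot <- integer(n)
  sec_slot <- integer(n)
  used <- integer(cfg$n_proteins)
  for (i in seq_len(n)) {
    p <- site_protein[i]
    used[p] <- used[p] + 1L
    slot[i] <- used[p]
    if (multi[i]) {
      used[p] <- used[p] + 1L
      sec_slot[i] <- used[p]
    }
  }
  position <- 8L + (slot - 1L) * 15L
  sec_position <- ifelse(multi, 8L + (sec_slot - 1L) * 15L, NA_integer_)
  seq_len_prot <- pmax(60L, used * 15L + 30L)
  sequences <- vapply(seq_len(cfg$n_proteins), function(p) {
    paste(sample(AA20, seq_len_prot[p], replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- protein_ids
  embed <- function(seqs, prot_idx, pos, wins) {
    for (i in seq_along(prot_idx)) {
      p <- prot_idx[i]
      substr(seqs[p], pos[i] - half, pos[i] + half) <-
        paste(wins[i, ], collapse = "")
    }
    seqs
  }
  sequences <- embed(sequences, site_protein, position, win)
  if (any(multi)) {
    sequences <- embed(sequences, site_protein[multi], sec_position[multi],
                       sec_win[multi, , drop = FALSE])
  }

  ## --- phospho intensities, noise, dropout --------------------------------
  set.seed(derive_seed(cfg$seed, 6L))
  templates <- class_templates(cfg)
  eps <- cfg$baseline_occupancy
  occ <- eps + (1 - eps) * templates[site_class, , drop = FALSE]
  occ_full <- cbind(occ, rowMeans(occ))
  colnames(occ_full) <- all_ch
  site_base <- rlnorm(n, meanlog = log(5e5), sdlog = 0.8)
  phos_rows <- vector("list", cfg$n_multiplexes)
  peptide_ids <- sprintf("pep%06d", seq_len(n))
  for (mi in seq_len(cfg$n_multiplexes)) {
    cells <- site_base * occ_full
    cells <- sweep(cells, 2, loading[mi, all_ch], `*`) * mux_scale_phos[mi]
    cells <- cells * matrix(lnoise(length(cells), cfg$noise_cv), nrow = n)
    colnames(cells) <- all_ch
    keep <- runif(n) >= cfg$missing_rate
    phos_rows[[mi]] <- bind_cols(
      tibble(
        peptide_id = peptide_ids,
        protein_id = protein_ids[site_protein],
        multiplex_id = muxes[mi],
        site_positions = purrr::map2(position, ifelse(multi, sec_position, NA_integer_),
                                     function(a, b) if (is.na(b)) a else c(a, b)),
        acceptor_residues = purrr::map2(acceptor, sec_acceptor,
                                        function(a, b) if (is.na(b)) a else c(a, b)),
        localization_probs = purrr::map2(loc_prob, sec_loc,
                                         function(a, b) if (is.na(b)) a else c(a, b))
      ),
      as_tibble(cells)
    )[keep, , drop = FALSE]
  }
  phospho <- bind_rows(phos_rows)

  peak_stage_of <- stages[apply(templates, 1, which.max)]
  names(peak_stage_of) <- rownames(templates)
  truth_sites <- tibble(
    peptide_id = peptide_ids,
    protein_id = protein_ids[site_protein],
    position = position,
    acceptor = acceptor,
    class = site_class,
    peak_stage = unname(peak_stage_of[site_class]),
    localization_prob = loc_prob,
    window = apply(win, 1, paste, collapse = ""),
    plus1_proline = unname(win[, centre + 1L] == "P"),
    plus2_residue = unname(win[, centre + 2L]),
    consensus_planted = consensus,
    minus4_basic = m4_basic,
    rvxf_planted = rvxf,
    multi_site = multi,
    template = purrr::map(site_class, function(cl) stats::setNames(templates[cl, ], stages))
  )
  truth_proteins <- tibble(
    protein_id = protein_ids,
    profile_class = prot_class,
    true_max_fold_change = apply(prot_templates, 1, function(x) max(x) / min(x))
  )

  structure(
    list(
      peptides = peptides,
      phospho = phospho,
      sequences = sequences,
      design = design,
      truth = list(sites = truth_sites, proteins = truth_proteins,
                   templates = templates, config = cfg)
    ),
    class = "phos_simulation"
  )
}

#' @export
print.phos_simulation <- function(x, ...) {
  cat("<phos_simulation> ", nrow(x$truth$sites), " phosphosites, ",
      nrow(x$truth$proteins), " proteins, ",
      length(design_multiplexes(x$design)), " multiplexes\n", sep = "")
  invisible(x)
}

#' Simulate a multi-timepoint treatment experiment
#'
#' Emulates a phosphatase-inhibitor style design: phosphosites measured over
#' ordered treatment timepoints in replicate multiplexes, with planted
#' response classes (e.g. 85% strong responders). Class counts are allocated
#' deterministically (largest remainder) so noiseless responder fractions
#' are exact.
#'
#' @param cfg A [sim_config()]; `n_phosphosites`, `n_multiplexes`,
#'   `noise_cv`, `missing_rate`, `loc_below_frac`, technical CVs and `seed`
#'   are used.
#' @param condition_labels Ordered treatment timepoint labels
#'   (default 0/30/70 min).
#' @param effect_spec Named list of response classes, each a list with
#'   `frac` (proportions summing to 1) and `profile` (noiseless occupancy
#'   per timepoint in `[0, 1]`).
#' @return A list of class `phos_condition_sim` with `phospho`, `design`,
#'   and `truth` (per-site class labels and profiles).
#' @export
simulate_condition_experiment <- function(cfg,
                                          condition_labels = c("0min", "30min", "70min"),
                                          effect_spec = list(
                                            increased_high = list(frac = 0.85, profile = c(0.05, 0.55, 0.95)),
                                            decreased = list(frac = 0.05, profile = c(0.90, 0.55, 0.20)),
                                            unchanged = list(frac = 0.10, profile = c(0.40, 0.40, 0.40))
                                          )) {
  validate_sim_config(cfg)
  if (length(condition_labels) < 2) abort("Need at least two condition labels.")
  if (length(effect_spec) == 0) abort("`effect_spec` must not be empty.")
  fracs <- vapply(effect_spec, function(e) e$frac, numeric(1))
  if (abs(sum(fracs) - 1) > 1e-9) abort("effect_spec fractions must sum to 1.")
  profiles <- lapply(effect_spec, function(e) {
    if (length(e$profile) != length(condition_labels)) {
      abort("Each effect profile needs one value per condition label.")
    }
    e$profile
  })

  L <- length(condition_labels)
  design <- stage_design(condition_labels, n_multiplexes = cfg$n_multiplexes)
  muxes <- design_multiplexes(design)
  chans <- names(design_channel_map(design, muxes[1]))
  refch <- design_reference(design, muxes[1])
  all_ch <- c(chans, refch)

  set.seed(derive_seed(cfg$seed, 11L))
  n <- cfg$n_phosphosites
  counts <- allocate_counts(n, fracs)
  site_class <- sample(rep(names(counts), counts))
  prof_mat <- do.call(rbind, profiles)[site_class, , drop = FALSE]
  eps <- cfg$baseline_occupancy
  occ <- eps + (1 - eps) * prof_mat
  occ_full <- cbind(occ, rowMeans(occ))
  colnames(occ_full) <- all_ch
  site_base <- rlnorm(n, meanlog = log(5e5), sdlog = 0.8)
  acceptor <- sample(c("S", "T", "Y"), n, replace = TRUE, prob = cfg$acceptor_props)
  loc_low <- runif(n) < cfg$loc_below_frac
  loc_prob <- ifelse(loc_low, runif(n, 0.3, 0.9 - 1e-6), 1 - 0.1 * rbeta(n, 1, 9))
  loading <- matrix(lnoise(cfg$n_multiplexes * length(all_ch), cfg$channel_loading_cv),
                    nrow = cfg$n_multiplexes, dimnames = list(muxes, all_ch))
  mux_scale <- lnoise(cfg$n_multiplexes, cfg$multiplex_scale_cv)

  peptide_ids <- sprintf("cpep%06d", seq_len(n))
  rows <- vector("list", cfg$n_multiplexes)
  for (mi in seq_len(cfg$n_multiplexes)) {
    cells <- site_base * occ_full
    cells <- sweep(cells, 2, loading[mi, all_ch], `*`) * mux_scale[mi]
    cells <- cells * matrix(lnoise(length(cells), cfg$noise_cv), nrow = n)
    colnames(cells) <- all_ch
    keep <- runif(n) >= cfg$missing_rate
    rows[[mi]] <- bind_cols(
      tibble(
        peptide_id = peptide_ids,
        protein_id = sprintf("CP%05d", seq_len(n)),
        multiplex_id = muxes[mi],
        site_positions = as.list(rep(8L, n)),
        acceptor_residues = as.list(acceptor),
        localization_probs = as.list(loc_prob)
      ),
      as_tibble(cells)
    )[keep, , drop = FALSE]
  }

  structure(
    list(
      phospho = bind_rows(rows),
      design = design,
      truth = tibble(
        peptide_id = peptide_ids,
        class = site_class,
        profile = purrr::map(site_class, function(cl) {
          stats::setNames(profiles[[cl]], condition_labels)
        })
      )
    ),
    class = "phos_condition_sim"
  )
}
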