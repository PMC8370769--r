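# Internal helpers shared across modules.

# Columns that are metadata rather than intensity channels.
.meta_cols <- c(
  "peptide_id", "protein_id", "multiplex_id",
  "site_positions", "acceptor_residues", "localization_probs",
  "ref_missing", "degenerate", "n_observed", "feature_id"
)

# Intensity (channel) columns of a quant table: numeric, not metadata.
intensity_cols <- function(tbl) {
  cand <- setdiff(names(tbl), .meta_cols)
  cand[vapply(tbl[cand], is.numeric, logical(1))]
}

# Sum/mean that treat all-missing as missing, never as zero.
sum_keep_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
mean_keep_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
sd_keep_na <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else sd(x, na.rm = TRUE)

# ';'-joined list fields used in the on-disk TSV representation.
join_field <- function(x) vapply(x, function(v) paste(v, collapse = ";"), character(1))
split_field <- function(x, f = identity) lapply(strsplit(as.character(x), ";", fixed = TRUE), f)

# Sample moments (used for abundance-distribution QC).
moment_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(NA_real_)
  mean((x - m)^3) / s^3
}

moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

# Derive a sub-stream seed from a master seed; keeps results stable when
# independent table draws are added or resized.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 10007) %% 2147483647)
}

# Extract a trajectory matrix (features x stages) from a wide tibble.
traj_matrix <- function(traj, stages) {
  stopifnot(all(stages %in% names(traj)))
  m <- as.matrix(traj[, stages, drop = FALSE])
  rownames(m) <- traj$feature_id
  m
}

traj_stages <- function(traj, stages = NULL) {
  stages %||% attr(traj, "stages") %||%
    abort("`stages` must be supplied or stored as an attribute of the trajectory table.")
}
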