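# Shared small fixtures built in code.

small_sim_config <- function(...) {
  sim_config(n_proteins = 40, n_phosphosites = 200, seed = 101, ...)
}

noiseless_config <- function(n_phosphosites = 300, ...) {
  sim_config(
    n_proteins = 50, n_phosphosites = n_phosphosites,
    noise_cv = 0, missing_rate = 0, loc_below_frac = 0,
    frac_stable_proteins = 1, multi_site_frac = 0,
    seed = 202, ...
  )
}

# A tiny hand-built quant table: two multiplexes, two stages + reference.
tiny_design <- function(n_multiplexes = 2) {
  stage_design(c("A", "B", "C"), n_multiplexes = n_multiplexes)
}

tiny_protein_table <- function() {
  tibble::tibble(
    protein_id = rep(c("P1", "P2"), each = 2),
    multiplex_id = rep(c("M1", "M2"), 2),
    C1 = c(10, 20, 30, 40),
    C2 = c(12, 24, 36, 48),
    C3 = c(8, 16, 24, 32),
    REF = c(10, 20, 30, 40)
  )
}
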