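# The generator: config validation, determinism, planted-structure fidelity.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(acceptor_props = c(S = 0.5, T = 0.5, Y = 0.5)),
               "sum to 1")
  expect_error(sim_config(class_mix = c(stable = 2)), "class_mix")
  expect_error(sim_config(stages = c("A", "B")), "3 stages")
  expect_error(sim_config(n_phosphosites = 3), "number of classes")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_s3_class(sim_config(), "phos_sim_config")
})

test_that("same config and seed give byte-identical tables", {
  cfg <- small_sim_config()
  s1 <- simulate_phospho_timecourse(cfg)
  s2 <- simulate_phospho_timecourse(cfg)
  expect_identical(s1$phospho, s2$phospho)
  expect_identical(s1$peptides, s2$peptides)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth$sites, s2$truth$sites)
  s3 <- simulate_phospho_timecourse(small_sim_config(noise_cv = 0.2))
  expect_false(identical(s1$phospho, s3$phospho))
})

test_that("acceptor, class and localization fractions converge to config", {
  cfg <- sim_config(n_proteins = 200, n_phosphosites = 8000,
                    loc_below_frac = 0.2, seed = 11)
  sim <- simulate_phospho_timecourse(cfg)
  sites <- sim$truth$sites
  # 99% binomial envelopes at n = 8000
  for (aa in c("S", "T", "Y")) {
    ci <- stats::binom.test(sum(sites$acceptor == aa), nrow(sites))$conf.int
    expect_true(cfg$acceptor_props[[aa]] >= ci[1] - 0.01 &&
                  cfg$acceptor_props[[aa]] <= ci[2] + 0.01)
  }
  frac_low <- mean(sites$localization_prob < 0.9)
  expect_lt(abs(frac_low - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(sites)) + 0.005)
  cls <- table(sites$class) / nrow(sites)
  for (cl in names(cfg$class_mix)) {
    expect_lt(abs(cls[[cl]] - cfg$class_mix[[cl]]), 0.02)
  }
})

test_that("emitted FASTA is consistent with declared site coordinates", {
  sim <- simulate_phospho_timecourse(small_sim_config(multi_site_frac = 0.2))
  sites <- sim$truth$sites
  at_pos <- substr(sim$sequences[sites$protein_id], sites$position, sites$position)
  expect_identical(unname(at_pos), sites$acceptor)
  # every record's declared sites match the sequence too (incl. secondary)
  rec <- sim$phospho[!duplicated(sim$phospho$peptide_id), ]
  for (i in seq_len(nrow(rec))) {
    pos <- rec$site_positions[[i]]
    acc <- rec$acceptor_residues[[i]]
    seqs <- sim$sequences[[rec$protein_id[i]]]
    expect_identical(vapply(pos, function(p) substr(seqs, p, p), character(1)), acc)
  }
  # planted windows are recoverable from the sequences
  w <- substr(sim$sequences[sites$protein_id], sites$position - 7, sites$position + 7)
  expect_identical(unname(w), sites$window)
})

test_that("noiseless fast-class truth drops by exactly dephos_delta at MI->MII", {
  cfg <- noiseless_config()
  tmpl <- class_templates(cfg)
  expect_equal(tmpl["MI_peak_fast", "MI"] - tmpl["MI_peak_fast", "MII"],
               cfg$dephos_delta[["fast"]])
  expect_equal(tmpl["MI_peak_stable", "MI"] - tmpl["MI_peak_stable", "MII"],
               cfg$dephos_delta[["stable"]])
  # MI-peak templates are anchored so unit scaling is the identity
  for (cl in c("MI_peak_fast", "MI_peak_intermediate", "MI_peak_stable")) {
    expect_equal(min(tmpl[cl, ]), 0)
    expect_equal(max(tmpl[cl, ]), 1)
  }
})

test_that("class-conditional acceptor draws preserve the S/T/Y marginal", {
  cfg <- sim_config()
  pr <- phosflow:::acceptor_class_probs(cfg)
  marginal <- colSums(pr * cfg$class_mix[rownames(pr)])
  expect_equal(unname(marginal), unname(cfg$acceptor_props[c("S", "T", "Y")]),
               tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
  # the TP tilt is real: fast class much more threonine-rich than marginal
  expect_gt(pr["MI_peak_fast", "T"], 2 * cfg$acceptor_props[["T"]])
})

test_that("condition experiment plants exact responder fractions and is seeded", {
  cfg <- noiseless_config(n_phosphosites = 1000)
  cs1 <- simulate_condition_experiment(cfg)
  cs2 <- simulate_condition_experiment(cfg)
  expect_identical(cs1$phospho, cs2$phospho)
  expect_equal(mean(cs1$truth$class == "increased_high"), 0.85)
  expect_error(simulate_condition_experiment(cfg, effect_spec = list()), "empty")
  expect_error(simulate_condition_experiment(cfg, condition_labels = "t0"),
               "two condition labels")
})

test_that("noiseless condition experiment is recovered exactly by response classification", {
  cfg <- noiseless_config(n_phosphosites = 400)
  cs <- simulate_condition_experiment(cfg)
  norm <- normalize_multiplexes(cs$phospho, cs$design)
  resp <- classify_treatment_response(norm, cs$design, high_threshold = 0.5)
  got <- resp$sites$class[match(cs$truth$peptide_id, resp$sites$feature_id)]
  expect_identical(got, cs$truth$class)
  frac <- resp$fractions$fraction[resp$fractions$class == "increased_high"]
  expect_equal(frac, 0.85)
})
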