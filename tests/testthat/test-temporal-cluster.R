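# Hierarchical clustering, peak stages, stage summaries.

mk_traj <- function(m, stages = paste0("S", seq_len(ncol(m)))) {
  tb <- tibble::as_tibble(m, .name_repair = "minimal")
  names(tb) <- stages
  tb <- dplyr::mutate(tb, feature_id = sprintf("f%02d", seq_len(nrow(m))),
                      .before = 1)
  attr(tb, "stages") <- stages
  tb
}

test_that("UPGMA clustering matches a brute-force oracle on small inputs", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 4), nrow = n)
    k <- sample(2:(n - 1), 1)
    res <- hierarchical_cluster(mk_traj(m), k = k)
    expect_true(same_partition(res$assignments$cluster, oracle_upgma_cut(m, k)))
  }
})

test_that("degenerate cuts behave: duplicates merge at zero, k = n is singleton, k > n errors", {
  m <- rbind(c(0, 1, 0), c(0, 1, 0), c(5, 5, 5))
  res <- hierarchical_cluster(mk_traj(m), k = 2)
  expect_equal(min(res$hclust$height), 0)
  expect_equal(res$assignments$cluster[1], res$assignments$cluster[2])
  res_n <- hierarchical_cluster(mk_traj(m), k = 3)
  expect_equal(sort(res_n$assignments$cluster), 1:3)
  expect_error(hierarchical_cluster(mk_traj(m), k = 4), "exceeds")
})

test_that("two well-separated planted groups are recovered at k = 2", {
  set.seed(42)
  m <- rbind(
    matrix(rep(c(0, 0, 1, 1), 4), nrow = 4, byrow = TRUE) + rnorm(16, sd = 0.01),
    matrix(rep(c(1, 1, 0, 0), 4), nrow = 4, byrow = TRUE) + rnorm(16, sd = 0.01)
  )
  res <- hierarchical_cluster(mk_traj(m), k = 2)
  expect_true(same_partition(res$assignments$cluster, rep(1:2, each = 4)))
})

test_that("the minimum-size cut leaves isolated outliers unassigned", {
  set.seed(43)
  m <- rbind(
    matrix(rep(c(0, 0, 1), 5), nrow = 5, byrow = TRUE) + rnorm(15, sd = 0.01),
    matrix(rep(c(1, 0, 0), 5), nrow = 5, byrow = TRUE) + rnorm(15, sd = 0.01),
    c(10, 10, 10)
  )
  res <- hierarchical_cluster(mk_traj(m), k = 2, min_cluster_size = 3)
  expect_true(is.na(res$assignments$cluster[11]))
  expect_true(same_partition(res$assignments$cluster[1:10], rep(1:2, each = 5)))
})

test_that("peak stage is the earliest argmax and survives monotone transforms", {
  stages <- c("Pro", "GVBD", "MI", "MII", "2-PN", "FC")
  m <- rbind(c(0.1, 0.2, 1.0, 0.3, 0.2, 0.1),
             c(1, 0, 0, 0, 0, 1),
             c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
  tr <- assign_peak_stage(mk_traj(m, stages))
  expect_equal(tr$peak_stage[1], "MI")
  expect_equal(tr$peak_stage[2], "Pro")  # earliest tie wins
  # strictly increasing transform leaves the argmax unchanged
  tr2 <- assign_peak_stage(mk_traj(exp(3 * m), stages))
  expect_equal(tr2$peak_stage, tr$peak_stage)
  # degenerate-flagged rows get NA
  sc <- scale_unit_interval(mk_traj(m, stages), min_stages = 3)
  trd <- assign_peak_stage(sc)
  expect_true(is.na(trd$peak_stage[3]))
})

test_that("stage summaries report peak fractions summing to one", {
  stages <- c("Pro", "MI", "FC")
  m <- rbind(c(0, 1, 0.5), c(0.2, 1, 0), c(0, 0.9, 1))
  tr <- assign_peak_stage(mk_traj(m, stages))
  ss <- stage_summaries(tr)
  expect_equal(sum(ss$peak_fraction), 1)
  expect_equal(ss$peak_fraction[ss$stage == "MI"], 2 / 3)
  expect_equal(unname(ss$mean_abundance), unname(colMeans(m)))
  all_mi <- assign_peak_stage(mk_traj(m[1:2, , drop = FALSE], stages))
  expect_equal(stage_summaries(all_mi)$peak_fraction[2], 1)
})

test_that("MI-peak singleton selection equals a brute-force predicate scan", {
  sim <- simulate_phospho_timecourse(small_sim_config(multi_site_frac = 0.25,
                                                      loc_below_frac = 0.3))
  norm <- normalize_multiplexes(sim$phospho, sim$design)
  traj <- assign_peak_stage(scale_unit_interval(stage_means(norm, sim$design)))
  sel <- select_mi_peak_singletons(norm, traj)
  # independent predicate scan over deduplicated records
  rec <- norm[!duplicated(norm$peptide_id), ]
  expected <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (length(rec$site_positions[[i]]) != 1) next
    if (rec$localization_probs[[i]][1] < 0.9) next
    ps <- traj$peak_stage[traj$feature_id == rec$peptide_id[i]]
    if (length(ps) == 1 && !is.na(ps) && ps == "MI") {
      expected <- c(expected, rec$peptide_id[i])
    }
  }
  expect_setequal(sel$peptide_id, expected)
  # doubly phosphorylated records never appear
  multi_ids <- sim$truth$sites$peptide_id[sim$truth$sites$multi_site]
  expect_length(intersect(sel$peptide_id, multi_ids), 0)
})

test_that("noiseless planted MI-peak classes are recovered perfectly at k = 3", {
  cfg <- noiseless_config(n_phosphosites = 240)
  sim <- simulate_phospho_timecourse(cfg)
  res <- run_phospho_pipeline(sim$phospho, sim$peptides, sim$design, k = 3)
  asg <- res$clusters$assignments
  truth_cl <- sim$truth$sites$class[match(asg$feature_id, sim$truth$sites$peptide_id)]
  keep <- !is.na(asg$cluster)
  expect_equal(oracle_ari(asg$cluster[keep], truth_cl[keep]), 1)
})
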