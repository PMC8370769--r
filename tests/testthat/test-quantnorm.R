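# Rollup, normalization, scaling, fold change.

test_that("protein rollup sums peptides per cell and keeps all-missing as NA", {
  peps <- tibble::tibble(
    peptide_id = c("a", "b", "c"),
    protein_id = c("P1", "P1", "P2"),
    multiplex_id = "M1",
    C1 = c(10, 30, 5), C2 = c(20, 40, NA), C3 = c(NA, NA, 2)
  )
  out <- rollup_proteins(peps)
  p1 <- out[out$protein_id == "P1", ]
  expect_equal(c(p1$C1, p1$C2), c(40, 60))
  expect_true(is.na(p1$C3))   # both contributing cells missing
  p2 <- out[out$protein_id == "P2", ]
  expect_true(is.na(p2$C2))
  expect_equal(rollup_proteins(peps[2, ])$C1, 30)  # single peptide: identity
  expect_equal(nrow(rollup_proteins(peps[0, ])), 0)
})

test_that("rollup equals a brute-force per-cell sum and is split-additive", {
  set.seed(5)
  n <- 1000
  peps <- tibble::tibble(
    peptide_id = sprintf("pep%04d", seq_len(n)),
    protein_id = sample(sprintf("P%02d", 1:50), n, replace = TRUE),
    multiplex_id = sample(c("M1", "M2"), n, replace = TRUE),
    C1 = stats::rlnorm(n), C2 = stats::rlnorm(n)
  )
  out <- rollup_proteins(peps)
  for (i in sample(nrow(out), 20)) {
    rows <- peps$protein_id == out$protein_id[i] &
      peps$multiplex_id == out$multiplex_id[i]
    expect_equal(out$C1[i], sum(peps$C1[rows]))
    expect_equal(out$C2[i], sum(peps$C2[rows]))
  }
  # splitting any peptide row into two rows summing to it changes nothing
  frac <- runif(n)
  split_peps <- dplyr::bind_rows(
    dplyr::mutate(peps, C1 = C1 * frac, C2 = C2 * frac),
    dplyr::mutate(peps, peptide_id = paste0(peptide_id, "_b"),
                  C1 = C1 * (1 - frac), C2 = C2 * (1 - frac))
  )
  out2 <- rollup_proteins(split_peps)
  expect_equal(out2, out, tolerance = 1e-12)
})

test_that("multiplex normalization equalizes reference channels per feature", {
  d <- tiny_design()
  tbl <- tiny_protein_table()
  tbl2 <- tbl
  # double every channel of M2: a pure multiplex scale factor
  for (ch in c("C1", "C2", "C3", "REF")) {
    tbl2[[ch]][tbl2$multiplex_id == "M2"] <- 2 * tbl[[ch]][tbl$multiplex_id == "M1"]
  }
  tbl2$REF[tbl2$multiplex_id == "M1"] <- tbl2$REF[tbl2$multiplex_id == "M2"] / 2
  norm <- normalize_multiplexes(tbl2, d)
  for (p in c("P1", "P2")) {
    refs <- norm$REF[norm$protein_id == p]
    expect_lt(diff(range(refs)), 1e-9)
  }
  # forced by definition: M2 stage values rescaled toward the mean reference
  set.seed(8)
  rand <- tbl
  for (ch in c("C1", "C2", "C3", "REF")) rand[[ch]] <- stats::rlnorm(4, 2)
  nr <- normalize_multiplexes(rand, d)
  for (p in c("P1", "P2")) {
    expect_lt(diff(range(nr$REF[nr$protein_id == p])), 1e-9)
  }
  # fixed point: renormalizing changes nothing
  nr2 <- normalize_multiplexes(nr, d)
  for (ch in c("C1", "C2", "C3", "REF")) {
    expect_equal(nr2[[ch]], nr[[ch]], tolerance = 1e-9)
  }
  expect_error(
    normalize_multiplexes(dplyr::select(rand, -REF), d),
    "reference channel"
  )
})

test_that("one multiplex normalization is a per-feature constant rescale", {
  d <- tiny_design(n_multiplexes = 1)
  tbl <- dplyr::filter(tiny_protein_table(), multiplex_id == "M1")
  out <- normalize_multiplexes(tbl, d)
  for (p in tbl$protein_id) {
    ratio <- unlist(out[out$protein_id == p, c("C1", "C2", "C3")]) /
      unlist(tbl[tbl$protein_id == p, c("C1", "C2", "C3")])
    expect_lt(diff(range(ratio)), 1e-12)
  }
})

test_that("loading adjustment equalizes column totals", {
  d <- tiny_design(n_multiplexes = 1)
  tbl <- tibble::tibble(
    protein_id = c("P1", "P2"), multiplex_id = "M1",
    C1 = c(10, 30), C2 = c(20, 20), C3 = c(5, 35), REF = c(15, 25)
  )
  # already equal totals: fixed point
  out <- adjust_channel_loading(tbl, d, mode = "protein_total")
  expect_equal(out$C1, tbl$C1, tolerance = 1e-12)
  expect_equal(out$C3, tbl$C3, tolerance = 1e-12)

  # a channel at 2x total is scaled down by its excess over the mean total
  dbl <- dplyr::mutate(tbl, C2 = C2 * 2)
  out2 <- adjust_channel_loading(dbl, d, mode = "protein_total")
  expect_equal(out2$C2, dbl$C2 * (50 / 80), tolerance = 1e-12)
  expect_equal(sum(out2$C1), sum(out2$C2), tolerance = 1e-9)

  # random tables: totals equal post hoc, to 1e-9 relative
  set.seed(9)
  rnd <- dplyr::mutate(tbl, C1 = stats::rlnorm(2, 3), C2 = stats::rlnorm(2, 1),
                       C3 = stats::rlnorm(2, 2), REF = stats::rlnorm(2))
  out3 <- adjust_channel_loading(rnd, d, mode = "protein_total")
  totals <- vapply(c("C1", "C2", "C3", "REF"), function(ch) sum(out3[[ch]]), 1)
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)

  zero <- dplyr::mutate(tbl, C2 = 0)
  expect_error(adjust_channel_loading(zero, d, mode = "protein_total"), "C2")
})

test_that("phospho loading adjustment divides out the protein input per channel", {
  d <- tiny_design(n_multiplexes = 1)
  prot <- tibble::tibble(protein_id = c("P1", "P2"), multiplex_id = "M1",
                         C1 = c(100, 100), C2 = c(200, 200), C3 = c(50, 50),
                         REF = c(100, 100))
  phos <- tibble::tibble(
    peptide_id = c("s1", "s2"), protein_id = c("P1", "P2"), multiplex_id = "M1",
    site_positions = list(1L, 1L), acceptor_residues = list("S", "S"),
    localization_probs = list(1, 1),
    C1 = c(10, 20), C2 = c(20, 40), C3 = c(5, 10), REF = c(10, 20)
  )
  out <- adjust_channel_loading(phos, d, mode = "phospho_protein_input",
                                protein_table = prot)
  # C2 carried 2x protein input, C3 carried 0.5x: adjusted values equal
  expect_equal(out$C1, out$C2, tolerance = 1e-12)
  expect_equal(out$C1, out$C3, tolerance = 1e-12)
  expect_error(adjust_channel_loading(phos, d, mode = "phospho_protein_input"),
               "protein_table")
})

test_that("unit-interval scaling maps min/max, flags degenerates, and is affine-invariant", {
  traj <- tibble::tibble(feature_id = c("f1", "f2"),
                         A = c(2, 5), B = c(4, 5), C = c(6, 5))
  attr(traj, "stages") <- c("A", "B", "C")
  out <- scale_unit_interval(traj, min_stages = 3)
  expect_equal(unlist(out[1, c("A", "B", "C")]), c(A = 0, B = 0.5, C = 1))
  expect_true(out$degenerate[2])
  expect_equal(unlist(out[2, c("A", "B", "C")]), c(A = 0, B = 0, C = 0))

  # idempotence and positive-affine invariance
  set.seed(10)
  rnd <- tibble::tibble(feature_id = sprintf("f%d", 1:20),
                        A = rnorm(20), B = rnorm(20), C = rnorm(20),
                        D = rnorm(20))
  attr(rnd, "stages") <- c("A", "B", "C", "D")
  s1 <- scale_unit_interval(rnd, min_stages = 3)
  s2 <- scale_unit_interval(s1, min_stages = 3)
  expect_equal(s2[, c("A", "B", "C", "D")], s1[, c("A", "B", "C", "D")],
               tolerance = 1e-12)
  aff <- rnd
  for (ch in c("A", "B", "C", "D")) aff[[ch]] <- 3.7 * aff[[ch]] + 11
  attr(aff, "stages") <- c("A", "B", "C", "D")
  s3 <- scale_unit_interval(aff, min_stages = 3)
  expect_equal(s3[, c("A", "B", "C", "D")], s1[, c("A", "B", "C", "D")],
               tolerance = 1e-9)
})

test_that("max fold change is max/min with positivity enforced", {
  traj <- tibble::tibble(feature_id = c("f1", "f2"),
                         A = c(1, 3), B = c(1, 3), C = c(2, 3))
  attr(traj, "stages") <- c("A", "B", "C")
  fc <- max_fold_change(traj)
  expect_equal(unname(fc$max_fold_change), c(2, 1))
  bad <- traj
  bad$A[1] <- 0
  expect_error(max_fold_change(bad), "positive")
  summ <- fold_change_summary(fc, thresholds = c(1.5, 2))
  expect_equal(sum(summ$histogram$count), 2)
  expect_equal(summ$fraction_below$fraction, c(0.5, 0.5))
})

test_that("abundance distribution of a lognormal proteome is near-normal in log space", {
  set.seed(12)
  prot <- tibble::tibble(
    protein_id = sprintf("P%04d", 1:2000), multiplex_id = "M1",
    C1 = stats::rlnorm(2000, 12, 1)
  )
  ad <- abundance_distribution(prot)
  expect_lt(abs(ad$skewness), 0.15)
  expect_equal(sum(ad$histogram$count), 2000)
  one <- abundance_distribution(prot[1, ])
  expect_equal(nrow(one$data), 1)
  empty <- abundance_distribution(prot[0, ])
  expect_equal(nrow(empty$data), 0)
})
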