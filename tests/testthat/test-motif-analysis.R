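# Window extraction, site classification, logos, KS, motif scanning.

test_that("window extraction pads termini, validates acceptors, equals string slicing", {
  seqs <- c(PX = "STAYKLMNPQRSTVWYACDE")
  w <- extract_window(seqs, "PX", 1)
  expect_equal(substr(w, 1, 7), strrep("-", 7))
  expect_equal(substr(w, 8, 8), "S")
  expect_error(extract_window(seqs, "PX", 3, acceptor = "T"), "mismatch")
  expect_error(extract_window(seqs, "PX", 99), "out of range")
  set.seed(51)
  seqs2 <- c(PA = paste(sample(phosflow:::AA20, 60, replace = TRUE), collapse = ""))
  for (pos in c(1, 5, 30, 57, 60)) {
    w <- extract_window(seqs2, "PA", pos)
    lo <- max(1, pos - 7); hi <- min(60, pos + 7)
    expect_equal(gsub("-", "", w, fixed = TRUE), unname(substr(seqs2, lo, hi)))
    expect_equal(nchar(w), 15)
  }
})

test_that("site classification follows the rule table", {
  sites <- tibble::tibble(window = c(
    "AAAAAAATPKAAAAA",   # T, +1 P, +2 basic
    "AAAAAAASPEAAAAA",   # S, +1 P, +2 acidic
    "AAAAAAATPPAAAAA",   # T, +1 P, +2 proline
    "AAAAAAASAGAAAAA",   # S, no +1 P, +2 small nonpolar
    "AAAAAAATPKRKRAA",   # downstream basic patch
    "AAAAAAAS-------"    # edge: gap at +1/+2
  ))
  cl <- classify_sites(sites)
  expect_equal(cl$acceptor, c("T", "S", "T", "S", "T", "S"))
  expect_equal(cl$plus1_proline, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(cl$plus2_class,
               c("basic", "acidic", "proline", "small_nonpolar", "basic", "other"))
  expect_true(cl$downstream_basic_patch[5])
  expect_false(cl$downstream_basic_patch[2])
  expect_true(cl$edge[6])

  # pure function of the window string: independent rule table on random windows
  set.seed(52)
  rnd <- tibble::tibble(window = vapply(1:200, function(i) {
    paste(sample(phosflow:::AA20, 15, replace = TRUE), collapse = "")
  }, character(1)))
  got <- classify_sites(rnd)
  p2 <- substr(rnd$window, 10, 10)
  lookup <- rep("other", 200)
  lookup[p2 %in% c("K", "R", "H")] <- "basic"
  lookup[p2 %in% c("D", "E")] <- "acidic"
  lookup[p2 %in% c("A", "G")] <- "small_nonpolar"
  lookup[p2 == "P"] <- "proline"
  expect_equal(got$plus2_class, lookup)
  expect_equal(got$plus1_proline, substr(rnd$window, 9, 9) == "P")
})

test_that("logo enrichment: identity gives zero differences; counts match binomial tails", {
  set.seed(53)
  wins <- vapply(1:50, function(i) {
    paste(sample(phosflow:::AA20, 15, replace = TRUE), collapse = "")
  }, character(1))
  ident <- logo_enrichment(wins, wins)
  expect_true(all(ident$pct_diff == 0))
  expect_true(all(ident$call == "none"))

  # exp: 10/20 K at +2; ref: 100/1000 K at +2
  mk <- function(center_plus2, n) {
    vapply(seq_len(n), function(i) {
      w <- rep("A", 15); w[10] <- center_plus2[i]; paste(w, collapse = "")
    }, character(1))
  }
  expw <- mk(rep(c("K", "G"), c(10, 10)), 20)
  refw <- mk(rep(c("K", "G"), c(100, 900)), 1000)
  le <- logo_enrichment(expw, refw)
  row <- le[le$offset == 2 & le$residue == "K", ]
  expect_equal(row$pct_diff, 40)
  # one-sample z against p0 = 0.1 at k = 10, n = 20: strongly selected,
  # consistent with the exact binomial tail
  p_binom <- stats::binom.test(10, 20, 0.1)$p.value
  expect_lt(p_binom, 0.001)
  expect_lt(row$p_value, 0.001)
  expect_equal(row$call, "selected")
  expect_equal(row$z, (0.5 - 0.1) / sqrt(0.1 * 0.9 / 20), tolerance = 1e-12)
})

test_that("dephos deltas read scaled trajectories", {
  traj <- tibble::tibble(feature_id = c("a", "b"),
                         MI = c(1, 0.4), MII = c(0.2, 0.4))
  attr(traj, "stages") <- c("MI", "MII")
  dd <- dephos_delta(traj)
  expect_equal(dd$delta, c(0.8, 0))
  expect_error(dephos_delta(traj, from = "GVBD"), "stages")
})

test_that("KS comparison matches brute-force ECDF evaluation", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_compare(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(ks_compare(c(1, 3), c(2, 4))$statistic, 0.5)
  set.seed(54)
  for (i in 1:20) {
    a <- round(rnorm(sample(2:30, 1)), 1)  # rounding forces ties sometimes
    b <- round(rnorm(sample(2:30, 1), sd = 2), 1)
    expect_equal(ks_compare(a, b)$statistic, oracle_ks_D(a, b), tolerance = 1e-12)
  }
  expect_error(ks_compare(numeric(0), 1:3), "at least 2")
})

test_that("RVxF scanning matches the pattern definition and a naive scanner", {
  hits <- scan_rvxf(c(PA = "KSVSF"),
                    tibble::tibble(protein_id = "PA", position = 4L,
                                   acceptor = "S", peptide_id = "s1"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$x_position, 4L)
  expect_true(hits$phospho)
  expect_equal(hits$site_ids[[1]], "s1")
  expect_equal(nrow(scan_rvxf(c(PA = "KSVPF"))), 0)  # P excluded at x

  # overlapping matches are all reported
  ov <- scan_rvxf(c(PB = "KKVVWWAA"))  # KKVVW and KVVWW
  expect_equal(ov$start, c(1L, 2L))

  set.seed(55)
  for (i in 1:200) {
    s <- paste(sample(phosflow:::AA20, 40, replace = TRUE,
                      prob = c(rep(1, 20)) + 2 * (phosflow:::AA20 %in% c("K", "R", "V", "F", "S"))),
               collapse = "")
    got <- scan_rvxf(setNames(s, "PX"))$start
    expect_identical(as.integer(got), oracle_scan_rvxf(s))
  }
})

test_that("phospho flags respect the two-residue window around the motif", {
  # motif at 5..9, x at 8; sites at 2 (outside), 3 (= start-2), 11 (= end+2)
  seqs <- c(PZ = "ASTAKSVAFASTAAA")
  ps <- tibble::tibble(protein_id = "PZ", position = c(2L, 3L, 11L),
                       acceptor = c("S", "T", "S"),
                       peptide_id = c("a", "b", "c"))
  hits <- scan_rvxf(seqs, ps)
  expect_equal(hits$start, 5L)
  expect_setequal(hits$site_ids[[1]], c("b", "c"))
})

test_that("RVxF occupancy averages the linked scaled sites", {
  traj <- tibble::tibble(feature_id = c("s1", "s2", "s3"),
                         Pro = c(0, 0.2, 0.9), MI = c(1, 0.8, 0.1))
  attr(traj, "stages") <- c("Pro", "MI")
  hits <- tibble::tibble(protein_id = "P", start = 1L, end = 5L, match = "KSVSF",
                         x_position = 4L, phospho = TRUE,
                         site_ids = list(c("s1", "s2")))
  occ <- rvxf_occupancy(hits, traj)
  expect_equal(occ$mean, c(0.1, 0.9))
  expect_equal(occ$sd, c(stats::sd(c(0, 0.2)), stats::sd(c(1, 0.8))))
  one <- rvxf_occupancy(dplyr::mutate(hits, site_ids = list("s3")), traj)
  expect_equal(one$mean, c(0.9, 0.1))
  none <- rvxf_occupancy(dplyr::mutate(hits, phospho = FALSE), traj)
  expect_equal(nrow(none), 0)
})

test_that("kinase consensus split partitions by early fold change and reads -4", {
  # R at -5 and -3 => consensus; -4 K basophilic vs A not
  sites <- tibble::tibble(
    peptide_id = c("s1", "s2", "s3"),
    window = c("AARKRAASAAAAAAA",   # consensus, -4 K
               "AARARAATAAAAAAA",   # consensus, -4 A
               "AAAKRAASAAAAAAA")   # no R at -5
  )
  traj <- tibble::tibble(feature_id = c("s1", "s2", "s3"),
                         Pro = c(1, 1, 1), GVBD = c(5, 2, 9))
  attr(traj, "stages") <- c("Pro", "GVBD")
  res <- kinase_consensus_split(sites, traj, fold_threshold = 3)
  expect_equal(sort(res$sites$peptide_id), c("s1", "s2"))
  expect_equal(res$sites$increased[res$sites$peptide_id == "s1"], TRUE)
  expect_equal(res$sites$increased[res$sites$peptide_id == "s2"], FALSE)
  m4 <- res$minus4
  expect_equal(m4$minus4_basophilic_freq[m4$increased], 1)
  expect_equal(m4$minus4_basophilic_freq[!m4$increased], 0)

  # planted truth at scale: fast increasers carry A at -4, slow carry K
  set.seed(56)
  n <- 200
  mk_win <- function(m4) paste0("AAR", m4, "RAAS", "AAAAAAA")
  fastw <- vapply(rep("A", n), mk_win, character(1))
  sloww <- vapply(rep("K", n), mk_win, character(1))
  big <- tibble::tibble(peptide_id = sprintf("x%03d", 1:(2 * n)),
                        window = c(fastw, sloww))
  btraj <- tibble::tibble(feature_id = big$peptide_id,
                          Pro = 1, GVBD = c(rep(10, n), rep(1.2, n)))
  attr(btraj, "stages") <- c("Pro", "GVBD")
  bres <- kinase_consensus_split(big, btraj)
  bm4 <- bres$minus4
  expect_gt(bm4$minus4_basophilic_freq[!bm4$increased],
            bm4$minus4_basophilic_freq[bm4$increased])
  krow <- bres$logo[bres$logo$offset == -4 & bres$logo$residue == "K", ]
  expect_lt(krow$z, 0)  # K at -4 deselected among the fast increasers
})

test_that("zero-baseline consensus sites are excluded with a message", {
  sites <- tibble::tibble(peptide_id = "s1", window = "AARKRAASAAAAAAA")
  traj <- tibble::tibble(feature_id = "s1", Pro = 0, GVBD = 5)
  attr(traj, "stages") <- c("Pro", "GVBD")
  expect_message(res <- kinase_consensus_split(sites, traj), "zero baseline")
  expect_equal(nrow(res$sites), 0)
})

test_that("SP/TP analysis contrasts acceptors and +2 classes with adjusted KS", {
  set.seed(57)
  n <- 120
  mkw <- function(acc, p2) paste0("AAAAAAA", acc, "P", p2, "AAAAA")
  sites <- tibble::tibble(
    peptide_id = sprintf("s%03d", 1:(2 * n)),
    window = c(vapply(rep("T", n), mkw, character(1), p2 = "K"),
               vapply(rep("S", n), mkw, character(1), p2 = "E"))
  ) |> classify_sites()
  stages <- c("Pro", "GVBD", "MI", "MII", "2-PN", "FC")
  base_t <- c(0, 0.6, 1, 0.4, 0.15, 0.05)
  base_s <- c(0, 0.6, 1, 0.9, 0.88, 0.85)
  vals <- rbind(
    matrix(rep(base_t, n), nrow = n, byrow = TRUE),
    matrix(rep(base_s, n), nrow = n, byrow = TRUE)
  ) + matrix(rnorm(12 * n, sd = 0.05), nrow = 2 * n)
  traj <- tibble::as_tibble(vals, .name_repair = "minimal")
  names(traj) <- stages
  traj <- dplyr::mutate(traj, feature_id = sites$peptide_id, .before = 1)
  attr(traj, "stages") <- stages
  res <- sp_tp_analysis(sites, traj)
  main <- res$ks[res$ks$family == "SP_vs_TP", ]
  expect_lt(main$p_value, 1e-6)
  expect_gt(mean(res$deltas$delta[res$deltas$acceptor == "T"]),
            mean(res$deltas$delta[res$deltas$acceptor == "S"]))
  expect_true(all(res$ks$p_adj >= res$ks$p_value))
  # ECDFs are valid distribution functions
  for (g in unique(res$cdf$group)) {
    cc <- res$cdf$cdf[res$cdf$group == g]
    expect_true(all(diff(cc) >= 0))
    expect_equal(max(cc), 1)
  }
  # single acceptor: contrast skipped with a message
  expect_message(
    single <- sp_tp_analysis(sites[1:n, ], traj),
    "fewer than two groups"
  )
})
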