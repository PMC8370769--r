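# Independent brute-force oracles. Deliberately naive: direct definitions,
# full enumeration, no shared code with the package internals.

# Two-sample KS statistic by evaluating both ECDFs at every data point.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Hypergeometric probability of a 2xC table with fixed margins.
oracle_table_prob <- function(m) {
  col <- colSums(m)
  N <- sum(m)
  r1 <- sum(m[1, ])
  exp(sum(lchoose(col, m[1, ])) - lchoose(N, r1))
}

# Two-sided Fisher exact p for a 2x2 table: full enumeration, summing the
# probabilities of all margin-preserving tables no more probable than the
# observed (with the same relative tie tolerance fisher.test uses).
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  p_obs <- oracle_table_prob(m)
  p <- 0
  for (a in max(0, r1 + c1 - N):min(r1, c1)) {
    tab <- matrix(c(a, c1 - a, r1 - a, N - r1 - c1 + a), nrow = 2)
    pt <- oracle_table_prob(tab)
    if (pt <= p_obs * (1 + 1e-7)) p <- p + pt
  }
  p
}

# Same definition for 2x3 tables, enumerating the two free cells.
oracle_fisher_2x3 <- function(m) {
  col <- colSums(m); r1 <- sum(m[1, ])
  p_obs <- oracle_table_prob(m)
  p <- 0
  for (a in 0:min(r1, col[1])) {
    for (b in 0:min(r1 - a, col[2])) {
      cc <- r1 - a - b
      if (cc > col[3]) next
      tab <- rbind(c(a, b, cc), col - c(a, b, cc))
      pt <- oracle_table_prob(tab)
      if (pt <= p_obs * (1 + 1e-7)) p <- p + pt
    }
  }
  p
}

# Welch t-test by direct summation formulas plus the t CDF.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Position-by-position RVxF scanner using explicit residue sets.
oracle_scan_rvxf <- function(seqs) {
  s1 <- c("K", "R", "L")
  s2 <- c("K", "R", "S", "T", "A", "M", "V", "H", "N")
  s3 <- c("V", "I")
  s4_excluded <- c("F", "I", "M", "Y", "D", "P")
  s5 <- c("F", "W")
  ch <- strsplit(seqs, "")[[1]]
  hits <- integer(0)
  if (length(ch) >= 5) {
    for (i in 1:(length(ch) - 4)) {
      if (ch[i] %in% s1 && ch[i + 1] %in% s2 && ch[i + 2] %in% s3 &&
          !(ch[i + 3] %in% s4_excluded) && ch[i + 4] %in% s5) {
        hits <- c(hits, i)
      }
    }
  }
  hits
}

# Naive UPGMA returning the flat partition at k clusters: cluster distance
# is the mean pairwise distance between original points.
oracle_upgma_cut <- function(m, k) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

# Partition agreement up to label permutation.
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1L))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1L))]))
}

# Adjusted Rand index (chance-corrected partition agreement).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
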