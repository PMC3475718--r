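# small in-code fixtures shared across test files

# a hand-sized two-island, two-locus table with one missing call
toy_table <- function() {
  genotype_table(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    island = c("A", "A", "A", "B", "B", "B"),
    sex = c("M", "F", "M", "F", "M", "F"),
    loci = c("L1", "L2"),
    a1 = matrix(c(1L, 1L, 2L, 3L, 3L, 4L,
                  5L, 5L, 6L, NA, 6L, 7L), 6, 2),
    a2 = matrix(c(2L, 1L, 2L, 4L, 3L, 4L,
                  6L, 5L, 6L, NA, 7L, 7L), 6, 2)
  )
}

# random table: `ni` individuals on each of `n_islands` islands, `L` loci,
# alleles drawn iid from `k` states (a Hardy-Weinberg null population)
random_table <- function(n_islands = 3, ni = 10, L = 2, k = 4,
                         missing_rate = 0) {
  n <- n_islands * ni
  a1 <- matrix(sample.int(k, n * L, TRUE), n, L)
  a2 <- matrix(sample.int(k, n * L, TRUE), n, L)
  if (missing_rate > 0) {
    drop <- matrix(runif(n * L) < missing_rate, n, L)
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  genotype_table(
    sample_id = sprintf("s%03d", seq_len(n)),
    island = rep(sprintf("P%d", seq_len(n_islands)), each = ni),
    sex = rep_len(c("M", "F"), n),
    loci = sprintf("L%d", seq_len(L)),
    a1 = a1, a2 = a2
  )
}

# brute-force Benjamini-Hochberg step-up: q_i = min_{j>=i} m p_(j)/j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force G statistic from two genotype-string vectors
g_brute <- function(gx, gy) {
  tab <- table(gx, gy)
  n <- sum(tab)
  g <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    o <- tab[i, j]
    if (o > 0) g <- g + 2 * o * log(o / (sum(tab[i, ]) * sum(tab[, j]) / n))
  }
  g
}

# brute-force AMOVA sums of squares: double loop over ordered pairs,
# SS = sum_{i<j in set} d2_ij / n_set
amova_brute <- function(tab) {
  n <- n_ind(tab)
  L <- n_loci(tab)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- 0; cmp <- 0
    for (l in seq_len(L)) {
      g1 <- c(tab$a1[i, l], tab$a2[i, l])
      g2 <- c(tab$a1[j, l], tab$a2[j, l])
      if (anyNA(c(g1, g2))) next
      shared <- 0
      for (al in unique(c(g1, g2)))
        shared <- shared + min(sum(g1 == al), sum(g2 == al))
      s <- s + (2 - shared); cmp <- cmp + 1
    }
    d2[i, j] <- d2[j, i] <- s * L / cmp
  }
  grp <- tab$ind$island
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(grp)) {
    sel <- which(grp == g)
    acc <- 0
    for (i in sel) for (j in sel) if (i < j) acc <- acc + d2[i, j]
    ss_within <- ss_within + acc / length(sel)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}
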