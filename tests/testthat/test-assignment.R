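# corrected assignment indices, sex-bias tests, dAIc

test_that("AIc matches the hand-computed two-individual example", {
  tab <- genotype_table(c("i1", "i2"), c("A", "A"), c("M", "F"), "L1",
                        matrix(c(1L, 1L)), matrix(c(1L, 2L)))
  rec <- assignment_index(tab)
  # L(i1) = (3/4)^2, L(i2) = 2 * 3/4 * 1/4
  expect_equal(10^rec$log10_likelihood, c(0.5625, 0.375), tolerance = 1e-12)
  m <- mean(log10(c(0.5625, 0.375)))
  expect_equal(rec$aic, log10(c(0.5625, 0.375)) - m, tolerance = 1e-12)
  expect_equal(rec$aic[1], 0.08804563, tolerance = 1e-7)
})

test_that("AIc is mean-zero per island and zero for identical genotypes", {
  set.seed(41)
  tab <- random_table(n_islands = 4, ni = 8, L = 3, k = 4, missing_rate = 0.1)
  rec <- assignment_index(tab)
  for (p in islands(tab)) {
    v <- rec$aic[rec$island == p & !is.na(rec$aic)]
    expect_lt(abs(mean(v)), 1e-9)
  }
  same <- genotype_table(c("a", "b", "c"), rep("A", 3), c("M", "F", "M"), "L1",
                         matrix(rep(1L, 3)), matrix(rep(2L, 3)))
  expect_equal(assignment_index(same)$aic, rep(0, 3))
})

test_that("AIc is invariant to bijective allele relabeling", {
  set.seed(42)
  tab <- random_table(n_islands = 3, ni = 10, L = 3, k = 5)
  rec <- assignment_index(tab)
  # relabel alleles 1..5 -> a random permutation, applied per locus
  perm <- sample(100, 5)
  tab2 <- tab
  for (l in seq_len(n_loci(tab))) {
    tab2$a1[, l] <- perm[tab$a1[, l]]
    tab2$a2[, l] <- perm[tab$a2[, l]]
  }
  tab2 <- genotype_table(tab2$ind$sample_id, tab2$ind$island, tab2$ind$sex,
                         tab2$loci, tab2$a1, tab2$a2)
  expect_equal(assignment_index(tab2)$aic, rec$aic, tolerance = 1e-12)
})

test_that("duplicating every individual leaves AIc unchanged (no leave-one-out)", {
  set.seed(43)
  tab <- random_table(n_islands = 2, ni = 6, L = 2, k = 4)
  rec <- assignment_index(tab)
  dup <- genotype_table(c(tab$ind$sample_id, paste0(tab$ind$sample_id, "_d")),
                        rep(tab$ind$island, 2), rep(tab$ind$sex, 2),
                        tab$loci, rbind(tab$a1, tab$a1), rbind(tab$a2, tab$a2))
  rec2 <- assignment_index(dup)
  expect_equal(rec2$aic[seq_len(n_ind(tab))], rec$aic, tolerance = 1e-12)
})

test_that("leave-one-out and zero-frequency substitution behave as documented", {
  tab <- genotype_table(c("i1", "i2"), c("A", "A"), c("M", "F"), "L1",
                        matrix(c(1L, 1L)), matrix(c(1L, 2L)))
  # with leave-one-out, i2's allele 2 vanishes from the counts: p -> zero_freq
  rec <- assignment_index(tab, leave_one_out = TRUE, zero_freq = 0.01)
  # i1: counts minus own (1,1): allele 1 has 1 of 2 copies -> p = 0.5
  expect_equal(10^rec$log10_likelihood[1], 0.25, tolerance = 1e-12)
  # i2: allele 1 p = 2/2 = 1, allele 2 p = 0 -> 0.01; f = 2 * 1 * 0.01
  expect_equal(10^rec$log10_likelihood[2], 0.02, tolerance = 1e-12)
  expect_error(assignment_index(genotype_table("x", "A", "M", "L1",
                                               matrix(1L), matrix(1L))),
               "single individual")
})

test_that("Mann-Whitney sex-bias test reproduces exact small-sample p-values", {
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:6), island = "01",
    sex = rep(c("M", "F"), each = 3),
    aic = c(1, 2, 3, -3, -2, -1), stringsAsFactors = FALSE)
  res <- sex_bias_test(rec)
  expect_equal(unname(res$u), 9)
  expect_equal(res$p_raw, 0.1, tolerance = 1e-12)  # 2/choose(6,3)
  expect_equal(res$direction, "female-biased")
  # identical multisets: exact two-sided p = 1
  rec2 <- rec; rec2$aic <- c(5, 7, 9, 5, 7, 9)
  expect_equal(sex_bias_test(rec2)$p_raw, 1.0)
  # a single-sex island is skipped with a warning
  rec3 <- rbind(rec, data.frame(sample_id = "t1", island = "02", sex = "M",
                                aic = 0.5))
  expect_warning(res3 <- sex_bias_test(rec3), "single sex")
  expect_equal(nrow(res3), 1L)
})

test_that("dAIc signs and pooled summary follow the convention", {
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:8), island = rep(c("01", "02"), each = 4),
    sex = rep(c("M", "M", "F", "F"), 2),
    aic = c(1, 2, -1, -2, -1, -2, 1, 2), stringsAsFactors = FALSE)
  dd <- daic(rec)
  expect_equal(dd$per_island$daic, c(3, -3))
  expect_equal(dd$per_island$direction, c("female-biased", "male-biased"))
  expect_equal(dd$pooled$daic, 0)
  # equal sex means give dAIc = 0 and direction "none"
  rec0 <- rec[rec$island == "01", ]; rec0$aic <- c(1, -1, 1, -1)
  expect_equal(daic(rec0)$per_island$direction, "none")
})

test_that("strongly female-biased migration yields positive dAIc on most islands", {
  set.seed(44)
  pos <- 0; tot <- 0
  for (r in 1:8) {
    sim <- simulate_islands(sim_config(m_f = 0.3, m_m = 0, seed = 4400 + r))
    dd <- daic(assignment_index(sim$table))
    pos <- pos + sum(dd$per_island$daic > 0, na.rm = TRUE)
    tot <- tot + sum(!is.na(dd$per_island$daic))
  }
  expect_gt(pos / tot, 0.5)
})
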