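# Two-level analysis of molecular variance (among vs within islands) from
# inter-individual genetic distances, with permutation significance.

# squared distance matrix between diploid multilocus genotypes.
# method "allele_mismatch": per locus, 2 minus the multiset intersection size
# of the two allele pairs (an FST-like number-of-different-alleles distance);
# method "rst": per locus, squared difference of summed allele sizes / 2
# (an RST-like sum-of-squared-size-differences distance).
# A locus is dropped from a pair when either call is missing; the summed
# distance is rescaled by n_loci / n_compared.
pairwise_d2 <- function(x, method = c("allele_mismatch", "rst")) {
  method <- match.arg(method)
  n <- n_ind(x)
  L <- n_loci(x)
  d2 <- matrix(0, n, n)
  cmp <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    a1 <- x$a1[, l]; a2 <- x$a2[, l]
    ok <- !is.na(a1)
    A1 <- a1[ok]; A2 <- a2[ok]
    if (method == "allele_mismatch") {
      eqpair <- outer(A1, A1, "==") & outer(A2, A2, "==")
      anym <- outer(A1, A1, "==") | outer(A1, A2, "==") |
              outer(A2, A1, "==") | outer(A2, A2, "==")
      shared <- ifelse(eqpair, 2, ifelse(anym, 1, 0))
      dl <- 2 - shared
    } else {
      s <- A1 + A2
      dl <- (outer(s, s, "-") / 2)^2
    }
    idx <- which(ok)
    d2[idx, idx] <- d2[idx, idx] + dl
    cmp[idx, idx] <- cmp[idx, idx] + 1L
  }
  zero <- cmp == 0L & row(cmp) != col(cmp)
  if (any(zero))
    stop("some individual pairs share no scored locus; cannot form distances")
  scale <- L / pmax(cmp, 1L)
  d2 * scale
}

# sums of squares from a squared-distance matrix and a grouping factor:
# SS = sum_{i<j in group} d2_ij / n_group  (Excoffier's formulation)
amova_ss <- function(d2, group) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(group)) {
    sel <- group == g
    ng <- sum(sel)
    ss_within <- ss_within + sum(d2[sel, sel]) / (2 * ng)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' Two-level AMOVA (among vs within islands)
#'
#' Partitions molecular variance among and within island populations following
#' Excoffier's sums-of-squares decomposition of the pairwise squared-distance
#' matrix, with variance components from the expected mean squares using the
#' standard unequal-sample-size coefficient `n0`, and `Phi_ST =
#' sigma2_a / (sigma2_a + sigma2_w)`. Significance of `Phi_ST` is assessed by
#' permuting individuals among islands.
#'
#' The default distance counts allele mismatches per locus summed over loci
#' (FST-like); `distance = "rst"` uses squared differences of summed allele
#' sizes (RST-like) instead. Negative variance components are reported raw and
#' clamped to zero only for the percentage columns.
#'
#' @param x a [genotype_table()] with at least two islands of >= 2 individuals.
#' @param permutations number of label permutations for the p-value.
#' @param seed optional integer seed.
#' @param distance `"allele_mismatch"` (default) or `"rst"`.
#' @return list of class `amova_result`: `ss_among`, `ss_within`, `ss_total`,
#'   `df_among`, `df_within`, `sigma2_a`, `sigma2_w`, `percent_among`,
#'   `percent_within`, `phi_st`, `p`, `n0`, `degenerate`.
#' @export
amova_two_level <- function(x, permutations = 999, seed = NULL,
                            distance = c("allele_mismatch", "rst")) {
  validate_genotype_table(x)
  group <- x$ind$island
  isl <- unique(group)
  if (length(isl) < 2L) stop("AMOVA needs at least two islands")
  if (any(table(group) < 2L)) stop("every island needs >= 2 individuals")
  if (permutations < 100) warning("permutations < 100: p-value is coarse")
  if (!is.null(seed)) set.seed(seed)
  d2 <- pairwise_d2(x, distance)
  n <- nrow(d2)
  G <- length(isl)
  ng <- as.numeric(table(group)[isl])
  ss <- amova_ss(d2, group)
  df_a <- G - 1L
  df_w <- n - G
  ms_a <- ss["among"] / df_a
  ms_w <- ss["within"] / df_w
  n0 <- (n - sum(ng^2) / n) / df_a
  s2w <- unname(ms_w)
  s2a <- unname((ms_a - ms_w) / n0)
  ca <- max(s2a, 0); cw <- max(s2w, 0)
  tot <- ca + cw
  degenerate <- tot <= 0
  pa <- if (degenerate) NA_real_ else 100 * ca / tot
  pw <- if (degenerate) NA_real_ else 100 * cw / tot
  phi <- if (degenerate) NA_real_ else s2a / (s2a + s2w)
  # permutation null for Phi_ST: shuffle island labels
  p_perm <- NA_real_
  phi_perm <- rep(NA_real_, permutations)
  if (!degenerate) {
    for (b in seq_len(permutations)) {
      gp <- group[sample.int(n)]
      ssb <- amova_ss(d2, gp)
      msab <- ssb["among"] / df_a
      mswb <- ssb["within"] / df_w
      s2ab <- unname((msab - mswb) / n0)
      phi_perm[b] <- s2ab / (s2ab + mswb)
    }
    p_perm <- (1 + sum(phi_perm >= phi - 1e-12)) / (1 + permutations)
  }
  structure(list(
    ss_among = unname(ss["among"]), ss_within = unname(ss["within"]),
    ss_total = unname(ss["total"]), df_among = df_a, df_within = df_w,
    sigma2_a = s2a, sigma2_w = s2w,
    percent_among = pa, percent_within = pw,
    phi_st = phi, p = p_perm, n0 = n0, degenerate = degenerate,
    phi_perm = phi_perm, distance = distance[1]
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Two-level AMOVA (", x$distance, " distance)\n", sep = "")
  cat(sprintf("  Among islands : SS = %9.3f  df = %3d  sigma2 = %8.4f  %6.2f%%\n",
              x$ss_among, x$df_among, x$sigma2_a, x$percent_among))
  cat(sprintf("  Within islands: SS = %9.3f  df = %3d  sigma2 = %8.4f  %6.2f%%\n",
              x$ss_within, x$df_within, x$sigma2_w, x$percent_within))
  cat(sprintf("  Phi_ST = %.4f   permutation p = %.4g\n", x$phi_st, x$p))
  if (x$degenerate) cat("  (degenerate: no molecular variance)\n")
  invisible(x)
}
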