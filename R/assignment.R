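# Corrected assignment indices (AIc), per-island sex-bias tests, and the
# dAIc disparity statistic -- the core dispersal inference.

#' Corrected assignment index (AIc) per individual
#'
#' For each individual, the expected frequency of its genotype is computed at
#' every scored (non-missing) locus from the allele frequencies of its own
#' island: `p^2` for a homozygote and `2pq` for a heterozygote (Hardy-Weinberg
#' form, as in the classical assignment-test method). The multilocus
#' likelihood is the product over scored loci, and the raw score is its
#' `log10`. The corrected index centers the raw score by the island mean:
#' `AIc = log10 L - mean(log10 L)`, so AIc averages zero within every island
#' and individuals with negative AIc carry genotypes atypical of their sampled
#' population — likely immigrants.
#'
#' With `leave_one_out = TRUE`, the individual's own two allele copies are
#' removed from the island counts before its frequencies are formed. Any
#' allele with frequency zero (possible under leave-one-out, or for
#' frequencies against another island) is replaced by `zero_freq` before the
#' product.
#'
#' @param x a [genotype_table()]; every island needs >= 2 individuals.
#' @param leave_one_out remove the individual's own alleles from the counts
#'   (default `FALSE`).
#' @param zero_freq substitute frequency for alleles unobserved after
#'   leave-one-out (default 0.01).
#' @return data.frame with columns `sample_id`, `island`, `sex`, `n_loci_scored`,
#'   `log10_likelihood`, `aic`. Individuals with zero scored loci get `NA`
#'   scores and are excluded from the island mean (with a warning).
#' @export
assignment_index <- function(x, leave_one_out = FALSE, zero_freq = 0.01) {
  validate_genotype_table(x)
  cnt <- freq_counts(x)
  n <- n_ind(x)
  logL <- rep(NA_real_, n)
  scored <- integer(n)
  for (i in seq_len(n)) {
    p <- x$ind$island[i]
    acc <- 0
    ns <- 0L
    for (l in x$loci) {
      a1 <- x$a1[i, l]; a2 <- x$a2[i, l]
      if (is.na(a1)) next
      tb <- cnt[[p]][[l]]
      ng <- sum(tb)
      c1 <- tb[as.character(a1)]
      c2 <- tb[as.character(a2)]
      c1 <- if (is.na(c1)) 0 else as.numeric(c1)
      c2 <- if (is.na(c2)) 0 else as.numeric(c2)
      if (leave_one_out) {
        if (a1 == a2) c1 <- c2 <- c1 - 2 else { c1 <- c1 - 1; c2 <- c2 - 1 }
        ng <- ng - 2
      }
      if (ng <= 0) next
      p1 <- c1 / ng; p2 <- c2 / ng
      if (p1 <= 0) p1 <- zero_freq
      if (p2 <= 0) p2 <- zero_freq
      f <- if (a1 == a2) p1 * p1 else 2 * p1 * p2
      acc <- acc + log10(f)
      ns <- ns + 1L
    }
    scored[i] <- ns
    if (ns > 0L) logL[i] <- acc
  }
  aic <- rep(NA_real_, n)
  for (p in islands(x)) {
    sel <- x$ind$island == p
    if (sum(sel) < 2L)
      stop("island '", p, "' has a single individual: AIc undefined")
    ok <- sel & !is.na(logL)
    if (sum(sel & is.na(logL)) > 0L)
      warning(sum(sel & is.na(logL)), " individual(s) on island '", p,
              "' have zero scored loci and are excluded from the mean")
    aic[ok] <- logL[ok] - mean(logL[ok])
  }
  data.frame(sample_id = x$ind$sample_id, island = x$ind$island,
             sex = x$ind$sex, n_loci_scored = scored,
             log10_likelihood = logL, aic = aic, stringsAsFactors = FALSE)
}

# Mann-Whitney comparison of two AIc vectors. Exact enumeration when both
# samples are <= 8 and tie-free, otherwise the normal approximation with
# continuity and tie correction (both via stats::wilcox.test).
mw_test <- function(male, female) {
  ties <- anyDuplicated(c(male, female)) > 0L
  exact <- length(male) <= 8L && length(female) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(male, female, exact = exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Per-island sex-bias tests on AIc scores
#'
#' For each island with at least one individual of each sex, compares male and
#' female AIc distributions with a two-sided Mann-Whitney U test (exact null
#' distribution when both samples have <= 8 values and no ties; normal
#' approximation with continuity and tie correction otherwise). P-values are
#' Benjamini-Hochberg corrected across the tested islands. The direction label
#' follows the dAIc sign convention: `dAIc = mean(male AIc) - mean(female
#' AIc)`; a positive dAIc means females score lower (female-biased dispersal),
#' a negative dAIc means male-biased dispersal.
#'
#' @param records output of [assignment_index()].
#' @param alpha significance level applied to the FDR-corrected p-values.
#' @return data.frame with one row per tested island: `island`, `n_male`,
#'   `n_female`, `mean_aic_male`, `mean_aic_female`, `daic`, `u`, `p_raw`,
#'   `p_fdr`, `significant`, `direction`.
#' @export
sex_bias_test <- function(records, alpha = 0.05) {
  rows <- list()
  skipped <- character(0)
  for (p in unique(records$island)) {
    sel <- records$island == p & !is.na(records$aic)
    m <- records$aic[sel & records$sex == "M"]
    f <- records$aic[sel & records$sex == "F"]
    if (length(m) == 0L || length(f) == 0L) {
      skipped <- c(skipped, p)
      next
    }
    mw <- mw_test(m, f)
    d <- mean(m) - mean(f)
    rows[[length(rows) + 1L]] <- data.frame(
      island = p, n_male = length(m), n_female = length(f),
      mean_aic_male = mean(m), mean_aic_female = mean(f),
      daic = d, u = mw$u, p_raw = mw$p, exact = mw$exact,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("islands skipped (single sex): ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no island has both sexes")
  fd <- fdr_bh(out$p_raw, alpha)
  out$p_fdr <- fd$q
  out$significant <- fd$significant
  out$direction <- ifelse(out$daic > 0, "female-biased",
                          ifelse(out$daic < 0, "male-biased", "none"))
  rownames(out) <- NULL
  out
}

#' Dispersal disparity statistic dAIc, per island and pooled
#'
#' `dAIc = mean(male AIc) - mean(female AIc)`. Because dispersers tend to
#' score negative, a positive dAIc indicates female-biased dispersal and a
#' negative dAIc male-biased dispersal. The pooled variant keeps AIc centered
#' within islands but pools all individuals for one global comparison
#' (Mann-Whitney, two-sided).
#'
#' @param records output of [assignment_index()].
#' @return list with `per_island` (data.frame `island`, `daic`, `direction`;
#'   `NA` where a sex is absent) and `pooled` (list `mean_aic_male`,
#'   `mean_aic_female`, `daic`, `u`, `p`).
#' @export
daic <- function(records) {
  per <- lapply(unique(records$island), function(p) {
    sel <- records$island == p & !is.na(records$aic)
    m <- records$aic[sel & records$sex == "M"]
    f <- records$aic[sel & records$sex == "F"]
    d <- if (length(m) && length(f)) mean(m) - mean(f) else NA_real_
    data.frame(island = p, daic = d,
               direction = if (is.na(d)) NA_character_
                           else if (d > 0) "female-biased"
                           else if (d < 0) "male-biased" else "none",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- !is.na(records$aic)
  m <- records$aic[ok & records$sex == "M"]
  f <- records$aic[ok & records$sex == "F"]
  pooled <- list(mean_aic_male = mean(m), mean_aic_female = mean(f),
                 daic = mean(m) - mean(f))
  if (length(m) && length(f)) {
    mw <- mw_test(m, f)
    pooled$u <- mw$u
    pooled$p <- mw$p
  }
  list(per_island = per, pooled = pooled)
}
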