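# Per-population allele frequencies, diversity, HWE exact tests, genotypic
# LD permutation tests, and Benjamini-Hochberg FDR correction.

# internal: nested list [[island]][[locus]] of allele count tables, plus
# n_genes = 2 * non-missing individuals
freq_counts <- function(x) {
  validate_genotype_table(x)
  out <- list()
  for (p in islands(x)) {
    rows <- x$ind$island == p
    out[[p]] <- list()
    for (l in x$loci) {
      al <- c(x$a1[rows, l], x$a2[rows, l])
      al <- al[!is.na(al)]
      out[[p]][[l]] <- if (length(al)) table(al) else table(integer(0))
    }
  }
  out
}

#' Per-(island, locus) allele frequencies
#'
#' Counts alleles over non-missing calls only. An (island, locus) cell with no
#' scored individuals yields no rows and is listed in the `"empty"` attribute.
#'
#' @param x a [genotype_table()].
#' @return a data.frame with columns `island`, `locus`, `allele`, `count`,
#'   `freq`, `n_genes` (2 x non-missing individuals). Frequencies sum to 1
#'   within each (island, locus) that has data.
#' @export
allele_frequencies <- function(x) {
  fc <- freq_counts(x)
  rows <- list(); empty <- character(0)
  for (p in names(fc)) for (l in names(fc[[p]])) {
    tb <- fc[[p]][[l]]
    ng <- sum(tb)
    if (ng == 0L) {
      empty <- c(empty, paste(p, l, sep = ":"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      island = p, locus = l, allele = as.integer(names(tb)),
      count = as.integer(tb), freq = as.numeric(tb) / ng, n_genes = ng,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "empty") <- empty
  out
}

#' Per-island diversity summary
#'
#' For each island: mean allele richness (MAR, the raw mean number of distinct
#' alleles per locus; no rarefaction unless `rarefy_n` is given), observed
#' heterozygosity (Ho, proportion of heterozygous non-missing calls averaged
#' over loci) and expected heterozygosity (He) averaged over loci. He uses
#' Nei's unbiased small-sample correction `2n/(2n-1) * (1 - sum(p^2))` by
#' default; `unbiased = FALSE` gives the plain gene-diversity estimator.
#' Loci with no scored individuals on an island are omitted from the means.
#'
#' @param x a [genotype_table()].
#' @param unbiased apply the `2n/(2n-1)` correction to He (default `TRUE`).
#' @param rarefy_n if not `NULL`, rarefied allelic richness standardized to a
#'   sample of `rarefy_n` genes per locus instead of the raw count.
#' @return data.frame with columns `island`, `n`, `n_male`, `n_female`,
#'   `mar`, `ho`, `he`.
#' @export
pop_summary <- function(x, unbiased = TRUE, rarefy_n = NULL) {
  validate_genotype_table(x)
  res <- lapply(islands(x), function(p) {
    rows <- which(x$ind$island == p)
    mar <- ho <- he <- numeric(0)
    for (l in x$loci) {
      a1 <- x$a1[rows, l]; a2 <- x$a2[rows, l]
      ok <- !is.na(a1)
      if (!any(ok)) next
      al <- c(a1[ok], a2[ok])
      tb <- table(al)
      n <- sum(ok)                      # individuals scored
      if (is.null(rarefy_n)) {
        mar <- c(mar, length(tb))
      } else {
        # expected number of alleles in a sample of rarefy_n genes
        g <- sum(tb)
        k <- min(rarefy_n, g)
        pr <- vapply(as.numeric(tb), function(ci)
          1 - exp(lchoose(g - ci, k) - lchoose(g, k)), numeric(1))
        mar <- c(mar, sum(pr))
      }
      ho <- c(ho, mean(a1[ok] != a2[ok]))
      p2 <- sum((as.numeric(tb) / (2 * n))^2)
      h <- 1 - p2
      if (unbiased) h <- h * (2 * n) / (2 * n - 1)
      he <- c(he, h)
    }
    data.frame(island = p, n = length(rows),
               n_male = sum(x$ind$sex[rows] == "M"),
               n_female = sum(x$ind$sex[rows] == "F"),
               mar = mean(mar), ho = mean(ho), he = mean(he),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- Hardy-Weinberg exact test (Levene conditional distribution) ----------

# log conditional probability of a genotype count array given allele counts
# (up to terms constant across arrays with the same allele margin):
#   log P = log n! + h log 2 + sum log a_j! - log (2n)! - sum log n_gg!
# The variable part is  h*log(2) - sum(lfactorial(n_gg)).
hwe_array_stat <- function(het_count, geno_counts) {
  het_count * log(2) - sum(lfactorial(geno_counts))
}

# enumerate all genotype arrays with the given allele-count margin, returning
# the vector of hwe_array_stat values; returns NULL when more than `cap`
# arrays exist. Entries n_ij (i <= j) are filled row by row; once row i is
# complete no later entry can consume allele i, so rem[i] must hit 0 exactly.
hwe_enumerate <- function(allele_counts, cap = 1e6) {
  k <- length(allele_counts)
  stats <- numeric(0)
  count <- 0L
  aborted <- FALSE
  rec <- function(rem, i, j, het, logf) {
    if (aborted) return()
    if (j > k) {                       # row i complete
      if (rem[i] != 0L) return()
      if (i == k) {
        count <<- count + 1L
        if (count > cap) { aborted <<- TRUE; return() }
        stats[count] <<- het * log(2) - logf
        return()
      }
      rec(rem, i + 1L, i + 1L, het, logf)
      return()
    }
    if (i == j) {
      if (j == k) {                    # last entry of the array: forced
        if (rem[i] %% 2L == 0L) {
          nij <- rem[i] %/% 2L
          r2 <- rem; r2[i] <- 0L
          rec(r2, i, j + 1L, het, logf + lfactorial(nij))
        }
        return()
      }
      for (nij in 0:(rem[i] %/% 2L)) {
        r2 <- rem; r2[i] <- r2[i] - 2L * nij
        rec(r2, i, j + 1L, het, logf + lfactorial(nij))
      }
    } else {
      if (j == k) {                    # last entry of row i: forced to rem[i]
        nij <- rem[i]
        if (rem[j] >= nij) {
          r2 <- rem; r2[i] <- 0L; r2[j] <- r2[j] - nij
          rec(r2, i, j + 1L, het + nij, logf + lfactorial(nij))
        }
        return()
      }
      for (nij in 0:min(rem[i], rem[j])) {
        r2 <- rem; r2[i] <- r2[i] - nij; r2[j] <- r2[j] - nij
        rec(r2, i, j + 1L, het + nij, logf + lfactorial(nij))
      }
    }
  }
  rec(as.integer(allele_counts), 1L, 1L, 0, 0)
  if (aborted) return(NULL)
  stats[seq_len(count)]
}

# exact p (probability-ordering, two-sided): total probability of arrays with
# conditional probability <= that observed
hwe_exact_p <- function(geno_tab, cap = 1e6) {
  # geno_tab: symmetric-matrix-free representation: named list with
  # counts[i,j] for i<=j as a matrix
  k <- nrow(geno_tab)
  ac <- integer(k)
  het <- 0L
  logf <- 0
  for (i in 1:k) for (j in i:k) {
    nij <- geno_tab[i, j]
    ac[i] <- ac[i] + nij
    ac[j] <- ac[j] + nij
    if (i != j) het <- het + nij
    logf <- logf + lfactorial(nij)
  }
  obs <- het * log(2) - logf
  # cheap gate: the number of arrays is bounded by the number of compositions
  # of n genotypes into k(k+1)/2 cells; only recurse when that bound fits
  n <- sum(ac) / 2
  m <- k * (k + 1) / 2
  if (lchoose(n + m - 1, m - 1) > log(cap)) return(NULL)
  stats <- hwe_enumerate(ac, cap)
  if (is.null(stats)) return(NULL)
  # normalize: P proportional to exp(stat); sum over arrays with stat <= obs
  m <- max(stats)
  w <- exp(stats - m)
  p <- sum(w[stats <= obs + 1e-9]) / sum(w)
  min(p, 1)
}

# Monte-Carlo estimate of the same probability: random pairings of the 2n gene
# copies sample genotype arrays from the Levene distribution.
hwe_mc_p <- function(geno_tab, iter) {
  k <- nrow(geno_tab)
  ac <- integer(k); het <- 0L; logf <- 0
  for (i in 1:k) for (j in i:k) {
    nij <- geno_tab[i, j]
    ac[i] <- ac[i] + nij; ac[j] <- ac[j] + nij
    if (i != j) het <- het + nij
    logf <- logf + lfactorial(nij)
  }
  obs <- het * log(2) - logf
  genes <- rep.int(seq_len(k), ac)
  n <- length(genes) / 2L
  hits <- 0L
  for (b in seq_len(iter)) {
    g <- sample(genes)
    g1 <- g[seq_len(n)]; g2 <- g[n + seq_len(n)]
    lo <- pmin(g1, g2); hi <- pmax(g1, g2)
    key <- (lo - 1L) * k + hi
    tb <- tabulate(key, k * k)
    stat <- sum(lo != hi) * log(2) - sum(lfactorial(tb[tb > 0L]))
    if (stat <= obs + 1e-9) hits <- hits + 1L
  }
  hits / iter
}

# build the upper-triangular genotype count matrix for one (island, locus)
geno_count_matrix <- function(a1, a2) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  i <- match(a1, alleles); j <- match(a2, alleles)
  for (t in seq_along(i)) m[i[t], j[t]] <- m[i[t], j[t]] + 1L
  m
}

#' Exact Hardy-Weinberg tests per (island, locus)
#'
#' Tests each (island, locus) combination against Hardy-Weinberg genotype
#' proportions using the exact conditional (Levene) distribution of genotype
#' arrays given the allele counts, with the probability-ordering two-sided
#' definition: the p-value is the total conditional probability of arrays no
#' more probable than the observed one. When the number of arrays exceeds
#' `enum_cap`, the same probability is estimated by Monte Carlo (random
#' re-pairings of the gene copies, which sample the Levene distribution).
#'
#' Monomorphic or nearly empty cells are untestable and reported with p = 1
#' and `flag = "untestable"`.
#'
#' @param x a [genotype_table()].
#' @param enum_cap maximum number of genotype arrays to enumerate exactly.
#' @param mc_iter Monte-Carlo iterations used above the cap.
#' @param seed optional integer seed for the Monte-Carlo fallback.
#' @param alpha significance level applied after FDR correction.
#' @return data.frame with columns `island`, `locus`, `method`
#'   (`"exact"`/`"mc"`/`"none"`), `p_raw`, `p_fdr`, `significant`, `flag`.
#' @references Levene's conditional distribution; Guo & Thompson-style Monte
#'   Carlo resampling.
#' @export
hwe_exact <- function(x, enum_cap = 1e6, mc_iter = 1e4, seed = NULL,
                      alpha = 0.05) {
  validate_genotype_table(x)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (p in islands(x)) {
    sel <- x$ind$island == p
    for (l in x$loci) {
      a1 <- x$a1[sel, l]; a2 <- x$a2[sel, l]
      ok <- !is.na(a1)
      alleles <- unique(c(a1[ok], a2[ok]))
      if (sum(ok) < 2L || length(alleles) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          island = p, locus = l, method = "none", p_raw = 1.0,
          flag = "untestable", stringsAsFactors = FALSE)
        next
      }
      m <- geno_count_matrix(a1, a2)
      pe <- hwe_exact_p(m, cap = enum_cap)
      if (is.null(pe)) {
        pe <- hwe_mc_p(m, mc_iter)
        meth <- "mc"
      } else meth <- "exact"
      rows[[length(rows) + 1L]] <- data.frame(
        island = p, locus = l, method = meth, p_raw = pe, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tested <- out$flag == ""
  out$p_fdr <- NA_real_
  out$p_fdr[tested] <- fdr_bh(out$p_raw[tested], alpha)$q
  out$significant <- !is.na(out$p_fdr) & out$p_fdr <= alpha
  rownames(out) <- NULL
  out[c("island", "locus", "method", "p_raw", "p_fdr", "significant", "flag")]
}

# ---- genotypic linkage disequilibrium ------------------------------------

# G (log-likelihood-ratio) statistic on a two-way contingency table of counts
g_statistic <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- tab
  sel <- o > 0
  2 * sum(o[sel] * log(o[sel] / e[sel]))
}

#' Genotypic linkage-disequilibrium permutation tests
#'
#' For each island and each pair of loci, tests the association between
#' single-locus genotypes with a log-likelihood-ratio G statistic on the
#' genotype x genotype contingency table. Significance is assessed by
#' permutation: one locus's genotype column is shuffled among the island's
#' individuals (which preserves both single-locus genotype distributions under
#' the null), and `p = (1 + #{G* >= G}) / (1 + permutations)`. Pairs where
#' either locus is monomorphic within the island are untestable (p = 1).
#'
#' @param x a [genotype_table()].
#' @param permutations number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param alpha significance level applied after FDR correction.
#' @return data.frame with columns `island`, `locus1`, `locus2`, `g`,
#'   `p_raw`, `p_fdr`, `significant`, `flag`.
#' @export
ld_test <- function(x, permutations = 1000, seed = NULL, alpha = 0.05) {
  validate_genotype_table(x)
  if (permutations < 100) stop("permutations must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  L <- x$loci
  rows <- list()
  for (p in islands(x)) {
    sel <- which(x$ind$island == p)
    geno <- lapply(L, function(l)
      ifelse(is.na(x$a1[sel, l]), NA_character_,
             paste(x$a1[sel, l], x$a2[sel, l], sep = "/")))
    names(geno) <- L
    for (i in seq_len(length(L) - 1L)) for (j in (i + 1L):length(L)) {
      gi <- geno[[i]]; gj <- geno[[j]]
      ok <- !is.na(gi) & !is.na(gj)
      ui <- unique(gi[ok]); uj <- unique(gj[ok])
      if (sum(ok) < 2L || length(ui) < 2L || length(uj) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          island = p, locus1 = L[i], locus2 = L[j], g = NA_real_,
          p_raw = 1.0, flag = "untestable", stringsAsFactors = FALSE)
        next
      }
      fi <- factor(gi[ok], levels = ui)
      fj <- factor(gj[ok], levels = uj)
      ii <- as.integer(fi); jj <- as.integer(fj)
      ni <- length(ui); nj <- length(uj)
      tab <- matrix(tabulate((jj - 1L) * ni + ii, ni * nj), ni, nj)
      g_obs <- g_statistic(tab)
      hits <- 0L
      for (b in seq_len(permutations)) {
        jp <- jj[sample.int(length(jj))]
        tb <- matrix(tabulate((jp - 1L) * ni + ii, ni * nj), ni, nj)
        if (g_statistic(tb) >= g_obs - 1e-12) hits <- hits + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        island = p, locus1 = L[i], locus2 = L[j], g = g_obs,
        p_raw = (1 + hits) / (1 + permutations), flag = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tested <- out$flag == ""
  out$p_fdr <- NA_real_
  out$p_fdr[tested] <- fdr_bh(out$p_raw[tested], alpha)$q
  out$significant <- !is.na(out$p_fdr) & out$p_fdr <= alpha
  rownames(out) <- NULL
  out[c("island", "locus1", "locus2", "g", "p_raw", "p_fdr", "significant", "flag")]
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted values `q_i = min_{j >= i} (m * p_(j) / j)` mapped back to
#' the input order, with a significance flag at `q <= alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level for the flags.
#' @return list with `q` (adjusted values) and `significant` (logical).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha)
}
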