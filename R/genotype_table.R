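#' Multilocus codominant genotype table
#'
#' The universal container for the package: diploid allele calls for a set of
#' individuals typed at a shared, ordered set of microsatellite loci, with an
#' island (population) code and a sex label per individual. Allele identifiers
#' are abstract positive integers (the simulator uses repeat counts); no
#' assumption is made that they are fragment lengths. Each call is an
#' unordered allele pair stored order-normalized (smaller identifier first);
#' a missing call is `NA` in both allele slots.
#'
#' @param sample_id character vector of unique individual identifiers.
#' @param island character vector of island (population) codes, one per
#'   individual. Island codes define the population partition.
#' @param sex character vector with values `"M"`, `"F"` or `"unknown"`.
#' @param loci character vector of locus names (ordered; shared by all
#'   individuals).
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   identifiers per call; both `NA` marks a missing call. Pairs are
#'   normalized so that `a1 <= a2`.
#'
#' @return An object of class `genotype_table`: a list with elements `ind`
#'   (data.frame `sample_id`, `island`, `sex`), `loci`, `a1`, `a2`.
#' @export
#' @examples
#' gt <- genotype_table(
#'   sample_id = c("s1", "s2"), island = c("A", "A"), sex = c("M", "F"),
#'   loci = "L1", a1 = matrix(c(2L, 1L)), a2 = matrix(c(1L, 1L))
#' )
#' gt$a1  # pairs are order-normalized: (2,1) became (1,2)
genotype_table <- function(sample_id, island, sex, loci, a1, a2) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  n <- length(sample_id)
  if (length(island) != n || length(sex) != n)
    stop("sample_id, island and sex must have equal length")
  if (nrow(a1) != n || nrow(a2) != n || ncol(a1) != length(loci) ||
      ncol(a2) != length(loci))
    stop("allele matrices must be n individuals x n loci")
  # order-normalize pairs; a call with any NA (or non-positive id) is missing
  bad <- is.na(a1) | is.na(a2) | a1 <= 0L | a2 <= 0L
  a1[bad] <- NA_integer_
  a2[bad] <- NA_integer_
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(sample_id, loci)
  obj <- structure(
    list(
      ind = data.frame(sample_id = as.character(sample_id),
                       island = as.character(island),
                       sex = as.character(sex),
                       stringsAsFactors = FALSE),
      loci = as.character(loci),
      a1 = a1, a2 = a2
    ),
    class = "genotype_table"
  )
  validate_genotype_table(obj)
  obj
}

#' Validate a genotype table
#'
#' Checks the structural invariants: unique sample ids, a single island per
#' individual, sex labels in `{M, F, unknown}`, at least one locus, and
#' order-normalized allele pairs.
#'
#' @param x a `genotype_table`.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (anyDuplicated(x$ind$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(x$ind$sample_id[duplicated(x$ind$sample_id)]), collapse = ", "))
  if (!all(x$ind$sex %in% c("M", "F", "unknown")))
    stop("sex must be 'M', 'F' or 'unknown'")
  if (length(x$loci) < 1L) stop("a genotype table needs at least one locus")
  if (anyDuplicated(x$loci)) stop("duplicated locus names")
  ok <- is.na(x$a1) | (!is.na(x$a2) & x$a1 <= x$a2)
  if (!all(ok)) stop("allele pairs are not order-normalized")
  if (any(xor(is.na(x$a1), is.na(x$a2))))
    stop("half-missing calls are not allowed")
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  isl <- table(x$ind$island)
  cat("genotype_table:", nrow(x$ind), "individuals,", length(x$loci),
      "loci,", length(isl), "islands\n")
  sx <- table(factor(x$ind$sex, levels = c("M", "F", "unknown")))
  cat("  sex: ", sx[["M"]], "M / ", sx[["F"]], "F",
      if (sx[["unknown"]] > 0) paste0(" / ", sx[["unknown"]], " unknown"),
      "\n", sep = "")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Number of individuals / loci, island codes
#'
#' Small accessors for `genotype_table` objects.
#' @param x a `genotype_table`.
#' @return `n_ind()` and `n_loci()` return integers; `islands()` returns the
#'   character vector of island codes in order of first appearance.
#' @export
n_ind <- function(x) nrow(x$ind)

#' @rdname n_ind
#' @export
n_loci <- function(x) length(x$loci)

#' @rdname n_ind
#' @export
islands <- function(x) unique(x$ind$island)

#' Drop loci from a genotype table
#'
#' Removes named loci (e.g. loci failing upstream reliability screens such as
#' null-allele or missing-data filters) while leaving individuals untouched.
#'
#' @param x a `genotype_table`.
#' @param loci character vector of locus names to remove; may be empty
#'   (identity).
#' @return the table without those loci.
#' @export
exclude_loci <- function(x, loci) {
  validate_genotype_table(x)
  if (length(loci) == 0L) return(x)
  unknown <- setdiff(loci, x$loci)
  if (length(unknown))
    stop("unknown loci: ", paste(unknown, collapse = ", "))
  keep <- setdiff(x$loci, loci)
  if (length(keep) == 0L)
    stop("cannot exclude all loci: an empty locus set is invalid")
  genotype_table(x$ind$sample_id, x$ind$island, x$ind$sex,
                 keep, x$a1[, keep, drop = FALSE], x$a2[, keep, drop = FALSE])
}

#' Flag individuals with a high fraction of missing calls
#'
#' Individuals with more than `threshold` missing loci are flagged with a
#' warning but retained; set `drop = TRUE` to remove them instead.
#'
#' @param x a `genotype_table`.
#' @param threshold missing-call fraction above which an individual is flagged
#'   (default 0.5).
#' @param drop remove flagged individuals instead of keeping them.
#' @return the (possibly reduced) table, with attribute `"flagged"` holding the
#'   flagged sample ids.
#' @export
flag_missing_individuals <- function(x, threshold = 0.5, drop = FALSE) {
  frac <- rowMeans(is.na(x$a1))
  bad <- x$ind$sample_id[frac > threshold]
  if (length(bad)) {
    warning(length(bad), " individual(s) exceed ", 100 * threshold,
            "% missing calls: ", paste(bad, collapse = ", "))
    if (drop) {
      keep <- !(x$ind$sample_id %in% bad)
      x <- genotype_table(x$ind$sample_id[keep], x$ind$island[keep],
                          x$ind$sex[keep], x$loci,
                          x$a1[keep, , drop = FALSE], x$a2[keep, , drop = FALSE])
    }
  }
  attr(x, "flagged") <- bad
  x
}
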