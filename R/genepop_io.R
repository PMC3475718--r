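#' Read a GenePop file with a sex-annotated metadata sidecar
#'
#' Parses the GenePop 4.x dialect: a title line, locus names (one per line or
#' comma-separated), case-insensitive `POP` separators, one sample per line as
#' `id ,  0102 0304 ...` with fixed-width 2- or 3-digit allele codes, where an
#' all-zeros code (`"0000"` / `"000000"`) marks a missing call. GenePop carries
#' no sex field, so sex (and the authoritative island code) comes from a
#' tab-separated sidecar with columns `sample_id`, `island`, `sex`.
#'
#' Every sample in the GenePop file must have exactly one sidecar row, and all
#' samples within one `POP` block must map to the same island.
#'
#' @param path path to the GenePop file.
#' @param metadata_path path to the TSV sidecar.
#' @return a validated [genotype_table()].
#' @seealso [write_genepop()], [read_sidecar()]
#' @export
read_genepop <- function(path, metadata_path) {
  meta <- read_sidecar(metadata_path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("GenePop file too short: ", path)
  blank <- grepl("^\\s*$", lines)
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("no POP separator found in ", path)
  locus_lines <- lines[2:(pop_idx[1] - 1L)]
  locus_lines <- locus_lines[nzchar(trimws(locus_lines))]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names found in ", path)

  block_of <- findInterval(seq_along(lines), pop_idx)
  sample_lines <- which(block_of > 0 & !(seq_along(lines) %in% pop_idx) & !blank)

  ids <- character(0); blocks <- integer(0)
  allele_rows <- vector("list", length(sample_lines))
  width <- NA_integer_
  for (k in seq_along(sample_lines)) {
    i <- sample_lines[k]
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2L)
      stop("line ", i, ": expected 'id , genotypes' with a comma separator")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci))
      stop("line ", i, ": sample '", id, "' has ", length(toks),
           " genotype fields, expected ", length(loci))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)) || any(grepl("\\D", toks)))
      stop("line ", i, ": malformed allele width (fields must be 4 or 6 digits)")
    w <- w / 2L
    if (is.na(width)) width <- w
    else if (w != width)
      stop("line ", i, ": inconsistent allele width (", w, " vs ", width, " digits)")
    a1 <- as.integer(substr(toks, 1L, width))
    a2 <- as.integer(substr(toks, width + 1L, 2L * width))
    a1[a1 == 0L | a2 == 0L] <- NA_integer_
    a2[is.na(a1)] <- NA_integer_
    ids <- c(ids, id)
    blocks <- c(blocks, block_of[i])
    allele_rows[[k]] <- c(a1, a2)
  }
  m <- match(ids, meta$sample_id)
  if (anyNA(m))
    stop("samples present in GenePop but absent from sidecar: ",
         paste(ids[is.na(m)], collapse = ", "))
  island <- meta$island[m]
  sex <- meta$sex[m]
  # population blocks must agree with the sidecar island partition
  for (b in unique(blocks)) {
    isl <- unique(island[blocks == b])
    if (length(isl) > 1L)
      stop("POP block ", b, " mixes sidecar islands: ",
           paste(isl, collapse = ", "))
  }
  L <- length(loci)
  a1 <- t(vapply(allele_rows, function(r) r[seq_len(L)], integer(L)))
  a2 <- t(vapply(allele_rows, function(r) r[L + seq_len(L)], integer(L)))
  if (L == 1L) { a1 <- matrix(a1, ncol = 1L); a2 <- matrix(a2, ncol = 1L) }
  genotype_table(ids, island, sex, loci, a1, a2)
}

#' Read / write the metadata sidecar
#'
#' The sidecar is a TSV with header `sample_id`, `island`, `sex`; sample ids
#' must be unique and sex must be `M` or `F`.
#'
#' @param path file path.
#' @return `read_sidecar()` returns a data.frame; `write_sidecar()` is called
#'   for its side effect and returns `path` invisibly.
#' @export
read_sidecar <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("sample_id", "island", "sex")
  if (!all(need %in% names(meta)))
    stop("sidecar must have columns sample_id, island, sex")
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in sidecar")
  bad <- setdiff(unique(meta$sex), c("M", "F"))
  if (length(bad))
    stop("sidecar sex values outside {M,F}: ", paste(bad, collapse = ", "))
  meta[need]
}

#' @rdname read_sidecar
#' @param x a `genotype_table`.
#' @export
write_sidecar <- function(x, path) {
  validate_genotype_table(x)
  utils::write.table(x$ind, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype table as a GenePop file
#'
#' Writes one `POP` block per island (islands in order of first appearance).
#' The allele digit width is chosen automatically: 2 digits when every allele
#' identifier is below 100, otherwise 3 digits; identifiers above 999 cannot
#' be encoded and raise an error. `read_genepop()` after `write_genepop()`
#' (with the matching sidecar) reproduces the table exactly.
#'
#' @param x a `genotype_table`.
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param width allele digit width, 2 or 3; `NULL` (default) selects
#'   automatically.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "dispersalkit genotypes", width = NULL) {
  validate_genotype_table(x)
  isl <- islands(x)
  cnt <- table(x$ind$island)
  if (length(isl) == 0L || any(cnt == 0L)) stop("empty population block")
  amax <- suppressWarnings(max(c(x$a1, x$a2), na.rm = TRUE))
  if (!is.finite(amax)) amax <- 1L
  if (is.null(width)) width <- if (amax <= 99L) 2L else 3L
  if (amax > 10^width - 1)
    stop("allele identifier ", amax, " exceeds the ", width, "-digit width")
  fmt <- function(a1, a2) {
    out <- sprintf(paste0("%0", width, "d%0", width, "d"),
                   ifelse(is.na(a1), 0L, a1), ifelse(is.na(a2), 0L, a2))
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  for (p in isl) {
    writeLines("POP", con)
    rows <- which(x$ind$island == p)
    for (i in rows) {
      geno <- fmt(x$a1[i, ], x$a2[i, ])
      writeLines(paste0(x$ind$sample_id[i], " ,  ", paste(geno, collapse = " ")), con)
    }
  }
  invisible(path)
}
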