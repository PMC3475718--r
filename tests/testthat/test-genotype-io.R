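# GenePop reading/writing, the metadata sidecar, and table validation

write_toy_files <- function(dir, genepop_lines, meta) {
  gp <- file.path(dir, "toy.gen")
  writeLines(genepop_lines, gp)
  mp <- file.path(dir, "toy.tsv")
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  c(gen = gp, meta = mp)
}

test_that("a hand-written 2-population 2-locus file parses with normalized pairs", {
  dir <- withr::local_tempdir()
  p <- write_toy_files(dir,
    c("toy data", "L1", "L2", "POP",
      "x1 ,  0201 0102", "x2 ,  0101 0000", "POP", "y1 ,  0102 0202"),
    data.frame(sample_id = c("x1", "x2", "y1"),
               island = c("A", "A", "B"), sex = c("M", "F", "F")))
  tab <- read_genepop(p["gen"], p["meta"])
  expect_equal(length(islands(tab)), 2L)
  expect_equal(n_loci(tab), 2L)
  # "0201" is stored order-normalized as (1, 2)
  expect_equal(unname(tab$a1["x1", "L1"]), 1L)
  expect_equal(unname(tab$a2["x1", "L1"]), 2L)
  # all-zeros code is a missing call, individual retained
  expect_true(is.na(tab$a1["x2", "L2"]))
  expect_equal(n_ind(tab), 3L)
})

test_that("parse and validation errors name the problem", {
  dir <- withr::local_tempdir()
  p <- write_toy_files(dir,
    c("bad width", "L1", "POP", "x1 ,  010"),
    data.frame(sample_id = "x1", island = "A", sex = "M"))
  expect_error(read_genepop(p["gen"], p["meta"]), "malformed allele width")

  p2 <- write_toy_files(dir,
    c("missing meta", "L1", "POP", "x1 ,  0101", "zz ,  0101"),
    data.frame(sample_id = "x1", island = "A", sex = "M"))
  expect_error(read_genepop(p2["gen"], p2["meta"]), "absent from sidecar")

  p3 <- write_toy_files(dir,
    c("bad sex", "L1", "POP", "x1 ,  0101"),
    data.frame(sample_id = "x1", island = "A", sex = "X"))
  expect_error(read_genepop(p3["gen"], p3["meta"]), "outside \\{M,F\\}")

  # a POP block mixing sidecar islands is rejected
  p4 <- write_toy_files(dir,
    c("mixed block", "L1", "POP", "x1 ,  0101", "x2 ,  0101"),
    data.frame(sample_id = c("x1", "x2"), island = c("A", "B"),
               sex = c("M", "F")))
  expect_error(read_genepop(p4["gen"], p4["meta"]), "mixes sidecar islands")
})

test_that("write/read round-trip is the identity, including 3-digit alleles", {
  dir <- withr::local_tempdir()
  set.seed(11)
  tab <- random_table(n_islands = 3, ni = 6, L = 3, k = 5, missing_rate = 0.1)
  gp <- file.path(dir, "rt.gen"); mp <- file.path(dir, "rt.tsv")
  write_genepop(tab, gp); write_sidecar(tab, mp)
  back <- read_genepop(gp, mp)
  expect_identical(back$a1, tab$a1)
  expect_identical(back$a2, tab$a2)
  expect_identical(back$ind, tab$ind)

  # microsatellite fragment sizes in the 244-258 bp range force 3-digit codes
  big <- genotype_table(c("s1", "s2"), c("A", "A"), c("M", "F"), "Osch11",
                        matrix(c(244L, 250L)), matrix(c(258L, 250L)))
  write_genepop(big, gp); write_sidecar(big, mp)
  line <- grep("^s1", readLines(gp), value = TRUE)
  expect_match(line, "244258")
  back <- read_genepop(gp, mp)
  expect_identical(back$a1, big$a1)
  # identifiers above the representable width are an encoding error
  expect_error(write_genepop(big, gp, width = 2), "exceeds")
})

test_that("the survey-shaped fixture reproduces the published sampling frame", {
  dir <- withr::local_tempdir()
  paths <- make_survey_fixture(dir, seed = 7)
  tab <- read_genepop(paths[["genepop"]], paths[["sidecar"]])
  expect_equal(n_ind(tab), 382L)
  expect_equal(length(islands(tab)), 14L)
  expect_equal(n_loci(tab), 10L)
  cnt <- table(tab$ind$island, tab$ind$sex)
  expect_equal(unname(cnt["02", "M"]), 11L)
  expect_equal(unname(cnt["02", "F"]), 30L)
  # per-island counts equal the sidecar row counts
  meta <- read_sidecar(paths[["sidecar"]])
  expect_equal(table(tab$ind$island), table(meta$island))
  # round-trip of the full fixture
  gp <- file.path(dir, "copy.gen")
  write_genepop(tab, gp)
  back <- read_genepop(gp, paths[["sidecar"]])
  expect_identical(back$a1, tab$a1)
  expect_identical(back$a2, tab$a2)
})

test_that("exclude_loci drops loci, is identity on empty set, errors on bad input", {
  tab <- toy_table()
  expect_identical(exclude_loci(tab, character(0)), tab)
  red <- exclude_loci(tab, "L2")
  expect_equal(red$loci, "L1")
  expect_equal(red$ind, tab$ind)
  expect_error(exclude_loci(tab, "nope"), "unknown loci")
  expect_error(exclude_loci(tab, c("L1", "L2")), "empty locus set")
  # 12-locus table minus two unreliable markers leaves ten
  set.seed(2)
  t12 <- random_table(n_islands = 2, ni = 4, L = 12)
  t10 <- exclude_loci(t12, c("L4", "L8"))
  expect_equal(n_loci(t10), 10L)
})

test_that("individuals with >50% missing loci are flagged but retained", {
  tab <- toy_table()
  tab$a1["b1", ] <- NA_integer_; tab$a2["b1", ] <- NA_integer_
  expect_warning(out <- flag_missing_individuals(tab), "exceed 50% missing")
  expect_equal(attr(out, "flagged"), "b1")
  expect_equal(n_ind(out), 6L)
  expect_warning(out2 <- flag_missing_individuals(tab, drop = TRUE))
  expect_equal(n_ind(out2), 5L)
})

test_that("writing an empty population block errors", {
  empty <- genotype_table(character(0), character(0), character(0), "L1",
                          matrix(integer(0), 0, 1), matrix(integer(0), 0, 1))
  dir <- withr::local_tempdir()
  expect_error(write_genepop(empty, file.path(dir, "e.gen")),
               "empty population block")
})
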