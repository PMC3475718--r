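# End-to-end orchestration: validate -> diversity -> HWE/LD -> AMOVA ->
# AIc -> sex-bias tests -> landscape regression, with per-stage TSV outputs
# and a combined plain-text report.

#' Pipeline run configuration
#'
#' Bundles input paths and analysis settings for [run_all()]. May also be
#' loaded from a YAML file with [read_run_config()]. One master `seed` drives
#' every stochastic stage; per-stage seeds are derived from it
#' deterministically, so two runs with the same configuration are identical.
#'
#' @param genepop,sidecar,attrs input file paths (GenePop genotypes, metadata
#'   sidecar, island-attribute TSV with columns `island`, `area_ha`,
#'   `perimeter_m`, `isolation_m`, `breeding_sites`).
#' @param out_dir output directory.
#' @param alpha significance level (default 0.05).
#' @param seed master integer seed.
#' @param hwe_mc_iter Monte-Carlo iterations for unenumerable HWE cells.
#' @param ld_perms,amova_perms permutation counts.
#' @param leave_one_out,zero_freq assignment-index options (see
#'   [assignment_index()]).
#' @param exclude_loci locus names to drop before analysis (upstream
#'   reliability filter), or `NULL`.
#' @return list of class `run_config`.
#' @export
run_config <- function(genepop, sidecar, attrs, out_dir,
                       alpha = 0.05, seed = 1L,
                       hwe_mc_iter = 5000, ld_perms = 500, amova_perms = 500,
                       leave_one_out = FALSE, zero_freq = 0.01,
                       exclude_loci = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(genepop = genepop, sidecar = sidecar, attrs = attrs,
                 out_dir = out_dir, alpha = alpha, seed = as.integer(seed),
                 hwe_mc_iter = hwe_mc_iter, ld_perms = ld_perms,
                 amova_perms = amova_perms, leave_one_out = leave_one_out,
                 zero_freq = zero_freq, exclude_loci = exclude_loci),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full dispersal analysis pipeline
#'
#' Executes every stage of the analysis in sequence, writing one TSV per stage
#' to `config$out_dir` plus a combined plain-text report (`report.txt`).
#' Stage outputs consumed by later stages are read back from disk, so each
#' stage can be re-run independently from its predecessors' files. Islands
#' with a single sampled sex are dropped from the sex-bias and landscape
#' stages with a log line in the report.
#'
#' Stages and outputs: `summary.tsv` (per-island n/MAR/Ho/He), `hwe.tsv`,
#' `ld.tsv`, `amova.tsv`, `aic.tsv` (per-individual AIc), `sexbias.tsv`
#' (per-island Mann-Whitney + dAIc), `model.tsv`, `stepwise_trace.tsv`,
#' `partition.tsv` (landscape regression), `report.txt`.
#'
#' @param config a [run_config()] (or path to its YAML form).
#' @return list with the main in-memory results (`table`, `summary`, `hwe`,
#'   `ld`, `amova`, `aic`, `sexbias`, `pooled`, `model`, `trace`,
#'   `partition`, `files`), invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  seeds <- config$seed + c(hwe = 101L, ld = 202L, amova = 303L)

  tab <- stage("validate", {
    t0 <- read_genepop(config$genepop, config$sidecar)
    if (!is.null(config$exclude_loci)) t0 <- exclude_loci(t0, config$exclude_loci)
    flag_missing_individuals(t0)
  })
  note("input: ", n_ind(tab), " individuals, ", n_loci(tab), " loci, ",
       length(islands(tab)), " islands")

  summ <- stage("summary", pop_summary(tab))
  write_tsv(summ, file.path(config$out_dir, "summary.tsv"))

  hwe <- stage("hwe", hwe_exact(tab, mc_iter = config$hwe_mc_iter,
                                seed = seeds[["hwe"]], alpha = config$alpha))
  write_tsv(hwe, file.path(config$out_dir, "hwe.tsv"))

  ld <- stage("ld", ld_test(tab, permutations = config$ld_perms,
                            seed = seeds[["ld"]], alpha = config$alpha))
  write_tsv(ld, file.path(config$out_dir, "ld.tsv"))

  am <- stage("amova", amova_two_level(tab, permutations = config$amova_perms,
                                       seed = seeds[["amova"]]))
  am_tab <- data.frame(
    source = c("Among populations", "Within populations"),
    sum_of_squares = c(am$ss_among, am$ss_within),
    df = c(am$df_among, am$df_within),
    variance_component = c(am$sigma2_a, am$sigma2_w),
    percent_variation = c(am$percent_among, am$percent_within),
    p = c(am$p, NA))
  write_tsv(am_tab, file.path(config$out_dir, "amova.tsv"))

  aic_path <- file.path(config$out_dir, "aic.tsv")
  stage("assignment", {
    rec <- assignment_index(tab, leave_one_out = config$leave_one_out,
                            zero_freq = config$zero_freq)
    write_tsv(rec, aic_path)
  })
  # downstream stages consume the on-disk AIc table
  rec <- utils::read.delim(aic_path, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character",
                                          island = "character"))

  single_sex <- with(rec, tapply(sex, island, function(s)
    length(unique(s[!is.na(s)])) < 2))
  if (any(single_sex))
    note("dropped single-sex islands: ",
         paste(names(single_sex)[single_sex], collapse = ", "))
  rec2 <- rec[!(rec$island %in% names(single_sex)[single_sex]), ]

  sb <- stage("sex_bias", suppressWarnings(sex_bias_test(rec2, config$alpha)))
  write_tsv(sb, file.path(config$out_dir, "sexbias.tsv"))
  dd <- stage("daic", daic(rec2))

  # landscape stage: per-island dAIc read back from sexbias.tsv
  sbb <- utils::read.delim(file.path(config$out_dir, "sexbias.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(island = "character"))
  attrs <- stage("landscape_inputs", {
    a <- utils::read.delim(config$attrs, stringsAsFactors = FALSE,
                           colClasses = c(island = "character"))
    sm <- shape_metrics(a$area_ha, a$perimeter_m)
    a$par <- sm$par; a$si <- sm$si
    cnt <- table(tab$ind$island, tab$ind$sex)
    a$n_male <- as.integer(cnt[a$island, "M"])
    a$n_female <- as.integer(cnt[a$island, "F"])
    a
  })
  m <- match(sbb$island, attrs$island)
  if (anyNA(m)) stop("stage 'landscape' failed: attribute rows missing for islands ",
                     paste(sbb$island[is.na(m)], collapse = ", "))
  land <- attrs[m, ]
  design <- data.frame(A = land$area_ha, I = land$isolation_m, PAR = land$par,
                       SI = land$si, SR = land$n_male / land$n_female,
                       BS = land$breeding_sites)
  y <- sbb$daic
  vf <- stage("vif", vif(design))
  keep <- vf$predictor[!vf$flagged]
  if (length(keep) < ncol(design))
    note("VIF-excluded predictors: ",
         paste(setdiff(vf$predictor, keep), collapse = ", "))
  sel <- stage("stepwise", backward_stepwise_aicc(y, design[keep]))
  write_tsv(sel$trace, file.path(config$out_dir, "stepwise_trace.tsv"))
  co <- sel$fit$coefficients
  model_tab <- data.frame(term = names(co), estimate = unname(co))
  model_tab <- rbind(model_tab,
                     data.frame(term = c("R2", "F", "p", "AICc", "n"),
                                estimate = c(sel$fit$r2, sel$fit$f, sel$fit$p,
                                             sel$fit$aicc, sel$fit$n)))
  write_tsv(model_tab, file.path(config$out_dir, "model.tsv"))

  part <- NULL
  if (length(sel$fit$predictors) >= 2) {
    p1 <- sel$fit$predictors[1]; p2 <- sel$fit$predictors[2]
    part <- stage("partition",
                  variance_partition(y, design[[p1]], design[[p2]]))
    write_tsv(data.frame(component = c(paste0("unique_", p1),
                                       paste0("unique_", p2),
                                       "shared", "unexplained"),
                         r2_fraction = c(part$unique_1, part$unique_2,
                                         part$shared, part$unexplained)),
              file.path(config$out_dir, "partition.tsv"))
  } else note("variance partition skipped: fewer than two predictors retained")

  chi <- sex_ratio_chi2(land$n_male, land$n_female)
  chi <- cbind(island = land$island, chi)
  write_tsv(chi, file.path(config$out_dir, "sexratio_chi2.tsv"))

  # ---- report ----
  rp <- file.path(config$out_dir, "report.txt")
  con <- file(rp, "w")
  w <- function(...) writeLines(paste0(...), con)
  w("dispersalkit pipeline report")
  w("seed: ", config$seed, "   alpha: ", config$alpha)
  w("")
  for (ln in log_lines) w("note: ", ln)
  w("")
  w("Total individuals: ", n_ind(tab))
  w("")
  w("Per-island diversity (n, M/F, MAR, Ho, He):")
  for (i in seq_len(nrow(summ)))
    w(sprintf("  %s  n=%3d  %2dM/%2dF  MAR=%5.2f  Ho=%.3f  He=%.3f",
              summ$island[i], summ$n[i], summ$n_male[i], summ$n_female[i],
              summ$mar[i], summ$ho[i], summ$he[i]))
  w("")
  w("HWE: ", sum(hwe$significant, na.rm = TRUE), " of ",
    sum(hwe$flag == ""), " testable (island, locus) cells significant after FDR")
  w("LD:  ", sum(ld$significant, na.rm = TRUE), " of ",
    sum(ld$flag == ""), " testable locus pairs significant after FDR")
  w("")
  w("AMOVA:")
  w(sprintf("  Among populations : SS=%9.2f  %%var=%6.2f  p=%.4g",
            am$ss_among, am$percent_among, am$p))
  w(sprintf("  Within populations: SS=%9.2f  %%var=%6.2f",
            am$ss_within, am$percent_within))
  w("")
  w("Per-island sex-bias (dAIc = mean male AIc - mean female AIc):")
  for (i in seq_len(nrow(sb)))
    w(sprintf("  %s  dAIc=%+.4f  U=%6.1f  p=%.3f  q=%.3f  %s%s",
              sb$island[i], sb$daic[i], sb$u[i], sb$p_raw[i], sb$p_fdr[i],
              sb$direction[i], if (sb$significant[i]) " *" else ""))
  w("")
  w(sprintf("Pooled: mean male AIc = %+.4f, mean female AIc = %+.4f, dAIc = %+.4f (p = %.3f)",
            dd$pooled$mean_aic_male, dd$pooled$mean_aic_female,
            dd$pooled$daic, dd$pooled$p))
  w("")
  w("Landscape model (backward stepwise, AICc):")
  w("  retained: ", if (length(sel$fit$predictors))
      paste(sel$fit$predictors, collapse = ", ") else "(intercept only)")
  w(sprintf("  R2 = %.3f  F = %.3f  p = %.4g  AICc = %.2f",
            sel$fit$r2, sel$fit$f, sel$fit$p, sel$fit$aicc))
  if (!is.null(part))
    w(sprintf("  partition: unique %.3f / %.3f, shared %.3f, unexplained %.3f",
              part$unique_1, part$unique_2, part$shared, part$unexplained))
  close(con)

  invisible(list(table = tab, summary = summ, hwe = hwe, ld = ld, amova = am,
                 aic = rec, sexbias = sb, pooled = dd$pooled, model = sel$fit,
                 trace = sel$trace, partition = part, chi2 = chi,
                 files = list.files(config$out_dir, full.names = TRUE)))
}
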