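## Report serialisation: fixed-schema TSV tables (two-decimal floats, "NA"
## for absent strata) and a single human-readable summary file assembling
## the count, accuracy and quality sections.

fmt2 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 2))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write the evaluation report tables
#'
#' Emits up to four fixed-schema TSV files into `out_dir`:
#' \describe{
#'   \item{counts.tsv}{per stratum (autosomes, X): imputed variant count,
#'     overlap count, percentage of no-calls;}
#'   \item{accuracy.tsv}{per stratum: match-class counts, accuracy \%,
#'     genome-wide error \%, adjusted accuracy \% (ambiguous no-matches
#'     counted correct);}
#'   \item{quality_by_class.tsv}{per stratum and match class: n, median
#'     quality;}
#'   \item{quality_by_maf.tsv}{per MAF bin: n and central quality.}
#' }
#' Floats are printed with two decimals; absent strata print `NA`.
#'
#' @param summary a `concordance_summary` from [summarize_concordance()]
#'   (or `NULL` to emit an all-NA accuracy table).
#' @param quality_by_class optional table from [quality_by_match_class()].
#' @param quality_by_maf optional table from [quality_by_maf()].
#' @param counts optional data frame `stratum`/`n_imputed`/`n_overlap`/
#'   `pct_no_call`; when `NULL`, derived from `summary` with `n_imputed` NA.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report_tables <- function(summary, quality_by_class = NULL,
                                quality_by_maf = NULL, counts = NULL,
                                out_dir = ".") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  written <- character(0)

  strata <- c("autosomes", "X")
  if (is.null(summary) || nrow(summary) == 0L) {
    summary <- data.frame(stratum = strata, n_overlap = 0L, n_excluded = 0L,
                          complete = 0L, flip = 0L, half = 0L, none = 0L,
                          none_ambiguous = 0L, accuracy_pct = NA_real_,
                          error_pct = NA_real_,
                          adjusted_accuracy_pct = NA_real_)
  }
  pooled <- summary[summary$stratum %in% strata, , drop = FALSE]

  if (is.null(counts)) {
    counts <- data.frame(stratum = pooled$stratum, n_imputed = NA_integer_,
                         n_overlap = pooled$n_overlap,
                         pct_no_call = NA_real_)
  }
  counts$pct_no_call <- fmt2(counts$pct_no_call)
  written <- c(written, write_tsv(counts, file.path(out_dir, "counts.tsv")))

  acc <- pooled
  for (col in c("accuracy_pct", "error_pct", "adjusted_accuracy_pct")) {
    acc[[col]] <- fmt2(acc[[col]])
  }
  written <- c(written, write_tsv(acc, file.path(out_dir, "accuracy.tsv")))

  if (!is.null(quality_by_class)) {
    quality_by_class$median_quality <- fmt2(quality_by_class$median_quality)
    written <- c(written, write_tsv(quality_by_class,
                                    file.path(out_dir,
                                              "quality_by_class.tsv")))
  }
  if (!is.null(quality_by_maf)) {
    for (col in intersect(c("median", "mean"), names(quality_by_maf))) {
      quality_by_maf[[col]] <- fmt2(quality_by_maf[[col]])
    }
    written <- c(written, write_tsv(quality_by_maf,
                                    file.path(out_dir,
                                              "quality_by_maf.tsv")))
  }
  invisible(written)
}

#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end evaluation run:
#' simulation, array split, QC, calling, concordance and quality
#' summarisation. One run directory per invocation.
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param seed integer seed governing every random draw of the run.
#' @param sim a [simulation_config()] (its own `seed` is overridden by
#'   `seed`).
#' @param thresholds a [qc_thresholds()].
#' @param calling a [calling_config()].
#' @param bins a [maf_binning()].
#' @param split list of the [split_arrays()] fractions.
#' @param do_qc run iterative QC on both arrays (default TRUE).
#' @param do_sex_check run the X sex-concordance check on the truth array
#'   when it carries X variants (default TRUE).
#' @param write_fixtures also write truth/imputed VCF, GEN/SAMPLE and the
#'   shared-variant list into the run directory (default FALSE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = simulation_config(n_samples = 120,
                                                    n_variants = 4000),
                            thresholds = qc_thresholds(),
                            calling = calling_config(),
                            bins = maf_binning(),
                            split = list(frac_shared_samples = 0.5,
                                         frac_shared_variants = 0.2,
                                         frac_array_a_only = 0.5),
                            do_qc = TRUE, do_sex_check = TRUE,
                            write_fixtures = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 thresholds = thresholds, calling = calling, bins = bins,
                 split = split, do_qc = isTRUE(do_qc),
                 do_sex_check = isTRUE(do_sex_check),
                 write_fixtures = isTRUE(write_fixtures)),
            class = "pipeline_config")
}

config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end evaluation pipeline on simulated data
#'
#' Executes simulate -> split -> (QC + sex check) -> pseudo-impute -> call
#' -> concordance -> quality summaries, writes the report TSVs, the
#' injected-label table and a JSON run manifest (package version, seed,
#' config hash, output checksums) into `cfg$out_dir`. Identical config and
#' seed reproduce byte-identical report files.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the key in-memory objects (`summary`,
#'   `classification`, `counts`, `qc_a`, `qc_b`, `no_call_fraction`,
#'   `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$sim
  sim$seed <- cfg$seed

  truth <- simulate_cohort(sim)
  arrays <- do.call(split_arrays, c(list(truth), cfg$split))

  qc_a <- qc_b <- NULL
  gm_a <- arrays$array_a; gm_b <- arrays$array_b
  if (cfg$do_qc) {
    res_a <- run_iterative_qc(gm_a, cfg$thresholds)
    res_b <- run_iterative_qc(gm_b, cfg$thresholds)
    gm_a <- res_a$gm; gm_b <- res_b$gm
    qc_a <- res_a$report; qc_b <- res_b$report
  }
  if (cfg$do_sex_check && any(gm_b$variants$chrom == "X")) {
    disc <- sex_concordance_check(gm_b, attr(truth, "sex"), cfg$thresholds)
    if (nrow(disc)) {
      gm_b <- gm_subset(gm_b, samples = setdiff(gm_b$samples, disc$sample))
    }
  }

  # pseudo-imputation of the truth-array region for the shared samples
  shared <- intersect(arrays$shared_samples, gm_b$samples)
  if (length(shared) == 0L) stop("no shared samples survived QC")
  region <- gm_subset(gm_b, samples = shared)
  pgm <- corrupt_as_imputed(region, sim)
  labels <- attr(pgm, "labels")

  pgm <- remove_indels(pgm)
  called <- call_genotypes(pgm, cfg$calling)
  gm_imp <- prune_uncalled_variants(called$gm, cfg$calling$uncalled_variant_rule)

  pair <- extract_overlap(gm_imp, gm_b,
                          pre_imputation_variants = arrays$shared_variants)
  cls <- classify_overlap(pair)
  summary <- summarize_concordance(cls)

  # per-stratum counts and no-call rates on the imputed (post-prune) data
  imp_x <- gm_imp$variants$chrom == "X"
  pct_nc <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * mean(is.na(called$gm$calls[, sel]))
  }
  counts <- data.frame(
    stratum = c("autosomes", "X"),
    n_imputed = c(sum(!imp_x), sum(imp_x)),
    n_overlap = summary$n_overlap[match(c("autosomes", "X"),
                                        summary$stratum)],
    pct_no_call = c(pct_nc(called$gm$variants$chrom != "X"),
                    pct_nc(called$gm$variants$chrom == "X")))

  # quality summaries on the imputed dataset, aligned to the overlap
  qual_at <- pgm$quality[match(paste(cls$chrom, cls$pos),
                               paste(pgm$variants$chrom, pgm$variants$pos))]
  qbc <- quality_by_match_class(cls, qual_at)
  maf <- compute_maf(gm_imp)
  qual_imp <- pgm$quality[match(variant_key(gm_imp$variants),
                                variant_key(pgm$variants))]
  qbm <- quality_by_maf(qual_imp, maf, cfg$bins, stat = "both")

  files <- write_report_tables(summary, qbc, qbm, counts, cfg$out_dir)
  files <- c(files, write_tsv(labels, file.path(cfg$out_dir, "labels.tsv")))

  if (cfg$write_fixtures) {
    files <- c(files,
               write_vcf(truth, file.path(cfg$out_dir, "truth.vcf")),
               write_vcf(pgm, file.path(cfg$out_dir, "imputed.vcf")),
               write_gen_sample(pgm, file.path(cfg$out_dir, "imputed.gen"),
                                file.path(cfg$out_dir, "imputed.sample")),
               write_tsv(arrays$shared_variants,
                         file.path(cfg$out_dir, "shared_variants.tsv")))
  }

  manifest <- list(
    tool = "impuconcord",
    version = as.character(utils::packageVersion("impuconcord")),
    seed = cfg$seed,
    config_md5 = config_digest(cfg),
    n_samples = sim$n_samples, n_variants = sim$n_variants,
    files = as.list(tools::md5sum(sort(unlist(files)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(summary = summary, classification = cls, counts = counts,
                 qc_a = qc_a, qc_b = qc_b,
                 no_call_fraction = called$no_call_fraction,
                 quality_by_class = qbc, quality_by_maf = qbm,
                 labels = labels, files = files))
}

#' Assemble a single table-style summary report
#'
#' Reads the TSV tables of a finished run directory and writes
#' `report.txt` with three sections: variant counts and no-call rates,
#' accuracy and genome-wide error, and per-class quality. Re-verifies the
#' report identities (error = 100 - accuracy; class counts sum to the
#' overlap) and aborts if a table is missing or inconsistent.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return Path of the report file, invisibly.
#' @export
make_summary_report <- function(run_dir) {
  need <- c("counts.tsv", "accuracy.tsv", "quality_by_class.tsv")
  for (f in need) {
    if (!file.exists(file.path(run_dir, f))) {
      stop("missing stage output: ", f)
    }
  }
  counts <- utils::read.delim(file.path(run_dir, "counts.tsv"))
  acc <- utils::read.delim(file.path(run_dir, "accuracy.tsv"))
  qbc <- utils::read.delim(file.path(run_dir, "quality_by_class.tsv"))

  ok <- is.na(acc$accuracy_pct) | is.na(acc$error_pct) |
    abs(acc$accuracy_pct + acc$error_pct - 100) < 0.015  # 2-dp rounding
  if (!all(ok)) stop("report identity violated: accuracy + error != 100")
  csum <- acc$complete + acc$flip + acc$half + acc$none
  if (!all(csum == acc$n_overlap)) {
    stop("report identity violated: class counts do not sum to overlap")
  }

  lines <- c(
    "== Imputed variants, overlap and no-call rate ==",
    utils::capture.output(print(counts, row.names = FALSE)),
    "",
    "== Accuracy and genome-wide error (%) ==",
    utils::capture.output(print(acc, row.names = FALSE)),
    "",
    "== Median quality by match class ==",
    utils::capture.output(print(qbc, row.names = FALSE)))
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
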