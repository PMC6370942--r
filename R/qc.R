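## Iterative pre-imputation array QC: per-sample and per-variant missingness,
## minor allele frequency, heterozygosity outliers (inbreeding F), and an
## X-chromosome sex-concordance check. Boundary comparisons are strict
## ("more than" / "below"), and the filters are repeated to a fixed point.

variant_freq_b <- function(gm) {
  n_called <- colSums(!is.na(gm$calls))
  fb <- colSums(gm$calls, na.rm = TRUE) / (2 * n_called)
  fb[n_called == 0L] <- NA_real_
  fb
}

#' Per-variant minor allele frequency
#'
#' MAF = min(f, 1 - f) of the B-allele frequency f, computed over called
#' genotypes only; variants with no called genotype get `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @return Numeric vector in \[0, 0.5\] (or `NA`), one value per variant.
#' @export
compute_maf <- function(gm) {
  fb <- variant_freq_b(gm)
  pmin(fb, 1 - fb)
}

#' Per-sample inbreeding statistic F
#'
#' F = 1 - observed heterozygote count / expected heterozygote count, the
#' expectation summing 2 p (1 - p) over the variants called in that sample,
#' with p the per-variant B-allele frequency over called genotypes. Values
#' near 0 are consistent with Hardy-Weinberg heterozygosity; strongly
#' negative values indicate excess heterozygosity; on the X chromosome
#' hemizygous males sit near 1.
#'
#' @param gm a `genotype_matrix`.
#' @return Named numeric vector, one F per sample (`NA` when the expected
#'   count is zero).
#' @export
sample_het_f <- function(gm) {
  fb <- variant_freq_b(gm)
  exp_het <- 2 * fb * (1 - fb)
  exp_het[is.na(exp_het)] <- 0
  called <- !is.na(gm$calls)
  e <- as.vector(called %*% exp_het)
  o <- rowSums(gm$calls == 1L, na.rm = TRUE)
  f <- 1 - o / e
  f[e == 0] <- NA_real_
  names(f) <- gm$samples
  f
}

removal_df <- function(type = character(0), id = character(0),
                       rule = character(0)) {
  data.frame(type = as.character(type), id = as.character(id),
             rule = as.character(rule), stringsAsFactors = FALSE)
}

#' One pass of array quality control
#'
#' Applies, in order: (1) remove samples missing more than
#' `sample_missing_max` of their genotypes; (2) remove variants with more
#' than `variant_missing_max` missingness, computed on the remaining
#' samples; (3) remove variants with MAF below `maf_min`; (4) remove samples
#' whose heterozygosity F lies outside mean(F) +/- `het_sd_multiplier` sd(F).
#' All comparisons are strict.
#'
#' @param gm a `genotype_matrix`.
#' @param thr a [qc_thresholds()] object.
#' @return A list with elements `gm` (the filtered matrix) and `removals`
#'   (data frame with columns `type`, `id`, `rule`).
#' @export
qc_pass <- function(gm, thr = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(thr, "qc_thresholds"))
  if (length(gm$samples) == 0L || nrow(gm$variants) == 0L) {
    stop("empty cohort")
  }
  removals <- removal_df()

  # (1) sample missingness
  smiss <- rowMeans(is.na(gm$calls))
  drop_s <- gm$samples[smiss > thr$sample_missing_max]
  if (length(drop_s)) {
    removals <- rbind(removals,
                      removal_df("sample", drop_s, "sample_missingness"))
    if (length(drop_s) == length(gm$samples)) stop("empty cohort")
    gm <- gm_subset(gm, samples = setdiff(gm$samples, drop_s))
  }

  # (2) variant missingness on remaining samples
  vmiss <- colMeans(is.na(gm$calls))
  drop_v <- vmiss > thr$variant_missing_max
  if (any(drop_v)) {
    removals <- rbind(removals,
                      removal_df("variant", gm$variants$id[drop_v],
                                 "variant_missingness"))
    gm <- gm_subset(gm, variants = !drop_v)
  }
  if (nrow(gm$variants) == 0L) stop("no variants remain after QC pass")

  # (3) MAF; an uncallable (all-missing) variant has undefined MAF -> removed
  maf <- compute_maf(gm)
  drop_v <- is.na(maf) | maf < thr$maf_min
  if (any(drop_v)) {
    removals <- rbind(removals,
                      removal_df("variant", gm$variants$id[drop_v], "maf"))
    gm <- gm_subset(gm, variants = !drop_v)
  }
  if (nrow(gm$variants) == 0L) stop("no variants remain after QC pass")

  # (4) heterozygosity outliers
  f <- sample_het_f(gm)
  mu <- mean(f, na.rm = TRUE)
  sdv <- stats::sd(f, na.rm = TRUE)
  if (is.finite(sdv) && sdv > 0) {
    drop_s <- gm$samples[!is.na(f) & abs(f - mu) > thr$het_sd_multiplier * sdv]
    if (length(drop_s)) {
      removals <- rbind(removals,
                        removal_df("sample", drop_s, "heterozygosity"))
      if (length(drop_s) == length(gm$samples)) stop("empty cohort")
      gm <- gm_subset(gm, samples = setdiff(gm$samples, drop_s))
    }
  }

  list(gm = gm, removals = removals)
}

#' Iterate QC passes to a fixed point
#'
#' Repeats [qc_pass()] until a pass removes nothing. Termination is
#' guaranteed by monotone shrinkage: every non-final pass removes at least
#' one sample or variant.
#'
#' @inheritParams qc_pass
#' @return A list with elements `gm` (the stable filtered matrix) and
#'   `report`, an object of class `qc_report` holding the per-iteration
#'   removal ledgers, the final genotyping rate, and the final per-sample F.
#' @export
run_iterative_qc <- function(gm, thr = qc_thresholds()) {
  iterations <- list()
  n_start <- length(gm$samples) + nrow(gm$variants)
  repeat {
    res <- qc_pass(gm, thr)
    iterations[[length(iterations) + 1L]] <- res$removals
    gm <- res$gm
    if (nrow(res$removals) == 0L) break
    if (length(iterations) > n_start) {
      stop("QC failed to reach a fixed point")  # unreachable by construction
    }
  }
  report <- structure(
    list(iterations = iterations,
         n_iterations = length(iterations),
         genotyping_rate = 1 - mean(is.na(gm$calls)),
         sample_f = sample_het_f(gm)),
    class = "qc_report")
  list(gm = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  removed <- sum(vapply(x$iterations, nrow, integer(1)))
  cat(sprintf(
    "qc_report: %d iteration(s), %d removal(s), genotyping rate %.4f\n",
    x$n_iterations, removed, x$genotyping_rate))
  invisible(x)
}

#' Flatten a QC report's removal ledger
#'
#' @param report a `qc_report`.
#' @return Data frame with columns `iteration`, `type`, `id`, `rule`.
#' @export
qc_removals <- function(report) {
  out <- do.call(rbind, lapply(seq_along(report$iterations), function(i) {
    r <- report$iterations[[i]]
    if (nrow(r) == 0L) return(NULL)
    cbind(iteration = i, r)
  }))
  if (is.null(out)) out <- cbind(iteration = integer(0), removal_df())
  out
}

#' Sex-concordance check on X-chromosome heterozygosity
#'
#' Computes the per-sample F statistic on X-linked variants only and infers
#' sex from it: female when F < `sex_f_female_max`, male when F >
#' `sex_f_male_min`, undetermined in the band between. Samples whose
#' inferred sex is determined and contradicts the reported sex are returned;
#' a reported sex of `"unknown"` (or a sample absent from `reported_sex`)
#' is never discordant, and neither is an undetermined inference.
#'
#' @param gm_x a `genotype_matrix`; only its X-chromosome variants are used.
#' @param reported_sex named character vector (values `"male"`, `"female"`,
#'   `"unknown"`) keyed by sample ID.
#' @param thr a [qc_thresholds()] object (uses the `sex_f_*` bands).
#' @return Data frame of discordant samples with columns `sample`,
#'   `reported`, `inferred`, `f`.
#' @export
sex_concordance_check <- function(gm_x, reported_sex,
                                  thr = qc_thresholds()) {
  on_x <- gm_x$variants$chrom == "X"
  if (!any(on_x)) stop("no X data")
  gm_x <- gm_subset(gm_x, variants = on_x)
  f <- sample_het_f(gm_x)
  inferred <- ifelse(is.na(f), "undetermined",
              ifelse(f < thr$sex_f_female_max, "female",
              ifelse(f > thr$sex_f_male_min, "male", "undetermined")))
  reported <- reported_sex[gm_x$samples]
  reported[is.na(reported)] <- "unknown"
  disc <- inferred != "undetermined" & reported %in% c("male", "female") &
    inferred != reported
  data.frame(sample = gm_x$samples[disc],
             reported = unname(reported[disc]),
             inferred = inferred[disc],
             f = unname(f[disc]),
             stringsAsFactors = FALSE)
}
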