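## Hard-calling of imputed posterior probabilities. A genotype is called
## when its posterior is the unique maximum of the triple and reaches the
## calling threshold (inclusive, matching PLINK's --vcf-min-gp); anything
## else — sub-threshold maximum, tied maximum, or the all-zero GEN no-call
## sentinel — is left missing ("N").

#' Call hard genotypes from posterior probabilities
#'
#' Per sample x variant entry, let m = max(p0, p1, p2). The entry is called
#' to the argmax genotype when m >= `threshold` and the maximum is unique;
#' otherwise it is missing. An all-zero triple has m = 0 and a three-way
#' tie, so it is missing at every threshold.
#'
#' @param pgm a [prob_genotype_matrix()].
#' @param config a [calling_config()]; only its `threshold` is used here
#'   (indel dropping and variant pruning are separate, composable steps).
#' @return A list with `gm` (the called [genotype_matrix()]) and
#'   `no_call_fraction`, the fraction of entries left missing.
#' @export
call_genotypes <- function(pgm, config = calling_config()) {
  stopifnot(inherits(pgm, "prob_genotype_matrix"),
            inherits(config, "calling_config"))
  t <- config$threshold
  p0 <- pgm$probs[, , 1L]; p1 <- pgm$probs[, , 2L]; p2 <- pgm$probs[, , 3L]
  m <- pmax(p0, p1, p2)
  n_at_max <- (p0 == m) + (p1 == m) + (p2 == m)
  call <- ifelse(p2 == m, 2L, ifelse(p1 == m, 1L, 0L))
  call[m < t | n_at_max > 1L] <- NA_integer_
  calls <- matrix(call, nrow = dim(pgm$probs)[1L])
  gm <- genotype_matrix(calls, pgm$variants, pgm$samples)
  list(gm = gm, no_call_fraction = mean(is.na(calls)))
}

#' Drop non-SNP (indel) variants
#'
#' Removes every variant for which [is_snp()] is false; the number removed
#' is reported via `message()` and attached as attribute `"n_indels_removed"`.
#'
#' @param x a `genotype_matrix` or `prob_genotype_matrix`.
#' @return The object restricted to SNPs (possibly with zero variants).
#' @export
remove_indels <- function(x) {
  keep <- is_snp(x$variants)
  n_drop <- sum(!keep)
  if (n_drop > 0L) message("remove_indels: dropped ", n_drop, " indel(s)")
  out <- if (inherits(x, "prob_genotype_matrix")) {
    pgm_subset_variants(x, keep)
  } else {
    gm_subset(x, variants = keep)
  }
  attr(out, "n_indels_removed") <- n_drop
  out
}

#' Prune variants left uncalled after hard-calling
#'
#' Under `"all_missing"` (the default) a variant is dropped only when every
#' genotype is missing; under `"any_missing"` one missing genotype suffices.
#'
#' @param gm a `genotype_matrix` (typically from [call_genotypes()]).
#' @param rule `"all_missing"` or `"any_missing"`.
#' @return The pruned `genotype_matrix`.
#' @export
prune_uncalled_variants <- function(gm, rule = c("all_missing",
                                                 "any_missing")) {
  rule <- match.arg(rule)
  n_missing <- colSums(is.na(gm$calls))
  drop <- if (rule == "all_missing") n_missing == nrow(gm$calls) else
    n_missing > 0L
  gm_subset(gm, variants = !drop)
}

#' Sweep the calling threshold against a truth set
#'
#' For each threshold, hard-calls the probabilistic data, prunes fully
#' uncalled variants, and evaluates allele concordance against the truth
#' matrix over their overlap — the trade-off between imputation accuracy and
#' the number of callable variants that motivates the 0.7 default.
#'
#' @param pgm a `prob_genotype_matrix`.
#' @param truth a `genotype_matrix` sharing samples and (chrom, pos) sites.
#' @param thresholds numeric vector of thresholds in \[0, 1\].
#' @return Data frame with one row per threshold: `threshold`,
#'   `n_called_variants`, `no_call_fraction`, `accuracy_pct` (pooled over
#'   all classified overlap variants; `NA` if none could be classified).
#' @export
sweep_threshold <- function(pgm, truth, thresholds) {
  if (any(!is.finite(thresholds) | thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  rows <- lapply(thresholds, function(t) {
    res <- call_genotypes(pgm, calling_config(threshold = t))
    called <- prune_uncalled_variants(res$gm, "all_missing")
    acc <- NA_real_
    if (nrow(called$variants) > 0L) {
      pair <- extract_overlap(called, truth)
      cls <- classify_overlap(pair)
      cls <- cls[!cls$excluded, , drop = FALSE]
      if (nrow(cls) > 0L) {
        acc <- 100 * mean(cls$match_class %in% c("COMPLETE", "FLIP"))
      }
    }
    data.frame(threshold = t,
               n_called_variants = nrow(called$variants),
               no_call_fraction = res$no_call_fraction,
               accuracy_pct = acc)
  })
  do.call(rbind, rows)
}
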