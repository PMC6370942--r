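## Variant-level allele concordance between an imputed dataset and an
## independent truth array. For each overlapping site the set of alleles
## actually observed in the called genotypes is compared between the two
## platforms: identical sets are a complete match; sets identical after
## base complementation are a flip (strand-swapped) match; one shared
## allele is a half match (typically a site imputed as monomorphic); no
## shared allele is a no-match. A no-match between two palindromic pairs
## (A/T vs G/C) is flagged ambiguous: on such sites a strand flip is
## indistinguishable from a genuine mismatch.

complement_alleles <- function(x) unname(ALLELE_COMPLEMENT[x])

#' Classify the allele-set match between imputed and truth
#'
#' Let S_i and S_t be the observed allele sets (size 1 or 2) and c() the
#' base-complement image. The class is `COMPLETE` when S_i = S_t, else
#' `FLIP` when c(S_i) = S_t, else `HALF` when the sets share exactly one
#' allele (direct orientation only — no complement retry), else `NONE`.
#' `ambiguous` is `TRUE` only for a `NONE` between two size-2 palindromic
#' pairs (\{A,T\} vs \{G,C\}). Identical palindromic pairs resolve to
#' `COMPLETE`: a flip is unobservable there. The classification is symmetric
#' in its two arguments.
#'
#' @param imputed_alleles,truth_alleles character vectors of 1 or 2 distinct
#'   single-base alleles.
#' @return A list with elements `match_class` (one of `"COMPLETE"`,
#'   `"FLIP"`, `"HALF"`, `"NONE"`) and `ambiguous` (logical).
#' @examples
#' classify_match(c("A", "G"), c("T", "C"))  # FLIP
#' classify_match(c("A", "T"), c("G", "C"))  # NONE, ambiguous
#' @export
classify_match <- function(imputed_alleles, truth_alleles) {
  si <- unique(as.character(imputed_alleles))
  st <- unique(as.character(truth_alleles))
  if (!length(si) %in% 1:2 || !length(st) %in% 1:2 ||
      !all(c(si, st) %in% names(ALLELE_COMPLEMENT))) {
    stop("allele sets must contain 1 or 2 alleles from {A, C, G, T}")
  }
  cls <- if (setequal(si, st)) "COMPLETE"
    else if (setequal(complement_alleles(si), st)) "FLIP"
    else if (length(intersect(si, st)) == 1L) "HALF"
    else "NONE"
  pal2 <- function(s) length(s) == 2L &&
    (setequal(s, c("A", "T")) || setequal(s, c("G", "C")))
  list(match_class = cls,
       ambiguous = cls == "NONE" && pal2(si) && pal2(st))
}

#' Alleles actually observed in a column of calls
#'
#' Returns the subset of the variant's allele pair with non-zero count over
#' the called genotypes: both alleles when the site is polymorphic in the
#' calls, a singleton when it is monomorphic (as with sites imputed
#' monomorphic, the dominant source of half matches).
#'
#' @param variant one-row variant table (alleles `a1`, `a2`).
#' @param calls integer vector of genotype codes (B-allele copies, `NA`
#'   missing).
#' @return Character vector of 1 or 2 alleles.
#' @export
observed_alleles <- function(variant, calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop("uninformative variant: all calls missing")
  n_b <- sum(calls)
  n_a <- 2L * length(calls) - n_b
  out <- c(variant$a1[if (n_a > 0L) 1L else integer(0)],
           variant$a2[if (n_b > 0L) 1L else integer(0)])
  out
}

#' Align two genotype matrices on shared samples and sites
#'
#' Restricts both matrices to their shared sample IDs and to variants
#' matched by (chrom, pos) — identifiers are ignored, since they differ
#' across arrays and panels — then removes any site listed in
#' `pre_imputation_variants` (sites genotyped on both platforms before
#' imputation, which would trivially agree and skew the accuracy). Ordering
#' follows the imputed input.
#'
#' @param imputed,truth `genotype_matrix` objects.
#' @param pre_imputation_variants optional data frame with columns `chrom`
#'   and `pos` of sites to exclude from both.
#' @return An object of class `overlap_pair`: list with aligned `imputed`
#'   and `truth` matrices and `overlap_by_chrom`, the per-chromosome site
#'   count.
#' @export
extract_overlap <- function(imputed, truth, pre_imputation_variants = NULL) {
  shared_s <- intersect(imputed$samples, truth$samples)
  if (length(shared_s) == 0L) stop("no shared samples between datasets")
  ki <- variant_key(imputed$variants)
  kt <- variant_key(truth$variants)
  shared_k <- ki[ki %in% kt]
  if (!is.null(pre_imputation_variants)) {
    excl <- paste(normalise_chrom(pre_imputation_variants$chrom),
                  pre_imputation_variants$pos, sep = ":")
    shared_k <- setdiff(shared_k, excl)
  }
  if (length(shared_k) == 0L) stop("no shared variants between datasets")
  gi <- gm_subset(imputed, samples = shared_s,
                  variants = match(shared_k, ki))
  gt <- gm_subset(truth, samples = shared_s,
                  variants = match(shared_k, kt))
  structure(list(imputed = gi, truth = gt,
                 overlap_by_chrom = table(gi$variants$chrom)),
            class = "overlap_pair")
}

#' Per-variant match classification over an aligned pair
#'
#' Computes the observed allele set on each side of every overlapping site
#' and classifies the match. Sites with all calls missing on either side
#' cannot be classified; they are flagged `excluded = TRUE` (with class
#' `NA`) and are reported separately by [summarize_concordance()].
#'
#' @param pair an `overlap_pair` from [extract_overlap()].
#' @return Data frame with one row per overlap site: `chrom`, `pos`, `id`,
#'   `match_class`, `ambiguous`, `excluded`.
#' @export
classify_overlap <- function(pair) {
  stopifnot(inherits(pair, "overlap_pair"))
  vi <- pair$imputed$variants
  vt <- pair$truth$variants
  ci <- pair$imputed$calls
  ct <- pair$truth$calls
  nv <- nrow(vi)

  obs_set <- function(calls_mat, vtab) {
    n_called <- colSums(!is.na(calls_mat))
    n_b <- colSums(calls_mat, na.rm = TRUE)
    n_a <- 2L * n_called - n_b
    list(has_a = n_a > 0L, has_b = n_b > 0L, none = n_called == 0L)
  }
  oi <- obs_set(ci, vi)
  ot <- obs_set(ct, vt)
  excluded <- oi$none | ot$none

  match_class <- rep(NA_character_, nv)
  ambiguous <- rep(NA, nv)
  for (j in which(!excluded)) {
    si <- c(vi$a1[j], vi$a2[j])[c(oi$has_a[j], oi$has_b[j])]
    st <- c(vt$a1[j], vt$a2[j])[c(ot$has_a[j], ot$has_b[j])]
    res <- classify_match(si, st)
    match_class[j] <- res$match_class
    ambiguous[j] <- res$ambiguous
  }
  data.frame(chrom = vi$chrom, pos = vi$pos, id = vi$id,
             match_class = match_class, ambiguous = ambiguous,
             excluded = excluded, stringsAsFactors = FALSE)
}

summarize_stratum <- function(cls, stratum) {
  inc <- cls[!cls$excluded, , drop = FALSE]
  n <- nrow(inc)
  cnt <- function(k) sum(inc$match_class == k)
  complete <- cnt("COMPLETE"); flip <- cnt("FLIP")
  half <- cnt("HALF"); none <- cnt("NONE")
  none_amb <- sum(inc$match_class == "NONE" & inc$ambiguous)
  acc <- if (n > 0L) 100 * (complete + flip) / n else NA_real_
  adj <- if (n > 0L) 100 * (complete + flip + none_amb) / n else NA_real_
  data.frame(stratum = stratum, n_overlap = n,
             n_excluded = sum(cls$excluded),
             complete = complete, flip = flip, half = half, none = none,
             none_ambiguous = none_amb,
             accuracy_pct = acc,
             error_pct = if (is.na(acc)) NA_real_ else 100 - acc,
             adjusted_accuracy_pct = adj,
             stringsAsFactors = FALSE)
}

#' Aggregate match classes into accuracy and error rates
#'
#' Counts the four match classes per chromosome and for the pooled
#' `"autosomes"` and `"X"` strata (the X row is always present, with `NA`
#' statistics when no X sites overlap). Flip matches count as correct:
#' accuracy_pct = 100 (COMPLETE + FLIP) / n_overlap, error_pct = 100 -
#' accuracy_pct (the genome-wide error rate when pooled), and
#' adjusted_accuracy_pct additionally counts ambiguous no-matches as
#' correct. Sites unclassifiable on either side are excluded from
#' `n_overlap` and reported in `n_excluded`.
#'
#' @param pair an `overlap_pair`, or a classification data frame from
#'   [classify_overlap()].
#' @return Data frame of class `concordance_summary`, one row per stratum.
#' @export
summarize_concordance <- function(pair) {
  cls <- if (inherits(pair, "overlap_pair")) classify_overlap(pair) else pair
  chroms <- intersect(VALID_CHROMS, unique(cls$chrom))
  rows <- lapply(chroms, function(ch) {
    summarize_stratum(cls[cls$chrom == ch, , drop = FALSE], ch)
  })
  auto <- cls$chrom != "X"
  rows <- c(rows,
            list(summarize_stratum(cls[auto, , drop = FALSE], "autosomes")))
  if (!"X" %in% chroms) {
    rows <- c(rows, list(summarize_stratum(cls[cls$chrom == "X", ,
                                               drop = FALSE], "X")))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_summary", class(out))
  out
}
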