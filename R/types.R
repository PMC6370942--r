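#' @keywords internal
"_PACKAGE"

VALID_CHROMS <- c(as.character(1:22), "X")

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Build and validate a variant table
#'
#' A variant table holds one row per biallelic site: chromosome (autosomes
#' `"1"`..`"22"` or `"X"`), 1-based position, identifier, and an unordered
#' allele pair `a1`/`a2` over the DNA alphabet. The second allele (`a2`) is
#' the B allele: genotype codes count copies of it.
#'
#' @param chrom character vector of chromosome labels in `"1"`..`"22"`, `"X"`.
#' @param pos integer vector of 1-based positions.
#' @param id character vector of variant identifiers.
#' @param a1,a2 character vectors of alleles (strings over A/C/G/T, length
#'   >= 1; length 1 for SNPs).
#' @return A `data.frame` with columns `chrom`, `pos`, `id`, `a1`, `a2`.
#' @examples
#' variant_table("1", 100, "rs1", "A", "G")
#' @export
variant_table <- function(chrom, pos, id, a1, a2) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    id = as.character(id), a1 = toupper(as.character(a1)),
    a2 = toupper(as.character(a2)), stringsAsFactors = FALSE
  )
  validate_variant_table(df)
  df
}

validate_variant_table <- function(vt) {
  stopifnot(is.data.frame(vt),
            all(c("chrom", "pos", "id", "a1", "a2") %in% names(vt)))
  bad_chrom <- !vt$chrom %in% VALID_CHROMS
  if (any(bad_chrom)) {
    stop("invalid chromosome label(s): ",
         paste(unique(vt$chrom[bad_chrom]), collapse = ", "))
  }
  if (any(is.na(vt$pos) | vt$pos < 1L)) stop("positions must be integers >= 1")
  ok_allele <- grepl("^[ACGT]+$", vt$a1) & grepl("^[ACGT]+$", vt$a2)
  if (!all(ok_allele)) {
    stop("invalid allele string at variant ",
         vt$id[which(!ok_allele)[1L]])
  }
  if (any(vt$a1 == vt$a2)) {
    stop("the two alleles of a variant must differ (variant ",
         vt$id[which(vt$a1 == vt$a2)[1L]], ")")
  }
  key <- paste(vt$chrom, vt$pos)
  if (anyDuplicated(key)) {
    stop("duplicated (chrom, pos): ", key[which(duplicated(key))[1L]])
  }
  invisible(vt)
}

#' SNP and palindromic-site predicates
#'
#' `is_snp()` is `TRUE` where both alleles are single bases; `is_palindromic()`
#' is `TRUE` where the allele set is \{A,T\} or \{G,C\}, i.e. where strand
#' orientation cannot be resolved from the alleles alone.
#'
#' @param vt a variant table (see [variant_table()]).
#' @return Logical vector, one element per variant.
#' @export
is_snp <- function(vt) nchar(vt$a1) == 1L & nchar(vt$a2) == 1L

#' @rdname is_snp
#' @export
is_palindromic <- function(vt) {
  p1 <- paste(pmin(vt$a1, vt$a2), pmax(vt$a1, vt$a2))
  is_snp(vt) & (p1 == "A T" | p1 == "C G")
}

variant_key <- function(vt) paste(vt$chrom, vt$pos, sep = ":")

#' Hard-call genotype matrix
#'
#' Container for samples x variants hard genotype calls coded 0/1/2 as the
#' number of copies of the B allele (`a2` in the variant table); `NA` encodes
#' a missing call ("N"). Sample order and variant order are preserved exactly
#' as supplied.
#'
#' @param calls integer matrix, samples in rows, variants in columns, values
#'   in \{0, 1, 2, NA\}.
#' @param variants variant table with one row per column of `calls`.
#' @param samples character vector of unique sample identifiers, one per row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `variants`, `calls`.
#' @export
genotype_matrix <- function(calls, variants, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  validate_variant_table(variants)
  if (nrow(calls) != length(samples)) {
    stop("calls has ", nrow(calls), " rows but ", length(samples), " samples")
  }
  if (ncol(calls) != nrow(variants)) {
    stop("calls has ", ncol(calls), " columns but ", nrow(variants),
         " variants")
  }
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  vals <- calls[!is.na(calls)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(samples, variants$id)
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a `genotype_matrix`.
#' @param samples character vector of sample IDs (order respected) or NULL.
#' @param variants integer/logical index into the variant table or NULL.
#' @return The subsetted `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else {
    idx <- match(samples, gm$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    idx
  }
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else variants
  genotype_matrix(gm$calls[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$samples[si])
}

#' Posterior-probability genotype matrix
#'
#' Container for imputed data: per sample x variant a posterior probability
#' triple (p0, p1, p2) over the three genotypes of a biallelic site, plus a
#' per-variant quality score in \[0, 1\] (the INFO score or r-squared emitted
#' by the imputation engine; `NA` when the source carried none). Probability
#' triples must be non-negative and sum to 1 within 1e-3; an all-zero triple
#' is the no-call sentinel used by GEN files and is accepted as-is.
#'
#' @param probs numeric array of dimension samples x variants x 3.
#' @param variants variant table.
#' @param samples character vector of unique sample IDs.
#' @param quality numeric vector of per-variant scores in \[0,1\] or `NA`.
#' @return An object of class `prob_genotype_matrix`.
#' @export
prob_genotype_matrix <- function(probs, variants, samples, quality = NULL) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L, dim(probs)[3L] == 3L)
  samples <- as.character(samples)
  validate_variant_table(variants)
  if (dim(probs)[1L] != length(samples) || dim(probs)[2L] != nrow(variants)) {
    stop("probs dimensions do not match samples/variants")
  }
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  if (anyNA(probs) || min(probs) < 0) {
    stop("genotype probabilities must be non-negative and non-missing")
  }
  sums <- probs[, , 1L, drop = FALSE] + probs[, , 2L, drop = FALSE] +
    probs[, , 3L, drop = FALSE]
  ok <- abs(sums - 1) <= 1e-3 | sums == 0  # all-zero triple = no-call sentinel
  if (!all(ok)) {
    stop("genotype probability triples must sum to 1 (+/- 1e-3) or be ",
         "all-zero no-calls")
  }
  if (is.null(quality)) quality <- rep(NA_real_, nrow(variants))
  quality <- as.numeric(quality)
  if (length(quality) != nrow(variants)) {
    stop("quality must have one value per variant")
  }
  qv <- quality[!is.na(quality)]
  if (length(qv) && (min(qv) < 0 || max(qv) > 1)) {
    stop("quality scores must lie in [0, 1]")
  }
  structure(list(samples = samples, variants = variants, probs = probs,
                 quality = quality),
            class = "prob_genotype_matrix")
}

#' @export
print.prob_genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "prob_genotype_matrix: %d samples x %d variants (quality defined for %d)\n",
    length(x$samples), nrow(x$variants), sum(!is.na(x$quality))))
  invisible(x)
}

#' @export
dim.prob_genotype_matrix <- function(x) dim(x$probs)[1:2]

#' Subset a probabilistic genotype matrix by variants
#'
#' @param pgm a `prob_genotype_matrix`.
#' @param variants integer/logical index into the variant table.
#' @return The subsetted `prob_genotype_matrix`.
#' @export
pgm_subset_variants <- function(pgm, variants) {
  prob_genotype_matrix(pgm$probs[, variants, , drop = FALSE],
                       pgm$variants[variants, , drop = FALSE],
                       pgm$samples, pgm$quality[variants])
}

#' Quality-control thresholds
#'
#' Thresholds for the iterative array QC: per-sample missingness cap, per-
#' variant missingness cap, minimum minor allele frequency, the multiplier on
#' the standard deviation of the per-sample inbreeding statistic F used to
#' flag excessive heterozygosity, and the X-chromosome F cut-offs used to
#' infer sex (female below `sex_f_female_max`, male above `sex_f_male_min`,
#' undetermined in between).
#'
#' @param sample_missing_max samples missing more than this fraction of
#'   genotypes are removed (default 0.10).
#' @param variant_missing_max variants with more than this missing fraction
#'   are removed (default 0.02).
#' @param maf_min variants with minor allele frequency below this are removed
#'   (default 0.05).
#' @param het_sd_multiplier samples with |F - mean(F)| beyond this many
#'   standard deviations are removed (default 3).
#' @param sex_f_female_max,sex_f_male_min X-chromosome F bands for sex
#'   inference (defaults 0.2 and 0.8).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_missing_max = 0.10,
                          variant_missing_max = 0.02,
                          maf_min = 0.05,
                          het_sd_multiplier = 3.0,
                          sex_f_female_max = 0.2,
                          sex_f_male_min = 0.8) {
  thr <- list(sample_missing_max = sample_missing_max,
              variant_missing_max = variant_missing_max,
              maf_min = maf_min,
              het_sd_multiplier = het_sd_multiplier,
              sex_f_female_max = sex_f_female_max,
              sex_f_male_min = sex_f_male_min)
  fracs <- thr[c("sample_missing_max", "variant_missing_max", "maf_min",
                 "sex_f_female_max", "sex_f_male_min")]
  if (any(vapply(fracs, function(x) !is.numeric(x) || x < 0 || x > 1,
                 logical(1)))) {
    stop("QC threshold fractions must lie in [0, 1]")
  }
  if (!is.numeric(het_sd_multiplier) || het_sd_multiplier <= 0) {
    stop("het_sd_multiplier must be positive")
  }
  structure(thr, class = "qc_thresholds")
}

#' Genotype-calling configuration
#'
#' @param threshold minimum posterior probability for a hard call (default
#'   0.7); the comparison is inclusive (`max(p) >= threshold` calls) and a
#'   tied maximum is never called.
#' @param drop_indels drop non-SNP variants before calling (default TRUE).
#' @param uncalled_variant_rule drop variants in which every genotype is
#'   missing (`"all_missing"`, the default) or any genotype is missing
#'   (`"any_missing"`).
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(threshold = 0.7, drop_indels = TRUE,
                           uncalled_variant_rule = c("all_missing",
                                                     "any_missing")) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("calling threshold must lie in [0, 1]")
  }
  structure(list(threshold = threshold,
                 drop_indels = isTRUE(drop_indels),
                 uncalled_variant_rule = match.arg(uncalled_variant_rule)),
            class = "calling_config")
}

#' Minor-allele-frequency binning scheme
#'
#' Half-open bins `(lo, hi]` over the MAF range, with the first bin closed at
#' 0 so a MAF of exactly 0 is kept.
#'
#' @param edges strictly increasing numeric vector starting at 0 and ending
#'   at 0.5.
#' @return An object of class `maf_binning`.
#' @export
maf_binning <- function(edges = c(0, 0.01, 0.05, 0.10, 0.20, 0.30,
                                  0.40, 0.50)) {
  if (any(diff(edges) <= 0)) stop("MAF bin edges must be strictly increasing")
  if (edges[1L] != 0 || edges[length(edges)] != 0.5) {
    stop("MAF bin edges must start at 0 and end at 0.5")
  }
  structure(list(edges = edges), class = "maf_binning")
}
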