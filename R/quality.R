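## MAF-stratified and match-class-stratified summaries of per-variant
## imputation quality scores (INFO / r-squared). Scores are summarised
## within one dataset only: INFO and r-squared are correlated but not
## numerically comparable across imputation engines.

maf_bin_labels <- function(edges) {
  paste0("(", utils::head(edges, -1L), ",", utils::tail(edges, -1L), "]")
}

#' Quality score summarised per MAF bin
#'
#' Bins variants by minor allele frequency into half-open `(lo, hi]` bins
#' (first bin closed at 0) and reports the median and/or mean quality per
#' bin. Variants with undefined MAF are dropped; the per-bin counts sum to
#' the number of variants with a defined MAF.
#'
#' @param quality numeric vector of per-variant scores in \[0, 1\] (`NA`
#'   allowed for variants whose source carried no score).
#' @param maf numeric vector of per-variant MAF aligned with `quality`.
#' @param bins a [maf_binning()] scheme.
#' @param stat `"median"`, `"mean"`, or `"both"`.
#' @return Data frame with columns `bin`, `maf_lo`, `maf_hi`, `n`, and
#'   `median` and/or `mean` (`NA` for empty bins).
#' @export
quality_by_maf <- function(quality, maf, bins = maf_binning(),
                           stat = c("median", "mean", "both")) {
  stat <- match.arg(stat)
  stopifnot(length(quality) == length(maf))
  qv <- quality[!is.na(quality)]
  if (length(qv) && (min(qv) < 0 || max(qv) > 1)) {
    stop("quality scores must lie in [0, 1]")
  }
  edges <- bins$edges
  keep <- !is.na(maf)
  idx <- cut(maf[keep], breaks = edges, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  q <- quality[keep]
  nb <- length(edges) - 1L
  out <- data.frame(bin = maf_bin_labels(edges),
                    maf_lo = utils::head(edges, -1L),
                    maf_hi = utils::tail(edges, -1L),
                    n = tabulate(idx, nbins = nb))
  per_bin <- function(fn) vapply(seq_len(nb), function(b) {
    x <- q[!is.na(idx) & idx == b]
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else fn(x)
  }, numeric(1))
  if (stat %in% c("median", "both")) out$median <- per_bin(stats::median)
  if (stat %in% c("mean", "both")) out$mean <- per_bin(mean)
  out
}

#' Histogram of variants by quality score
#'
#' Counts variants in half-open quality bins `(lo, hi]` of the given width
#' (first bin closed at 0, so a score of exactly 0 lands in the first bin
#' and 1.0 in the top bin), optionally per chromosome stratum. Counts
#' conserve the total number of scored variants.
#'
#' @param quality numeric vector of scores in \[0, 1\] (`NA` dropped).
#' @param bin_width bin width (default 0.05; must divide 1 evenly).
#' @param chrom optional character vector of chromosome labels aligned with
#'   `quality`; when given, one histogram per chromosome is returned in a
#'   long data frame with a `stratum` column.
#' @return Data frame with columns (`stratum`,) `bin_lo`, `bin_hi`, `n`.
#' @export
quality_histogram <- function(quality, bin_width = 0.05, chrom = NULL) {
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9) stop("bin_width must divide 1 evenly")
  edges <- seq(0, 1, length.out = nb + 1L)
  one <- function(q) {
    q <- q[!is.na(q)]
    if (length(q) && (min(q) < 0 || max(q) > 1)) {
      stop("quality scores must lie in [0, 1]")
    }
    idx <- cut(q, breaks = edges, include.lowest = TRUE, right = TRUE,
               labels = FALSE)
    data.frame(bin_lo = utils::head(edges, -1L),
               bin_hi = utils::tail(edges, -1L),
               n = tabulate(idx, nbins = nb))
  }
  if (is.null(chrom)) return(one(quality))
  stopifnot(length(chrom) == length(quality))
  strata <- intersect(VALID_CHROMS, unique(chrom))
  do.call(rbind, lapply(strata, function(ch) {
    cbind(stratum = ch, one(quality[chrom == ch]))
  }))
}

#' Quality score per match class
#'
#' Reports, per stratum (autosomes and X), the number of sites and median
#' quality for all overlap sites (`total`) and for the `HALF` and `NONE`
#' match classes — the problem classes whose quality profile indicates
#' whether a quality-score filter would remove them.
#'
#' @param classification data frame from [classify_overlap()] (columns
#'   `chrom`, `match_class`, `excluded`).
#' @param quality numeric vector of per-variant scores aligned with the
#'   classification rows.
#' @return Data frame with columns `stratum`, `class`, `n`,
#'   `median_quality`.
#' @export
quality_by_match_class <- function(classification, quality) {
  stopifnot(nrow(classification) == length(quality))
  inc <- !classification$excluded
  strata <- list(autosomes = inc & classification$chrom != "X",
                 X = inc & classification$chrom == "X")
  rows <- lapply(names(strata), function(s) {
    in_s <- strata[[s]]
    sub <- function(sel, lab) {
      q <- quality[sel]
      q <- q[!is.na(q)]
      data.frame(stratum = s, class = lab, n = sum(sel),
                 median_quality = if (length(q)) stats::median(q) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    }
    rbind(sub(in_s, "total"),
          sub(in_s & classification$match_class == "HALF", "HALF"),
          sub(in_s & classification$match_class == "NONE", "NONE"))
  })
  do.call(rbind, rows)
}
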