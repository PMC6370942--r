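## Shared fixture builders and independent oracles. All fixtures are built
## in code; nothing is read from disk except files the tests write first.

# small genotype matrix; calls given variant-major as a list of columns
make_gm <- function(calls_by_variant, chrom = NULL, pos = NULL,
                    a1 = NULL, a2 = NULL, samples = NULL) {
  nv <- length(calls_by_variant)
  ns <- length(calls_by_variant[[1L]])
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = nv)
  if (is.null(a1)) a1 <- rep("A", nv)
  if (is.null(a2)) a2 <- rep("G", nv)
  if (is.null(samples)) samples <- paste0("s", seq_len(ns))
  calls <- do.call(cbind, calls_by_variant)
  genotype_matrix(calls, variant_table(chrom, pos, paste0("v", seq_len(nv)),
                                       a1, a2), samples)
}

# small probabilistic matrix from a list (per variant) of per-sample triples
make_pgm <- function(triples_by_variant, quality = NULL, ...) {
  nv <- length(triples_by_variant)
  ns <- nrow(triples_by_variant[[1L]])
  probs <- array(0, dim = c(ns, nv, 3L))
  for (j in seq_len(nv)) probs[, j, ] <- triples_by_variant[[j]]
  gm <- make_gm(rep(list(rep(0L, ns)), nv), ...)
  prob_genotype_matrix(probs, gm$variants, gm$samples, quality)
}

# every valid observed allele set: 4 singletons + 6 unordered pairs
all_allele_sets <- function() {
  bases <- c("A", "C", "G", "T")
  sets <- as.list(bases)
  for (i in 1:3) for (j in (i + 1):4) {
    sets[[length(sets) + 1L]] <- c(bases[i], bases[j])
  }
  sets
}

# independent brute-force oracle for the match taxonomy, written against the
# definitions directly (sorted string codes, no shared code with the package)
oracle_classify <- function(set_i, set_t) {
  comp <- function(s) c(A = "T", C = "G", G = "C", T = "A")[s]
  code <- function(s) paste(sort(unique(s)), collapse = "")
  ci <- code(set_i); ct <- code(set_t)
  cls <- if (ci == ct) {
    "COMPLETE"
  } else if (code(comp(set_i)) == ct) {
    "FLIP"
  } else {
    n_shared <- sum(strsplit(ci, "")[[1]] %in% strsplit(ct, "")[[1]])
    if (n_shared == 1) "HALF" else "NONE"
  }
  is_pal_pair <- function(cd) cd %in% c("AT", "CG")
  list(match_class = cls,
       ambiguous = cls == "NONE" && is_pal_pair(ci) && is_pal_pair(ct))
}

# independent fixed-point QC oracle: re-applies the four filters in a loop
# until nothing changes, recomputing statistics from scratch each time
oracle_iterative_qc <- function(calls, thr) {
  repeat {
    changed <- FALSE
    smiss <- rowMeans(is.na(calls))
    if (any(smiss > thr$sample_missing_max)) {
      calls <- calls[smiss <= thr$sample_missing_max, , drop = FALSE]
      changed <- TRUE
    }
    vmiss <- colMeans(is.na(calls))
    if (any(vmiss > thr$variant_missing_max)) {
      calls <- calls[, vmiss <= thr$variant_missing_max, drop = FALSE]
      changed <- TRUE
    }
    fb <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
    maf <- pmin(fb, 1 - fb)
    if (any(is.na(maf) | maf < thr$maf_min)) {
      calls <- calls[, !is.na(maf) & maf >= thr$maf_min, drop = FALSE]
      changed <- TRUE
    }
    fb <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
    eh <- 2 * fb * (1 - fb)
    e <- (!is.na(calls)) %*% ifelse(is.na(eh), 0, eh)
    f <- 1 - rowSums(calls == 1L, na.rm = TRUE) / as.vector(e)
    mu <- mean(f, na.rm = TRUE); sdv <- sd(f, na.rm = TRUE)
    if (is.finite(sdv) && sdv > 0) {
      out <- !is.na(f) & abs(f - mu) > thr$het_sd_multiplier * sdv
      if (any(out)) {
        calls <- calls[!out, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) return(calls)
  }
}
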