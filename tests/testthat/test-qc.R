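thr <- qc_thresholds()

test_that("missingness and MAF filters use strict boundary comparisons", {
  # 25 variants; sample s1 misses 3/25 = 12% (> 10%, removed),
  # sample s2 misses exactly 10% when thresholds allow (retained)
  set.seed(3)
  nv <- 25L; ns <- 10L
  calls <- matrix(sample(0:2, ns * nv, replace = TRUE,
                         prob = c(0.36, 0.48, 0.16)), ns, nv)
  calls[1, 1:3] <- NA
  gm <- make_gm(lapply(seq_len(nv), function(j) calls[, j]),
                pos = seq_len(nv) * 10L)
  res <- qc_pass(gm, thr)
  expect_equal(res$removals$id[res$removals$rule == "sample_missingness"],
               "s1")

  gm10 <- make_gm(lapply(1:10, function(j) {
    v <- sample(0:2, 10, replace = TRUE, prob = c(0.36, 0.48, 0.16))
    if (j == 1) v[1] <- NA  # s1 misses exactly 1/10 = 0.10
    v
  }))
  res10 <- qc_pass(gm10, qc_thresholds(variant_missing_max = 0.2))
  expect_false("s1" %in% res10$removals$id)
})

test_that("low-MAF variants are removed under rule maf", {
  # variant 1: 2 B alleles / 50 = MAF 0.04 < 0.05; variant 2: MAF 0.2
  v1 <- c(rep(0L, 23), 1L, 1L)
  v2 <- c(rep(0L, 15), rep(1L, 10))
  gm <- make_gm(list(v1, v2))
  res <- qc_pass(gm, qc_thresholds(variant_missing_max = 1))
  expect_equal(res$removals$id[res$removals$rule == "maf"], "v1")
  expect_equal(res$gm$variants$id, "v2")
})

test_that("iterative QC reaches a fixed point and is idempotent", {
  set.seed(9)
  nv <- 40L; ns <- 30L
  calls <- matrix(sample(0:2, ns * nv, replace = TRUE,
                         prob = c(0.4, 0.45, 0.15)), ns, nv)
  gm <- make_gm(lapply(seq_len(nv), function(j) calls[, j]),
                pos = seq_len(nv) * 10L)
  res <- run_iterative_qc(gm, thr)
  # post conditions hold directly
  expect_true(all(rowMeans(is.na(res$gm$calls)) <= thr$sample_missing_max))
  expect_true(all(colMeans(is.na(res$gm$calls)) <= thr$variant_missing_max))
  expect_true(all(compute_maf(res$gm) >= thr$maf_min))
  # final iteration removes nothing; rerunning removes nothing more
  expect_equal(nrow(res$report$iterations[[res$report$n_iterations]]), 0L)
  res2 <- run_iterative_qc(res$gm, thr)
  expect_equal(res2$report$n_iterations, 1L)
  expect_equal(res2$gm$calls, res$gm$calls)
  # removal ledger plus survivors reconstitutes the input exactly
  rem <- qc_removals(res$report)
  expect_setequal(c(res$gm$samples, rem$id[rem$type == "sample"]),
                  gm$samples)
  expect_setequal(c(res$gm$variants$id, rem$id[rem$type == "variant"]),
                  gm$variants$id)
  expect_lte(res$report$n_iterations, ns + nv)
})

test_that("a planted cascade resolves across iterations as the oracle says", {
  # 60 samples x 50 variants. Pass 1 removes v1..v10 for low MAF. Sample
  # s1 misses exactly 5/50 = 10% of genotypes (retained, strict ">"), but
  # once the ten low-MAF variants are gone it misses 5/40 = 12.5% and is
  # removed in iteration 2. Variant v50's MAF clears 5% only through s1's
  # homozygous-B genotype (7/120 = 5.8%); with s1 gone it falls to 5/118
  # = 4.2% and cascades out under rule maf, also in iteration 2.
  set.seed(21)
  ns <- 60L; nv <- 50L
  calls <- matrix(sample(0:2, ns * nv, replace = TRUE,
                         prob = c(0.35, 0.48, 0.17)), ns, nv)
  for (j in 1:10) {                            # MAF 1/120, het spread so no
    calls[, j] <- 0L                           # single sample turns F-outlier
    calls[30L + j, j] <- 1L
  }
  calls[1, 11:15] <- NA                        # s1: 5/50 = 10% missing
  calls[, 50] <- 0L
  calls[1, 50] <- 2L
  calls[21:25, 50] <- 1L
  gm <- make_gm(lapply(seq_len(nv), function(j) calls[, j]),
                pos = seq_len(nv) * 10L)
  res <- run_iterative_qc(gm, thr)
  rem <- qc_removals(res$report)
  expect_true(all(rem$iteration[rem$id %in% paste0("v", 1:10)] == 1L))
  expect_equal(rem$iteration[rem$id == "s1"], 2L)
  expect_equal(rem$rule[rem$id == "s1"], "sample_missingness")
  expect_equal(rem$iteration[rem$id == "v50"], 2L)
  expect_equal(rem$rule[rem$id == "v50"], "maf")
  # exhaustive-filtering oracle agrees on the surviving matrix
  oracle <- oracle_iterative_qc(gm$calls, thr)
  expect_equal(unname(res$gm$calls), unname(oracle))
})

test_that("QC errors on an emptied cohort and bad thresholds", {
  gm <- make_gm(list(c(NA, NA), c(NA, NA), c(0L, 1L)))
  expect_error(qc_pass(gm, qc_thresholds(sample_missing_max = 0.5)),
               "empty cohort")
  expect_error(qc_thresholds(sample_missing_max = -0.1), "\\[0, 1\\]")
})

test_that("sex inference from X heterozygosity flags contradictions only", {
  # 40 X variants, B-allele frequency ~0.5; het-rich samples infer female,
  # all-homozygous samples infer male
  set.seed(5)
  nv <- 40L
  female_like <- function() sample(c(0L, 1L, 1L, 2L), nv, replace = TRUE)
  male_like <- function() sample(c(0L, 2L), nv, replace = TRUE)
  calls <- rbind(female_like(), female_like(), male_like(), male_like())
  gm <- make_gm(lapply(seq_len(nv), function(j) calls[, j]),
                chrom = rep("X", nv), pos = seq_len(nv) * 10L,
                samples = c("f_ok", "f_bad", "m_ok", "m_bad"))
  reported <- c(f_ok = "female", f_bad = "male",  # contradicts het-rich X
                m_ok = "male", m_bad = "female")  # contradicts all-hom X
  disc <- sex_concordance_check(gm, reported)
  expect_setequal(disc$sample, c("f_bad", "m_bad"))
  expect_equal(disc$inferred[disc$sample == "f_bad"], "female")

  # unknown reported sex is never discordant
  reported2 <- c(f_ok = "female", f_bad = "unknown", m_ok = "male",
                 m_bad = "unknown")
  expect_equal(nrow(sex_concordance_check(gm, reported2)), 0L)

  # an F in the undetermined band abstains
  half_het <- matrix(rep(c(1L, 0L, 2L, 0L), each = 10), nrow = 1)
  gm_mid <- make_gm(lapply(seq_len(nv), function(j) {
    c(calls[, j], half_het[1, j])
  }), chrom = rep("X", nv), pos = seq_len(nv) * 10L,
    samples = c(rownames(calls, do.NULL = FALSE), "mid")[1:5])
  f_mid <- sample_het_f(gm_subset(gm_mid, samples = NULL))["mid"]
  if (f_mid > 0.2 && f_mid < 0.8) {
    disc_mid <- sex_concordance_check(gm_mid, c(mid = "male"))
    expect_false("mid" %in% disc_mid$sample)
  }

  # no X variants at all is an error
  gm_auto <- make_gm(list(c(0L, 1L)))
  expect_error(sex_concordance_check(gm_auto, reported), "no X data")
})
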