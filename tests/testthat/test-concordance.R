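test_that("match classification agrees with the brute-force oracle and is symmetric", {
  sets <- all_allele_sets()
  for (si in sets) for (st in sets) {
    got <- classify_match(si, st)
    want <- oracle_classify(si, st)
    expect_equal(got$match_class, want$match_class,
                 info = paste(paste(si, collapse = "/"), "vs",
                              paste(st, collapse = "/")))
    expect_equal(got$ambiguous, want$ambiguous,
                 info = paste(paste(si, collapse = "/"), "vs",
                              paste(st, collapse = "/")))
    # symmetry under swapping imputed and truth
    rev <- classify_match(st, si)
    expect_equal(rev$match_class, got$match_class)
    expect_equal(rev$ambiguous, got$ambiguous)
    # the ambiguity flag only ever decorates a no-match
    expect_true(!got$ambiguous || got$match_class == "NONE")
  }
})

test_that("taxonomy spot checks: identity, complement, shared allele, ambiguity", {
  expect_equal(classify_match(c("A", "G"), c("A", "G"))$match_class,
               "COMPLETE")
  expect_equal(classify_match(c("A", "G"), c("T", "C"))$match_class, "FLIP")
  expect_equal(classify_match(c("A", "G"), c("A", "C"))$match_class, "HALF")
  amb <- classify_match(c("A", "T"), c("G", "C"))
  expect_equal(amb$match_class, "NONE")
  expect_true(amb$ambiguous)
  # monomorphic imputation: one observed allele against the truth pair
  expect_equal(classify_match("A", c("A", "G"))$match_class, "HALF")
  # palindromic identity resolves COMPLETE (a flip is unobservable there)
  pal <- classify_match(c("A", "T"), c("A", "T"))
  expect_equal(pal$match_class, "COMPLETE")
  expect_false(pal$ambiguous)
  expect_error(classify_match(c("A", "N"), c("A", "G")), "A, C, G, T")
})

test_that("observed alleles reflect the calls actually made", {
  v <- variant_table("1", 100, "rs1", "A", "G")
  expect_setequal(observed_alleles(v, c(0L, 1L, 2L)), c("A", "G"))
  expect_equal(observed_alleles(v, c(0L, 0L, 0L)), "A")
  expect_equal(observed_alleles(v, c(2L, 2L)), "G")
  expect_equal(observed_alleles(v, c(NA, 2L, NA)), "G")
  expect_error(observed_alleles(v, c(NA, NA)), "uninformative")
})

test_that("overlap extraction intersects by position and honours exclusions", {
  imp <- make_gm(list(c(0L, 1L), c(1L, 1L), c(2L, 0L)),
                 pos = c(100L, 200L, 300L))
  tru <- make_gm(list(c(0L, 1L), c(1L, 2L), c(0L, 0L)),
                 pos = c(200L, 300L, 400L))
  pair <- extract_overlap(imp, tru)
  expect_equal(pair$imputed$variants$pos, c(200L, 300L))
  expect_equal(pair$truth$variants$pos, c(200L, 300L))
  excl <- data.frame(chrom = "1", pos = 200L)
  pair2 <- extract_overlap(imp, tru, excl)
  expect_equal(pair2$imputed$variants$pos, 300L)

  tru_other <- make_gm(list(c(0L, 1L)), pos = 200L,
                       samples = c("x1", "x2"))
  expect_error(extract_overlap(imp, tru_other), "shared samples")
  tru_far <- make_gm(list(c(0L, 1L)), pos = 999L)
  expect_error(extract_overlap(imp, tru_far), "shared variants")
})

test_that("accuracy, error and adjusted accuracy aggregate as stated", {
  # counts {COMPLETE 850, FLIP 43, HALF 65, NONE 42}: accuracy 89.3
  cls1 <- data.frame(
    chrom = "1", pos = seq_len(1000), id = paste0("v", 1:1000),
    match_class = rep(c("COMPLETE", "FLIP", "HALF", "NONE"),
                      c(850, 43, 65, 42)),
    ambiguous = FALSE, excluded = FALSE)
  s1 <- summarize_concordance(cls1)
  a1 <- s1[s1$stratum == "autosomes", ]
  expect_equal(a1$accuracy_pct, 89.3)
  expect_equal(a1$error_pct, 10.7)
  expect_equal(a1$accuracy_pct + a1$error_pct, 100)

  # ambiguous no-matches promoted: {850, 43, 20, 87 of which 70 ambiguous}
  cls2 <- data.frame(
    chrom = "1", pos = seq_len(1000), id = paste0("v", 1:1000),
    match_class = rep(c("COMPLETE", "FLIP", "HALF", "NONE", "NONE"),
                      c(850, 43, 20, 70, 17)),
    ambiguous = rep(c(FALSE, TRUE, FALSE), c(913, 70, 17)),
    excluded = FALSE)
  a2 <- summarize_concordance(cls2)
  a2 <- a2[a2$stratum == "autosomes", ]
  expect_equal(a2$accuracy_pct, 89.3)
  expect_equal(a2$adjusted_accuracy_pct, 96.3)
  expect_gte(a2$adjusted_accuracy_pct, a2$accuracy_pct)

  # an absent X stratum is reported with zero overlap and NA statistics
  x_row <- s1[s1$stratum == "X", ]
  expect_equal(x_row$n_overlap, 0L)
  expect_true(is.na(x_row$accuracy_pct))
})

test_that("all-complete overlap yields 100% accuracy at both levels", {
  imp <- make_gm(list(c(0L, 1L, 2L), c(1L, 1L, 0L)), pos = c(10L, 20L))
  s <- summarize_concordance(extract_overlap(imp, imp))
  a <- s[s$stratum == "autosomes", ]
  expect_equal(a$accuracy_pct, 100)
  expect_equal(a$adjusted_accuracy_pct, 100)
})

test_that("sites unclassifiable on one side are excluded, not guessed", {
  imp <- make_gm(list(c(NA, NA, NA), c(1L, 1L, 0L)), pos = c(10L, 20L))
  tru <- make_gm(list(c(0L, 1L, 2L), c(1L, 1L, 0L)), pos = c(10L, 20L))
  cls <- classify_overlap(extract_overlap(imp, tru))
  expect_equal(cls$excluded, c(TRUE, FALSE))
  s <- summarize_concordance(cls)
  a <- s[s$stratum == "autosomes", ]
  expect_equal(a$n_overlap, 1L)
  expect_equal(a$n_excluded, 1L)
  # partition: classified counts + excluded reconstitute the overlap
  expect_equal(a$complete + a$flip + a$half + a$none + a$n_excluded, 2L)
})

test_that("injected corruption rates are recovered from the classification", {
  set.seed(29)
  cfg <- simulation_config(n_samples = 80, n_variants = 4000,
                           error_rate = 0.08, flip_rate = 0.06,
                           mono_rate = 0.03, seed = 29)
  truth <- simulate_cohort(cfg)
  pgm <- corrupt_as_imputed(truth, cfg)
  labels <- attr(pgm, "labels")
  called <- call_genotypes(pgm, calling_config(threshold = 0))
  cls <- classify_overlap(extract_overlap(called$gm, truth))
  merged <- merge(cls, labels, by = c("chrom", "pos"))
  # exact recovery: every corruption channel lands in its designated class
  expect_true(all(merged$match_class[merged$label == "clean"] == "COMPLETE"))
  expect_true(all(merged$match_class[merged$label == "flip"] == "FLIP"))
  expect_true(all(merged$match_class[merged$label == "error"] == "NONE"))
  expect_true(all(merged$match_class[merged$label == "mono"] == "HALF"))
  # and the measured proportions sit within 3 binomial SE of the rates
  n <- nrow(merged)
  for (pair in list(c("FLIP", cfg$flip_rate), c("HALF", cfg$mono_rate),
                    c("NONE", cfg$error_rate))) {
    p <- as.numeric(pair[2])
    obs <- mean(merged$match_class == pair[1])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
})
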