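## Synthetic admixed-cohort generator. Truth genotypes follow the
## Balding-Nichols model with Dirichlet individual admixture: per variant an
## ancestral frequency p ~ Uniform(p_range); per population k a drifted
## frequency p_k ~ Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k); per individual
## admixture proportions q ~ Dirichlet(alpha) and genotype ~ Binomial(2,
## sum_k q_k p_k) (hemizygous males on X draw one allele, coded 0/2).
## Pseudo-imputed data is the truth with per-variant corruption channels of
## known rates — discordant alleles, strand flips, monomorphic collapse —
## plus a posterior-mass model that produces controllable no-call rates and
## a quality score rising with MAF. No linkage disequilibrium is simulated:
## the evaluation statistics under test are LD-free.

#' Named admixture preset: five-way admixed cohort
#'
#' Dirichlet concentration vector for a five-way admixed cohort with a
#' dominant first (KhoeSan-like) component, in the style of the South
#' African Colored population (KhoeSan, Bantu-speaking African, European,
#' South Asian, East Asian). Cosmetic realism only: the evaluation
#' statistics do not depend on the admixture skew.
#'
#' @export
alpha_five_way_admixed <- c(khoesan = 3.2, bantu = 2.4, european = 1.8,
                            south_asian = 1.0, east_asian = 0.6)

#' Simulation configuration
#'
#' All generative parameters of the synthetic cohort and of the
#' pseudo-imputation corruption channels.
#'
#' @param n_samples,n_variants cohort dimensions.
#' @param frac_x fraction of variants placed on chromosome X (default 0.05).
#' @param K number of ancestral populations (default 5).
#' @param fst per-population differentiation F_ST in (0, 1); scalar recycled
#'   to length K (default 0.1).
#' @param alpha Dirichlet concentration vector of length K for individual
#'   admixture proportions (default [alpha_five_way_admixed]).
#' @param p_range ancestral allele-frequency bounds (default c(0.05, 0.95)).
#' @param frac_palindromic fraction of variants given a palindromic (A/T or
#'   G/C) allele pair (default 0.15, in the range typical of array content
#'   after harmonisation).
#' @param error_rate fraction of variants whose imputed alleles are made
#'   discordant with truth (no shared allele).
#' @param flip_rate fraction of variants strand-complemented (placed on
#'   non-palindromic variants, where a flip is observable).
#' @param mono_rate fraction of variants collapsed to monomorphic for the
#'   major truth allele (placed on truth-polymorphic variants).
#' @param gp_max_range bounds of the Uniform law of the winning posterior
#'   probability (default c(0.5, 1.0)).
#' @param quality_maf_slope slope of the logistic MAF-quality relation
#'   (default 8: quality ~ 0.5 at MAF 0, ~ 0.98 at MAF 0.5 before noise).
#' @param seed integer RNG seed, or `NULL` to continue the current stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples, n_variants, frac_x = 0.05, K = 5L,
                              fst = 0.1, alpha = alpha_five_way_admixed,
                              p_range = c(0.05, 0.95),
                              frac_palindromic = 0.15,
                              error_rate = 0, flip_rate = 0, mono_rate = 0,
                              gp_max_range = c(0.5, 1.0),
                              quality_maf_slope = 8, seed = NULL) {
  fst <- rep_len(fst, K)
  if (length(alpha) != K) stop("alpha must have length K")
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              frac_x = frac_x, K = as.integer(K), fst = fst,
              alpha = unname(alpha), p_range = p_range,
              frac_palindromic = frac_palindromic,
              error_rate = error_rate, flip_rate = flip_rate,
              mono_rate = mono_rate, gp_max_range = gp_max_range,
              quality_maf_slope = quality_maf_slope, seed = seed)
  rates <- c(error_rate, flip_rate, mono_rate, frac_x, frac_palindromic)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (error_rate + flip_rate + mono_rate > 1) {
    stop("error_rate + flip_rate + mono_rate must not exceed 1")
  }
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (any(cfg$alpha <= 0)) stop("alpha must be strictly positive")
  if (cfg$n_samples < 1L || cfg$n_variants < 1L) {
    stop("n_samples and n_variants must be positive")
  }
  if (p_range[1L] >= p_range[2L] || p_range[1L] < 0 || p_range[2L] > 1 ||
      gp_max_range[1L] >= gp_max_range[2L] || gp_max_range[1L] < 0 ||
      gp_max_range[2L] > 1) {
    stop("p_range and gp_max_range must be increasing sub-intervals of [0,1]")
  }
  structure(cfg, class = "simulation_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
PAL_PAIRS <- list(c("A", "T"), c("C", "G"))

#' Simulate an admixed truth cohort
#'
#' Draws a Balding-Nichols / Dirichlet-admixture genotype matrix (see the
#' model summary at the top of this file). Variants are assigned random
#' SNP allele pairs (palindromic with probability `frac_palindromic`),
#' positions unique per chromosome, and a `frac_x` share on chromosome X
#' where simulated males are hemizygous (calls 0/2 only). Deterministic
#' under a fixed `seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A [genotype_matrix()] with attributes `sex` (named vector),
#'   `admixture` (samples x K matrix of q), and `ancestral_freq`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ns <- cfg$n_samples; nv <- cfg$n_variants; K <- cfg$K

  p_anc <- stats::runif(nv, cfg$p_range[1L], cfg$p_range[2L])
  pop_freq <- matrix(0, nrow = K, ncol = nv)
  for (k in seq_len(K)) {
    f <- cfg$fst[k]
    shape1 <- p_anc * (1 - f) / f
    shape2 <- (1 - p_anc) * (1 - f) / f
    pop_freq[k, ] <- stats::rbeta(nv, shape1, shape2)
  }
  q <- rdirichlet(ns, cfg$alpha)
  pi_mat <- q %*% pop_freq                      # ns x nv individual freqs

  sex <- sample(c("female", "male"), ns, replace = TRUE)
  calls <- matrix(stats::rbinom(ns * nv, 2L, pi_mat), nrow = ns)

  # variant map: X share, unique sorted positions per chromosome
  n_x <- round(cfg$frac_x * nv)
  chrom <- c(sample(as.character(1:22), nv - n_x, replace = TRUE),
             rep("X", n_x))
  ord <- order(match(chrom, VALID_CHROMS))
  chrom <- chrom[ord]
  pos <- integer(nv)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(2^28, length(i)))
  }
  pal <- stats::runif(nv) < cfg$frac_palindromic
  pair_idx <- ifelse(pal, sample.int(2L, nv, replace = TRUE),
                     sample.int(4L, nv, replace = TRUE))
  a1 <- a2 <- character(nv)
  for (j in seq_len(nv)) {
    p <- if (pal[j]) PAL_PAIRS[[pair_idx[j]]] else NONPAL_PAIRS[[pair_idx[j]]]
    a1[j] <- p[1L]; a2[j] <- p[2L]
  }
  vt <- variant_table(chrom, pos, sprintf("snp%06d", seq_len(nv)), a1, a2)

  # hemizygous males on X: one allele copy, coded 0/2
  x_cols <- which(vt$chrom == "X")
  males <- which(sex == "male")
  if (length(x_cols) && length(males)) {
    hemi <- matrix(stats::rbinom(length(males) * length(x_cols), 1L,
                                 pi_mat[males, x_cols]),
                   nrow = length(males)) * 2L
    calls[males, x_cols] <- hemi
  }

  gm <- genotype_matrix(calls, vt, sprintf("ind%05d", seq_len(ns)))
  names(sex) <- gm$samples
  rownames(q) <- gm$samples
  attr(gm, "sex") <- sex
  attr(gm, "admixture") <- q
  attr(gm, "ancestral_freq") <- p_anc
  attr(gm, "population_freq") <- pop_freq
  gm
}

#' Split a cohort across two partially overlapping arrays
#'
#' Emulates a study design in which two genotyping arrays share a subset of
#' samples and a subset of variants: array A (the sparser, imputation-input
#' array) receives the shared variants plus a fraction of the rest; array B
#' (the denser truth array) receives the shared variants plus the
#' remainder. Shared samples appear on both arrays; the remaining samples
#' are split evenly. Uses the current RNG stream.
#'
#' @param truth a `genotype_matrix` from [simulate_cohort()].
#' @param frac_shared_samples fraction of samples genotyped on both arrays.
#' @param frac_shared_variants fraction of variants present on both arrays
#'   (the pre-imputation overlap to be excluded from accuracy).
#' @param frac_array_a_only fraction of the non-shared variants that go to
#'   array A only.
#' @return List with `array_a`, `array_b` (genotype matrices),
#'   `shared_samples` (character), and `shared_variants` (data frame
#'   `chrom`/`pos`/`id`).
#' @export
split_arrays <- function(truth, frac_shared_samples = 0.5,
                         frac_shared_variants = 0.2,
                         frac_array_a_only = 0.5) {
  fr <- c(frac_shared_samples, frac_array_a_only)
  if (any(fr <= 0 | fr >= 1)) stop("split fractions must lie in (0, 1)")
  if (frac_shared_variants < 0 || frac_shared_variants >= 1) {
    stop("frac_shared_variants must lie in [0, 1)")
  }
  ns <- length(truth$samples); nv <- nrow(truth$variants)

  shared_s <- sort(sample.int(ns, max(1L, round(frac_shared_samples * ns))))
  rest_s <- setdiff(seq_len(ns), shared_s)
  a_extra <- rest_s[seq_len(floor(length(rest_s) / 2))]
  b_extra <- setdiff(rest_s, a_extra)

  shared_v <- sort(sample.int(nv, round(frac_shared_variants * nv)))
  rest_v <- setdiff(seq_len(nv), shared_v)
  a_only <- sort(sample(rest_v, round(frac_array_a_only * length(rest_v))))
  b_only <- setdiff(rest_v, a_only)
  if (length(b_only) == 0L || length(a_only) == 0L) {
    stop("degenerate array split: one array would carry no private variants")
  }

  list(array_a = gm_subset(truth,
                           samples = truth$samples[sort(c(shared_s, a_extra))],
                           variants = sort(c(shared_v, a_only))),
       array_b = gm_subset(truth,
                           samples = truth$samples[sort(c(shared_s, b_extra))],
                           variants = sort(c(shared_v, b_only))),
       shared_samples = truth$samples[shared_s],
       shared_variants = truth$variants[shared_v, c("chrom", "pos", "id")])
}

## pick the homozygous allele for a discordant variant so the classifier
## sees NONE: avoid the allele whose complement equals a monomorphic truth set
discordant_allele <- function(a1, a2, truth_has_a, truth_has_b) {
  new1 <- unname(ALLELE_COMPLEMENT[a1])   # complement pair = the only
  new2 <- unname(ALLELE_COMPLEMENT[a2])   # allele pair disjoint from truth
  if (truth_has_a && !truth_has_b) return(new2)  # avoid c(new1) = a1
  if (truth_has_b && !truth_has_a) return(new1)
  new1
}

#' Corrupt truth genotypes into pseudo-imputed probabilistic data
#'
#' Assigns each variant a corruption label with probabilities
#' (1 - e - f - m, e, f, m) for \{clean, error, flip, mono\}:
#' \describe{
#'   \item{clean}{posterior mass m* ~ Uniform(`gp_max_range`) on the true
#'     genotype, the remainder split randomly over the other two;}
#'   \item{error}{the allele pair is replaced by its complement pair (the
#'     only pair sharing no allele with truth) and every sample's mass is
#'     concentrated on one homozygous genotype, chosen so the observed
#'     allele set is discordant with truth (for palindromic truth both new
#'     alleles are observed, yielding an ambiguous no-match);}
#'   \item{flip}{alleles strand-complemented, genotype codes preserved;}
#'   \item{mono}{every sample's mass concentrated on the homozygote of the
#'     major truth allele.}
#' }
#' A flip label landing on a palindromic variant (where a flip is
#' unobservable) and a mono label landing on a truth-monomorphic variant
#' (where collapse is a no-op) are moved to a randomly chosen eligible clean
#' variant, so the injected rates are preserved; moves are counted in the
#' attribute `"n_reassigned"`. Per-variant quality is
#' `plogis(quality_maf_slope * MAF + N(0, 0.5))`, halved for error and mono
#' variants. Deterministic under the current RNG stream.
#'
#' @param truth a `genotype_matrix` (e.g. the truth restricted to the
#'   evaluation region).
#' @param cfg a [simulation_config()] (rates, GP and quality parameters).
#' @return A [prob_genotype_matrix()] with attribute `"labels"`, a data
#'   frame `chrom`/`pos`/`id`/`label`, and attribute `"n_reassigned"`.
#' @export
corrupt_as_imputed <- function(truth, cfg) {
  stopifnot(inherits(truth, "genotype_matrix"),
            inherits(cfg, "simulation_config"))
  ns <- length(truth$samples); nv <- nrow(truth$variants)
  e <- cfg$error_rate; f <- cfg$flip_rate; m <- cfg$mono_rate

  labels <- sample(c("clean", "error", "flip", "mono"), nv, replace = TRUE,
                   prob = c(1 - e - f - m, e, f, m))

  pal <- is_palindromic(truth$variants)
  n_b <- colSums(truth$calls, na.rm = TRUE)
  n_called <- colSums(!is.na(truth$calls))
  n_a <- 2L * n_called - n_b
  poly <- n_a > 0L & n_b > 0L

  # move ineligible flip/mono labels onto eligible clean variants, so the
  # injected per-class rates are preserved across the whole variant set
  n_reassigned <- 0L
  bad_flip <- which(labels == "flip" & pal)
  for (j in bad_flip) {
    cand <- which(labels == "clean" & !pal)
    labels[j] <- "clean"
    if (length(cand)) labels[cand[sample.int(length(cand), 1L)]] <- "flip"
    n_reassigned <- n_reassigned + 1L
  }
  bad_mono <- which(labels == "mono" & !poly)
  for (j in bad_mono) {
    cand <- which(labels == "clean" & poly)
    labels[j] <- "clean"
    if (length(cand)) labels[cand[sample.int(length(cand), 1L)]] <- "mono"
    n_reassigned <- n_reassigned + 1L
  }

  vt <- truth$variants
  target <- truth$calls                     # genotype the GP mass lands on
  for (j in which(labels == "flip")) {
    vt$a1[j] <- unname(ALLELE_COMPLEMENT[vt$a1[j]])
    vt$a2[j] <- unname(ALLELE_COMPLEMENT[vt$a2[j]])
  }
  for (j in which(labels == "mono")) {
    major_is_b <- n_b[j] >= n_a[j]
    target[, j] <- if (major_is_b) 2L else 0L
  }
  for (j in which(labels == "error")) {
    if (pal[j]) {
      # palindromic truth: the disjoint pair is the *other* palindromic
      # pair; drawing both alleles yields an ambiguous no-match
      other <- if (vt$a1[j] %in% c("A", "T")) c("C", "G") else c("A", "T")
      new1 <- other[1L]; new2 <- other[2L]
      target[, j] <- 2L * stats::rbinom(ns, 1L, 0.5)
    } else {
      # non-palindromic truth: the complement pair is the only disjoint
      # pair; concentrate on one homozygote so the imputed side is a
      # monomorphic novel allele (a plain no-match, never a flip)
      keep_allele <- discordant_allele(vt$a1[j], vt$a2[j],
                                       n_a[j] > 0L, n_b[j] > 0L)
      new1 <- unname(ALLELE_COMPLEMENT[vt$a1[j]])
      new2 <- unname(ALLELE_COMPLEMENT[vt$a2[j]])
      target[, j] <- if (keep_allele == new2) 2L else 0L
    }
    vt$a1[j] <- new1; vt$a2[j] <- new2
  }

  # posterior mass: winner gets m* ~ U(gp_max_range), rest split randomly
  mstar <- matrix(stats::runif(ns * nv, cfg$gp_max_range[1L],
                               cfg$gp_max_range[2L]), nrow = ns)
  u <- matrix(stats::runif(ns * nv), nrow = ns)
  rest1 <- (1 - mstar) * u
  rest2 <- (1 - mstar) * (1 - u)
  probs <- array(0, dim = c(ns, nv, 3L))
  for (g in 0:2) {
    others <- setdiff(0:2, g)
    sel <- !is.na(target) & target == g
    pk <- probs[, , g + 1L]; pk[sel] <- mstar[sel]
    probs[, , g + 1L] <- pk
    pk <- probs[, , others[1L] + 1L]; pk[sel] <- rest1[sel]
    probs[, , others[1L] + 1L] <- pk
    pk <- probs[, , others[2L] + 1L]; pk[sel] <- rest2[sel]
    probs[, , others[2L] + 1L] <- pk
  }
  # missing truth entries keep the all-zero no-call triple

  maf <- compute_maf(truth)
  maf[is.na(maf)] <- 0
  quality <- stats::plogis(cfg$quality_maf_slope * maf +
                             stats::rnorm(nv, 0, 0.5))
  quality[labels %in% c("error", "mono")] <-
    quality[labels %in% c("error", "mono")] * 0.5

  pgm <- prob_genotype_matrix(probs, vt, truth$samples, quality)
  attr(pgm, "labels") <- data.frame(chrom = vt$chrom, pos = vt$pos,
                                    id = vt$id, label = labels,
                                    stringsAsFactors = FALSE)
  attr(pgm, "n_reassigned") <- n_reassigned
  pgm
}

#' Expected no-call fraction of the clean channel
#'
#' With the winning posterior drawn Uniform(lo, hi) and an inclusive calling
#' threshold t, the expected fraction of entries left uncalled is the
#' uniform CDF at t: 0 for t <= lo, (t - lo) / (hi - lo) between, 1 for
#' t >= hi.
#'
#' @param cfg a [simulation_config()] (uses `gp_max_range`).
#' @param threshold the calling threshold t.
#' @return Expected no-call fraction in \[0, 1\].
#' @export
expected_no_call_fraction <- function(cfg, threshold) {
  lo <- cfg$gp_max_range[1L]; hi <- cfg$gp_max_range[2L]
  pmin(pmax((threshold - lo) / (hi - lo), 0), 1)
}
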