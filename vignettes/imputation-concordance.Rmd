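---
title: "Evaluating genotype imputation by allele concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genotype imputation by allele concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impuconcord)
```

## The problem

Genotype imputation infers ungenotyped variants from a sparse genotyping
array and a phased haplotype reference panel. When the same individuals have
also been genotyped on a second, denser array, the imputed genotypes can be
checked against real ones: restrict both datasets to the shared individuals,
drop the sites both arrays genotyped directly (they would trivially agree),
and compare, site by site, the alleles the two platforms actually observed.
`impuconcord` implements that evaluation — posterior-probability hard
calling, iterative array QC, a four-class allele-concordance taxonomy with
strand-flip and palindromic-ambiguity handling, and MAF-stratified quality
summaries — together with a simulator of admixed cohorts so the whole
pipeline can be exercised, and its calibration verified, without access to
any restricted cohort.

This matters particularly for multi-way admixed cohorts, whose mosaic
haplotypes are poorly represented in most reference panels, and for the X
chromosome, which many evaluations skip; every statistic here is therefore
reported for autosomes and X separately.

## Hard-calling model

Imputation engines emit, per sample and biallelic site, posterior
probabilities $(p_0, p_1, p_2)$ over the three genotypes. A hard call is
made when $\max_g p_g \ge t$ *and* the maximum is unique; otherwise the
entry is missing ("N"). The threshold comparison is inclusive, matching the
behaviour of PLINK's `--vcf-min-gp`; a tied maximum abstains because no
genotype then dominates the posterior. The default $t = 0.7$ is the
conventional operating point balancing accuracy against the number of
callable genotypes; `sweep_threshold()` recomputes that trade-off for any
dataset. An all-zero probability triple (the Oxford GEN convention for a
failed site) is missing at every threshold.

Two input routes exist — VCF with `GP` FORMAT fields, and GEN/SAMPLE — and
they are required by construction (and verified by test) to produce
identical genotype matrices for equivalent content. Probabilities are
linear-scale, as emitted by Minimac and PBWT; quality scores are read from
the first INFO key found among `INFO`, `R2`, `DR2`, a deterministic
precedence covering the IMPUTE2 / Minimac / Beagle conventions.
Multiallelic and symbolic records are skipped with a logged count rather
than an error, since the evaluation is defined for biallelic SNPs.

## Match taxonomy

For each overlapping site, the alleles *observed in the calls* on each side
form a set of size 1 or 2 (a site imputed or genotyped monomorphic
contributes a singleton — operating on observed sets rather than declared
pairs is what lets the taxonomy catch monomorphic imputation). With $c(\cdot)$
the base-complement image:

| condition | class |
|---|---|
| $S_i = S_t$ | **COMPLETE** |
| $c(S_i) = S_t$ | **FLIP** (strand-swapped) |
| $|S_i \cap S_t| = 1$ | **HALF** |
| otherwise | **NONE** |

Rules are tried in that order, and the classification is symmetric in its
arguments. HALF uses the direct orientation only: the strand flip is
defined for the full pair, so no complement retry is attempted on a partial
intersection. Two deliberate conventions handle palindromic (A/T, G/C)
sites, where strand cannot be resolved from alleles alone: an identical
palindromic pair resolves to COMPLETE (a flip is unobservable there, and
the call is the conservative deterministic choice), and a NONE between two
size-2 palindromic pairs is flagged *ambiguous* — it may be a genuine
mismatch or an unrecognised strand flip, and no evidence in the data can
distinguish the two.

Accuracy counts flips as matches, since a flipped site is recoverable by
strand alignment to a reference:

$$\text{accuracy} = 100\cdot\frac{n_\text{COMPLETE}+n_\text{FLIP}}{n_\text{overlap}},
\qquad \text{error} = 100 - \text{accuracy},$$

and the *adjusted* accuracy additionally counts ambiguous no-matches as
correct, bounding the effect of the palindromic-ambiguity convention from
the other side. Sites with every call missing on either side cannot be
classified; they are excluded from $n_\text{overlap}$ and reported
separately, so either inclusion convention can be reconstituted from the
output. Sites are paired across datasets by (chromosome, position), never
by identifier, because identifiers differ across arrays and panels.

## Iterative QC

Pre-imputation array QC applies, in a fixed order within one pass: samples
missing more than 10% of genotypes; variants with more than 2% missingness
(on the remaining samples); variants with MAF below 5%; and samples whose
heterozygosity statistic $F = 1 - O(\text{het})/E(\text{het})$ lies more
than 3 standard deviations from the cohort mean. Passes repeat until one
removes nothing; monotone shrinkage guarantees termination, and the final
matrix provably satisfies every threshold. All boundary comparisons are
strict, matching the "more than" / "below" reading of the rules. The
filter order within a pass and the 3-SD operationalisation of "excessive
heterozygosity" are this package's own conventions (the field's usual
ones), fixed for determinism.

The concluding sex-concordance check computes $F$ on X-linked variants
only: hemizygous males sit near $F = 1$, females near 0. Inference uses a
guard band — female below 0.2, male above 0.8, undetermined between — and
only a *determined* inference contradicting the reported sex is flagged, so
noisy mid-band samples and unknown reported sex never generate removals.

## The synthetic cohort

`simulate_cohort()` draws truth genotypes from the standard minimal model
of a $K$-way admixed population — Balding–Nichols with Dirichlet admixture:

- ancestral frequency $p_j \sim \mathrm{Uniform}(0.05, 0.95)$;
- population frequency $p_{kj} \sim \mathrm{Beta}\!\big(p_j\tfrac{1-F_k}{F_k},\,(1-p_j)\tfrac{1-F_k}{F_k}\big)$ with $F_k = 0.1$ by default;
- admixture $q_i \sim \mathrm{Dirichlet}(\alpha)$, by default the five-way
  skewed preset `alpha_five_way_admixed` (dominant KhoeSan-like component);
- genotype $\sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kj})$, with one draw
  (coded 0/2) for males on the X.

Defaults: 5% of variants on X, 15% palindromic allele pairs (a level
typical of array content after harmonisation — enough to exercise the
ambiguity machinery without dominating the classification).

`corrupt_as_imputed()` then emulates imputation output with known failure
rates. Each variant draws a label from {clean, error, flip, mono} with
probabilities $(1-e-f-m, e, f, m)$:

- **clean** — posterior mass $m^\ast \sim \mathrm{Uniform}(0.5, 1)$ on the
  true genotype, remainder split randomly over the other two. The winning
  mass is uniform, so the expected no-call fraction at threshold $t$ is the
  closed form $(t - 0.5)/0.5$ on $[0.5, 1]$ — the analytic companion the
  tests check against (40% at $t = 0.7$).
- **error** — the allele pair is replaced by the unique disjoint pair (its
  complement for non-palindromic sites; the other palindromic pair for
  palindromic ones). Non-palindromic errors concentrate on one homozygote,
  chosen so a monomorphic truth site cannot accidentally read as a flip;
  palindromic errors draw both alleles, producing exactly the ambiguous
  A/T-vs-G/C no-matches seen in real palindromic discordance.
- **flip** — alleles complemented, genotype codes preserved.
- **mono** — every sample collapsed to the homozygote of the major truth
  allele, the dominant real-world source of half matches.

Flip labels landing on palindromic sites (where a flip is unobservable) and
mono labels landing on already-monomorphic sites (where collapse is a
no-op) are moved to a randomly chosen eligible clean variant, so the
*realized* per-class rates stay at $(e, f, m)$ rather than being silently
diluted; moves are counted in an attribute. With this construction the
classifier recovers the label table exactly at threshold 0 — clean →
COMPLETE, flip → FLIP, error → NONE, mono → HALF — which is the package's
strongest self-check, and measured class proportions sit within binomial
noise of the injected rates.

Per-variant quality is $\mathrm{logit}^{-1}(8\,\mathrm{MAF} +
\varepsilon)$, $\varepsilon \sim N(0, 0.5)$, halved for error and mono
variants. The slope of 8 spans roughly 0.5 at MAF 0 to 0.98 at MAF 0.5,
giving the rising quality-vs-MAF profile characteristic of real INFO/r²
scores at a noise level that leaves per-bin medians monotone at the
problem sizes used; the halving makes the problem classes separable by a
quality filter, as they should be.

**What the generator does not emulate.** No linkage disequilibrium, no
realistic chip ascertainment, and no imputation HMM: corruption is injected
per variant, independently. The evaluation statistics under test are
LD-free, so passing tests validate the *evaluator* — calling, taxonomy,
aggregation, QC — not the quality of any real imputation engine, and say
nothing about LD-dependent error correlation along real chromosomes.

## Quality summaries

MAF is the folded B-allele frequency over called genotypes. Binning is
half-open $(lo, hi]$ with the first bin closed at 0, default edges
$\{0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5\}$ (a conventional ladder,
denser at the rare end where imputation quality moves fastest). Both the
median and the mean are available and emitted, because both conventions
are in live use for quality-vs-MAF curves; neither is privileged. Scores
from different engines (INFO vs r²) are summarised within a dataset only,
never compared across datasets numerically. The per-class table reports
total/HALF/NONE medians per stratum, the view that shows whether a quality
filter would remove the problem classes.

## Numerical choices and degenerate inputs

- Probability triples must sum to 1 within $10^{-3}$; the all-zero triple
  is accepted as the GEN no-call sentinel.
- Ties at the posterior maximum, including the all-zero triple, always
  abstain; comparisons are exact floating-point equality, which is the
  intended semantics for written-then-parsed probability text.
- Variants pruned for being uncalled default to the *all-missing* rule;
  the any-missing alternative is implemented but would be incompatible
  with realistic 25–45% per-entry no-call rates, after which essentially
  no variant would survive.
- Empty strata (e.g. no X sites in the overlap) propagate as `NA`
  statistics, never as errors; an emptied cohort in QC is an error.
- Serialisations print probabilities with six significant digits; both
  readers parse the same text to the same doubles, which is what makes the
  two-route calling equivalence exact.

## Problem sizes

The test-suite study conditions are 200 samples × 20,000 variants (5% on
X) for parameter recovery and quality-curve checks, with injected rates
$e = 0.10$, $f = 0.05$, $m = 0.02$, and smaller cohorts (tens of samples,
hundreds of variants) for exhaustive and fixed-point checks — sizes at
which three binomial standard errors resolve the injected rates cleanly on
both autosomes and X. `scripts/acceptance.R` re-runs the same conditions
from scratch at a caller-supplied seed.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_samples = 200, n_variants = 20000,
                         error_rate = 0.10, flip_rate = 0.05,
                         mono_rate = 0.02, seed = 1)
truth <- simulate_cohort(cfg)
imputed <- corrupt_as_imputed(truth, cfg)
called <- call_genotypes(imputed, calling_config(threshold = 0))
s <- summarize_concordance(extract_overlap(called$gm, truth))
s[s$stratum %in% c("autosomes", "X"),
  c("stratum", "n_overlap", "complete", "flip", "half", "none",
    "accuracy_pct", "adjusted_accuracy_pct")]
```

## Known limitations

- Genotype-level (per-sample) concordance, dosage $r^2$ against truth and
  haplotype switch error are out of scope: matching is variant-level on
  observed allele sets.
- PLINK binary and BGEN inputs are not parsed; convert to VCF or GEN first.
- LD-based strand harmonisation against a reference panel is an external
  pre-processing step, not reimplemented here.
- The heterozygosity and sex-inference thresholds are field conventions
  with no universal standard; they are exposed in `qc_thresholds()` and
  should be tuned to the cohort when used in anger.
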