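---
title: "Methods: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented by `pathcross`,
the scope of the synthetic-data generator, and the numerical and design
choices that are not obvious from the function signatures. Code chunks are
shown for illustration and are not evaluated when the vignette is built;
every quantitative claim made here is one the test suite
(`tests/testthat/`) or the acceptance script (`scripts/acceptance.R`)
computes directly.

## 1. Summary-statistics dialects and harmonization

Two text dialects are supported.

* **Dialect A (PGC-style TSV)**: tab-separated with columns
  `CHR, BP, SNP, A1, A2, BETA|OR, SE, P, N` (plus optional
  `NCAS`/`NCON`). `OR` is converted to `beta = log(OR)` on read.
* **Dialect B (GWAS-VCF)**: VCFv4.2 with one sample column whose FORMAT is
  `ES:SE:LP:SS` — effect size of the ALT allele, standard error,
  $-\log_{10} p$, and per-variant sample size. ALT is the effect allele.
  Study-level metadata (trait name, genome build, effective N) travels in a
  `##trait_meta=<...>` header line. The reader also accepts plain
  `ES:SE:LP` records, taking N from the header. Multi-allelic records are
  skipped and ledgered; a $p$ that underflows double precision
  (`LP` ≥ ~308) is floored at the smallest positive double, never zero; a
  missing `LP` is recovered from $z = \beta/\mathrm{se}$.

**Bit-exact round trips.** Numeric columns are written with `%.17g`, which
is sufficient to reproduce any double exactly, and read back as character
then converted with `as.numeric()` (R's `strtod`, which is correctly
rounded). This makes `beta`, `se`, `pvalue`, and `n` survive a
write/read cycle bit for bit in both dialects. The derived `z` column is
always recomputed as `beta/se` on construction, so it is bitwise
reproducible from the stored columns rather than stored redundantly. The
pipeline consequently produces *identical* downstream results (gene
p-values, NES, TWAS z, h², r_g) whether its input arrived as TSV or VCF —
asserted with `expect_identical()` in the tests.

**Harmonization** of a study pair proceeds per variant: match by
chromosome+position, falling back to rsID (a position disagreement under an
rsID match within one chromosome is tolerated and position taken from study
A; a chromosome disagreement is a conflict and the variant is dropped).
Allele pairs are then reconciled in this order: exact match; swap (effect
and other allele exchanged — study B's beta and z are negated); strand flip
(both alleles complemented); flipped swap. Palindromic variants (A/T, C/G)
are dropped unconditionally, because a strand flip is indistinguishable
from a swap for them. Every dropped or transformed row lands in an
exclusion ledger whose counts are conserved: shared + ledgered = input, a
property tested directly.

## 2. Synthetic two-trait generator

`sim_config()` fixes a scene: `m_snps` SNPs in LD blocks of 100,
`n_genes` genes tiled along a single chromosome, `n_sets` gene sets,
per-trait heritabilities `h2`, genetic correlation `rg`, sample sizes `n`,
and optional annotations with heritability multipliers. All downstream
randomness flows from `seed` through `derive_seed(seed, label)`, a
deterministic integer hash that keeps independent streams (effects, trait
A draws, trait B draws, tracks) decoupled, so e.g. redrawing trait B never
perturbs trait A.

**LD.** Each block of 100 SNPs gets an AR(1) correlation
$R_{jk} = \rho^{|j-k|}$. The block $\rho$ values cycle through
`seq(0.1, 0.9, length.out = 20)` rather than being constant. This is a
deliberate design choice: with a uniform $\rho$, per-SNP LD scores are
nearly constant across the genome, and a regression of $\chi^2$ on LD
scores has essentially no leverage — the LDSC slope and intercept become
unidentifiable and null-scene estimates scatter far beyond their nominal
standard errors. Heterogeneous $\rho$ yields LD scores spanning roughly
1–9.5, comparable to the dynamic range in real genomes, and makes every
LDSC-layer estimand identifiable at desk scale.

**Effects.** True per-SNP effects are drawn bivariate normal with
$\mathrm{Var}(\beta_t) = h_t^2/m$ per SNP and correlation `rg`;
annotation multipliers scale the per-SNP variance inside the annotation
and the baseline is rescaled so the *total* $h^2$ is preserved exactly (a
conservation property tested to machine precision). Marginal (LD-confounded)
effects are $R\beta$, and z-scores are drawn
$z \sim \mathcal N(\sqrt{N} R \beta, R)$ per block, the standard
summary-statistics sampling model.

**Tracks.** The scene also carries gene coordinates with strands, a
priority-ordered gene-set panel, expression-prediction weights for several
tissues, and the matching SNP covariance panel — everything needed to run
all four layers against known truth.

**Scope.** The generator makes no attempt at minor-allele-frequency
spectra, population stratification, sample overlap, imputation quality, or
real LD panels. It is a calibration instrument for the estimators in this
package, not a population-genetics simulator.

## 3. Gene-based association

For a gene's SNP z-scores $z$ and local LD $R$ (read from the block
structure, never densified genome-wide), the statistic is the mean χ²,
$T = \frac1m\sum z_j^2$. Under the null $mT$ is a mixture
$\sum_j \lambda_j \chi^2_1$ over the eigenvalues of $R$; we use the
Satterthwaite two-moment approximation
$mT \approx (S_2/S_1)\,\chi^2_{S_1^2/S_2}$. The approximation is *exact*
in three regimes — a single SNP, fully independent SNPs, and perfect LD —
and the tests pin each against its closed form at `1e-12`. Eigenvalues
below $-10^{-8} \cdot \lambda_{\max}$ trigger an error (non-PSD input)
rather than silent truncation; small negative noise eigenvalues are
clamped to zero. Gene p-values convert to probit scores
$z_g = \Phi^{-1}(1-p)$ with clamping to keep them finite at the double
boundaries.

The competitive set test is a one-sided Welch $t$ comparing in-set versus
out-of-set $z_g$; a zero-variance configuration is flagged `degenerate`
and returns $p = 1$ instead of `NaN`. Panels are deduplicated by
*priority*: a gene appearing in several sets is kept only in the
highest-priority (lowest number) set, and the operation is idempotent.

## 4. GSEA and cross-disorder DGSEA

The running-sum enrichment score is computed in $O(k)$ from the sorted hit
positions rather than by materializing the full $N$-step walk; the tests
compare it against a literal brute-force walk. With weight exponent 0 it
reduces to the classical KS statistic, checked against `ks.test`, and the
weighted form is cross-checked against `fgsea::calcGseaStat`. Ties in the
maximum deviation resolve in favor of the positive excursion when
`|pos| == |neg|`.

Null distributions come from gene-label permutations. Permutation scores
are cached per set *size*, so same-sized sets share one null and a
200-set uniformity screen stays cheap. NES divides ES by the mean
absolute value of same-sign permutation scores, and p-values use the
add-one rule $p = (1 + \#\{|ES^\ast| \ge |ES|\})/(1 + n_{\mathrm{perm}})$,
which can never return 0.

DGSEA compares all ordered set pairs across the two disorders (for $k$
sets: $k(k-1)$ cross pairs plus within-disorder contrasts as configured;
an 8-set panel yields 56 cross comparisons), using a *shared* permutation
stream so $\Delta NES = NES_A(S_1) - NES_B(S_2)$ is compared to a null
that preserves the coupling between the two rankings.

## 5. TWAS

$z_{\mathrm{TWAS}} = w^\top z \big/ \sqrt{w^\top \Sigma w}$ from
expression weights $w$ and reference covariance $\Sigma$, after aligning
the study's effect alleles to the weight panel (swapped alleles negate
$z$; incompatible allele pairs drop the SNP, or error under
`strict = TRUE`). Weights for SNPs absent from the study are subset out of
both $w$ and $\Sigma$. A single-SNP model reduces to
$\mathrm{sign}(w)\,z$, pinned exactly in the tests. Set enrichment is a
one-sided Mann–Whitney on $|z_{\mathrm{TWAS}}|$, in-set versus
out-of-set, per tissue.

## 6. LD score regression

LD scores $\ell_j = \sum_k r_{jk}^2$ are computed block-wise and checked
against closed forms for small AR(1) blocks. `estimate_h2` fits
$\chi^2_j = 1 + (N h^2 / M)\,\ell_j$ by weighted least squares with the
canonical **two-step weights**: pass 1 uses $1/\max(1, \ell_j)$
(overcounting correction); pass 2 multiplies by
$1/\hat\mu_j^2$ where $\hat\mu_j = \max(1 + \hat h^2_{(1)} N \ell_j / M,\ 0.1)$
is the pass-1 predicted mean χ² (heteroskedasticity correction), with
$\hat h^2_{(1)}$ clamped to $[0,1]$ for weighting only. Simple single-pass
$1/\max(1,\ell)$ weights gave visibly wider $r_g$ scatter in calibration
runs, which is why the two-step scheme is used throughout.

Cross-trait regression fits $z_a z_b$ on $\ell$ with the analogous
cross-weights $1/(\max(1,\ell)(\hat\mu_a\hat\mu_b + \hat\mu_c^2))$, and
$r_g = \hat\rho_g / \sqrt{\hat h_a^2 \hat h_b^2}$; non-positive component
heritabilities abort with an explanatory error rather than returning a
complex or unstable ratio.

**Jackknife.** Standard errors come from an exact delete-one-block
jackknife over 200 contiguous SNP blocks, implemented from per-block
$X^\top W X$ / $X^\top W y$ sufficient statistics so each leave-one-out
refit is algebraically exact (validated against 200 literal `lm.wfit`
refits). Columns are rescaled by their root-mean-square before solving for
conditioning; rank deficiency raises an error.

**Partitioned h² and fallback.** Partitioned heritability regresses χ²
on per-annotation LD scores; enrichment is
$(\mathrm{prop}\ h^2)/(\mathrm{prop\ SNPs})$ with jackknife SEs and
one-tailed p-values. The stratified-χ² fallback is regression-free:
$\mathrm{ratio} = (\bar\chi^2_{\mathrm{in}} - 1)/(\bar\chi^2_{\mathrm{out}} - 1)$
computed on LD-score-floored means, used as a directional concordance
check rather than a calibrated estimator.

## 7. Pipeline and determinism

`run_all()` chains harmonization → gene layer → enrichment → TWAS → LDSC
for a pair of input files (either dialect) or an in-memory scene, caching
each layer as RDS and writing CSV/BED outputs. All permutation seeds
derive from the single config seed via `derive_seed`, so two runs of the
same config are byte-identical (asserted by MD5 in the tests) and resuming
from cache changes nothing. Numeric CSV output uses `%.17g` via the same
full-precision formatter as the sumstats writers.

## 8. Limitations

* The gene test's Satterthwaite approximation is a two-moment match;
  extreme tail accuracy for very large, highly structured genes is not
  guaranteed (only the exact regimes are).
* LDSC at desk scale (tens of thousands of SNPs) has Monte Carlo noise of
  the same order as small tolerance bands; calibration assays in the tests
  are sized so the band is ≥ 2.5 sampling SDs.
* The generator's LD is block-diagonal AR(1); estimators are not exercised
  against long-range LD, MAF-dependent architectures, or sample overlap.
* The fallback enrichment ratio is directional only; its magnitude is not
  comparable to the partitioned-regression enrichment.
* TWAS assumes the covariance panel matches the weight panel's LD; panel
  mismatch is not modeled.
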