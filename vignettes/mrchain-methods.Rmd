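---
title: "Methods: a multi-stage Mendelian randomization chain on summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-stage Mendelian randomization chain on summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrchain)
```

mrchain implements the complete summary-statistics causal-inference
chain used to establish, dissect and decompose a causal effect of one
trait on another from GWAS and molecular-QTL summary data: genetic
correlation, bidirectional two-sample MR with sensitivity analyses,
multivariable MR, colocalization, SMR with HEIDI filtering, phenome-wide
screening, and two-step mediation MR. The motivating application is the
question whether gestational diabetes mellitus (GDM) causally raises the
risk of carpal tunnel syndrome (CTS), and whether circulating levels of
the copper chaperone for superoxide dismutase (CCS) carry part of that
effect. Everything operates on summary statistics only — per-variant
effect sizes, standard errors, p-values and allele frequencies — so no
individual-level genotypes are ever required.

This vignette documents the models, the defaults and their rationale,
the synthetic-data generators, the numerical choices, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model, quality control and instrument selection

A summary-statistics table has one row per SNP:
`snp, chr, pos, ea, oa, eaf, beta, se, pval, n`, with `beta` the effect
per copy of the effect allele `ea` (log-odds for binary traits).
`read_sumstats()` validates rows on entry — positive SE, distinct
alleles, p in (0,1], frequency in (0,1), and a z-to-p consistency check
that rejects rows whose printed p-value disagrees with `|beta/se|` by
more than 10% on the log10 scale — and keeps the rejects with reasons
rather than silently dropping them.

`qc_filter()` applies the standard pre-analysis variant filters in a
fixed order: non-SNP variants (indels, non-ACGT alleles), then
strand-ambiguous A/T and C/G SNPs, then duplicate identifiers, then
MAF < 0.01. The order matters only for the attribution of removals in
the report; the retained set is the same under any order.

Two strand-ambiguity policies coexist deliberately. The LDSC stage uses
`qc_filter()`'s hard drop of all palindromic SNPs. MR harmonization
(`harmonize()`) instead tries to resolve palindromes by allele
frequency: a palindromic SNP is kept only when both traits' EAFs lie
outside a window of ±0.08 around 0.5, and the side of 0.5 decides
whether the outcome effect is flipped. The window half-width of 0.08 is
a conventional choice (frequencies closer to 0.5 cannot distinguish
strands reliably); it is exposed as `palindrome_eaf_window`.

Instrument selection (`clump()`, `select_instruments()`) is greedy
p-value-ordered LD clumping with the study's thresholds as defaults:
p < 5e-8, pairwise r² < 0.001 within a 10,000-kb window, then an
F-statistic floor of 10 with F = (beta/se)². Three tie-break and
missing-data rules make the selection deterministic and conservative:

* ties on p are broken by (chromosome, position, SNP id);
* a missing LD entry between two SNPs on the same chromosome within the
  window is treated as r² = 1, so unknown correlation blocks
  co-selection rather than admitting possibly correlated instruments;
* cross-chromosome (or beyond-window) pairs are r² = 0 by definition.

Coordinates are 1-based and the window is `|pos_i − pos_j| ≤ window_kb·1000`
on the same chromosome.

## Univariable estimators

All estimators consume harmonized pairs `(beta_x, se_x, beta_y, se_y)`.
With instrument-exposure effects `bx` and instrument-outcome effects
`by`:

* **Wald ratio** (single SNP): `by/bx`, first-order SE `|se_y/bx|`; the
  second-order SE adding `by²·se_x²/bx⁴` under the root is available by
  flag and is never smaller.
* **IVW**: the inverse-outcome-variance weighted estimator
  `Σ(bx·by/se_y²)/Σ(bx²/se_y²)`, identical to no-intercept WLS of `by`
  on `bx`. Random-effects mode multiplies the SE by
  `sqrt(max(1, Q/(k−1)))`; the floor at 1 prevents anti-conservative
  SEs when Q is small by chance.
* **MR-Egger**: WLS of `by` on `bx` *with* intercept after orienting
  every pair to `bx > 0`; the intercept estimates directional
  pleiotropy. SEs scale by `sqrt(max(1, RSS_w/(k−2)))` and inference is
  t-based with k−2 df.
* **dIVW**: replaces the IVW denominator with `Σ((bx²−se_x²)/se_y²)`,
  removing the weak-instrument attenuation that `E[bx²] = γ² + se_x²`
  induces. No closed-form SE is committed to; the SE is a seeded
  nonparametric bootstrap over instruments (2000 resamples by default).
* **RAPS**: maximizes the profile log-likelihood
  `−½ Σ (by − θ·bx)²/(se_y² + θ²·se_x²)`, which accounts for sampling
  error on both sides; the SE comes from the numerical curvature at the
  optimum. The overdispersion variant adds a jointly profiled τ² ≥ 0 to
  each denominator — that joint profile uses the full Gaussian
  likelihood (with log-determinant term), since τ² has no interior
  optimum without it. Robust (Huber/Tukey) loss variants are not
  implemented.

Sensitivity analyses: Cochran's Q with first-order weights
`bx²/se_y²` against any pooled estimate (chi-square, k−1 df);
leave-one-out re-estimation flagging SNPs whose removal changes the
sign or the 0.05 significance of the random-effects IVW estimate; and
the Steiger directionality test comparing instrument-explained variance
`Σ F/(F+n−2)` between the two traits, with a one-sided p from the
difference of Fisher-transformed correlations. Binary-trait
liability-scale corrections are not applied to the Steiger r²; for the
large-n, small-r² regimes simulated here the ranking of the two r²
values, which is all the verdict uses, is unaffected.

`bidirectional_mr()` combines the two directions. Its per-SNP Steiger
filter (on by default) removes individual instruments whose
directionality is unconfirmed (one-sided p ≥ 0.05) before estimation —
this is what keeps instruments of the outcome from leaking into the
reverse analysis, and on forward-causal simulations it typically leaves
the reverse direction with no instruments at all, which is reported as
"not estimable" rather than an error.

## Multivariable MR

`mv_ivw()` estimates direct effects of p exposures jointly:
`theta = (BᵀWB)⁻¹BᵀW·by` with `W = diag(1/se_y²)` and no intercept,
SEs from `(BᵀWB)⁻¹` scaled by `max(1, Q_mv/(k−p))`. With p = 1 this is
exactly univariable IVW. Instruments are pooled across exposures by
strict intersection of SNP ids by default; the union rule (absent
effects imputed as 0) exists behind a flag but is appropriate only when
the missing SNPs were genuinely screened genome-wide in the source
GWAS. Instrument strength per exposure is a simplified conditional
statistic — the mean weighted squared residual of that exposure's
effects after regressing on the other exposures' effects — which
reduces to the mean univariable F for a single exposure. It is labeled
`simplified conditional F` in output; the Sanderson–Windmeijer
conditional F is not implemented.

## Colocalization

`coloc_abf()` is the single-causal-variant Bayesian comparison of five
hypotheses for a region: no causal variant (H0), causal for one trait
only (H1, H2), two distinct causal variants (H3), one shared variant
(H4). Per-variant evidence is the Wakefield approximate Bayes factor
`labf = ½[ln(se²/(se²+W)) + z²·W/(se²+W)]` with prior effect variance
W. Priors default to the conventional p1 = p2 = 1e-4 and p12 = 1e-5 per
SNP, and prior effect SDs 0.15 (quantitative traits) and 0.2
(case-control log-odds); the study this package reimplements reports
only posterior thresholds, not priors, so the conventional values are
used and exposed in the interface. All hypothesis sums are assembled in
log space with log-sum-exp; the H3 term uses the stable difference
`log(Σe^{l1}·Σe^{l2} − Σe^{l1+l2})`.

One property worth stating explicitly: with a fixed `prior_sd` on the
effect scale, the ABF depends on the measurement units of beta and se,
not only on z. Rescaling both by a common constant changes the
shrinkage factor `W/(se²+W)`. In the regime where sampling variance is
small against the prior variance (se² ≪ W, which holds for the GWAS
sample sizes simulated here) the posteriors are insensitive to such
rescaling, and the test suite checks exactly that; unit-invariance is
not exact and is not claimed.

Classification follows the study's two thresholds: `shared_causal` when
PP.H4 > 0.8 (primary), `distinct_or_shared` when PP.H3 + PP.H4 ≥ 0.8
(the expanded inclusion rule), else `unresolved`.

## SMR and HEIDI

`smr_test()` tests whether a molecular trait (expression or protein
level) mediates outcome risk, using the top cis-QTL variant:
`b_xy = beta_gwas/beta_qtl`, with test statistic
`T = z_qtl²·z_gwas²/(z_qtl²+z_gwas²)` referred to chi-square with 1 df,
and `se_xy = |b_xy|/sqrt(T)`. A top-SNP QTL F below 10 is refused as a
weak instrument.

`heidi_test()` distinguishes one shared causal variant from linkage of
two distinct variants: under a single shared variant every LD-linked
SNP implies the same `b_xy` up to sampling noise. Eligible non-top SNPs
follow the conventions of the original SMR software, which the source
study names but does not re-specify: QTL chi² > 10 (p < 1.57e-3),
LD with the top SNP 0.05 ≤ r² ≤ 0.9, capped at the 20 most significant.
The statistic `T = Σ(d_i/sd_i)²` with `d_i = b_xy(i) − b_xy(top)` uses
delta-method covariances of the ratios through the LD correlations; its
null distribution — a sum of correlated squared normals — is evaluated
by seeded Monte Carlo (10,000 draws by default) rather than a
Satterthwaite moment approximation, trading a little runtime for exact
reproducibility under a recorded seed. A singular correlation matrix of
`d` is ridge-regularized (1e-6 on the diagonal) with a warning. Fewer
than 3 eligible SNPs yields a missing p with the reason recorded; the
delta-method linearization also degrades when the outcome-GWAS signal
at the locus is weak, which is why the simulated regions default to an
eQTL-sized QTL sample (30,000) against a biobank-sized GWAS (480,000).

`smr_screen()` converts SMR p-values to Benjamini–Hochberg q-values
across probes and flags probes passing `q < 0.05` with
`p_HEIDI > 0.05`. The cis window convention is 1 Mb around the probe.

## LD score regression

`h2_regression()` regresses per-SNP `z²` on `N·ℓ/M` with a free
intercept: the slope estimates SNP heritability and the intercept is
near 1 absent confounding. `rg_regression()` regresses `z1·z2` on
`sqrt(N1·N2)·ℓ/M`; the slope is the genetic covariance and
`rg = gencov/sqrt(h2_1·h2_2)`. Two implementation choices are
deliberate simplifications, and output from this module should be read
as "simplified-LDSC":

* heteroskedasticity weights `1/(1 + N·ĥ2·ℓ/M)²` come from a single
  unweighted pass (the reference implementation iterates a two-step
  scheme);
* standard errors are delete-one-block jackknives over 200 contiguous
  blocks in input order (genome order assumed), computed from
  per-block moment sums so the 200 refits cost one pass over the data.
  For `rg` the jackknife reruns the full pipeline — both
  heritabilities and the covariance — per deleted block, so `se_rg`
  reflects all three estimation stages.

All LD scores equal makes the slope unidentifiable; this is flagged
`degenerate` rather than silently returning a number. Nonpositive
heritability estimates make rg undefined and raise an error carrying
both h2 estimates.

## Phenome-wide screening and mediation

`phewas_screen()` runs Wald/IVW MR of one exposure's instruments (for a
protein, cis instruments clumped at r² < 0.1 within 10,000 kb) against
each outcome of a panel and applies BH FDR across the panel. Outcomes
with no overlapping SNPs are reported with missing estimates and
excluded from the FDR denominator — the multiplicity correction counts
tests actually performed.

`mediate()` is the product-of-coefficients decomposition: with a the
exposure→mediator effect, b the mediator→outcome effect and c the total
exposure→outcome effect, `indirect = a·b` with Sobel SE
`sqrt(a²se_b² + b²se_a²)`, `direct = c − a·b` (difference method, so
the decomposition identity `indirect + direct = total` holds to machine
precision by construction), and `proportion = indirect/c` with a
delta-method CI. Two covariances are unavailable from summary data and
are set to zero, and the output labels both approximations: the
covariance between the total and indirect estimates (affects
`se_direct`) and the one inside the proportion's delta method. The
source study's printed proportion CI is not exactly reproducible
without its unreported covariance, which is why only the point
estimates and the difference/ratio identities are treated as exact
arithmetic. `two_step_mediation()` runs the three IVW legs from raw
summary files; b is univariable mediator→outcome IVW by default, with
an MVMR-conditioned b (adjusting for the exposure) behind a flag since
the source analysis does not state which was used.

## Synthetic-data generators

The generators produce every input the chain consumes and are pure
functions of (configuration, seed): the caller's RNG state is saved and
restored, and equal seeds give byte-identical files.

* `simulate_two_sample()`: instrument effects `γ_j ~ N(0, gamma_sd²)`
  with `beta_x = γ + e_x`, `beta_y = θγ + α·sign(γ) + e_y`; sampling
  SEs follow the continuous-trait convention
  `se = 1/sqrt(2·n·eaf·(1−eaf))` with EAF uniform on (0.1, 0.9) and
  non-palindromic allele pairs, so output passes default QC unchanged.
  Pleiotropy α is none, balanced `N(0, sd²)`, or directional
  `N(mean, sd²)` expressed relative to the exposure-increasing allele —
  the orientation under which an Egger intercept is defined. Binary
  outcomes are emulated by supplying the SE directly; no liability
  model is assumed. Defaults (k = 50, θ = 0.2, gamma_sd = 0.1,
  n = 200,000) give mean instrument F in the hundreds, the regime of a
  well-powered exposure GWAS.
* `simulate_region_pair()`: z-vectors from `MVN(Rλ, R)` with AR(1) LD
  (ρ = 0.9 by default) and causal positions per scenario H0–H4. The H3
  default separates the two causal variants far enough for r² < 0.01
  (distinct aetiology); `h3_separation = 3` gives the r² ≈ 0.5 linkage
  configuration HEIDI is meant to reject.
* `simulate_smr_region()`: a cis region where the outcome signal is
  either driven by the QTL's causal variant with a chosen `b_xy`
  (shared; the HEIDI null) or by a variant `separation` SNPs away
  (linkage).
* `simulate_ldsc()`: z-pairs drawn per SNP from the bivariate normal
  with `Var(z_i) = 1 + N_i·h2_i·ℓ/M` and
  `Cov = sqrt(N1N2)·rg·sqrt(h2_1h2_2)·ℓ/M` — exactly the generating
  model the regression estimates; LD scores are gamma-distributed
  (mean ≈ 40) and sorted to mimic genome-ordered structure.
* `simulate_mediation_chain()`: exposure instruments act on the
  mediator with slope a and on the outcome with slope `direct + a·b`;
  independent mediator instruments act on the outcome with slope b; the
  exposure GWAS draw is shared between the two legs that use it, as
  with real data.

What the generators do *not* emulate — and hence what passing tests do
not establish about real data: realistic MAF spectra, LD beyond AR(1)/
block toy structures, sample overlap between the two GWAS,
population stratification, winner's-curse from discovery-based
instrument selection in an external GWAS, and liability-scale effects
for binary traits.

## Pipeline orchestration and problem sizes

`run_pipeline()` executes the stages in dependency order from a single
config (R list or YAML), deriving each stage's seed as
`master seed + stage index`, so a rerun with the same config reproduces
every table. A failing stage is recorded with its error and does not
halt independent stages. All thresholds default to the study's values:
p < 5e-8, r² < 0.001, 10,000 kb, F ≥ 10, PP.H4 > 0.8,
PP.H3+PP.H4 ≥ 0.8, p_HEIDI > 0.05, FDR < 0.05.

The repository is organised as an analysis workflow: the numbered
scripts under `analysis/` are thin narrative drivers over the package
functions and write their tables under `results/`; the package itself
carries all computation, tests and documentation.

Simulation sizes used by the test suite and the acceptance script are
the package's own choices, picked to estimate each property tightly at
desk scale: 500 repetitions for estimator recovery (k = 50 instruments),
1000 for the IVW type-I rate, 200 per colocalization scenario (m = 100
SNP regions), 300 for HEIDI size (m = 60 regions, 10,000 Monte-Carlo
null draws), M = 20,000 SNPs with 200 jackknife blocks for LD score
regression (200 repetitions for the null-calibration rate), and 500
repetitions of the full mediation chain. The dIVW bootstrap runs 200
resamples inside repetition loops and 2000 when called once.

## Known limitations

* Correlated-instrument (generalized) IVW, CML-MA, BWMR, MVMR-Egger and
  MVMR-median are not implemented; nor are SuSiE-style multi-causal
  colocalization, multi-SNP SMR, or the binary BESD format.
* The LDSC weighting is one-step, and its intercepts are reported but
  not used to correct estimates.
* Instrument adjustment for a covariate (as in a covariate-adjusted
  source GWAS) is outside scope; instrument lists are taken as given.
* The mediation SEs rest on the stated zero-covariance approximations.
* Colocalization assumes at most one causal variant per trait per
  region; violations typically deflate PP.H4.
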