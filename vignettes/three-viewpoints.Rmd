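---
title: "Three viewpoints of the transcriptome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three viewpoints of the transcriptome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An RNA-seq count says how many reads hit a transcript; it says nothing, by
itself, about *how much of the transcript there was* in the tissue. Turning
counts into abundances requires a denominator, and the denominator defines
the biological question being answered:

* **per-library-size** — counts relative to the (composition-corrected) total
  of sequenced reads. This is the compositional viewpoint: a transcript's
  share of the mRNA pool.
* **per-total-RNA** — counts relative to the fixed mass of total RNA loaded
  into library preparation. An absolute viewpoint per unit RNA.
* **per-sample-size** — counts relative to the milligrams of tissue the RNA
  came from. An absolute viewpoint per unit tissue.

In a stable system the three coincide up to noise. In a growing tissue they
do not: resistance training drives *global transcriptome amplification* —
total RNA per mg rises, and the mRNA pool rises with (or faster than) it.
Compositional normalization is blind to any change shared by most genes, so
a transcript whose absolute abundance rises with the pool looks flat
per-library-size, while a transcript that is truly constant per mg looks
*down-regulated*. `trinorm` implements the full pipeline that makes this
divergence measurable: mode-specific stable-reference-gene selection,
stable-gene sample references, offset-based count models, and a cross-mode
comparison of differential-expression calls.

## The pipeline

1. **Robust filter.** Stable-gene candidates must have a count of at least 30
   in every sample (`min_count_stable`, the default follows common practice
   for reference-gene work: reference genes must be quantifiable everywhere).
2. **Mode-specific log-CPM.** Counts are divided by the mode's denominator
   (TMM-scaled library size; the constant \(10^6\) standing for the fixed RNA
   input; tissue mass \(\times 10^6\)) and log-transformed. The natural log is
   used; every downstream t-value, ICC and p-value is provably invariant to
   the log base and to any common rescaling of the denominators, so these
   constants are conventions, not choices that matter.
3. **Stability screen.** Per gene, a Gaussian linear mixed model
   \(y = X\beta + u_{participant} + e\) is fitted to log-CPM by REML with a
   participant random intercept. The fixed design is intercept + time dummies
   (weeks 2 and 12 vs baseline) + volume dummy + time-by-volume interactions.
   Genes with \(\max |t| < 1.5\) over the non-intercept coefficients are free
   of systematic condition effects and survive.
4. **ICC ranking.** Survivors are ranked by the intraclass correlation
   \(\sigma^2_{participant} / (\sigma^2_{participant} + \sigma^2_e)\):
   a good reference gene is one whose level is a stable *personal*
   characteristic — consistent within a participant across time, however much
   it differs between participants. The top ten per mode are that mode's
   stable reference genes. Ties are broken by gene identifier.
5. **Sample references.** Each stable gene's raw-count profile is scaled by
   its maximum across samples (\(x/\max(x)\)) and the scaled profiles are
   averaged per sample. Because a gene that is stable under mode \(m\)
   has raw counts proportional to mode \(m\)'s effective denominator, this
   average is an internal, data-driven estimate of that denominator, in
   \((0,1]\) by construction.
6. **Differential expression.** Every gene with a count of at least 1 in all
   samples (stable genes excluded; a shared universe for all modes) is fitted
   with a negative binomial GLMM: log link, time fixed effects (legs pooled
   as biological replicates), participant random intercept, and the log
   sample reference as offset. Wald z tests per time contrast are adjusted by
   Benjamini–Hochberg within contrast; direction calls use FDR < 0.05.
7. **Cross-mode comparison.** Per gene and contrast, the triple of
   direction calls across modes is tabulated; intersection percentages are
   relative to all genes differentially expressed in at least one mode, and
   genes called up in one mode but down in another are reported as conflicts.

## Why the sample reference lives on the count scale

Step 5 deliberately feeds *raw counts* (equivalently, the per-total-RNA CPM,
which differs only by a constant) rather than each mode's own CPM. A mode's
stable genes are, by construction, flat in that mode's own CPM; max-scaling
flat profiles would give every mode the same near-constant reference, the
between-mode ratio analysis would be identically 1, and the three DE analyses
would collapse into one. On the common count scale the stable genes do the
work they are selected for: their count profiles track the mode's effective
denominator per sample, so the log reference is exactly the offset that
expresses counts in that mode's viewpoint. This is also the only reading
under which offsets are "mode-specific" in any meaningful sense.

## The mixed models

**Gaussian LMM (screen).** For a single random intercept the REML criterion
is profiled down to one dimension, the variance ratio
\(\lambda = \sigma^2_b/\sigma^2_e\): for fixed \(\lambda\),
\(V^{-1}\) has a closed form per participant block and the GLS estimates and
profiled \(\hat\sigma^2_e\) follow directly. \(\lambda\) is optimized on the
log scale by bounded one-dimensional search (tolerance 1e-9) with the
boundary \(\lambda = 0\) evaluated explicitly and flagged; boundary fits
(ICC = 0) remain valid, maximally un-clustered candidates. t-values use the
REML standard errors with no small-sample df correction — they feed a fixed
screening threshold, not confidence statements. The fit agrees with `lme4`
to ~1e-6 and with a dense grid-search oracle to 1e-4 in \(\lambda\) (both
asserted in the test suite).

**NB GLMM (DE).** The marginal likelihood integrates the participant
intercept by adaptive Gauss–Hermite quadrature (default 5 nodes; 1 node is
the Laplace approximation; the suite checks that 15 nodes moves coefficients
by < 1e-3). Dispersion uses the \(\mu + \phi\mu^2\) convention and is
estimated jointly, as is \(\sigma_u\); both are profiled on the log scale
with box constraints. Starting values come from a Poisson GLM and moment
estimates; the optimizer (L-BFGS-B with cached forward-difference gradients)
restarts from three deterministic perturbations on failure, and the optimum
is polished by full Newton steps so structural identities — adding a
constant to the offset shifts only the intercept, exactly — hold to ~1e-7.
Standard errors come from the inverse observed information; p-values are
two-sided normal tails. Wald rather than likelihood-ratio tests are a
documented limitation: with 25 participants they are mildly liberal at worst
(the suite checks empirical type-I error at nominal 5% stays within
[0.03, 0.07]). All-zero genes are flagged degenerate and reported as
non-significant rather than dropped, and a gene that fails in any mode is
set non-significant in all modes so no "unique" call can be a fitting
artifact.

**TMM.** The trimmed mean of M-values is implemented from scratch following
the original algorithm: reference = sample whose upper-quartile proportion is
closest to the mean; per sample, gene-wise M and A over genes expressed in
both; double trimming (30% on M, 5% on A, rank-based); inverse
asymptotic-variance weights; factors anchored to geometric mean 1. It matches
an independently coded step-by-step oracle to 1e-10 and `edgeR` to 1e-8 on
random matrices.

## The synthetic study

Real data for this design (human biopsies) are restricted, so the package
ships a generator whose defaults *are* the study conditions: 25 participants,
two legs (low/moderate volume, treated as replicates; an optional volume
effect, default 0, gives the screen a real target when wanted), biopsies at
weeks 0/2/12, 1000 ng fixed total-RNA input, total RNA per mg rising 27% at
week 2 and 17% at week 12.

The generative model is compositional with a fixed input:

* per-mg abundance \(T_{gs} = \exp(\alpha_g + u_{g,p(s)} + \delta_{g,t(s)})\),
  with gene-wise baseline \(\alpha_g\), participant intercepts
  \(u_{g,p} \sim N(0, \sigma^2_{u,g})\) and per-mg log fold-changes
  \(\delta_{g,t}\);
* mRNA pool per mg \(M_s = \sum_g T_{gs}\); total-RNA yield per mg
  \(Y_s \propto A_t \eta_s\) with log-normal noise \(\eta_s\);
* recorded tissue mass \(mg_s = mg^{base}_s / (A_t \eta_s)\): with a fixed
  RNA input, higher yield means less tissue used — an observed feature of the
  emulated study;
* library size \(L_s = D_s\, M_s/(A_t \eta_s M_{ref})\): the sequenced depth
  tracks the mRNA fraction of the fixed input (library molarity), which is
  why library sizes rise with training despite less tissue;
* expected counts \(\mu_{gs} = L_s T_{gs}/M_s\) (so \(\sum_g \mu_{gs} = L_s\)
  exactly), counts \(\sim\) NB\((\mu, \phi_g)\).

Two couplings above (tissue mass inversely tracking yield; depth tracking
the mRNA fraction) are what make the three viewpoints *measurably* distinct:
without them, dividing counts by mg or by a constant would differ from the
library-size viewpoint only by noise.

Gene classes encode each viewpoint's ground truth. `tissue_stable` genes
have \(\delta = 0\) (constant per mg). `totalrna_stable` genes track total
RNA (\(\delta = \log A_t\)). `library_stable` genes keep a constant pool
share (\(\delta = \log G_t\), where \(G_t\) is the mRNA-pool amplification).
`de` genes draw independent per-time effects
(\(\delta \sim N(0, 0.5^2)\)), and background genes follow the pool
(\(\log G_t\) plus per-gene wobble, sd 0.15), which is what *makes* the pool
grow by \(G_t\). The designated stable classes draw their participant sd
from a higher range (0.3–0.5 vs 0.05–0.2) — being a high-ICC gene is part of
what "stable reference gene" means, and gene-wise (not shared) intercept
scales keep the ICC ranking non-degenerate.

**Choice of \(G_t\).** The mRNA amplification defaults to (1, 1.6, 1.4),
above the total-RNA amplification (1, 1.27, 1.17). The direction is dictated
by the emulated study's own observations — its library-size-stable genes
*rose* when expressed per total RNA, which requires the pool to outgrow
total RNA — and the magnitude is chosen to separate the three stable classes
cleanly at the default noise level. With \(G_t = A_t\) the per-library and
per-total-RNA viewpoints would be statistically indistinguishable and the
design would degenerate to two viewpoints.

Remaining defaults are desk-scale choices of realism: 2000 genes; log-normal
depth (median 5M reads, sdlog 0.2); log-normal baseline tissue requirement
(median 25 mg, sdlog 0.1); baseline log-abundance \(N(4, 1.2^2)\);
dispersion log-normal around 0.02 (sdlog 0.4) — modest, because participant
heterogeneity is modeled separately by the random intercept; yield noise
sdlog 0.15. Gene-class fractions are 5% per stable class and 10% DE, i.e.
100 designated stable genes per viewpoint among 2000.

**What the generator does not emulate.** No read-level process (no FASTQ,
alignment or multi-mapping), no isoforms, no rRNA-depletion variability, no
batch structure, no correlation between genes beyond the shared pool, and
gene classes are cleanly separated rather than a continuum. Passing tests on
this generator demonstrate that the pipeline recovers the truth of the
mechanism it encodes — amplification made invisible by compositional
normalization — not that any particular real dataset satisfies that
mechanism.

## Numerical and design notes

* **Where the \(10^6\) sits** in the denominators is a convention; a config
  switch (`million_scale`) restores CPM magnitude, and the scale-invariance
  of all downstream statistics is asserted numerically in the suite.
* **Per-total-RNA and depth.** The paper-literal reading divides by a
  constant only, i.e. raw counts stand for abundance per unit total RNA
  (reads track library molarity). An optional `totalrna_depth_rescale`
  config divides by relative library size instead; default off.
* **Reference ratios** are reported both as per-time levels and as changes
  vs baseline (Wald 95% CIs on the log scale from the same random-intercept
  LMM). The level of a ratio of max-scaled references carries an arbitrary
  scale; the baseline-relative change is the quantity with a clean
  interpretation (global amplification) and is what the ratio panel shows.
* **Fewer than k survivors** of the screen: proceed with all survivors plus
  a prominent warning; zero survivors is an error suggesting the threshold.
* **BH families**: adjustment is applied per time contrast across genes;
  week-2 and week-12 calls are separate families, matching per-contrast
  reporting of the overlap panel.
* **Degenerate inputs**: all-zero samples error in `library_sizes()`;
  all-zero genes are flagged, excluded from references with a warning, and
  never silently dropped from DE results; a zero-variance log ratio yields
  fold-change 1 with a degenerate CI rather than an unstable fit.
* **Problem sizes in the shipped checks**: the full-scale shared run uses
  the default 2000-gene study (≈1200 stable-candidate fits per mode and
  ≈1900 NB-GLMM fits per mode); calibration studies use 500 genes; oracle
  comparisons use 100 random instances each. These sizes give Monte-Carlo
  error comfortably below every asserted margin while keeping a full run in
  the minutes range on a single core.

## Known limitations

* Wald inference with 25 participants is approximate; no small-sample df or
  Kenward–Roger-style correction is applied anywhere.
* Dispersion is estimated per gene with no shrinkage across genes (no
  empirical Bayes, no quasi-likelihood), so very-low-count genes have noisy
  \(\hat\phi\).
* A single participant random intercept: no leg-level random effect and no
  heteroscedastic residuals (the screen treats legs as exchangeable
  replicates by design).
* The stability screen's design (with volume and interactions) and the
  t-value convention (no df correction) are configurable because the
  procedure they implement is a screening heuristic, not an inferential
  contract.
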