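---
title: "From F2 intercross to candidate causal variant: the crossfsv workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From F2 intercross to candidate causal variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crossfsv)
```

# The problem

Crosses between divergent pig breeds — a Western commercial line and an
Asian native breed — segregate large-effect variants for meat-quality
traits such as reddish meat colour (a\*) and intramuscular fat (IMF).
Finding the causal regulatory variant behind such a QTL requires a chain
of analyses, each narrowing the candidate space: genome-wide association
on a SNP chip, linkage and haplotype-based mapping with support
intervals, intersection of intervals across independent crosses,
segregation analysis of individual F1 sires, a filter cascade over
sequence variants in the critical region, and Bayesian fine-mapping with
colocalization across the two traits.  `crossfsv` implements that whole
chain as tested, reusable functions, together with a synthetic-data
generator that plants a known causal variant so every stage can be
validated against truth.

# The synthetic study design

`cross_config()` + `simulate_cross()` emulate a two-generation intercross:
F0 sires of breed A (Western-like) mated to F0 dams of breed B
(native-like), F1 intercrossed to a large F2 cohort.  The defaults are the
package's study conditions:

* **Design sizes.** 17 F0 sires x 19 F0 dams, 40 F1, and an `n_f2` chosen
  per analysis (the drivers use 1,000 for the large cross and 380 for the
  replication cross, emulating cohorts of ~1,100 and ~380 F2 animals).
* **Marker panel.** `build_genetic_map()` places evenly spaced markers
  (1–2 cM) with physical positions near 1 Mb/cM, a desk-scale stand-in
  for a 60K chip.  Founder allele frequencies at chip markers differ
  between breeds by 0.6 on average (`freq_divergence`), mimicking
  divergent breeds.
* **The QTL.** One biallelic locus, snapped to a marker position and
  mirrored in the sequence-variant panel as a 6-bp promoter deletion.
  The high allele Q is absent in breed A and, by default, fixed in breed
  B.  The real native breed segregates the high allele at intermediate
  frequency; the default plants a fixed line difference because that is
  the identifying assumption of line-cross mapping — the contract the
  mapping modules are tested against.  `qtl_freq_Q` exposes the weaker
  setting, and `sire_qtl` conditions the F1 males' QTL genotypes (by
  fixing their founder dams' genotypes, so Mendelian consistency is
  preserved) to reproduce a required segregating/nonsegregating sire
  composition such as 8 het / 4 hom.
* **Trait model.** Two traits,
  y = mu + sex + batch + beta·carcass_weight + a·x_add + d·x_dom + u + e,
  with x_add in {-1, 0, 1}, x_dom in {0, 1, 0}; u is drawn from
  N(0, A·sigma_g2) over the full pedigree (A from the tabular method); e
  is bivariate normal with residual correlation 0.35 between the two
  traits (a moderate phenotypic correlation between colour and fat
  traits).  Defaults a = 1, d = 0.2 (mostly additive), sigma_g2 = 0.6,
  sigma_e2 = 0.93 put the QTL variance (0.5·a² + 0.25·d² = 0.51) at 25%
  of the phenotypic variance (2.04) — the calibration target for the
  recovery analyses; cohort-scale %Var values from real animals are not
  desk-available, so this share is a design choice, not a reproduced
  quantity.
* **Meiosis.** Interference-free: each inter-marker interval recombines
  independently with the Kosambi fraction r = tanh(2m)/2 of its map
  distance, and chromosomes restart on a random strand.  Marker-pair
  recombination fractions therefore match the Kosambi map distances,
  which is all the two-marker analyses consume.
* **Covariate assignment.** Sexes alternate and batches cycle in pairs so
  the fixed-effect design is full-rank at any n; dams are assigned to
  offspring randomly (seeded).  An earlier deterministic dam cycle
  aliased with the batch cycle and visibly biased the REML variance
  components — a useful reminder that "balanced" periodic designs can
  confound.
* **Phase.** Haplotypes and their founder-breed origins are carried as
  truth.  The haplotype-based modules read this phase directly; rule-based
  trio phasing was not implemented because the generator provides phase
  and phasing itself is not part of the inference chain under test.

The sequence-variant panel (`simulate_variant_panel()`) holds founder and
F1-sire genotypes over a ~488-kb window around the QTL: multi-allelic
decoys (10%), random biallelic variants (resampled if they accidentally
match the sire segregation pattern, so stage counts are exact), a chosen
number of pattern-consistent decoys, and the planted causal deletion,
VCF-style (POS is the base before the deleted bases).  The motif track is
BED convention (0-based half-open) with one motif covering the deleted
span when `causal_in_motif = TRUE`.

# GRAMMAR association

`fit_polygenic()` fits y = Xb + u + e with u ~ N(0, A·sigma_g2) by REML:
a single eigendecomposition of A turns the likelihood into a
one-dimensional profile over h², maximized by a coarse grid plus
golden-section refinement (tolerance 1e-8).  Numerical choices: ties on a
flat profile resolve to the smallest h² (so identity kinship collapses
exactly to OLS), and the h² -> 0 boundary is preferred whenever it is not
beaten by the interior optimum.  `grammar_scan()` then regresses the
residuals y - Xb - u on each marker's minor-allele count; monomorphic
markers are flagged with effect 0 and p = 1; missing genotypes are
dropped per marker.

Two deliberate scale decisions:

* **Effects at top markers.** GRAMMAR residual regression deflates effect
  sizes (part of the QTL signal is absorbed by the polygenic BLUP), so
  `gls_marker_effect()` provides the standard measured-genotype estimate:
  the marker refitted as a fixed covariate in the mixed model at the
  fitted variance ratio.  Scanning uses GRAMMAR p-values; reporting uses
  GLS effects.
* **%Var_SNP.** The formula 100·2p(1-p)a²/sigma_g2 divides by the additive
  genetic variance.  In a fixed-line-difference F2, all F1 parents are
  Qq, the locus has no between-family variance, and pedigree REML cannot
  allocate its variance to the kinship term; the no-SNP sigma_g2 estimate
  is therefore polygenic-only.  The workflow reconstructs the total
  additive variance as sigma_g2(polygenic) + 2p(1-p)a²(GLS) before
  applying the formula.  Under the default design the target value is
  0.5/1.1 = 45.5% — the QTL's share of additive genetic variance — which
  is a different denominator from %Var_QTL's phenotypic share (25%); the
  two are reported side by side, not reconciled.

`significance_thresholds()` implements Bonferroni (alpha/n) and
suggestive (1/n) thresholds; with the two printed chip panel sizes these
give 1.23e-6 / 2.46e-5 and 1.25e-6 / 2.50e-5, and -log10 thresholds of
5.91 and 5.90 (the published figure legends print 5.90; the first panel's
count gives 5.91 at two decimals, an inconsistency of the printed
rounding, not of the arithmetic).  Bonferroni-adjusted per-marker
p-values are reported as p·n capped at 1.  `genomic_inflation()` is the
median association chi-square over 0.4549; on a genome scan containing
the planted QTL lambda is far above 1 (true signal plus linkage), so the
null calibration is checked on polygenic-only traits against unlinked
markers, where GRAMMAR is known to be slightly conservative.

# Haley–Knott linkage and MASA

`line_cross_probabilities()` computes, per phased haplotype, the
probability of breed-B origin at a position by Markov interpolation
between the two flanking markers with known origin (transition
probability = Kosambi recombination fraction).  This two-marker
conditioning, rather than full multipoint hidden-state computation, is an
approximation that is essentially exact at chip density.
`line_cross_scan()` regresses the trait on covariates plus the additive
(p_QQ - p_qq) and dominance (p_Qq) coefficients; F compares full against
covariates-only, and %Var_QTL = 100·(RSS_reduced - RSS_full)/RSS_reduced.

`permutation_thresholds()` shuffles covariate-adjusted residuals and
records the maximum scan statistic per permutation.  Because the
permuted statistic is computed on residualized coefficients, the
observed maximum is returned on the same scale, keeping the empirical
test exact under exchangeability of residuals.  Quantiles use the
lower-tail-exact type-1 definition so alpha = 1 returns the smallest
permuted maximum.

`halfsib_family_scan()` works within one sire family, regressing the
trait on the paternal transmission probability.  `masa_genotype_sires()`
turns this into a QTL-genotype call per sire: the log10 likelihood ratio
of a fixed paternal substitution effect (the GLS estimate from the
across-family analysis; either sign, because sire haplotype phase is
arbitrary) against zero effect, with the maternal transmission
probability fitted as a nuisance covariate so the dam-transmitted allele
does not inflate the family residual.  Calls follow the ±2 rule:
heterozygous above +2, homozygous below -2, undetermined between.  The
published rule as printed ("homozygous if score > -2") contradicts its
own undetermined band and is implemented as < -2.  At 80 offspring per
family the expected scores sit near ±3: most sires are called, a
minority is left undetermined, and wrong-direction calls require a ~3
standard deviation accident — rare but not impossible, which is why the
filter cascade treats undetermined sires as unconstraining.

# LALD: founder-haplotype clusters

`assign_haplotype_clusters()` groups phased haplotypes that are identical
over a window (default 5 markers) centred at the scan position, merging
the smallest clusters into their Hamming-nearest neighbour when more
than K = 20 remain.  This window-identity clustering replaces
HMM-based phasing/clustering software: the inference target — up to K
founder-haplotype groups whose fitted effects separate into two modes
under a biallelic QTL — is preserved, while HMM re-implementation stays
out of scope.

`lald_scan()` first absorbs fixed covariates and the pedigree polygenic
effect with the GRAMMAR fit, then models the adjusted trait per position
with i.i.d. random cluster effects, h ~ N(0, sigma_h2·I).  Fitting uses
the low-rank structure of the cluster design (K <= 20), so each position
costs a K-dimensional eigendecomposition and a one-dimensional REML
profile; LOD is the log10 REML likelihood ratio against the no-cluster
model (fixed effects identical, so REML ratios are valid).  Absorbing
the polygenic term once, rather than refitting a three-component model
per position, is the package's design choice; it is exact under the
null and slightly conservative near the QTL.  With
`cofactor_position` set, the cluster indicators at that position enter
as fixed effects — the conditional scan that should show no residual
signal once the true QTL is accounted for.

`lod_drop_interval()` walks outward from the argmax while the LOD stays
within `drop` units of the maximum, reporting marker-resolution bp
endpoints (no interpolation; boundaries are at scanned positions).  The
contiguous-walk convention was chosen over "outermost position anywhere
above the threshold"; for unimodal profiles they coincide.  The default
drop is the conservative 2; 3 is conventional for larger cohorts.
`intersect_intervals()` implements [max(starts), min(ends)] with
length_kb = (end - start + 1)/1000 rounded to 0.1 — the arithmetic that
reproduces the published 718.4 / 858.6 / 488.1-kb intervals from their
printed coordinates.

`haplotype_effect_bimodality()` splits the fitted cluster effects by
exact one-dimensional 2-means and measures |mean1 - mean2| / pooled
within-cluster SD.  A 2-means split of a single Gaussian yields
separations near 2.6 on average with a spread that depends on the number
of effects, so a fixed small cutoff misclassifies unimodal samples; the
verdict is instead calibrated against the separation distribution of
standard-normal samples of the same size (deterministic parametric
bootstrap, level 0.05).  A fixed `threshold` can still be supplied; BLUP
shrinkage compresses real-data separations, so fixtures that want the
classic 2-SD rule can ask for it explicitly.

# The variant-filter cascade

Four stages, each a set operation with recorded counts:

1. **Biallelic** — exactly two alleles observed across founders and
   sires (a bimodal haplotype-effect distribution implies a biallelic
   causal variant).
2. **Segregation pattern** — heterozygous in every heterozygous-called
   sire, homozygous in every homozygous-called sire; undetermined sires
   impose no constraint; a missing sire genotype fails the variant
   (conservative, since a true FSV should be typed in all sires).
3. **Cross intersection** — present by position, REF and ALT in both
   crosses' candidate sets.
4. **Motif overlap** — the affected span intersects a motif interval;
   SNPs occupy POS, deletions the deleted bases POS+1 .. POS+len(REF)-1.

Counts are monotone non-increasing, stages 1–2 commute, and with
error-free genotypes the planted variant survives by construction — the
end-to-end test asserts it is the *only* survivor on the default
two-cross fixture.

# Bayesian fine-mapping

`caviar_posteriors()` models the Z-score vector as N(0, Sigma +
sigma²·Sigma·I_c·Sigma) for each causal configuration c up to size k,
with prior gamma^|c|(1-gamma)^(m-|c|), enumerated exhaustively (null
configuration included) and accumulated in log space with
max-subtraction.  Priors gamma = 0.01, NCP scale sigma = 5.2 and k = 2
are the reference defaults of the summary-statistic fine-mapping
literature, not values stated by the study; all are arguments.
Correctness is pinned by an independent brute-force enumeration over all
2^m configurations for m <= 10 (agreement to 1e-10).

`credible_set()` grows the set greedily by PIP (ties by position) until
the posterior mass of configurations fully contained in the set reaches
rho; this configuration-mass rule, not the naive PIP sum, is what makes
the set a credible set of causal *configurations*.  `clpp()` multiplies
the two traits' PIPs per variant; with both traits driven by the same
planted variant, its CLPP approaches 1 while LD neighbours are
suppressed.  LD comes from `compute_ld()` (pairwise-complete Pearson
correlation of genotype codes, monomorphic variants dropped, epsilon
ridge if not PSD).

# Diversity diagnostics

`nucleotide_diversity()` uses the per-site effective-sample-size
estimator pi = sum_i [n_i/(n_i-1)]·2p_i(1-p_i) / L over callable length
L, which equals the average pairwise difference exactly when no data are
missing (the test oracle).  `tajimas_d()` evaluates the classic
constants at n* = the rounded mean per-site called-allele count — a
pragmatic missing-data adjustment; exact per-site weighting of the
variance constants is a possible extension.  S = 0 raises an explicit
error rather than returning 0.  Indels are excluded; sites are SNPs.
On chip-ascertained markers D is strongly positive by construction
(common alleles are over-sampled), so the drivers label that output a
diagnostic, not an estimate of selection.

# What the passing tests do and do not show

The generator produces error-free, completely typed, truth-phased
genotypes; one biallelic QTL; no selection, drift, genotyping error,
imputation uncertainty, or X chromosome.  Passing recovery tests
therefore demonstrate that the inference chain is correct under its own
assumptions — they do not certify performance on real data with phasing
error, relatedness misspecification, or multiple linked QTL.  The
printed-arithmetic checks (interval lengths, thresholds) are exact
reproductions; cohort-level biological quantities (real %Var values,
allele frequencies across breed panels, resequencing pi and Tajima's D)
derive from animal data that is not desk-available and are not
reproduced.

Problem sizes used by the test suite and acceptance script: two
chromosomes x 70 markers at 1 cM for recovery (n_F2 = 1,000, 10 seeds),
one chromosome x 40 markers for MASA (12 sires x 80 offspring), 200
regions of 30 variants for credible-set coverage, 2,000 unlinked markers
for null calibration, and 200-permutation thresholds over 60–100 null
replicates.  These sizes were chosen so the full chain exercises every
code path at stable statistical power.

# Known limitations

* Line-cross machinery assumes a fixed (or near-fixed) allele difference
  between founder breeds; at intermediate native-breed frequencies the
  origin-based contrasts attenuate, as the frequency parameter lets you
  demonstrate.
* The LALD scan absorbs the polygenic term before fitting cluster
  effects instead of refitting both variance components jointly.
* Exhaustive configuration enumeration caps the practical region size
  (m choose k up to ~1e6 configurations); no stochastic search.
* The missing-data Tajima's D uses a single effective n rather than
  per-site variance weighting.
* PED/MAP, VCF and BED support is the minimal dialect these analyses
  need (GT-only VCF, no BCF/PLINK-binary).
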