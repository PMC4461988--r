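---
title: "Modelling the genetic load of complementary sex determination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the genetic load of complementary sex determination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdload)
```

## The model

Haplodiploid Hymenoptera produce males from unfertilized (haploid) eggs
and females from fertilized (diploid) eggs. Under complementary sex
determination (CSD), a diploid egg homozygous at the sex locus — at
*every* sex locus, when there are two — develops as a male. Diploid
males are usually sterile or produce sterile triploid offspring, so a
population paying this cost carries a genetic load that grows with the
frequency of "matched" matings, in which the father's sex allele(s)
also occur in the mother's genotype.

`csdload` models the proportion of diploids that develop as males (DMP)
as a function of four quantities: the number of sex loci (1 or 2), the
number of equally frequent sex alleles per locus (*k*, and *l* for the
second locus), the sibmating rate α, and the developmental survival of
diploid males relative to females (default 1).

**Sibmating and inbreeding.** A population in which a proportion α of
matings are between full siblings equilibrates at inbreeding
coefficient F = α / (4 − 3α); `sibmating_from_fis()` inverts this to
α = 4F / (3F + 1), the field estimator applied to an observed F_IS.
Negative F_IS values (heterozygote excess) carry no sibmating signal
and are floored at α = 0 with a warning. We verified the equilibrium by
an independent derivation: writing F for a female's identity by descent
and γ for the coancestry of mated pairs, full-sib mating in
haplodiploids gives F′ = (1 + F_mother)/4 + γ/2, whose fixed point
under partial sibmating is exactly α / (4 − 3α); the individual-based
simulator below reproduces the pure-sibmating trajectory
1/4, 3/8, 1/2, … without any tuning.

**Single-locus CSD.** Random matings are matched with probability
θ = 2/k; half of sibmatings are matched regardless of allele diversity;
matched matings yield 50% diploid males among diploids. Hence
DMP = 0.25·α + (1 − α)/k (`dmp_sl()`).

**Two-locus CSD.** Viable females are heterozygous at one or both loci.
With equal allele frequencies, the female genotype classes among
viable diploids have frequencies proportional to
(1 − 1/k)(1 − 1/l), (1/k)(1 − 1/l) and (1 − 1/k)(1/l), normalized by
1 − 1/(kl) because the double-homozygous class develops male. This
viability conditioning is required for the class frequencies to sum to
one among females and is what reproduces the published consistency
range of 9–20 alleles; an unconditioned reading shifts the band.
A male matches a heterozygous locus with probability 2/alleles and a
homozygous locus with probability 1/alleles; matings matched at both
loci yield 25% diploid males with double-heterozygous mothers and 50%
with single-locus-homozygous mothers. Sibmatings are matched with
probability 1/4 (double-het mothers) or 1/2 (homozygous mothers).
`dmp_2l()` assembles these pieces; `enumerate_mating_table()` builds
the complete female-class × match-pattern distribution and its expected
DMP agrees with the closed forms to 1e−12 — the table, not the formula,
is the package's ground truth.

**Survival adjustment.** When diploid-male survival s < 1, the male
share among surviving diploids is s·m / (s·m + 1 − m), where m is the
conceived fraction. The default s = 1 reflects laboratory evidence of
high diploid-male viability in the motivating system; the adjustment is
an extension, off by default, and it breaks the affinity of DMP in α,
which is why prediction bands are only computed analytically at s = 1.

```{r headline}
dmp_sl(0.081, 100)
consistent_allele_range(dmp_obs = 0.014, alpha_low = 0, alpha_high = 0.151)
```

Because DMP is affine in α at s = 1, the band over an α interval is
spanned by its endpoints (`dmp_band()`); containment of an observed DMP
is tested inclusively, and the default allele grid is 3–100 with k = l
imposed under the two-locus model.

## Simulators and what they check

Two stochastic layers sit beneath the closed forms.

`simulate_matings()` in *paper-conditional* mode is a Monte-Carlo
rendering of the enumeration table. In *pedigree* mode it builds each
sibmating explicitly — grandmother × grandfather, then a viable
daughter mated to a brother drawn uniformly from the maternal
haplotypes. The sibling pair is drawn by conditional sampling from the
idealized large sibship (a redraw-until-viable scheme, equivalent to
rejecting inviable daughters in a finite brood). Pedigree mode exposes
a known internal tension of the two-locus closed form: a female
homozygous at one locus *because her heterozygous mother mated a
matched male* has sib-matched rate 1/4, not the 1/2 the formula assumes
for homozygous females (her homozygosity says nothing about her
brothers). The simulator reports the realized rate; it never corrects
the closed form, which is implemented exactly as stated.

`simulate_generations()` is an individual-based, discrete-generation
population model: each female lays a fixed brood (default 10 eggs,
fertilization probability 0.5 — the observed field sex ratio near 0.5
motivates the default, but the primary sex ratio is a free parameter,
not a modelled quantity), diploid males are removed from the breeding
pool, and each female mates one brother with probability α, else a
random male. Unlinked neutral biallelic loci track F_IS. Population
extinction (no daughters or no sons) truncates the series with a flag
rather than an error.

Two numerical caveats are documented rather than hidden. First, the
multilocus F_IS estimator (1 − ΣHo/ΣHe with unbiased gene diversity)
shows a small negative bias (≈ −0.002 at α = 0 with 500 females)
because breeding females are sampled from full sibships, so the
contemporary allele-frequency reference is itself computed from a
family-structured sample. Second, 10 generations suffice for the
equilibrium (the recursion converges in ~3), so longer runs only add
drift. Consequently the equilibrium check is framed predictively: over
20 seeds at 500 females × 10 generations the across-seed 95% interval
covers α/(4 − 3α), and the recovered α is within ±0.02 of truth.

## Field statistics

All estimators operate on a `genotype_matrix` (diploid calls, field and
region labels, missing calls as `NA`, never zero-coded).

- **F-statistics**: Weir–Cockerham variance components summed over
  alleles and loci; the combined estimates satisfy
  (1 − F_IT) = (1 − F_IS)(1 − F_ST) by construction. Confidence
  intervals are percentile bootstrap over loci (the CI method behind
  published F-statistic intervals of this kind is rarely stated;
  bootstrap-over-loci is the conventional choice). Per-locus groups
  with fewer than 2 genotyped individuals are dropped for that locus.
- **Pairwise F_ST**: same estimator per field pair, significance by
  permutation of individuals between the two fields with
  p = (exceedances + 1)/(permutations + 1).
- **AMOVA**: locus-by-locus, gene-copy level (each individual
  contributes two copies; distance 0/1 per locus), three strata
  (between regions, between fields within regions, within fields) with
  unequal-size nested-ANOVA coefficients. Degrees of freedom follow the
  sampling design (total 2N − 1; e.g. 3/4/270/277 for 139 individuals
  in 8 fields and 4 regions); missing calls reduce sums of squares but
  not the reported df.
- **Hardy–Weinberg**: the exact conditional test. Biallelic loci are
  enumerated outright; the general case runs a Markov chain over
  allele pairings (uniform stationary distribution over matchings,
  which *is* the exact conditional null) with the conventional
  1,000,000 post-dememorization steps after 100,000 dememorization
  steps as defaults; tests scale the chain down since the enumerated
  answer is exact anyway.
- **Linkage disequilibrium**: EM haplotype frequencies for unphased
  two-locus genotypes (only double heterozygotes are ambiguous; the
  implementation aggregates individuals into at most 9 genotype classes
  first, so cost is independent of sample size), likelihood ratio
  against the product of single-locus frequencies, and a permutation
  p-value (default 5 EM starts; the linkage-equilibrium start is always
  included, random restarts guard against local optima).
- **Locus filtering**: HWE-deviant loci are removed at a raw per-locus
  α = 0.05 by default — the multiple-testing correction is applied to
  the LD pair tests (sequential Bonferroni), mirroring the asymmetric
  treatment in the motivating study — then one random locus of each
  significant LD pair is excluded iteratively (seeded) until no pair
  remains. A provably minimal vertex-cover removal mode exists but is
  not the default, because the reference procedure was explicitly
  random.
- **SNP panel selection**: MAF floor 0.2, exclusion of both members of
  any pair within 50 bp on the same scaffold (1-based positions,
  absolute distance), at most two alleles, MAF bins
  (0.2,0.3]/(0.3,0.4]/(0.4,0.5] with quotas 20/40/40, quality-ranked,
  at most one SNP per scaffold across all bins.
- **DMP from ploidy counts**: diploid males / (diploid males +
  females); haploid and unknown-ploidy males never enter. The interval
  is Clopper–Pearson (exact, hence conservative), level 0.95 by
  default — the motivating study reports no interval for DMP, so the
  choice is ours and is stated here.

## Synthetic data: what it emulates, and what it does not

`gen_structured_genotypes()` draws ancestral frequencies uniform on
[0.2, 0.5], field frequencies from the Balding–Nichols Beta with
parameter F_ST, and genotypes with a within-field homozygote excess
F_IS; defaults copy the shape of the motivating study (4 regions × 2
fields × 17 females × 81 SNPs, F_ST 0.05, F_IS 0.02, 2.5% missing) so
study-scale simulations run in seconds. Balding–Nichols is the minimal
generative model consistent with a target F_ST — the real data assert
no generative model, so parameter-recovery tests on these draws
demonstrate estimator correctness, not that the real population is
Balding–Nichols. Likewise the generators produce unlinked loci, no
genotyping-error structure, and missingness completely at random;
passing tests say nothing about linked markers or informative
missingness. `gen_sibmating_genotypes()` instead uses the explicit
pedigree simulator, so its F_IS is genealogical, not injected.

`gen_ploidy_counts()` draws diploid-male counts binomially against the
female counts (so the pooled DMP estimator is centred on the requested
truth) and thins only the haploid male pool by the assay fraction;
diploid males are treated as confirmed. This matches the estimand —
DMP ignores haploid males by definition — and keeps the generator
consistent with its own recovery test.

## Interfaces and determinism

Genepop (2- or 3-digit codes, `POP` blocks) and a CSV dialect
(`id,region,field,<locus...>`, calls `A1/A2`, missing `./.`) round-trip
losslessly up to normalization. Every stochastic function requires a
seed; `run_csd_pipeline()` threads one seed through filtering,
bootstraps, permutations and predictions, and reruns are byte-identical.
Report writers round; all internal values are full precision.

## Known limitations

Equal sex-allele frequencies are assumed throughout (implied by
θ = 2/k); unequal frequencies, more than two sex loci, mate choice,
biased fertilization and multi-generation allele-frequency dynamics of
the sex loci are out of scope (the generation simulator tracks sex
allele survival empirically but the closed forms do not). The two-locus
sibmating conditionals are implemented as stated even where pedigree
logic shows the homozygous-female rate can be 1/4 rather than 1/2; the
discrepancy is quantified by the simulator and inflates the closed-form
DMP slightly for small k. Reproduction of published decimal values from
the original field dataset is best-effort: the exact estimator variants
and missing-data conventions of the original analysis software are not
fully documented.
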