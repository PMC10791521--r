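---
title: "Recombination-rate dynamics and signatures of selection: models and methods"
author: "recsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination-rate dynamics and signatures of selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`recsel` implements a comparative population-genomic analysis of how
recombination rate and its evolutionary dynamics shape genomic signatures of
selection, for a study design with two sister-species pairs (focal species A
and B, each with a closely related sister used for differentiation
estimates) plus a single haploid outgroup for variant polarization. Two
families of signatures are contrasted:

* **indirect selection** — the diversity-reducing effect of selection at
  linked neutral sites: selective sweep signatures (composite likelihood
  ratio scan) and differentiation islands (windowed Weir–Cockerham F~ST~
  peaks), both predicted to concentrate where recombination is low;
* **direct selection** — the efficacy of selection on coding sites
  themselves: π~N~/π~S~, d~N~/d~S~ and the adaptive substitution rate ω~a~,
  predicted by Hill–Robertson interference to vary with recombination rate.

Because the real whole-genome data are not consumable at desk scale, the
package ships a first-class synthetic-data generator that emulates the joint
structure the analysis assumes, with a truth table for every implanted
feature. All results in the test suite and the acceptance script are
computed on this synthetic system.

# Recombination aggregation and conservation classification

LD-based estimators deliver per-SNP-pair interval estimates of the
population-scaled recombination rate ρ = 4N~e~r per bp. `window_weighted_rho()`
aggregates these to windows (default 200 kb, fixed from coordinate 0,
trailing partial windows kept at true length) or gene spans, weighting each
interval by the bp it contributes inside the target so intervals spanning a
boundary are apportioned between neighbours. Windows covered on less than
20% of their length are set missing: sparse coverage makes the weighted mean
high-variance.

Conversion to pedigree scale uses cM/Mb = ρ/(4N~e~)·10^8^, with the
genome-wide N~e~ estimated by `estimate_genomewide_ne()` from 5 Mb windows
— the resolution at which LD-based and pedigree-based rates correlate
best — as mean(ρ)/(4·mean(pedigree rate in events/bp)), both means weighted
by covered bp.

`classify_rate_conservation()` standardizes the two species' rates, runs a
PCA on the two-column matrix and calls a window *conserved* when its PC2
score lies within one standard deviation of the PC2 mean; divergent windows
are sub-labelled by which species' standardized rate is higher. Under a
bivariate normal the conserved fraction is the normal 1-SD mass, 68.3%.
The function's default operates on raw standardized rates; the pipeline
passes `log10_transform = TRUE` because recombination landscapes are
log-normal — on the raw scale a halved rate in a low-ρ window is an
absolutely tiny difference and divergence recall collapses (we measured
recall ≈ 0.47 raw vs ≈ 1.0 on the log scale at the generator's default
noise). Both options are exposed; the choice is a property of the data
scale, not of the rule.

# Sweep scan

`sweep_site_spectrum()` implements the hard-sweep spectrum distortion: at
distance d from a completed sweep of intensity α, each of n sampled lineages
escapes with probability p~e~ = 1 − e^(−αd)^; escapees are a hypergeometric
subsample of a pre-sweep sample from the background spectrum, and all
non-escapees inherit the type of one additional background draw (the
sweeping haplotype). p~e~ = 1 returns the background unchanged; p~e~ = 0
forces a monomorphic sample.

`clr_scan()` tests every polarized variant position: the composite log
likelihood of the flanking variants' derived counts under the distorted
spectrum, maximized over α on 25 log-spaced values spanning
p~e~ ∈ [10^−4^, 0.9999] at the median inter-variant spacing plus
golden-section refinement, against the background-only likelihood,
Λ = 2(log CL(α̂) − log CL~0~), floored at zero since the background model is
a candidate. The likelihood conditions on the observable site classes
(derived copies 1..n, i.e. segregating or fixed-derived). Numerical
choices: the distorted spectrum is tabulated on a fixed p~e~ grid and
linearly interpolated; flanking variants where p~e~ ≥ 0.999 are skipped
(they contribute < 10^−3^ to Λ) and the horizon is additionally capped
(default 200 kb, 100 kb in the pipeline) for tractability.

Post-processing follows the study's rules exactly: maximal runs of
consecutive significant sites become regions; regions with fewer than two
significant sites or below one significant site per kb are discarded;
windows are flagged by ≥ 1 bp overlap. The significance threshold default,
46.25, is the background-selection-aware value imported by the study. At
desk scale (n = 20 haplotypes, ~1 variant per 400 bp) implanted sweeps reach
Λ ≈ 30–75, so region calls at that imported threshold are sporadic even
though localization of the Λ maximum is precise; the threshold is a
configurable input precisely because its calibration belongs to the data
scale it was simulated for.

# Differentiation peaks

`wc_fst_components()` computes the Weir & Cockerham (1984) two-population
variance components a (among populations), b (among individuals within
populations) and c (within individuals) per site from diploid genotypes and
observed heterozygosity; window F~ST~ is the ratio of sums Σa/Σ(a+b+c) over
polymorphic sites. F~ST~ is Z-transformed per chromosome (to absorb
chromosome-level differences in mean differentiation), smoothed with a
7-point cubic Savitzky–Golay filter (edges: the cubic is fitted to the
terminal 7 points and evaluated at the edge positions, so any cubic is
reproduced exactly everywhere; missing windows are dropped and the filter
runs on present-window order), and windows with smoothed Z > 2 are merged
into peaks. Peaks from the two species comparisons are classified *shared*
on any ≥ 1 bp overlap, otherwise unique to their comparison.

A practical detectability constraint follows from standardizing within
chromosomes: a k-window peak on a W-window chromosome can reach a smoothed
Z of at most about 0.9·sqrt((W−k)/k), so peaks must span several windows
(the study's islands stretch several hundred kb) and chromosomes should
contribute ≥ ~25 windows. The generator's default chromosome sizes and peak
widths respect this geometry.

`positional_peak_enrichment()` bins windows by relative position
min(distance to either end)/(chromosome length/2) — four equal bins, bin 1 =
ends — per chromosome class (macro/micro), and compares observed per-bin
peak fractions with circular permutations of the peak labels within
chromosomes (two-sided p, (1+k)/(1+N) convention).

# Coding statistics

`classify_degeneracy()` classes each coding position fourfold (all three
alternative bases synonymous), zerofold (none synonymous) or other, from the
standard genetic code, reverse-complement-consistent for minus-strand genes.
π per class is Σ 2p(1−p)·n/(n−1) over variants divided by the class's
callable sites; with the GC-conservative filter the numerator is restricted
to strong↔strong (C/G) and weak↔weak (A/T) variants — immune to GC-biased
gene conversion — while the denominator is unchanged.

`map_substitutions()` assigns substitutions to the focal branch by outgroup
parsimony on three aligned sequences (focal major-allele consensus, sister
clade, outgroup): the focal base must differ while the other two agree;
sites where all three differ are skipped. Counts are classified by
single-base codon comparison against the ancestral (majority) codon, and
mutational opportunities are enumerated per ancestral codon — each position
contributes its synonymous/nonsynonymous thirds, or, under the
GC-conservative filter, only its single complementary change (A↔T or C↔G),
keeping numerator and denominator on the same opportunity space. This
parsimony mapping replaces likelihood-based substitution mapping; at the
shallow divergences simulated here (≈ 0.05 synonymous substitutions per
site on the focal branch) multiple hits are rare and the recovered d~N~/d~S~
matches the generator's ω within a few percent. Genes with summed coding
exon length below 200 bp are excluded ("exon length" is read as summed
coding length; the alternative — shortest exon — is a stricter subset), and
the gene-set summary is mean(d~N~)/mean(d~S~), which is stable when many
genes have few substitutions.

`bin_genes()` ranks genes by recombination rate into equal-count terciles
(ties broken by genomic position for determinism) and splits each tercile at
the median functional density — the fraction of exon + conserved
non-coding-element bp in the surrounding 200 kb — into low/high halves.

# DFE, adaptive rate and gBGC

`expected_selected_sfs()` is the Poisson random field expectation:
E[count~i~] = θ·r~i~·∫ C(n,i)x^i^(1−x)^(n−i)^ H(x;γ) dx with
H(x;γ) = (1−e^(−γ(1−x))^)/(x(1−x)(1−e^(−γ)^)), H(x;0) = 1/x, γ = 4N~e~s
(semidominant). The integral uses composite Gauss–Legendre quadrature with
nodes geometrically refined towards both endpoints, stable and accurate for
γ from −10^5^ to +700 (the neutral case is exact to machine precision,
θ·r~i~/i).

`fit_dfe()` maximizes a Poisson likelihood over the selected-class mutation
scale and a gamma distribution of deleterious effects (mean and shape on the
4N~e~s scale; log-spaced support on [10^−4^, 10^5^] with ≥ 200 points and
tail masses on the boundary points), with per-frequency nuisance factors
r~i~ shared between the neutral and selected class to absorb demography and
polarization artefacts. The r~i~ are profiled analytically,
r~i~ = (neutral~i~+selected~i~)/(1/i + θ~s~S~i~), which replaces an explicit
two-epoch demographic model by the frequency-class correction it implies.
The DFE mean is intrinsically hard: the SFS only observes effects up to
γ ~ O(n), and the information bound at ~5·10^4^ SNVs gives SE(log mean) ≈
0.2 even with r known — accuracy claims about the mean are therefore made
on medians over seeded replicates, while the shape is tightly recovered
(±0.03 per replicate in our tests).

`adaptive_rate()` decomposes ω = d~N~/d~S~ into
ω~na~ = E~DFE~[γ/(1−e^(−γ)^)] (the expected relative fixation rate of
deleterious mutations, 1 at neutrality) and ω~a~ = ω − ω~na~, which may be
negative; α = ω~a~/ω.

`fit_gbgc()` fits a single conversion-bias coefficient B = 4N~e~b jointly
to the WS (γ = +B), SW (γ = −B) and GC-conservative (γ = 0) spectra of one
species and region class, with shared nuisance factors anchored by the
GC-conservative class. `gbgc_contrast()` reports ΔB = B~A~ − B~B~ per
window conservation class; if inferred rate divergence is real, the species
with the higher recombination rate in divergent windows shows the stronger
bias, giving ΔB(divergent-A-higher) > ΔB(conserved) > ΔB(divergent-B-higher).
This SFS-based check is independent of the LD information that produced the
rate classification.

# The synthetic study system

The generator is a pure function of its configuration (`sim_config()`),
seed included; identical configurations yield byte-identical datasets. Its
defaults define the study conditions:

* **genome**: four chromosomes (10, 7, 5.6, 4.8 Mb; two macro, two micro),
  200 kb windows; callable mask = chromosomes minus a few 5–20 kb gaps;
  µ = 4.6·10^−9^ and L = 95% of the genome give θ~0~ = 4µL exactly.
* **recombination**: shared AR(1) log-landscape (autocorrelation 0.7) around
  ρ = 0.037/bp with a positional trend — macrochromosomes reduced towards
  the centre, microchromosomes towards the ends; a Bernoulli(0.24) subset of
  windows is shifted by ±1.2 log units in one species (the study's 24%
  divergent windows); implanted differentiation peaks sit on reduced-ρ
  baselines in both species. Window landscapes are expanded to SNP-pair
  intervals with jittered breakpoints (mean 2 kb) and log-normal interval
  noise, so window aggregation is exercised across boundaries. The pedigree
  map is species B's landscape divided by 4N~e~ (N~e~ = 2·10^5^) with
  log-normal window noise.
* **variants**: per-window site density and within-pair drift couple to the
  focal species' relative recombination rate (exponent 0.6) — more
  diversity and less drift where recombination is high; baseline density
  1/400 bp (the real system is an order of magnitude denser); implanted
  peaks multiply drift intensity (Balding–Nichols F) in the affected
  pair(s); two shared, one A-unique and one B-unique peak spanning 3–4
  windows each, the micro-chromosome peaks near chromosome ends; three hard
  sweeps (α = 2·10^−5^), one inside a shared peak; near-sweep derived counts
  are drawn from the sweep spectrum of the pre-sweep segregating background;
  WS/SW frequencies are tilted on the logit scale in proportion to each
  species' local recombination rate (gBGC, baseline B = 1.5 at the mean
  rate); the outgroup is one haploid sequence carrying the ancestral allele
  at 97.5% of sites, so the three-group polarization rule is consistent at
  ≥ 95% of sites by construction. Samples: 10 diploids per focal species,
  5 per sister.
* **coding**: 300 non-overlapping genes (2–6 exons, 300–1800 coding bp);
  fourfold SFS drawn Poisson around the neutral PRF expectation, zerofold
  around the gamma-DFE expectation (mean 190, shape 0.4 on the 4N~e~s
  scale); branch substitutions implanted by proposal–acceptance (synonymous
  always, nonsynonymous with probability ω = 0.2), which makes the realized
  d~N~/d~S~ equal ω on the opportunity scale; conserved non-coding elements
  with variable density supply the functional-density axis. Coding variants
  are provided as per-gene polarized tables; the genome VCFs exercise the
  polarization path.

What the generator does **not** emulate: coalescent genealogies with
recombination (no linkage disequilibrium structure within windows — the
interval ρ values are landscape draws, not LD estimates), gene conversion
tracts, mutation-rate heterogeneity, shared ancestral polymorphism between
the species pairs (~2% in the real system), missing genotypes, or
alignment error. Passing tests therefore validate the estimators and their
couplings under the assumed generative structure, not robustness to those
real-data complications.

# Problem sizes and reproducibility

Desk-scale sizes are used throughout: the default pipeline run handles
~10^5^ variant sites and 300 genes in a few minutes on one core, with the
CLR scan dominating. The DFE-recovery experiment uses n = 130 haplotypes
(the larger focal sample of the study) and ~5·10^4^ SNVs; determinism
checks run on a 4 Mb two-chromosome configuration, since determinism is
configuration-independent. Every stochastic stage derives its stream from
the master seed via a fixed integer hash (`stage_seed()`), so any stage can
be re-run in isolation and reproduces its output exactly.

# Known limitations

* The sweep-region threshold imported from the real study (46.25) is not
  recalibrated for the synthetic scale; region calls at desk scale are
  conservative. Localization of the CLR maximum is accurate regardless.
* The parsimony substitution mapping underestimates divergence when
  multiple hits become common; it is intended for the shallow focal
  branches simulated here.
* The gamma-DFE mean is weakly identified from SFS data at realistic SNV
  counts (see above); treat single-fit means as order-of-magnitude.
* Peaks narrower than ~3 windows are attenuated below the calling threshold
  by the 7-point smoother; this mirrors the method, not a bug.
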