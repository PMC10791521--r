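# recsel

Comparative analysis of recombination-rate dynamics and genomic signatures
of selection in sister-species pairs.

## The problem

Recombination shapes genomic signatures of selection in two distinct ways.
*Indirect* selection — selective sweeps and background selection — removes
neutral diversity at linked sites, so sweep signatures and differentiation
islands (F<sub>ST</sub> peaks) concentrate where recombination is low.
*Direct* selection on coding sites is predicted by Hill–Robertson
interference to become less efficient where recombination is low, which
would leave π<sub>N</sub>/π<sub>S</sub> and d<sub>N</sub>/d<sub>S</sub>
negatively, and the adaptive substitution rate ω<sub>a</sub> positively,
correlated with recombination rate. Testing these predictions across
species requires recombination maps for *both* lineages, because the
landscape itself evolves: windows where the rate has diverged between
species dilute any single-species correlation.

`recsel` implements the full analysis for a design with two focal species
(A and B), their sister species (for pairwise F<sub>ST</sub>) and one
haploid outgroup (for polarization):

* interval-weighted aggregation of LD-based ρ = 4N<sub>e</sub>r estimates
  into 200 kb windows and gene spans; conversion to cM/Mb through a
  pedigree linkage map (`window_weighted_rho`, `estimate_genomewide_ne`,
  `convert_to_cm`);
* PCA classification of windows/genes into conserved vs divergent
  recombination rate, conserved = |PC2| within 1 SD
  (`classify_rate_conservation`);
* composite likelihood ratio sweep scan against the genome-wide background
  SFS with the hard-sweep escape model
  p<sub>e</sub> = 1 − e<sup>−αd</sup>, merged into sweep regions and
  per-window presence calls (`sweep_site_spectrum`, `clr_scan`,
  `merge_significant_sites`);
* windowed Weir–Cockerham F<sub>ST</sub>, per-chromosome Z-transform,
  7-point cubic Savitzky–Golay smoothing, peak calling at smoothed Z > 2,
  shared/lineage-specific classification and positional enrichment
  (`window_fst`, `smooth_zfst`, `call_fst_peaks`, `classify_peaks`);
* GC-conservative π<sub>N</sub>/π<sub>S</sub> on fourfold/zerofold sites,
  outgroup-parsimony substitution mapping, mean(d<sub>N</sub>)/mean(d<sub>S</sub>)
  aggregation with the <200 bp exon exclusion, and recombination ×
  functional-density gene bins (`classify_degeneracy`, `map_substitutions`,
  `aggregate_dnds`, `bin_genes`);
* Poisson random field fits: gamma DFE with per-frequency demographic
  nuisance factors, ω<sub>a</sub> = d<sub>N</sub>/d<sub>S</sub> −
  E<sub>DFE</sub>[γ/(1−e<sup>−γ</sup>)], and gBGC strength B = 4N<sub>e</sub>b
  from WS/SW/GC-conservative spectra with conserved/divergent contrasts
  (`expected_selected_sfs`, `fit_dfe`, `adaptive_rate`, `fit_gbgc`,
  `gbgc_contrast`);
* permutation and regression machinery for the summary grids
  (`permutation_diff_test`, `logistic_sweep_model`, `peak_category_table`).

A seeded synthetic-data generator (`sim_config`, `sim_dataset`,
`write_dataset`) emulates the whole data structure — autocorrelated
per-species recombination landscapes with a configurable divergent-window
fraction, diversity/differentiation coupled to recombination, implanted
sweeps and differentiation peaks, coding variation under a gamma DFE — and
writes standard formats (VCF 4.2, BED, TSV, FASTA, YAML manifest). The
methods vignette (`vignettes/methods.Rmd`) documents every model and
default.

## Worked example

```r
library(recsel)

cfg <- sim_config(seed = 1)          # default synthetic study system
cfg
#> sim_config: seed 1, 4 chromosomes (27.4 Mb), 200 kb windows
#>   theta0 = 4*mu*L = 0.479; rho_mean = 0.037; divergent fraction 0.24
#>   3 sweeps, 4 peaks, DFE (mean 190, shape 0.4), omega 0.2

bundle <- run_all(run_config(sim = cfg))
bundle$summaries$grid$fst_rho_A$R    # Spearman FST ~ recombination, species A
#> [1] -0.7864964
mean(bundle$windows$conservation != "conserved", na.rm = TRUE)
#> [1] 0.240876                       # fraction of divergent-rate windows
bundle$dfe$A$adaptive$omega_a        # adaptive substitution rate, species A
#> [1] 0.1175102
bundle$gbgc$contrast$ordering_ok     # gBGC tracks the rate divergence
#> [1] TRUE
```

The F<sub>ST</sub>–recombination Spearman correlation is strongly negative
(linked selection), 24% of windows carry divergent recombination rates
(the generator's truth fraction), ω<sub>a</sub> is recovered near its
implanted value ω − ω<sub>na</sub> ≈ 0.095, and the gBGC contrast orders
the species by their local recombination rate. Exact numbers vary with the
seed; the ones above are from seed 1.

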