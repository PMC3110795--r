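# strpop

Population-genetic analysis of diploid multi-allelic STR (microsatellite)
genotypes in two-species hybrid-zone settings — the situation exemplified by
African forest and savanna elephants, where two deeply diverged nuclear gene
pools meet in a narrow contact zone, hybrids are rare, and sex-biased
backcrossing has pushed one species' mitochondrial DNA far into the other's
range while the nuclear genomes stayed separate. The package is aimed at
population geneticists and wildlife-forensics researchers who need the full
chain from raw genotype tables to cluster assignments, trees and marker
panels, with every stage testable against a generator of known truth.

## What it computes

* **Bayesian admixture clustering** (`gibbs_admixture()`): the standard
  admixture model for multi-allelic loci — per-individual ancestry vectors
  *q<sub>i</sub>* ~ Dirichlet(α), per-cluster allele frequencies
  *p<sub>kl</sub>* ~ Dirichlet(λ), allele-copy origins *z* — fitted by Gibbs
  sampling, with optional inference of α, replicate-run label alignment
  (`align_cluster_labels()`), the model log-probability estimator
  L̂ = mean(ℓ) − var(ℓ)/2, and the Evanno second-difference statistic
  ΔK = mean<sub>r</sub>|L(K+1) − 2L(K) + L(K−1)| / sd<sub>r</sub> L(K) for
  choosing the number of clusters (`evanno_delta_k()`).
* **Ordination and trees**: factorial correspondence analysis of the
  0/1/2 allele-dosage table (`fca()`), Cavalli-Sforza chord distances
  d = √(2(1 − Σ√(p<sub>A</sub>p<sub>B</sub>))) combined over loci by RMS
  (`chord_distance()`), and neighbor-joining locale trees with
  negative-branch clamping (`neighbor_joining()`, `locale_tree()`).
* **Marker informativeness**: per-locus Shannon Information Content
  profiles SIC(m) = H(m·p₁ + (1−m)·p₂) − [m·H(p₁) + (1−m)·H(p₂)] in bits
  (`sic_profile()`), locus ranking (`rank_loci()`) and likelihood-based
  panel assignment accuracy (`evaluate_panel()`) for building
  geographic-assignment panels (e.g. ivory forensics).
* **Mito-nuclear concordance**: per-locale mtDNA clade frequencies,
  deviation of nuclear cluster means from the clade diagonal
  (`concordance_table()`), and an exact two-tailed habitat × clade-presence
  association test by hypergeometric enumeration (`fisher_exact_2x2()`,
  `habitat_association()`).
* **Locus QC**: Monte-Carlo exact Hardy–Weinberg test (Levene/Guo–Thompson
  statistic), Brookfield null-allele estimate (He − Ho)/(1 + He), and a
  permutation G-test linkage screen (`qc_report()`, `linkage_screen()`).
* **I/O**: STRUCTURE (two-row and two-column) and GenePop text dialects,
  TSV sample tables, and Allelogram-style fragment-size binning
  (`bin_alleles()`).
* **Synthetic data** (`simulate_dataset()`): two Balding–Nichols-drifted
  gene pools, locale structure (forest / savanna / mixed), constructed F1
  and backcross hybrids with exact (1/2)^(g+1) ancestry, F-clade mtDNA
  introgressed into ~20% of savanna individuals, and S-clade structurally
  absent from forest — with full ground truth for recovery tests.

The whole chain can be driven from a YAML/JSON config via `run_pipeline()`,
which writes every artifact plus a manifest with the config hash and seed;
`inst/cli/strpop.R` is a thin Rscript wrapper.

## Worked example

```r
library(strpop)

sim <- simulate_dataset(sim_config(seed = 1))
sim
#> str_sim: 460 individuals at 23 locales, 12 loci (seed 1)

est <- gibbs_admixture(sim$genotypes,
                       admixture_spec(K = 2, alpha = "infer",
                                      sweeps = 300, burnin = 100, seed = 2))
m <- mean_cluster_by_locale(est, sim$samples)
head(m[order(m$habitat), ], 8)
#>    locale habitat  n cluster1 cluster2
#> 1    FO01  forest 20  0.00297  0.99703
#> 2    FO02  forest 20  0.00384  0.99616
#> 3    FO03  forest 20  0.00407  0.99593
#> 4    FO04  forest 20  0.00358  0.99642
#> 5    FO05  forest 20  0.00840  0.99160
#> 23   MX01   mixed 20  0.15396  0.84604
#> 6    SV01 savanna 20  0.99605  0.00395
#> 7    SV02 savanna 20  0.99339  0.00661
```

Cluster labels are arbitrary; in this run cluster 2 tracks forest ancestry.
Forest and savanna locales partition almost completely (>99% mean
membership in their own cluster), while the mixed-habitat locale — the only
one holding constructed hybrids — shows 84.6% forest ancestry, the
hybrid-zone signature.

Ranking loci by information content for the forest/savanna comparison:

```r
f <- allele_freqs(sim$genotypes, sim$samples$individual_id[sim$samples$habitat == "forest"])
s <- allele_freqs(sim$genotypes, sim$samples$individual_id[sim$samples$habitat == "savanna"])
head(rank_loci(f, s), 4)
#>    locus m_star sic_star
#> 8    p08   0.51    0.870
#> 3    p03   0.51    0.804
#> 2    p02   0.50    0.716
#> 11   p11   0.48    0.697
```

The best locus carries 0.87 bits about an allele's species of origin near
the 50% mixture point; maxima sit near, but not exactly at, m = 0.5.

Mito-nuclear discordance shows up as an exact association between habitat
and S-clade presence, even though savanna locales vary freely in their
F-clade proportion:

```r
assoc <- habitat_association(clade_frequencies(sim$samples))
assoc$table
#>                forest other_or_mixed
#> S_present           0             17
#> S_not_detected      5              1
format(assoc$p, digits = 3)
#> [1] "0.000178"
```

No forest locale carries the savanna mtDNA clade — the structural signature
of one-way, female-mediated introgression.

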