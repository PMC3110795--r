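---
title: "Methods: STR population structure, marker informativeness and mito-nuclear concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STR population structure, marker informativeness and mito-nuclear concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and setting

`strpop` analyses diploid multi-allelic short tandem repeat (STR) genotypes
in a two-species hybrid-zone setting of the kind exemplified by African
forest and savanna elephants: two deeply diverged nuclear gene pools, a
narrow contact zone with rare hybrids, and sex-biased introgression that
leaves mitochondrial DNA geographically decoupled from the nuclear genome
(hybrid females backcross into one species, so their mtDNA clade persists
while the minor species' nuclear contribution halves every generation).
The package covers the full analysis chain — locus QC, Bayesian admixture
clustering with model choice, ordination, locale trees, marker-informativeness
ranking, and mito-nuclear concordance — and ships a synthetic-data generator
with known ground truth so every stage can be validated end to end.

```{r, eval = FALSE}
library(strpop)
sim <- simulate_dataset(sim_config(seed = 1))
```

# The admixture model and its Gibbs sampler

For $N$ diploid individuals typed at $L$ multi-allelic loci, the admixture
model assumes each individual $i$ has an ancestry vector
$q_i \sim \mathrm{Dirichlet}(\alpha, \ldots, \alpha)$ over $K$ clusters, and
each of the $2L$ allele copies $x_{ilc}$ independently picks an origin
$z_{ilc} \sim q_i$ and then an allele from that cluster's frequency vector
$p_{kl} \sim \mathrm{Dirichlet}(\lambda, \ldots, \lambda)$. `gibbs_admixture()`
cycles the standard conditional updates:

1. origins: $\Pr(z_{ilc} = k) \propto q_{ik}\, p_{kl,x_{ilc}}$;
2. frequencies: $p_{kl} \mid z \sim \mathrm{Dirichlet}(\lambda + \text{counts})$;
3. ancestries: $q_i \mid z \sim \mathrm{Dirichlet}(\alpha + \text{origin counts})$
   (admixture model), or one cluster label per individual (no-admixture
   model).

Missing calls are skipped in every count and in the likelihood. Posterior
means of $Q$ and $P$ are averaged over post-burn-in sweeps and the data
log-likelihood trace is retained. Cluster frequency priors are independent
across clusters; a correlated-frequencies variant is deliberately out of
scope.

Two additions matter in practice:

* **Alpha inference.** With `alpha = "infer"` the Dirichlet admixture
  parameter gets a Metropolis random-walk update (normal proposal,
  sd 0.025, uniform prior on $(0, 10]$, started at 1) — the customary
  configuration for this sampler family. A small posterior $\alpha$ says
  most genomes are unadmixed. The package default keeps $\alpha$ fixed at
  1.0 for transparency; inference is recommended whenever realistic data
  are analysed, because with $\alpha$ fixed at 1 the posterior mean
  ancestry of even a perfectly pure individual is bounded near
  $(2L + 1)/(2L + 2K)$ (about 0.96 at 12 loci), a prior artefact rather
  than a biological signal.
* **Cluster-transposition moves.** Each sweep proposes, per individual, a
  joint swap of two cluster labels in $(z_i, q_i)$. The symmetric Dirichlet
  prior and the $q$ factors cancel, leaving the allele-frequency likelihood
  ratio as the acceptance probability. For pure individuals the move is
  essentially always rejected; for genuinely admixed individuals it lets
  the chain hop between mirrored modes that the plain conditional updates
  traverse only slowly when $\alpha$ is small — without it a lone F1's
  chain can be absorbed near 0 or 1, because at tiny $\alpha$ a state in
  which every copy is assigned to one cluster is nearly absorbing.

Label switching across replicate runs is resolved by
`align_cluster_labels()`, which maximises the summed dot product of matched
$Q$ rows over all $K!$ permutations — exact for the small $K$ used here.

## Model choice by second differences

`estimate_log_prob_data()` turns a post-burn-in likelihood trace into
$\hat L = \overline{\ell} - \mathrm{var}(\ell)/2$, and `evanno_delta_k()`
forms, from replicate $\hat L$ values at consecutive $K$,
$\Delta K = \mathrm{mean}_r\,|L(K{+}1,r) - 2L(K,r) + L(K{-}1,r)| \,/\,
\mathrm{sd}_r\,L(K,r)$. The uppermost level of structure is the interior
$K$ at which $\Delta K$ peaks; boundary values are undefined, and a zero
replicate standard deviation is reported as an infinite $\Delta K$ with a
warning rather than silently dropped.

## Run lengths

Defaults are desk-scale: 300–500 sweeps with 100–200 burn-in. These are
package choices suited to the simulated problem sizes used throughout the
documentation (tens of individuals, ~12 loci); production-scale chains of
$10^6$ sweeps remain reachable through `admixture_spec()`. Replicate scans
(`admixture_scan()`) derive their seeds from one master seed so results are
reproducible run to run.

# Ordination and locale trees

`fca()` performs correspondence analysis of the individuals × alleles dosage
table (0/1/2 copies; missing calls contribute nothing): the chi-square-metric
SVD of $(P - rc^\top)/\sqrt{rc^\top}$ with standard row/column-mass
weighting. Reported coordinates are principal coordinates and axis inertia
percentages are eigenvalues over total inertia. Whether the original
genotype-ordination software weighted per allele or per locus is not
documented; the standard CA weighting is used here and validated against an
independent CA implementation in tests. Axis signs are fixed by forcing the
largest-magnitude coordinate positive, so output is reproducible.

`chord_distance()` implements, per locus,
$d_\ell = \sqrt{2\,(1 - \sum_j \sqrt{p_{Aj} p_{Bj}})}$ on the union allele
set, combined across loci as the root mean square. The classical $2/\pi$
angular normalisation is available via `angular = TRUE`; the unnormalised
form is the default because the variant actually used by the original
tooling is not documented. The distance satisfies symmetry and identity but
not, in general, the triangle inequality — it is used for tree building,
not metric embedding. Locales with no data at a locus are dropped pairwise.

`neighbor_joining()` delegates Saitou–Nei agglomeration to `ape::nj` and
then clamps any negative branch length to zero, shifting the deficit onto
the sister edge so path lengths through the parent are preserved. On
additive input the tree and all branch lengths are recovered exactly.

# Marker informativeness (SIC)

For a pair of populations with locus frequencies $p_1, p_2$ and a mixture
that draws an allele from population 1 with probability $m$,
`sic_profile()` computes the mutual information between an allele and its
population of origin, in bits:

$$\mathrm{SIC}(m) = H(m p_1 + (1-m) p_2) - [\,m H(p_1) + (1-m) H(p_2)\,],$$

with $H$ the base-2 Shannon entropy and $0 \log 0 := 0$. This is the
canonical "reduction in uncertainty" reading of information content and
reproduces the properties that matter for marker ranking: zero for
identical frequency vectors, a maximum near $m = 0.5$ that shifts when a
locus detects one population inside the other more effectively than the
reverse, concavity in $m$, and the centrality property (alleles rare in one
population but common in the other score high). The exact published routine
this mirrors lives in supplementary material that is not reproduced here,
and whether the original treats alleles or genotypes as the information
channel is not recoverable; the allele-level channel is used and stated as
an assumption. The default $m$ grid is 99 points at 0.01 spacing.

`rank_loci()` orders loci by maximum SIC (ties lexicographic; loci
monomorphic in both populations are retained at 0 bits so rankings cover
the whole panel), and `evaluate_panel()` scores a locus subset by
likelihood-based assignment under within-population Hardy–Weinberg, with
unseen-allele frequencies floored at $1/(2n+1)$ and ties broken at random
under a seed.

# Mito-nuclear concordance

`clade_frequencies()` summarises per-locale S-clade mtDNA proportions
(unknowns excluded from the denominator; a locale with no classified
individuals is missing, not zero). `concordance_table()` pairs each
locale's S-clade proportion with its mean savanna-cluster membership;
`deviation` is their difference, so a savanna locale fixed for introgressed
F-clade mtDNA with pure savanna nuclear genotypes scores the maximal
discordance $+1$. `habitat_association()` dichotomises locales as tropical
forest versus other-or-mixed (mixed groups with non-forest) and S-clade
present (at least one classified S individual) versus not detected, and
applies `fisher_exact_2x2()` — a log-gamma hypergeometric enumeration whose
two-tailed p sums all tables with probability at most the observed one's
(within $10^{-12}$ relative slack for floating-point ties). Counting
presence at locale level follows the mapping convention of the source
surveys; where those surveys mix locales and samples as counting units, the
locale-level reading is used and the ambiguity documented here.

# The synthetic-data generator

`simulate_dataset()` emulates the study design the analyses assume:

* **Design defaults.** 5 forest, 17 savanna and 1 mixed-habitat locale,
  20 individuals per locale; 12 loci with 2–20 alleles each. These mirror
  the sampling layout of the motivating continent-wide survey.
* **Divergence.** Two gene pools drift from a shared ancestral spectrum
  under the Balding–Nichols parameterisation: pool frequencies are
  Dirichlet draws with concentration $p\,(1-F)/F$, so `divergence_F` acts
  as an $F_{ST}$-like one-parameter control that is analytically checkable
  (the expected frequency is the ancestral one; the variance is
  $p(1-p)F$). The default 0.3 represents deeply diverged species-level
  pools, consistent with nuclear divergence on the order seen between the
  two elephant species.
* **Hybrids are constructed, not sampled.** A configured fraction of
  mixed-locale individuals (default 0.2) is made hybrid, cycling through
  F1 and backcross generations $g = 0..$`backcross_generations` (default 1).
  A backcross-$g$ individual has minor-species nuclear ancestry exactly
  $(1/2)^{g+1}$. Remaining mixed-locale individuals are pure forest, making
  the expected mixed-locale forest ancestry 0.875 — chosen to bracket, not
  match, the contact-zone value reported in the motivating study (90.8%),
  since no per-locale hybrid fraction is published. A separate
  `hybrid_fraction_savanna` flag (default 0) can place rare savanna-side
  hybrids.
* **Sex-biased mtDNA introgression.** Forest individuals and all
  hybrid-lineage descendants carry the F clade (maternal transmission along
  the backcrossing line); pure savanna individuals carry F with probability
  `savanna_Fclade_rate` (default 0.20, the reported introgression level)
  and S otherwise. No forest individual ever receives S — the structural
  constraint the habitat-association test should detect.
* **Missingness** is completely at random (default 2%), since no
  missingness mechanism is documented for the real data.
* **Reproducibility.** One master seed fans out into per-locale substreams
  via stable integer hashing (`derive_seed()`), so datasets are
  byte-identical across runs and partial regeneration is stable.

What the generator does *not* emulate: forward-in-time demography, linkage
between loci, allele-size mutation models, null alleles, or spatially
autocorrelated sampling. Tests passing on this generator therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to the messiness of field data.

# Locus QC

`hwe_exact_test()` is a Monte-Carlo exact test whose statistic is the
conditional probability of the genotype array given allele counts (the
Levene distribution, appropriate for sparse multi-allelic STR tables);
alleles are pooled and re-paired uniformly, and the p-value is add-one
corrected so it is never zero. `null_allele_estimate()` is the closed-form
homozygote-excess estimator $r = (H_e - H_o)/(1 + H_e)$, floored at zero —
the standard reading of "excess homozygosity" when only summary
heterozygosities are available. `linkage_test()` permutes one locus's
genotype column under a G statistic; degenerate tables return p = 1 with a
warning. QC results are *flagged, never silently applied*: excluding a
locus is the caller's decision, and the linkage screen reports raw and
Bonferroni-adjusted p side by side because the appropriate multiplicity
correction for this screen is a judgement call.

# Numerical choices and edge cases

* Probabilities that enter logs are floored at $10^{-300}$; hypergeometric
  and array probabilities are computed via `lgamma`/`lchoose` so counts in
  the hundreds stay exact.
* `bin_alleles()` fits the fragment-size ladder offset by exhaustive search
  on a 0.1-base grid (the published binning tool's exact algorithm is not
  documented; a transparent deterministic rule is used instead), and flags
  as unbinnable any size farther than half a motif from every rung — a
  defensive guard, since a full ladder always has a rung within half a
  motif.
* SIC values within $10^{-12}$ of zero are snapped to zero so identical
  profiles report exactly no information; chord cosines within $10^{-12}$
  of 1 likewise give exactly zero distance.
* Ties: SIC grid maxima break toward $m = 0.5$; locus rankings break
  lexicographically; assignment ties break uniformly at random under a
  seed.
* Missing sentinel conventions are dialect-exact: −9 in STRUCTURE files,
  zero-padded 00/000 in GenePop. Allele pairs are stored unordered (sorted)
  because phase is never used.

# Validation strategy and problem sizes

The test suite validates each stage against independent oracles: Dirichlet
moments for the drift model, full enumeration and `dhyper` brute force for
the exact test (all tables with $N \le 30$), an independent CA
implementation for FCA inertias, patristic-distance checks on additive
matrices for NJ, dense-grid maximisation for SIC optima, and ground-truth
recovery on generator output for the sampler (pure-individual mean absolute
error, F1 placement, and a $\Delta K$ peak at the true $K = 2$). Admixture
experiments use 30+30 individuals at 12 loci with 300-sweep chains — sizes
chosen so the full suite runs in minutes while keeping every comparison
informative. The F1-placement check is summarised by medians across five
independent experiments: the exact flat-prior posterior of a single F1's
ancestry given the true pool frequencies already scatters beyond
$0.5 \pm 0.15$ for roughly one data draw in ten at these conditions, so a
single-draw assertion would test the luck of the draw rather than the
sampler.

# Known limitations

* Only the independent-frequencies prior is implemented; the correlated
  (F-model) variant is out of scope.
* No linkage model, prior population information, or consensus-over-runs
  clustering beyond exhaustive label alignment.
* The chord/NJ stage reports no bootstrap support.
* Panel evaluation assumes within-population Hardy–Weinberg and
  independent loci — the same assumptions under which SIC ranks markers.
* Real-data quantities that require the unreleased genotype matrix of the
  motivating study (exact cluster percentages, FCA inertia values,
  locale-specific partitions) are deliberately not reproduced; the package
  validates the corresponding *patterns* on synthetic data instead.
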