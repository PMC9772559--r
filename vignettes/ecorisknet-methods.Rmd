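---
title: "Methods: graded heavy-metal risk and soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded heavy-metal risk and soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecorisknet)
```

# Scope

`ecorisknet` implements the analytical stack used to characterise soil
microbial communities along a designed gradient of heavy-metal ecological
risk: an uncontaminated control (CK) and three spiking levels (L, M, H)
targeting Hakanson risk indices of 100, 200 and 400. The package covers the
risk-index design itself, genetic and functional diversity, Biolog
community-level physiological profiling (CLPP), high-throughput qPCR
functional-gene quantification, co-occurrence network construction and
stability analysis, and community-assembly inference. A seeded synthetic-data
generator produces every input with known ground truth, so the entire
pipeline can be exercised and validated end to end without sequencing data.

# Risk index and inverse design

The potential ecological risk index of a metal mixture is
$RI = \sum_i TF_i \, C_i / C_{bg,i}$, with $C_i$ the soil concentration,
$C_{bg,i}$ the regional background and $TF_i$ the metal's toxicity factor.
Defaults use the conventional factors $TF_{Pb} = 5$ and $TF_{Cd} = 30$,
and backgrounds of 20 and 0.2 mg/kg — typical uncontaminated topsoil values;
all are configurable because regional backgrounds vary.

Because $RI$ is linear in each concentration, the spike needed to move a
soil from its current $RI_0$ to a designed target $RI_t$ has the closed form
$added_i = a_i (RI_t - RI_0) C_{bg,i}/TF_i$, where the allocation fractions
$a_i$ (summing to 1) split the added risk among metals.
`solve_additions()` implements this and the test suite verifies the
round trip through `ecological_risk_index()` to $10^{-9}$.

Treatments are classified against the *designed* targets (nearest target,
ties to the lower level) rather than the classical published risk bands,
because microcosm groups are labelled by the RI they were designed to reach.

# Diversity

* **ACE** follows the Chao–Lee abundance-based coverage estimator with the
  conventional rare-taxon cutoff of 10 reads; when every rare taxon is a
  singleton the coverage term degenerates and the function falls back to
  Chao1 with a warning.
* **Shannon** is reported in nats (natural log); no base was imposed by the
  study design and nats are the common default.
* **Faith PD** uses the rooted convention: the minimal spanning subtree
  always includes the path to the root, so a single-tip sample already has
  positive PD. `picante::pd(include.root = TRUE)` is used as an independent
  oracle in the tests, never as the implementation.
* Taxa are split into **abundant (> 1%) and rare (< 1%)** by mean relative
  abundance across all samples; the exact 1% boundary is assigned to rare.
  Mean-across-samples was chosen over per-sample classification so a taxon
  has one identity throughout an analysis.
* **Beta diversity** is Bray–Curtis on counts; PCoA reports the full
  eigenvalue spectrum, including negative eigenvalues, and explained
  fractions over the positive part only. PERMANOVA is delegated to
  `vegan::adonis2` (one factor, free permutation of labels, 999 permutations
  by default) with the permutation stream fixed by a seed; its p-value has
  resolution $1/(n_{perm}+1)$.
* Group letters come from Holm-adjusted pairwise t tests at
  $\alpha = 0.05$ via an insert-and-absorb compact letter display; the
  post-hoc test is a package choice, as letters alone do not identify one.

# Metabolic profiling (Biolog ECO/FF)

The bundled schemes pin the plates' group structure: ECO has 31 substrates
in triplicate plus 3 water controls, in six groups
(carbohydrates 12, amino acids 6, polymers 4, carboxylic acids 5, amines 2,
phenolic compounds 2); FF has 95 substrates plus one water control in eight
groups (carbohydrates 29, carboxylic acids 20, amino acids 10, glycosides 4,
polymers 5, polyols 10, amines and amides 9, miscellaneous 8). Well-to-group
assignments follow standard plate documentation; group sizes are the fixed
points the tests assert.

Correction averages replicate wells, subtracts the mean water control per
timepoint and floors negatives at zero (standard CLPP practice). AWCD is the
substrate mean of corrected OD at the reading time of record, 168 h, and the
functional diversity indices are computed at the same time: with
$p_i$ the proportion of total corrected OD, $H' = -\sum p_i \ln p_i$,
$D = 1 - \sum p_i^2$, and McIntosh $U = \sqrt{\sum c_i^2}$ on the corrected
ODs themselves. All indices are exposed per-timepoint should a different
reading time be wanted.

# Functional genes

Target genes with amplification efficiency outside 1.8–2.2 are eliminated
before quantification. The chip convention converts threshold cycles to
relative copy numbers as $10^{(31 - CT) \cdot 3/10}$ — one log10 of template
per 10/3 cycles — with the detection limit at CT = 31: missing or at-limit
reactions score 0, matching the semantics that a non-detect is an absence.
Per-cycle (C/N/P/S) sums conserve the grand total exactly.

# Co-occurrence networks

Taxa with mean relative abundance strictly above 0.01% enter the network.
Pearson correlations are computed on log10 relative abundances with
half-minimum replacement of zeros — abundances are heavy-tailed and
log-scaled association is the convention of molecular ecological network
analysis; the untransformed alternative remains a known open question of
that pipeline family.

The cut-off is chosen by random-matrix theory: for each candidate threshold
the eigenvalue spectrum of the binary adjacency matrix is unfolded (degenerate
eigenvalues removed, cumulative spectral density smoothed by a spline) and
the nearest-neighbour spacing distribution tested against the Poisson form
$e^{-s}$ by chi-square goodness of fit (bins of width 0.5 up to 3, one
degree of freedom charged for the unit-mean normalisation). The chosen
threshold is the smallest scan value whose spacings are Poisson-consistent
(p > 0.05) — the point where Wigner-type noise correlations have decayed.
If the scan is exhausted (for example, the graph fragments below 20 active
nodes first), a configured fallback of 0.80 is used with a warning.

Topology reports node/edge counts, positive-edge fraction, average local
clustering (nodes of degree < 2 contribute 0), average shortest-path
distance (unweighted; computed on the largest component when disconnected,
with a note), and the modularity of a seeded fast-greedy partition
(Louvain available behind a flag). Zi–Pi roles use the classical cut-offs
(module hub $Z_i \ge 2.5$, connector $P_i \ge 0.62$); modules with zero
within-degree spread assign $Z_i = 0$.

Stability follows two simulations. **Robustness**: remove 50% of nodes
uniformly at random, prune secondary extinctions (surviving nodes left with
no edges), and report the surviving fraction over 100 iterations —
unweighted, so a complete graph scores exactly $1 - f$ with zero variance,
which the tests assert. An abundance-weighted variant is a possible
extension, not implemented. **Vulnerability**: the maximal relative loss of
global efficiency $E$ (mean inverse shortest-path length over ordered
pairs) caused by deleting one node; zero for complete graphs and strictly
positive for any cut vertex.

# Community assembly

**Neutral model.** The Sloan formulation predicts taxon occurrence
frequency as $1 - \mathrm{Beta}(d;\, Nmp,\, Nm(1-p))$. The migration rate
$m$ is fitted by least squares on a log grid refined by golden-section
search, and $R^2$ is computed about the mean observed frequency. The
detection limit defaults to $d = \ln 2 / N$: occurrence in count data means
"at least one read", whose probability given true relative abundance $x$ is
$1-(1-x)^N$, crossing one half at $x \approx \ln 2/N$. This choice makes the
prediction the exact dual of count-based detection; with the naive
$d = 1/N$, fitted migration rates are biased upward by roughly a quarter
under the model's own sampling. The 95% band around predictions uses Wilson
intervals at the sample count, and taxa are partitioned into
above/within/below the band.

**Modified stochasticity ratio.** Observed pairwise Bray–Curtis
dissimilarities $D$ are compared to a null expectation $E$ from a
proportional–proportional randomisation preserving each sample's richness
and total reads (taxa drawn without replacement with probability
proportional to regional occurrence, reads filled proportionally to
regional abundance, each drawn taxon keeping at least one read). The ratio
is piecewise: $MST = (d_{max} - D)/(d_{max} - E)$ when $D \ge E$, else
$D/E$, clamped to $[0,1]$, with $d_{max} = 1$ for Bray–Curtis. It equals 1
when observation matches the null and falls toward 0 when communities are
more similar (homogeneous selection) or more different (heterogeneous
selection/dispersal limits) than chance; group means above 0.5 read as
stochastic. The exact published variant of the ratio differs between
implementations; this construction (fixed point 1 at the null expectation,
0 at both extremes) should be kept in mind when interpreting absolute
values, while the 0.5 boundary behaves as intended in the validation below.

# Synthetic data: what it emulates, and what it does not

The generator reproduces the study design, not any measured dataset:

* Metacommunities are lognormal rank-abundance curves (σ = 2 by default),
  giving both > 1% and < 1% taxa; 300 bacterial and 120 fungal taxa at
  2,000 reads per sample keep the default experiment desk-sized.
* Groups CK/L/M/H carry 5, 5, 6 and 6 replicates; metal additions are
  solved to hit RI 100/200/400 exactly and re-scored through the index.
* Bacterial totals (and hence gene copies) fall with risk
  (multipliers 1/0.8/0.6/0.4) while fungal totals rise (1/1.3/1.6/2.0) —
  opposite-signed responses mirroring the qualitative field pattern; the
  magnitudes are free design parameters, not measured values.
* Assembly regimes per group: bacterial CK and H neutral (m = 0.3 and
  0.15), L and M filtered (Gaussian niche kernel, strengths 25 and 15,
  replicate noise sdlog 0.05); fungal CK filtered, L/M/H neutral — so
  designed deterministic/stochastic contrasts exist for the MST to find.
* Plate colour development is logistic from zero OD,
  $A[\sigma(r(t-t_0)) - \sigma(-r t_0)]$, with treatment-scaled rates
  (ECO rates fall with risk; FF only at H), shared baseline and drift
  removed by control correction, and Gaussian OD noise (sd 0.02).
* Gene copies are lognormal around a per-gene baseline (meanlog ln 50,
  sdlog 1.5) scaled by the group multiplier, so a realistic share of
  reactions sits near the CT = 31 detection limit; CT values are written as
  $31 - (10/3)\log_{10}(copies)$ and non-detects as blanks.
* Trees are random coalescents — adequate for exercising PD, with no
  pretence of real phylogenetic signal.

What passing tests therefore show is that the pipeline's mathematics and
plumbing are correct under its own generative assumptions. They do not show
that real communities satisfy those assumptions: no compositional bias,
chimeras, sequencing error, spatial structure, or taxon interactions are
simulated, and real OTU tables are far sparser and deeper than the
desk-scale defaults.

# Validation conditions and numerical choices

The test suite validates, among others: neutral-model parameter recovery
(true m = 0.1, N = 1000, 50 samples, 300 taxa, ten seeds; median relative
error of $\hat m$ within 20% and all $R^2 > 0.8$); MST discrimination
(neutral m = 0.3 vs filtering strength 25 with noise sdlog 0.02, 6 samples
of 5,000 reads, 100 null draws, ten seeds per side; at least 9/10 correct on
each side of 0.5); PERMANOVA type-I error within [0.03, 0.07] over 500 null
datasets at 99 permutations; and exact agreement of every network metric
with brute-force recomputation on all graphs of at most 12 nodes, including
robustness of $K_{10}$ at exactly 0.5 with zero variance. These problem
sizes were chosen so the whole suite runs in well under a minute per
property while keeping Monte-Carlo error far from the asserted margins.

Tie-breaks and degenerate inputs are fixed deliberately: risk levels tie to
the lower target; the 1% abundance boundary goes to rare; the 0.01% network
filter is strictly greater-than; zero-variance taxa are dropped from
correlation matrices with a warning; single-node modules and zero-spread
modules score $Z_i = 0$; an exhausted RMT scan falls back to 0.80 with a
warning; all-zero samples are errors, never silent zeros.

All randomness flows from one master seed, forked per stage by a stable
hash of the stage name (`fork_seed()`), so stages are independently
reproducible and two runs of the CLI with the same seed are byte-identical.

# Known limitations

* The RMT threshold search, not the online network-analysis service, decides
  the cut-off; numerical agreement with that service is not a goal.
* Robustness is unweighted; vulnerability uses global efficiency — other
  stability definitions exist and can disagree in ordering networks.
* The MST null model is one member of a family; absolute values shift with
  the null, even though the 0.5 boundary discriminates reliably here.
* Salt-mass to metal-ion conversion is out of scope: metal inputs are
  elemental concentrations.
* The command-line interface is the exported `run_cli()` function (thin
  argument parsing over the stage functions); the package functions and this
  vignette are the primary interface.
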