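---
title: "Co-occurrence networks, stability and assembly processes with micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks, stability and assembly processes with micronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

# Scope

`micronet` implements the network-ecology workflow used to compare soil
microbiome communities across treatments (for example, crop cultivars under
continuous cropping): co-occurrence network construction for one domain
(bacteria or fungi) and across domains (bacteria–fungi), topological
characterization against random-graph nulls, two stability/complexity
statistics (wMIS robustness and cohesion), and a phylogenetic-bin
null-model partition of community assembly processes. A synthetic community
generator with planted structure provides ground truth for validating every
stage.

# The statistics

## Association inference

Intra-domain associations are Pearson correlations of per-sample relative
abundances (a `log_relative` transform, `log(rel + pc)` with `pc` half the
smallest nonzero relative abundance, is available). Inter-domain
associations use a SparCC estimator: the log-ratio variance
$t_{ij} = \mathrm{var}\,\log(x_i/x_j)$ is closure-invariant, and under the
sparsity assumption $\sum_{j \ne i} \rho_{ij}\,\omega_i\,\omega_j \approx 0$
the row sums of $T$ give a linear system for the basis variances
$\omega_i^2$, from which
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\,\omega_i\,\omega_j)$.
Pairs with $|\rho| > 0.8$ violate the sparsity assumption and are excluded
one per iteration (at most 10) before re-solving. Counts get a pseudocount
of 1 before log-ratios. Pseudo-$p$-values come from permutation datasets in
which each taxon's counts are shuffled independently across samples
(two-sided, 100 permutations by default).

## Threshold selection by random matrix theory

For a grid of candidate cutoffs (0.30–0.95, step 0.01), sub-threshold
entries are zeroed and the nearest-neighbour spacing distribution (NNSD) of
the unfolded eigenvalues is scored by chi-square (20 bins, polynomial
unfolding of degree 5) against the Poisson law $e^{-s}$ and the GOE Wigner
surmise. Random-matrix noise gives GOE spacings; a modular signal matrix
decomposes into near-independent blocks and gives Poisson spacings. The
chosen threshold is the first grid point where the Poisson fit beats GOE for
3 consecutive points — the 3-point run guards against single-point noise
flips. If no cutoff qualifies, the scan fails loudly and carries its full
scan table; the pipeline then falls back to a configurable fixed cutoff.

## Topology

Edges are retained at $|s_{ij}| \ge$ cutoff, keeping sign and weight;
isolated nodes are dropped. Paths are unweighted (GD is the mean shortest
path over connected pairs); modularity uses $|w|$ as connection strength,
so a strong negative association binds a module as strongly as a positive
one — sign is kept as an edge attribute only. Node roles follow the
Guimerà–Amaral Zi–Pi convention with the thresholds used throughout the
molecular-ecological-network literature: $Z_i \ge 2.5$ marks module hubs,
$P_i \ge 0.62$ connectors, both network hubs, the rest peripherals. When a
module's within-degrees have zero spread, $Z_i$ is defined as 0 rather than
excluding the module — excluding would silently change the hub census.
Degree-preserving nulls rewire $10|E|$ edge swaps per replicate, and
empirical GD and $Q$ are contrasted with the ensemble by a one-sample
Student's $t$ test. On structureless graphs the greedy optimizer can return
a (negative-$Q$) split; `detect_modules()` then falls back to the
single-module partition with $Q = 0$.

Bipartite (inter-domain) descriptors are connectance $L/(RC)$, web
asymmetry $(C-R)/(C+R)$ with $R$ fungal and $C$ bacterial node counts,
links per species $L/(R+C)$, and NODF on the binary incidence matrix. NODF
follows the strict decreasing-fill definition: pairs with equal marginal
totals contribute zero, so a completely filled matrix scores 0, not 100.

## Stability: wMIS robustness

The abundance-weighted mean interaction strength of node $i$ is
$$\mathrm{wMIS}_i = \frac{\sum_{j \ne i} b_j s_{ij}}{\sum_{j \ne i} b_j},$$
with $b_j$ the neighbour's relative abundance (its mean relative abundance
over the samples behind the network) and $s_{ij}$ the signed association on
the edge. A robustness replicate removes a fraction (default 50%) of nodes
at random, then removes every node whose wMIS on the remaining subgraph is
$\le 0$ — isolated survivors count as extinct — iterating to a fixed point
(a single-pass mode is available). Robustness is the fraction of original
nodes remaining, reported as mean ± sd over replicates (default 100).
Associations are fixed edge attributes; they are not re-estimated on
subgraphs. Consequences worth knowing: an all-positive network loses
exactly the removed fraction, an all-negative network collapses to 0.

## Complexity: cohesion

Connectedness $\bar r_i$ is the mean null-corrected correlation of taxon
$i$, split into positive and negative parts; cohesion per sample $j$ is
$$c_j^{pos} = \sum_i a_{ij}\,\bar r^{pos}_i \ \ge 0, \qquad
  c_j^{neg} = \sum_i a_{ij}\,\bar r^{neg}_i \ \le 0,$$
with $a_{ij}$ relative abundances. The null shuffles each taxon's
abundances independently across samples (200 permutations by default) and —
important detail — re-normalizes each permuted sample to sum to one before
correlating. Relative abundances of even independent taxa are negatively
correlated by closure (about $-1/(n-1)$); re-closing the null reproduces
that bias so the corrected correlations are centred on zero for independent
taxa. Without re-closure the calibration fails by exactly the closure bias.

## Assembly processes

Taxa are grouped into phylogenetic bins by single-linkage clustering of
patristic distances at radius 0.2 (bins under 12 taxa merge into their
nearest bin). Per within-group sample pair and bin, two null models are
evaluated:

* **βNRI** — the abundance-weighted between-sample mean pairwise
  phylogenetic distance (βMPD $= f_A^\top D f_B$ on within-bin relative
  abundances), standardized against shuffles of taxon identity across the
  bin's tips: $\beta NRI = (obs - \mu_{null})/\sigma_{null}$.
* **RC (modified Raup–Crick)** — observed within-bin Bray–Curtis ranked
  against null communities drawn to each sample's observed richness (taxa
  $\propto$ occupancy) and read total (individuals $\propto$ mean relative
  abundance); $RC = 2\,(\text{fraction of null below obs, ties half}) - 1$.
  For grouped designs the occupancy and abundance behind the null draws
  come from the pair's *group* samples (the local species pool), not the
  whole table: when groups are differentially selected, a global pool
  would inflate the null with taxa that never occur locally and push every
  within-group comparison toward $RC = -1$.

The decision rule assigns heterogeneous selection (βNRI > 1.96),
homogeneous selection (βNRI < −1.96), dispersal limitation (RC > 0.95),
homogenizing dispersal (RC < −0.95), else drift; the ±1.96/±0.95 cuts are
the standard defaults of the phylogenetic-bin framework. Bins whose null
βMPD has zero variance are excluded from aggregation (forcing them to
drift would silently inflate stochastic fractions). Group fractions weight
each (pair × bin) turnover by the bin's mean relative abundance and are
normalized to sum to one. Null iteration counts default to 1000; the test
suite and examples use 200, trading some SES precision for speed.

# The synthetic community generator

The generator is the package's ground-truth instrument, not a model of any
particular soil. Its stages mirror the processes the assembly stage is
meant to detect:

1. a rooted ultrametric tree (unit depth, tips `OTU_1..n`) shaped like a
   cross-taxa OTU phylogeny: up to 5 deeply divergent clades (phylum-like
   lineages, crown age 0.15) joined near the root, coalescent branching
   within each clade — a single Kingman coalescent is a within-population
   genealogy and produces erratic, chain-merged phylogenetic bins, whereas
   the clade structure gives well-separated bins in every realization;
2. niche optima by Brownian motion along the tree;
3. a log-normal metacommunity pool (`pool_sd`, default 0.3);
4. per group, Gaussian niche filtering
   $w_i \propto \text{pool}_i\, e^{-s\,(z_i - e_g)^2}$;
5. per sample, `drift_steps` rounds of multinomial resampling at
   `community_size` individuals, mixing with the metacommunity at
   `dispersal_rate`, and a final multinomial read draw at `depth`;
6. optional correlation blocks: block taxa are re-driven by a shared
   latent factor with loading `block_strength` (expectation-preserving),
   giving planted positive within-block correlations.

Defaults (200 taxa, 8 groups × 6 samples, depth 2000) mirror a 48-sample
field survey at desk scale and run in seconds.

Two deliberate design choices deserve explanation:

* **A moderately even pool (`pool_sd = 0.3`).** The phylogenetic null
  models gain power with the effective number of taxa carrying abundance
  inside each bin. Real surveys reach that effective richness with
  thousands of OTUs; a desk-scale community of 100–200 taxa reaches it by
  evenness instead. With a long-tailed pool (`pool_sd` ≈ 1) per-bin SES
  values are dominated by a handful of taxa and the null spread swamps the
  signal.
* **Band-limited niche evolution in the selection regime.** With a plain
  Brownian trait, the most abundant bin under filtering is the one whose
  niche distribution is centred on the environment — and the taxa nearest
  a central optimum are a phylogenetically scattered (polyphyletic) set
  within that bin, so within-bin clustering (the only signal βNRI's
  within-bin shuffle can see) vanishes exactly where the abundance weight
  sits. The `selection_dominated` preset therefore confines niche
  evolution to the node-age band 0.02–0.12 (`niche_band`): deep lineages
  share a common baseline, subclades inside each bin diverge, and very
  recent splits change little — strong niche conservatism at the subclade
  scale. Selection toward any environment then favours one coherent
  subclade per bin, the pattern homogeneous selection produces when
  niches track diversification. βMPD distances always come from the
  original tree.
* **Per-group environments in the selection preset.** The preset gives
  each group its own optimum (spread over ±0.45 on the niche axis), like
  field plots that each select their own community. Within-group turnover
  — the only turnover scored by default — still faces a single, uniform
  environment, i.e. homogeneous selection; spreading the optima prevents
  one bin from absorbing all abundance in every group, which would let a
  single uninformative bin decide the abundance-weighted partition.

## Regime presets

`regime_config()` fixes the generator so one process dominates turnover:

| regime | selection $s$ | dispersal $m$ | drift steps | community size | niche band | expected label |
|---|---|---|---|---|---|---|
| selection_dominated | 80 | 0 | 0 | — | 0.02–0.12 | homogeneous selection |
| drift_dominated | 0 | 0 | 20 | 200,000 | — | drift |
| dispersal_limited | 0 | 0 | 200 | 5,000 | — | dispersal limitation |
| homogenizing_dispersal | 0 | 0.95 | 2 | 5,000 | — | homogenizing dispersal |

The drift preset keeps per-sample drift noise of the same order as the
multinomial read noise, which is what "drift" means to the Raup–Crick null:
turnover consistent with stochastic sampling. The dispersal-limited preset
drifts far beyond the null band. Homogenizing dispersal is the hardest
signature at desk scale: with near-complete mixing the observed turnover
equals sampling noise, which the tight taxonomic null reads as drift rather
than as significantly *less* turnover than expected; the preset exists and
is labelled in the ground truth, but its recovery is not asserted by the
test suite.

# What passing tests do and do not show

The synthetic generator produces multinomial sequencing noise at fixed
depth, log-normal abundances, Brownian (or recent-weighted) niches and
latent-factor correlation blocks. It does not produce overdispersed counts,
spatial autocorrelation, true ecological interaction dynamics, chimeric or
mis-clustered OTUs, or compositional effects beyond closure. Recovery of
planted structure here validates the estimators and their null models; it
does not certify biological claims on any real data set.

# Numerical choices and degenerate inputs

* Association matrices are forced symmetric with unit diagonal and clipped
  to $[-1, 1]$; zero-variance taxa are dropped with a warning everywhere.
* The RMT scan needs at least 20 retained taxa for a meaningful spectrum;
  degenerate spectra (zero spacing spread) are skipped, and a fully
  degenerate scan is an error that carries the scan table.
* SparCC basis variances that solve negative are clamped to the smallest
  positive solution with a warning; identical compositions across all
  samples (all log-ratios constant) are a hard error.
* `detect_modules()` is deterministic and never touches the global RNG —
  it is safe inside resampling loops (its `seed` argument is interface
  sugar).
* Patristic-zero branch lengths read from Newick are replaced by a small
  epsilon with a warning, since zero distances break single-linkage
  binning.
* Every stochastic stage takes an explicit integer seed; per-(pair, bin)
  sub-seeds in `score_turnovers()` are derived arithmetically from the
  stage seed so results do not depend on evaluation order.

# Problem sizes used by the packaged checks

The test suite and the acceptance script run the full pipeline at desk
scale: communities of 40–200 taxa, 2–8 groups × 3–6 samples, depth
1,000–2,000, null-model iteration counts of 100–200, 10–100 robustness
replicates and 10–20 rewired graphs per null ensemble. These sizes are the
package's chosen defaults for reproducible examples; all of them scale up
through the corresponding arguments.
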