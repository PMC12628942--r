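---
title: "Multitrophic co-occurrence networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrophic co-occurrence networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mconet)
```

## The analysis in one paragraph

`mconet` infers signed co-occurrence networks that span four soil domains —
bacteria (16S), fungi (ITS), protists (18S) and nematodes (28S) — from ASV
count tables. Counts are rarefied per domain, merged with domain-prefixed
ids, filtered to taxa detected in more than half of a climatic group's
samples, log10-transformed, and correlated pairwise (Pearson, with SparCC as
a compositionally aware alternative). Taxon pairs with `|r| >= 0.6` and
Benjamini–Hochberg `q < 0.001` become edges whose sign records the direction
of co-variation. Each network is decomposed into modules by fast-greedy
modularity maximization; nodes are classified by within-module degree
(`Zi`) and among-module participation (`Pi`) into peripherals, connectors,
module hubs and network hubs — the latter three being putative keystone
taxa. Module eigengenes and keystone functional-group abundances are then
correlated with environmental variables (pH, nutrient stocks, vegetation,
rainfall and temperature summaries).

## Statistical model of an edge

For taxa $i, j$ with log-abundance profiles $x_i, x_j$ over $n$ samples, the
edge statistic is the sample Pearson correlation $r_{ij}$, tested with
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. With $D$ retained
taxa the family of $D(D-1)/2$ pair tests is corrected by the BH step-up
rule; the default gate ($|r| \ge 0.6$ *and* $q < 0.001$) is deliberately
conservative because co-occurrence edges are easily inflated by indirect and
compositional effects. Taxa with constant profiles get $r = 0$, $p = 1$ and
a flag rather than removal, so matrix dimensions stay aligned with the
filtered table. Both cutoffs are exposed as arguments: sources differ on
whether a raw $p < 0.05$ or the FDR rule defines a "significant" pairwise
association, so the pipeline makes the gate explicit instead of guessing.

SparCC (`sparcc()`) estimates basis correlations from compositions: taxon
fractions are posterior means of `n_dirichlet = 20` Dirichlet draws on
counts + 1; the log-ratio variances $T_{ij} = \mathrm{Var}\log(x_i/x_j)$
are inverted for basis variances $\omega_i$ under the sparsity assumption
$t_i = (D-2)\,\omega_i + \sum_k \omega_k$; and the strongest pair above
`excl_threshold = 0.1` is excluded for up to `excl_iters = 10` rounds.
Non-positive $\omega$ solutions (a known edge case) are clipped to `1e-6`
with a warning. Permutation p-values use the add-one estimator
$p = (1 + \#\{|\rho_{null}| \ge |\rho|\})/(1 + n_{boot})$, so $p = 0$ is
unattainable by design. On non-compositional data with sparse correlation,
SparCC and Pearson on log counts agree closely (the package tests assert a
median absolute difference below 0.15), which is why the cheaper Pearson
route is the default.

## The RMT threshold diagnostic

The correlation threshold itself can be chosen by a random-matrix argument:
the nearest-neighbour spacing distribution (NNSD) of a correlation matrix's
unfolded eigenvalues follows Gaussian-orthogonal-ensemble (Wigner)
statistics while the matrix is noise-dominated, and Poisson statistics once
only modular block structure remains. `unfold_spacings()` removes the global
spectral density with a monotone cubic (Hyman) interpolant of the empirical
cumulative spectral function over `ceiling(N/10)` quantile knots, then
rescales spacings to mean exactly 1; eigenvalues are deduplicated at 1e-8
and at least 20 distinct values are required, otherwise the caller is told
to lower the threshold. `rmt_scan()` sweeps thresholds (default 0.30–0.95 by
0.01), zeroes `|r|` below each, and tests the spacings against the Poisson
law by a chi-square on bins of width 0.1 over [0, 3] (overflow mass in the
last bin, 29 degrees of freedom, `alpha = 0.001`). The scan acts on the
absolute thresholded matrix with unit diagonal, since NNSD theory concerns
magnitude structure.

The reported optimum is the smallest threshold accepted as Poisson whose
acceptance persists for all larger thresholds in the grid. Two consequences
are worth knowing. First, strongly modular inputs can be Poisson-accepted
already at the grid's lower edge, in which case the optimum simply marks
"already modular". Second, near the top of the grid the retained matrix can
fragment until its spectrum is degenerate; those thresholds reject Poisson
for reasons that have nothing to do with noise, and a scan whose tail is
dominated by such fragments returns no optimum rather than a misleading one.
The full pipeline therefore defaults to the fixed, widely used threshold
0.6 and treats the scan as provenance and diagnostic, not as the gatekeeper.

## Topology, null models, modules and roles

Paths, clustering and modularity are computed on the unsigned skeleton;
signs stay as edge attributes (a single unsigned metric set per network is
the field convention). `topology_summary()` reports `N`, `E`, signed edge
counts and their ratio, `avgK = 2E/N`, the mean local clustering
coefficient (`C_i = 0` where degree < 2), and `GD`, the mean unweighted
shortest path over connected pairs only — the common convention for
fragmented co-occurrence graphs. Isolated taxa are not nodes: published node
counts for such networks sit far below the filtered taxon counts, implying
edge-bearing nodes only.

`null_ensemble()` baselines the observed metrics against random graphs with
the same node and edge counts. The default `"rewire"` mode is the stronger
null — degree-preserving double-edge swaps (10·E attempts per replicate)
with the observed sign multiset reassigned at random — while `"er"` draws a
uniform graph with the same N and E, covering the weaker "same nodes and
edges" reading. Because published descriptions of randomization are often
ambiguous between these two constructions, both are implemented and the
manifest records which was used.

`fast_greedy_partition()` delegates the Clauset–Newman–Moore agglomeration
to igraph but cuts the merge dendrogram explicitly at the modularity maximum
of the merge path and recomputes Q for the returned membership; igraph's own
cut was observed to disagree with its path optimum on near-tied Q values
(e.g. complete graphs). Test oracles verify the optimum by exhaustive
enumeration of all partitions on graphs of up to 8 nodes.

For roles, $\kappa_{is}$ counts the links of node $i$ into module $s$;
$Z_i$ standardizes the own-module count within the module using the sample
standard deviation (the sources are silent on the denominator; nodes in
modules with zero spread get $Z_i = 0$, i.e. "topologically average"), and
$P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$. Hub thresholds are strict
(`Zi > 2.5`, `Pi > 0.62`); boundary values fall in the low class. Module
eigengenes are WGCNA-style: the first left singular vector of the z-scored
samples × members matrix, sign-oriented so summed member correlations are
non-negative, reported with its variance-explained fraction, and restricted
to modules of 5 or more nodes. Module–environment tables use Pearson r with
raw-p significance flags at `alpha = 0.05` and BH q alongside — published
module correlations are customarily reported as raw P values, so no
correction is imposed on the flag by default.

## Guild annotation

Bacteria are split by mean rRNA operon copy number at the deepest matching
rank (genus, then family, then unknown): ≥ 5 copies is copiotroph, < 5
oligotroph. Fungi take the first-listed mode of their guild string
("Pathotroph-Saprotroph-Symbiotroph" → pathotroph); an explicit override
table exists for expert reassignment but nothing is ever inferred beyond
the first-listed rule. Protists are classified by feeding habit at genus
level (consumer / phototroph / pathotroph); nematodes are collectively
consumers. The packaged lookup tables are small, clearly labelled synthetic
stand-ins that keep the code paths testable offline; real analyses should
supply full rrnDB/FUNGuild/feeding-habit tables in the same TSV formats.
Keystone–environment associations use Spearman's rho with average ranks for
ties, the appropriate choice for monotone, non-normal abundance responses.

## What the synthetic generator emulates

`generate_dataset()` draws a sparse latent factor model on log abundance:
taxon $j$ in module $k$ has
$\lambda_j = \mu_j + s_j\,\beta f_k + \varepsilon_j$ with one standard
normal factor per module and sample, loading sign $s_j$ negative with
probability `frac_negative`, and residual sd `sigma_noise`. Planted
connectors load equally on three modules (scaled by $1/\sqrt 3$); background
taxa carry independent noise. Counts are multinomial per sample *within each
domain* at that domain's depth, mirroring separate amplicon assays, with
default depths 4485/10526/1079/412 and the default design of 3 climatic
groups × 18 samples. Environmental variables are placed on field-realistic
locations and scales (e.g. MAP centred at 340 mm with sd 60 mm, matching a
227–462 mm site range) and coupled variables add the designated factor with
unit noise, so correlation signs — not magnitudes — are the recoverable
ground truth. Default effect sizes (`beta = 1`, `sigma_noise = 0.3`,
`frac_negative = 0.3`) give within-module latent correlations near 0.9 and
mixed edge signs, i.e. networks dense enough to survive the conservative
edge gate at n = 18, as real dryland networks evidently were.

Two caveats delimit what passing tests show. Compositional closure is real
in this generator: with few taxa per domain, module factors move domain
totals, and background taxa acquire spurious correlations through the
shared denominator — at default settings some background taxa enter the
network and attach to modules, exactly the artifact compositional methods
warn about. And the generator deliberately omits sequencing error, chimeras,
primer bias and phylogenetic signal, so recovery results speak to the
statistical pipeline, not to upstream bioinformatics.

The parameter-recovery validation uses 3 modules × 20 taxa plus the 3
planted connectors, n = 50 samples, a shared depth of 5×10⁴ and seed 1; at
these settings the pipeline's partition reaches an adjusted Rand index above
0.8 against the planted labels, connectors rank above other nodes in
participation coefficient, and every planted module–environment coupling is
recovered with the correct sign. Problem sizes throughout the test suite
(≤ 200 × 200 spectra, ≤ 100 null replicates, ≤ 83-taxon communities) were
chosen so the whole validation runs in seconds on one core while leaving
the statistical contrasts unambiguous.

## Numerical choices and degenerate inputs

* Rarefaction is seeded subsampling without replacement; samples below depth
  are dropped with a warning, never padded. A single root seed derives all
  sub-stream seeds, so every artifact is reproducible end to end.
* The log transform replaces zeros with `pseudo = 0.01` (−2 on the log10
  scale) before log10; both the fill value and base are arguments because
  "default parameters" of upstream pipelines leave them unstated.
* The prevalence rule is strict: presence in exactly half the samples is
  not enough.
* Correlation values are clipped away from ±1 by 1e-15 before the t
  transform; `|r| = 1` maps to `p = 0` exactly.
* Empty networks (nothing passes the edge gate) are warnings carrying an
  empty graph, not errors; downstream pipeline stages are skipped for that
  group.
* ΔQ tie-breaks inside the agglomeration are igraph's deterministic order;
  the explicit dendrogram cut makes the returned partition reproducible
  across platforms.

## Known limitations

Correlation networks are not interaction networks: edges conflate direct
dependence, shared environmental response and compositional coupling.
The RMT optimum is undefined when the scan's upper tail fragments the
matrix (reported as `NA`, never extrapolated). SparCC p-values are bounded
below by `1/(n_boot + 1)`, so FDR control at very small q needs more
permutations than the default 100. Guild fixtures are illustrative, not
reference data. Nematode guild resolution stops at the blanket consumer
rule.
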