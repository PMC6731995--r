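---
title: "Resolving reprogramming routes by fractional identity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving reprogramming routes by fractional identity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reprogramming of primed epiblast stem cells (EpiSCs) to naive pluripotency is
heterogeneous and asynchronous: at any harvest time a culture mixes cells at
many stages of the transition, and different inducing factors (Esrrb, Klf2,
activated Stat3) may drive cells along different transcriptional routes —
including transient excursions through identities that are neither origin nor
destination, such as a mesoderm-like or an early-ICM-like state. Bulk
averages hide all of this. fateline implements the single-cell analysis
chain that resolves it: each cell is placed on a trajectory by comparing its
transcriptome with reference ("signature") transcriptomes, and expression
kinetics are then read along the resulting pseudotime.

## The core model: fractional identity

For a cell with expression vector $x$ (linear FPKM over $G$ genes) and a
signature matrix $S \in \mathbb{R}_{\ge 0}^{G \times k}$ whose columns are
mean expression profiles of $k$ reference states, the cell's fractional
identity $f$ solves the simplex-constrained least-squares problem

$$\hat f = \arg\min_f \; \lVert x - S f \rVert_2^2
\quad \text{s.t.} \quad f \ge 0,\; \textstyle\sum_j f_j = 1 .$$

$\hat f_j$ is read as the fraction of state $j$'s identity the cell carries.
Deconvolution uses the whole transcriptome (all genes shared between matrix
and signatures, matched by id) by default; a gene-subset argument and a
log-scale switch exist for sensitivity analysis but are not defaults,
because mixing is approximately linear on the linear expression scale, not
after a log transform.

**Solver.** `solve_simplex_qp()` is a deterministic active-set method:
solve the equality-constrained least squares on the current support via the
KKT system, drop the most negative coefficient to the boundary until the
support solution is feasible, then test the Karush–Kuhn–Tucker conditions of
the zero components (on the support the Lagrangian gradient must be a common
constant; off it, no smaller) and re-admit the worst violator. Tolerance
1e-10, at most $10k$ support changes, no randomness. Exactly duplicated
signature columns make the optimum non-unique; they are collapsed before
solving, the mass is split evenly among the duplicates afterwards, and the
profile is flagged `non_unique`. Tests hold the solver to an exhaustive
simplex-grid search (step 0.01) and to a direct KKT residual below 1e-8.

**Pseudotime.** With an origin and a destination anchor, each cell gets
$\tau = f_\mathrm{dest} / (f_\mathrm{origin} + f_\mathrm{dest})$; cells are
sorted by $\tau$ (ties broken by residual norm, then cell id, so the result
is independent of input order) and rank-normalized to the even grid
$0, 1/(n-1), \dots, 1$. The ratio form is this package's convention — when
deconvolution uses exactly the two anchors, $f_\mathrm{origin} +
f_\mathrm{dest} = 1$ and $\tau$ is simply the destination fraction. Cells
with $f_\mathrm{origin} + f_\mathrm{dest} = 0$ carry no anchor information
and are excluded with a warning. Rank normalization discards the absolute
magnitude of $\tau$ deliberately: the coordinate is an ordering, not a
clock, and downstream smoothing only assumes monotonicity.

## Upstream of the model

**Library QC.** Two filters, both with the standard constants as defaults:
libraries with fewer than 500,000 mapped reads are excluded (a library at
exactly the threshold is kept — the rule is "fewer than"), and libraries
whose gene-body coverage is 3'-skewed are excluded via the bias ratio =
reads in positional bins covering percentiles 50–100 of gene length over
reads in bins 1–49, summed over genes. With 100 bins that split is 51 bins
versus 49, so uniform coverage scores 51/49 ≈ 1.04, not 1; the asymmetry is
preserved on purpose. A ratio strictly greater than 2 fails; exactly 2
passes; an empty 5' denominator is undefined and fails with reason
"no 5' coverage". The two filters commute and the overall pass set is the
intersection.

**Normalization.** FPKM = counts / (length in kb × mapped reads / 10^6),
using the library's total mapped reads — not the column sum of the gene
count matrix — as the per-million denominator. Log transform is
$\log_2(\mathrm{FPKM} + c)$ with pseudocount $c = 1$ by default; $c = 0$
reproduces raw logs of positive values. All-zero genes are omitted before
global analyses (`filter_expressed`).

**Variable genes.** CV² = variance / mean² is computed per gene on linear
FPKM with the sample variance (n−1): CV² is conventionally a linear-scale
statistic and is scale-free, which the tests assert. The per-gene mean is
reported as $\log_2(\mathrm{mean} + c)$ because the selection thresholds
live on those axes: a gene is selected iff mean $> 1$ (log2 FPKM) and CV²
$> 0.5$, both strict. A hyperbolic trend CV²(m) = a1/m + a0 is fitted by
least squares for diagnostics — for Poisson-limited counts a1 ≈ 1 and
a0 ≈ 0, which the tests verify — but selection depends only on the two
thresholds, so results are robust to the trend's functional form. Per-group
(per-driver) lists are merged by set union, sorted for determinism.

## Downstream of the model

**Kinetics.** `loess_fit()` is a local polynomial regression with the
conventions stated explicitly because they are the numerical contract: at
each query point the window is the $k = \lceil \mathrm{span} \cdot n \rceil$
nearest neighbours; tricube weights $(1 - (d/d_{max})^3)^3$ with $d_{max}$
the distance to the $k$-th neighbour (a point at $d_{max}$ gets weight zero;
if every weight vanishes the window grows by one); a weighted polynomial of
the requested degree is fitted and evaluated at the query; a singular local
design falls back to a lower degree with a warning. Defaults span = 1/3,
degree = 2; no robustness iterations. Degree-2 windows reproduce linear and
quadratic data exactly, and each fitted value equals an independent one-shot
weighted-least-squares solve to 1e-10, which is how the tests pin the
implementation. `kinetics_table()` fits each (gene, group) pair on a shared
100-point grid over [0, 1], re-grading pseudotime within each group so every
group's own ordering spans the unit interval.

**Gating and image quantification.** `co_expression_gate()` classifies
cells into double-negative / A-only / B-only / double-positive by strict
thresholds (default 1 on log2(FPKM+1), a package convention consistent with
the variable-gene mean threshold). `if_percent_positive()` implements the
stringent immunofluorescence positivity call: threshold = control mean + 2
sample SDs (n−1 denominator — the package's explicit choice), positive =
strictly above. For a normal test population identical to the control this
calls ≈2.3% of cells; this false-positive floor is inherent to the rule. A
caveat worth knowing: for skewed (e.g. lognormal) negative intensities the
mass beyond mean + 2 SD can reach ~4%, so the percent-positive estimate
carries a $(1 - \pi) \cdot \mathrm{FP}$ upward bias where $\pi$ is the true
positive fraction; recovery experiments in the tests therefore use a
tight-tailed negative population and compare against the generator's
realized per-cell labels.

**Structure.** PCA runs on cells over a gene subset (typically the merged
variable genes), centred and unit-scaled by default, via singular value
decomposition; zero-variance genes are dropped with a warning when scaling,
and component signs are fixed by making each loading column's
largest-magnitude entry positive so results are fully deterministic.
Hierarchical clustering uses Euclidean distances with either Ward.D2 or
average (UPGMA) linkage — both dialects are used for expression data, so the
choice is an explicit argument with no default; dendrograms export as
Newick. k-means uses Lloyd's algorithm from k-means++ starts, best of
`n_restarts` by within-cluster sum of squares, and the elbow is formalized
as the interior $k$ maximizing the WCSS second difference
$W(k{-}1) - 2W(k) + W(k{+}1)$ — "the elbow method" needs a concrete rule to
be reproducible, and this is the one this package uses. DE lists are
partitioned into exact Venn regions (`de_partition`); the DE caller itself
is a two-sided Wilcoxon rank-sum test per gene with Benjamini–Hochberg
adjustment — a deliberately simple, distribution-free caller; per-cell
error-model methods are out of scope, and published DE gene counts that
depend on them (and on the original sequencing data) are not reproduction
targets.

## The synthetic experiment

Because the original sequencing accessions are not required, every stage is
exercised on generated data with full ground truth. The generator emulates:

- a gene universe of 2,000 genes (50 markers for each of origin,
  destination, mesoderm-like and ICM-like modules; the rest housekeeping),
  lognormal baselines and transcript lengths — large enough for stable
  deconvolution, small enough for desk-scale tests;
- signature profiles per state: markers of a state's modules elevated
  10-fold over baseline, with a small lognormal wobble (sd 0.1) so profiles
  are correlated but distinct, as real bulk references are;
- cells along a route: trajectory position $t \sim$ Uniform(0,1) by default
  (asynchronous progression; Beta shapes available to mimic staged
  harvests), detour weight $w = A \exp(-(t - c)^2 / 2\sigma^2)$ with
  defaults $A = 0.3$, $c = 0.5$, $\sigma = 0.15$ (the transient
  mid-trajectory excursion; only $A$ has a stated scale, centre and width
  are this package's choices), raw weights clipped and renormalized onto
  the simplex and recorded as the truth;
- counts: negative binomial with mean FPKM × length(kb) × library/10^6 and
  variance $\mu + \phi\mu^2$ (φ = 0.1 by default; the parameterization is
  stated because "dispersion" is overloaded), lognormal library sizes
  around 10^6 reads (cv 0.3), logistic dropout in log mean available but
  off by default, as appropriate for full-length library chemistry;
- positional coverage with bin probabilities ∝ exp(bias × bin/n_bins), and
  lognormal immunofluorescence intensity mixtures with per-cell labels.

What the generator does **not** emulate: batch and cell-cycle effects,
amplification artifacts, gene–gene correlation beyond the mixture structure,
UMI counting, or realistic dropout for 3'-tagged chemistries. Passing
recovery tests therefore demonstrates correctness of the computations under
the stated noise model, not robustness to every failure mode of real data.
The harvest-time composition of sorted fractions in the real experiment is
unknown, so synthetic staging is parametric rather than calibrated.

## Numerical and design choices

- Problem sizes in the default pipeline and tests (3 routes × 200 cells ×
  2,000 genes; 100 QP oracle instances at k = 3 and 50 genes; 20 DE
  replicates of 1,000 genes × 60 cells) were chosen so the whole suite runs
  in about a minute on a laptop while leaving the statistical contrasts
  far from their thresholds.
- One global seed drives everything; per-stage seeds are derived by hashing
  stage names (`derive_seed`), so toggling a stage never shifts another
  stage's random stream, and two runs from one config are byte-identical
  (verified by md5 in the manifest; the manifest's own timestamp is outside
  the checksummed content).
- Tabular outputs are UTF-8 TSV with one header line and floats at 10
  significant digits; the YAML config round-trips at 15 significant digits.
- Ties: pseudotime ties break by (residual norm, cell id); nearest-neighbour
  ties in the local regression break by point index; minimum-distance ties
  in hclust follow the underlying implementation (observed-zero probability
  for continuous data, which is what the oracle comparisons use).
- Degenerate inputs: zero mapped totals or gene lengths are errors in FPKM;
  an all-zero 5' coverage half flags the library rather than dividing by
  zero; a constant gene has CV² = 0; cells with no anchor signal are
  excluded from pseudotime with a warning rather than silently placed.

## Known limitations

- Fractional identity is a point estimate; no uncertainty intervals are
  attached (probabilistic deconvolution is a non-goal).
- Pseudotime assumes a single origin→destination axis; branching inference
  and multi-anchor graphs are out of scope.
- The rank-sum DE caller is less sensitive than error-model methods at very
  low counts; it is the package's documented substitute, not a
  reimplementation of any published caller.
- The mean + 2 SD positivity rule has the false-positive floor discussed
  above; thresholds derived from skewed controls should be interpreted with
  that bias in mind.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes the package's
headline quantities from scratch — solver-versus-grid objective gaps, KKT
residuals, mixture and pseudotime recovery, detour contrasts, QC pass sets
on an engineered fixture, the Poisson CV² trend slope, IF quantification,
clustering oracle agreement, DE partition identities, empirical FDR, and
pipeline rerun determinism — and writes them as JSON.
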