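# fateline

Trajectory analysis of cell-identity change by **fractional identity**:
simplex-constrained deconvolution of single-cell transcriptomes against
signature reference states, pseudotime from origin/destination similarity,
and the QC, normalization, variable-gene, kinetics, gating, and
population-structure machinery around it.

## Who this is for

Groups studying directed transitions between two transcriptional identities
— the motivating case is reprogramming of primed epiblast stem cells
(EpiSCs) to naive pluripotency under single inducible drivers — who need to
resolve *asynchronous* single-cell data into an ordered trajectory and ask
whether different conditions take different routes, including transient
detours through third identities (mesoderm-like, early-ICM-like).

## The core method

Each cell's linear-FPKM expression vector $x$ is decomposed against a
signature matrix $S$ (genes × states, column = mean expression of a
reference population) by constrained least squares:

$$\hat f = \arg\min_f \lVert x - Sf \rVert_2^2
\quad\text{s.t.}\quad f \ge 0,\ \textstyle\sum_j f_j = 1$$

solved by a deterministic active-set algorithm (`solve_simplex_qp()`). The
fitted simplex vector $\hat f$ is the cell's fractional identity. With an
origin and destination anchor, pseudotime orders cells by
$\tau = f_{dest}/(f_{origin}+f_{dest})$, rank-normalized to $[0,1]$.
Expression kinetics along pseudotime are summarized by local polynomial
(LOESS) regression with span 1/3 and degree 2.

Around the core: mapped-read (≥ 500,000) and gene-body 3′/5′ bias-ratio
(> 2 excluded) library filters; FPKM and log2(FPKM+1) normalization;
CV²-versus-mean variable-gene selection (log₂ FPKM > 1, CV² > 0.5, strict);
co-expression gating; immunofluorescence positivity at control mean + 2 SD;
PCA, Ward.D2/average hierarchical clustering, k-means with a formalized
elbow rule, Venn partitioning of DE lists; and a fully seeded synthetic
generator producing reprogramming-like data with ground truth, so the whole
chain is testable end to end with no external data.

## Worked example

Simulate one route that transiently detours through an early-ICM-like
state, deconvolve every cell against the four signature states, and order
the cells:

```r
library(fateline)

gm    <- gene_universe(seed = 1)                       # 2,000 genes
sigs  <- build_signatures(gm, default_states(), seed = 1)
route <- route_config("icm_route", n_cells = 200,
                      detour_signature = "icm", detour_amplitude = 0.3,
                      seed = 1)
sim   <- simulate_cells(sigs, route, gm)

fpkm <- compute_fpkm(sim$matrix)
pr   <- fractional_identity(fpkm, sigs)    # QP deconvolution per cell
pt   <- assign_pseudotime(pr)              # origin -> destination ordering
pr
#> fraction_profiles: 200 cells x 4 states (origin, destination, mesoderm, icm); 2000 genes used
pt
#> pseudotime_assignment: 200 cells ordered origin -> destination (tau_raw 0.000-1.000)

cor(pt$pseudotime,
    sim$truth$t_true[match(pt$cell_id, sim$truth$cell_id)],
    method = "spearman")
#> [1] 0.947
```

The recovered ordering tracks the generator's hidden trajectory position
(Spearman ρ = 0.947 here). The detour is visible as a mid-trajectory peak
in the ICM fraction:

```r
phase <- cut(sim$truth$t_true[match(pr$cell_id, sim$truth$cell_id)],
             c(0, 1/3, 2/3, 1), labels = c("start", "mid", "end"),
             include.lowest = TRUE)
s <- similarity_summary(pr, phase)
s[s$state == "icm", c("group", "n", "q1", "median", "q3")]
#>  group  n          q1     median         q3
#>    end 69 0.000000000 0.02508146 0.06224682
#>    mid 61 0.233716831 0.25653820 0.28752851
#>  start 70 0.008713019 0.03796757 0.08718302
```

Cells in the middle third of the trajectory carry a median 26% ICM
fraction versus ~3–4% at the endpoints — the signature of a transient
detour rather than terminal differentiation.

The full pipeline (simulate → qc → hvg → deconvolve → pseudotime →
kinetics → structure → report) runs from one YAML-serializable config:

```r
run_pipeline(default_config(seed = 1), out_dir = "run1")
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/fateline.R run --out run1 --seed 1
```

Every run writes its resolved config and a manifest with md5 checksums;
two runs from the same config are byte-identical.

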