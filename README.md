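# cytotraj

Trajectory analysis of mass cytometry (CyTOF) data for human hematopoietic
stem and progenitor cells (HSPCs), for analysts who need the full path from
raw FCS events to annotated, batch-corrected, pseudotime-ordered
populations — with every stage testable against a known ground truth.

Multi-batch CyTOF studies of hematopoiesis face three coupled problems:
per-batch channel distortions that must be removed without flattening
biology; a differentiation *continuum* that clustering has to over-resolve
and then re-merge into interpretable populations; and cross-tissue
comparisons that must not force novel phenotypes into reference labels.
cytotraj implements one coherent pipeline for all three, plus the
downstream statistics used to compare tissues and order expression programs
along differentiation.

## What is inside

**Anchor-sample batch correction.** One anchor (common) sample is acquired
in every batch. Per channel, batch distributions are shifted downward onto
identical anchor medians (`delta_b = median_b − min_b median_b`), values
pushed below zero are resampled from the channel's half-normal noise floor
`|N(0, sigma²)|`, and each batch is rescaled so its 99.8th percentile meets
the cross-batch minimum. The anchor-fitted transform is applied to every
sample of the batch.

**Graph / trajectory scaffold.** knn graph (k = 60 for the diffusion
operator, adaptive Gaussian kernel) → diffusion-map embedding (m = 10) →
second knn graph in diffusion space (k = 15) → Leiden over-clustering
(resolution 10) → cluster-connectivity graph
(observed inter-cluster edges over a configuration-model expectation;
random split of one population scores ≈ 1) → diffusion pseudotime from a
randomly selected root HSC, with distances
`sqrt(sum_l (lambda_l/(1-lambda_l))² (psi_l(i) − psi_l(root))²)`.
Arm-specific re-analyses restrict to annotated, graph-connected clusters
and re-run the scaffold on the proteins those cells express.

**Cluster-constrained label transfer.** Reference and query tissues are
clustered jointly; each query cell votes among the k nearest reference
cells *within its own joint cluster*, and clusters with too few reference
cells yield `"unannotated"` — novel query phenotypes stay unlabeled instead
of being forced into the reference vocabulary.

**Downstream statistics.** 200-bin equal-count pseudotime summaries with
smoothed derivative and inflection detection; Manhattan-distance sample
dissimilarity on cluster proportions with hierarchical clustering; exact
small-sample Wilcoxon rank-sum comparisons with local-FDR/BH adjustment;
percent-positive summaries.

**Synthetic ground truth.** A first-class generator simulates branching
hematopoiesis (HSC → EMP1-3 → erythroid; HSC → MPP → MP → MDP → {pDC arm,
monocyte/cDC arm}; 11 populations, 30 channels) with logistic marker
programs on latent time, zero-inflated log-normal-like noise, per-batch
gain/shift/floor distortions, and a replicated anchor sample per batch.
Minimal FCS 3.1 read/write round-trips the data through the field's format.

## Worked example

```r
library(cytotraj)

lineage  <- build_default_lineage()
dynamics <- default_marker_dynamics()
sheet    <- make_sample_sheet(c("B1", "B2", "B3"), c("BM", "mPB"), 1)
effects  <- random_batch_effects(c("B1", "B2", "B3"), dynamics, seed = 41)
sim      <- simulate_dataset(lineage, dynamics, effects, 2300, sheet, seed = 41)

events   <- arcsinh_transform(sim$events)                       # cofactor 5
anchors  <- subset_events(events, which(events$pheno$is_anchor))
tf       <- fit_anchor_transform(anchors)                       # 99.8th pct
events   <- apply_anchor_transform(events, tf, seed = 41)
events   <- percentile_scale(events)                            # 99.9th pct

traj <- trajectory_pipeline(events$exprs, root_population = "HSC",
                            labels = sim$truth$population, seed = 41)
traj$partition
#> ClusterPartition: 199 clusters over 20700 nodes (resolution 10.00, seed 1042946789)

ann <- majority_labels(traj$partition, sim$truth$population)
er  <- edge_recovery(population_graph(traj$cluster_graph, ann)$edges, lineage)
length(er$recovered); length(er$spurious)
#> [1] 10
#> [1] 5

sel <- sim$truth$branch == "Ery"
cor(traj$pseudotime$pseudotime[sel], sim$truth$latent_time[sel],
    method = "spearman")
#> [1] 0.974
```

All 10 true lineage edges are present in the thresholded cluster graph
(the extra inter-population edges come from clusters straddling boundaries
of the simulated continuum — see the methods vignette), and pseudotime
orders the erythroid arm at Spearman ρ ≈ 0.97 against the generator's
latent time.

The whole flow also runs from one YAML config:

```r
run_pipeline(default_config(output_dir = "runs/demo", seed = 1))
```

writing partition, cluster-graph, composition, dissimilarity, binned
trajectory, derivative and QC tables as TSV plus a checksummed manifest;
rerunning the same config reproduces identical files. A thin CLI wrapper
lives in `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R demo --out runs/demo`).

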