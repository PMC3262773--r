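# mircoord

Genomically clustered microRNAs — precursor miRNA genes lying within ~10 kb
of each other — are typically transcribed as one unit, which raises the
question of how the members of a cluster coordinate their downstream
regulation. `mircoord` answers it on a directed miRNA–TF regulatory
network (typed nodes: transcription factor, miRNA, non-TF gene; edges from
regulator to regulated), for analysts working with miRNA genomics and
regulatory-network data.

The package implements the full analysis as tested, reusable stages:

* **cluster calling** by transitive distance chaining (gap ≤ `cutoff_bp`,
  default 10 kb), with cutoff-sensitivity scans and an optional genomic
  span cap;
* **composition entropies** — for a cluster with members of `N_fam`
  families in proportions `p_i`,

  `E_fam = -(1/ln N_fam) * Σ_i p_i ln p_i  ∈ [0, 1]`,

  0 for a homo-cluster (one family), 1 when all members differ; the same
  statistic over genomic-cluster labels of a module's miRNAs is the module
  cluster entropy `E_c`;
* **target overlap** of a miRNA pair,

  `TO_ij = |T_i ∩ T_j| / (min(|T_i|, |T_j|) + 1)`,

  where `T_i` is the set of nodes reachable from miRNA *i* within *k*
  regulation steps (*k* = 1 for direct targets, `"closure"` for unbounded
  reachability) — the curve of mean TO versus *k* separates immediate from
  delayed coordination;
* **dense-module detection** with a canonical MCODE implementation
  (neighborhood k-core vertex weights, seeded expansion, haircut/fluff
  post-processing) on the undirected projection;
* **permutation null models** — size-preserving random miRNA clusters,
  random module membership, pair-label permutation — reporting the
  never-zero estimator `p = (1 + #{null ≥ obs}) / (1 + B)`;
* a **synthetic scenario generator** that plants clusters, shared-target
  pools, delayed hetero-cluster convergence and dense modules with full
  ground truth, plus an end-to-end **pipeline** (`run_pipeline()`, YAML
  config, CLI at `inst/cli/mircoord`).

Standard formats are consumed directly: GFF3/BED annotation (via
rtracklayer), a TSV family table, Cytoscape SIF for the network, and a
plain TF list.

## Worked example

Generate the default planted scenario, call clusters, detect modules and
test homo-cluster coordination against size-matched random clusters:

```r
library(mircoord)

scen <- generate_scenario(scenario_config(seed = 101))
cc <- detect_clusters(scen$annotation, cutoff_bp = 10000)
cc
#> miRNA cluster call: 10 clusters, 30 isolated of 57 genes (cutoff 10000 bp)
#>   homo: 5  hetero: 5

mods <- mcode(scen$network)
mods
#> MCODE: 8 modules
#>   module_id    seed size    score
#> 1         1 TFM01-1   14 8.615385
#> ...

rs    <- generate_random_clusters(cc$genes$id, cc, B = 20, seed = 7)
pairs <- category_pairs(cc, scen$network, random_sets = rs)
homo  <- target_overlap_table(scen$network, pairs$homo, steps = 1)
rnd   <- target_overlap_table(scen$network,
                              pairs$random[, c("mirna_i", "mirna_j")], steps = 1)
mean(homo$to); mean(rnd$to)
#> [1] 0.7839827
#> [1] 0.005952381

to_contrast_test(homo, rnd, B = 1000, seed = 8)
#> empirical test (greater): observed=0.7777, B=1000, p=0.000999
#>   null quantiles: 5%=-0.0238, 50%=-0.0238, 95%=0.0703

clustered_mirna_enrichment(mods, cc, scen$network, B = 1000, seed = 9)$homo
#> empirical test (greater): observed=1.375, B=1000, p=0.001998
#>   null quantiles: 5%=0.375, 50%=0.625, 95%=1
```

Read: homo-clustered miRNA pairs share ~78% of their direct targets while
size-matched random groupings share essentially none (mean-difference
permutation p at the `1/(B+1)` floor), and the detected modules carry on
average 1.375 homo-clustered miRNAs each — far above random membership.
The same scenario shows hetero-clustered pairs overlapping only from
regulation step 3 on (`to_vs_steps_curve()`).

The full pipeline runs from a YAML configuration:

```sh
Rscript inst/cli/mircoord simulate --preset default --out data/ --seed 101
Rscript inst/cli/mircoord run --config config.yaml
```

writing per-stage TSVs, permutation-test JSON and a `summary.json`, each
stamped with the seed and a configuration hash.

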