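# ecoassembly

Quantify the ecological processes assembling microbial metacommunities —
heterogeneous and homogeneous **selection**, **dispersal limitation**,
**homogenizing dispersal**, and **drift** — from three standard inputs:

* an OTU count table (taxa × samples, TSV),
* a rooted phylogeny with branch lengths (Newick) whose tips match the
  OTU IDs,
* sample metadata (CSV: coordinates, depth layer, environmental
  variables).

The package is aimed at microbial ecologists analysing amplicon surveys of
plankton or other microbial communities across environmental gradients.

## The inference

Every pair of samples is classified by two null-model statistics:

1. **βNTI** — the standardized effect size of the abundance-weighted
   β-mean nearest taxon distance (βMNTD) against a null that shuffles
   taxon identities across the tips of the pool's phylogeny (999
   randomizations). βNTI > 2 ⇒ heterogeneous selection; βNTI < −2 ⇒
   homogeneous selection.
2. **RC<sub>Bray</sub>** — for pairs with |βNTI| ≤ 2, a Raup–Crick test of
   Bray–Curtis dissimilarity against probabilistic community assembly from
   the regional pool (9,999 null assemblies), rescaled to [−1, 1].
   RC > 0.95 ⇒ dispersal limitation; RC < −0.95 ⇒ homogenizing dispersal;
   otherwise drift.

The fraction of pairs in each class is the relative contribution of each
process. Supporting statistics: a Mantel-correlogram test of phylogenetic
signal in niche optima (the inference's prerequisite), the Sloan neutral
community model (immigration rate *m*, *R*², 95% prediction bounds),
Levins' niche breadth *B* and its community mean, Mantel/partial-Mantel
tests linking βNTI to environmental factors, PCNM spatial eigenvectors,
VIF + permutation factor screening, variation partitioning (Hellinger RDA,
adjusted *R*²), distance-decay regression, ANOSIM, and rarefaction /
α-diversity utilities. A synthetic metacommunity generator with known
ground truth (Yule tree, Brownian niche optima, Gaussian niche filtering
along a 170°W-style transect, Dirichlet-multinomial neutral sampling)
backs the test suite end to end.

## Worked example

```r
library(ecoassembly)

sim <- simulate_metacommunity(benchmark_scenario("selection", seed = 42))
b   <- bnti(sim$table, sim$tree, n_null = 999, seed = 42)
rc  <- rc_bray(sim$table, n_null = 9999, seed = 42)
partition_processes(b, rc, group_id = "benchmark")
#> process_partition [benchmark]: 275 pairs
#>   heterogeneous_selection   67.27%
#>   homogeneous_selection      2.55%
#>   dispersal_limitation       5.09%
#>   homogenizing_dispersal    18.91%
#>   drift                      6.18%
```

The benchmark scenario filters 100 taxa through a steep temperature
gradient (three zonally clustered station groups, Gaussian niche width
1.5 °C), so heterogeneous selection dominates by construction — and the
pipeline recovers it. One pair with identical presence sets is degenerate
under the tip-shuffling null and is excluded (hence 275 of 276 pairs).
The within-cluster pairs, pushed toward the same optimum, are more similar
than the Raup–Crick null expects and surface as homogenizing
dispersal/drift.

On a neutral metacommunity the same machinery stays quiet
(|βNTI| ≤ 2 for ~91% of pairs), and the Sloan model recovers dispersal:

```r
neu <- simulate_metacommunity(benchmark_scenario("neutral", seed = 42))
ncm_fit(rarefy(neu$table, seed = 42))
#> ncm_fit: m = 0.4318, N = 1000, R^2 = 0.9405 (99 taxa, 24 samples)
#>   taxa above/within/below prediction: 27/72/0
```

(*m* is an effective immigration rate; see the vignette for its known
upward bias at high *m*.)

## Full pipeline on files

```r
run_pipeline("table.tsv", "tree.nwk", "meta.csv", out_dir = "results",
             group_by = "zone", n_null = 999, n_rc = 9999,
             physical = c("temperature", "salinity", "par", "mld", "eld"),
             nutrient = c("nitrate", "phosphate", "silicate", "ammonia",
                          "iron"),
             seed = 42)
```

writes per-stage CSVs (`alpha.csv`, `bray_curtis.csv`, `anosim.csv`,
`ddr.csv`, `phylo_signal.csv`, `bnti.csv`, `rcbray.csv`,
`process_partition.csv`, `ncm.csv`, `niche.csv`, `mantel_table.csv`,
`heterogeneity.csv`, `vpa.csv`) plus a JSON manifest with seeds and group
sizes. Output is byte-deterministic for a fixed seed. A command-line
wrapper lives at `inst/cli/ecoassembly.R`
(`Rscript inst/cli/ecoassembly.R run --config run.yaml`).

## Documentation

The methods vignette (`vignettes/assembly-inference.Rmd`) describes the
models, their assumptions, all tunable thresholds (±2, ±0.95, 999/9,999
nulls, VIF < 10), the synthetic generator's design rationale, and known
limitations.
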