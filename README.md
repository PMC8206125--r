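# locusnet

Signed weighted gene co-expression networks for locus-centric driver-gene
prioritization.

## What this is for

Recurrent multi-gene deletions (the motivating case is a 21-gene interval
deleted in a neurodevelopmental syndrome) confer large disease risk, but the
culprit genes inside the interval are usually unknown and often poorly
annotated. locusnet implements the systems-biology route to unbiased
hypotheses: build a co-expression network from a healthy bulk transcriptome,
find the modules that harbor the interval genes, show those modules are
reproducible in an independent cohort, and use guilt by association — do an
interval gene's strongest network partners overlap known disease risk
genes? — to prioritize drivers, validating the network's predictions
against an independent differential-expression study.

It is aimed at computational biologists analyzing bulk expression cohorts
(e.g. postmortem brain RNA-Seq) around any genomic interval of interest.

## The statistics at its core

* **Similarity**: biweight midcorrelation; **adjacency**: signed
  soft-threshold, a_ij = ((1 + cor_ij)/2)^beta, with beta the lowest power
  reaching scale-free fit R^2 >= 0.8.
* **Topological overlap**: TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij),
  clustered by average linkage and cut by a two-phase dynamic hybrid-style
  tree cut with a reserved "unassigned" label.
* **Module eigengenes**: first principal component per module; kME = Pearson
  correlation of a gene with an eigengene (hub rule: kME > 0.8, p < 0.05);
  modules with eigengene correlation > 0.8 are merged; meta-modules are
  branches of the eigengene dendrogram.
* **Preservation**: permutation-standardized Zsummary composites of density
  and connectivity statistics against a test cohort (Zsummary > 10 strong,
  2–10 moderate, < 2 none), plus a split-half quality analogue.
* **Prioritization**: intramodular top neighbors (Spearman rho >= 0.5,
  p < 0.05) screened against disease and control gene-set panels with exact
  hypergeometric tests and Benjamini–Hochberg correction per family.
* **Validation**: consensus DEGs (two methods, nominal p < 0.05, concordant
  sign), one-to-one homology filtering, and enrichment at three network
  scales (interval modules, top-neighbor subnetwork, drivers).

A synthetic-study generator (factor-model cohorts with planted modules,
covariates, enriched gene-set panels, and a negative-binomial DEG study)
makes the whole pipeline runnable and testable without any external data.

## Worked example

```r
library(locusnet)

cfg <- sim_config(seed = 1)              # 2,000 genes, 5 planted modules
sim <- simulate_cohort(cfg)
expr <- residualize(sim$ref, sim$covariates)

net <- build_network(expr, network_config(beta = 8))
table(net$partition)
#>
#>   0   1   2   3   4   5
#> 799 445 300 205 150 101

pres <- z_summary_pres(expr, sim$test, net$partition,
                       n_perm = 200, seed = 1, beta = net$beta)
pres[, c("module", "size_used", "z_summary", "category")]
#>   module size_used z_summary category
#> 1      1       445 32.254663   strong
#> 2      2       300 35.041241   strong
#> 3      3       205 15.213275   strong
#> 4      4       150 11.401532   strong
#> 5      5       101  8.414947 moderate

panels <- plant_disease_sets(sim$truth, sim$ref)
pri <- prioritize_interval(expr, net$partition, net$kme,
                           sim$truth$interval_genes,
                           panels$disease, panels$control)
#> seeds with empty neighbor sets skipped: IVG19
pri$screen$specificity
#>    family n_tests n_significant fraction_significant
#> 1 control      60             0            0.0000000
#> 2 disease      90            12            0.1333333
head(pri$drivers$prioritized_seeds)
#> [1] "IVG01" "IVG02" "IVG03" "IVG04" "IVG05" "IVG07"
```

Reading the output: the partition recovers the five planted modules with an
adjusted Rand index of 0.91 against the planted truth (label 0 is the
unassigned background); the planted modules show strong test-cohort
preservation, with the smallest landing in the moderate band exactly as
small modules do in real cohorts; and the enrichment screen flags the seeds
whose neighborhoods carry planted disease genes (12 of 90 disease tests)
while all 60 control-panel tests stay null — the specificity contrast that
justifies the guilt-by-association prioritization. The three planted target
seeds (here IVG01, IVG07, IVG12) are among the prioritized seeds; their
strong co-module seeds join them because co-module seeds share
neighborhoods, and one seed with no qualifying intramodular neighbor is
skipped with a message.

The same stages are scriptable from the shell via
`Rscript inst/cli/locusnet.R <simulate|preprocess|network|preserve|prioritize|validate-degs> ...`;
rerunning any stage with the same configuration and seed reproduces its
output files byte for byte.

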