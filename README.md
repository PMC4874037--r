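# ipanet

Integrative multi-omics pathway enrichment with network-based validation.

`ipanet` is for systems-biology analysts who have matched gene-expression
and metabolite-abundance profiles on the same two-class tissue design (for
example benign vs tumour) and want a single, variability-aware ranking of
biochemical pathways — plus a network-level significance check on the
pathways that ranking nominates.

## The method

Each pathway *j* = 1, …, *J* is enriched twice, once per omics layer:

* **Gene layer (GSA).** Per-gene Welch *t* statistics are summarized per
  pathway by the *maxmean* statistic
  (s⁺ = Σᵢ max(zᵢ, 0)/m vs s⁻ = Σᵢ max(−zᵢ, 0)/m, whichever dominates),
  restandardized against randomly drawn gene sets of the same size, and
  tested by class-label permutation.
* **Metabolite layer (network mixed model).** A substrate–product reaction
  graph is turned into an influence matrix Λ = (I − ρĀ)⁻¹ (Ā the
  row-normalized adjacency), and condition effects are modeled as
  yᵢ = Λβₖ + Λγᵢ + εᵢ with sample-level and residual variance components
  estimated by REML. Pathway contrasts ℓⱼ = Λᵀbⱼ are tested with an exact
  *t* reference on the projected profile (a model-based Satterthwaite
  route is also available).

Both rankings are bootstrapped (stratified resampling of samples within
class, 1,000 resamples by default). With R(j,G), S(j,G), R(j,M), S(j,M)
the bootstrap mean and SD of pathway *j*'s rank in the gene (G) and
metabolite (M) layers, the combined integrative score is

    R(j) = (J + 1 − R(j,G)) / S(j,G)  +  (J + 1 − R(j,M)) / S(j,M)

(higher = more enriched; for J = 87 pathways the reversal constant is 88).
Outlier pathways are nominated by an iterative one-sided Grubbs (normal
outlier) test at α = 0.03.

Nominations are then validated on the pathway-interaction network (two
pathways interact when their members are linked by a cross-pathway
reaction edge or a curated gene–gene interaction). For nominated pathway
*j*, N(j) counts its enriched neighbors — neighbors ranked in the top 50 %
of the gene-layer enrichment — and is compared against N(j,b) on
*B* = 10,000 degree-preserving random networks (double edge swaps):

    P(j) = (1/B) · #{b : N(j,b) > N(j)}

A concordance report (fraction of pathways whose gene-vs-metabolite rank
difference lies within one SD of all differences) summarizes agreement
between the two layers.

## Worked example

Everything below is generated in code — no downloads. Plant one enriched
pathway (effect 2.5 SD in both layers) in a synthetic 16 + 12 study with
87 pathways and run the whole pipeline:

```r
library(ipanet)

cfg <- simulation_config(
  planted_pathways = data.frame(pathway_id = "PW005",
                                delta_gene = 2.5, delta_metab = 2.5),
  seed = 7)
study <- generate_study(cfg)
dir <- tempfile(); write_study(study, dir)

pcfg <- pipeline_config(
  expression     = file.path(dir, "expression.tsv"),
  metabolites    = file.path(dir, "metabolites.tsv"),
  labels         = file.path(dir, "labels.tsv"),
  gene_gmt       = file.path(dir, "pathways_genes.gmt"),
  metabolite_gmt = file.path(dir, "pathways_metabolites.gmt"),
  reactions      = file.path(dir, "reactions.tsv"),
  n_boot = 50, n_perm = 200, n_catalog = 100, B = 1000, seed = 11)
res <- run_pipeline(pcfg, tempfile())

head(res$combined, 3)
#>   pathway_id R_gene S_gene R_metab  S_metab    score     grubbs_p is_top
#> 5      PW005      1      0    1.00  0.00000 348.0000 1.246208e-20   TRUE
#> 4      PW004      2      0   31.52 24.08170 174.3453 1.121803e-12   TRUE
#> 6      PW006      3      0   45.78 25.70023 171.6428 1.119417e-91   TRUE
res$concordance
#> concordance: 67.8% of pathways within 1 SD (SD of rank differences = 33.47)
res$permutation[res$permutation$pathway_id == "PW005", ]
#>   pathway_id degree N_obs P_strict     P_geq    B
#> 1      PW005      3     2    0.131 0.5084915 1000
```

The planted pathway PW005 holds rank 1 in both bootstrap rankings (rank SD
0, so its score hits the SD floor: (88 − 1)/0.5 × 2 = 348) and is
Grubbs-flagged; its ring neighbors PW004/PW006 inherit part of the signal
through shared members. The run directory additionally contains every
stage table (enrichment, bootstrap, combined scores, pathway graph,
permutation test), a JSON manifest, and a plain-text summary.

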