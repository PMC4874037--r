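# Shared fixture builders; everything is generated in code.

two_class_labels <- function(n1, n2) {
  ids <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  class_labels(stats::setNames(rep(c(1L, 2L), c(n1, n2)), ids))
}

named_matrix <- function(values, n_feat, n_samp, prefix = "f",
                         samples = NULL) {
  m <- matrix(values, n_feat, n_samp)
  rownames(m) <- sprintf("%s%02d", prefix, seq_len(n_feat))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(n_samp))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Study conditions used by the calibration and recovery simulations: the
# two-class 16 + 12 design with 87 pathways; pathway sizes kept at the low
# end so that many replicates fit in a test run.
calibration_config <- function(seed, planted = NULL) {
  simulation_config(genes_per_pathway = c(5L, 8L),
                    metabolites_per_pathway = c(3L, 5L),
                    planted_pathways = planted, seed = seed)
}

# One full integrative pass (both layers enriched, bootstrapped, combined)
# without file IO; mirrors run_pipeline()'s in-memory flow.
integrate_study <- function(st, n_boot = 100L, n_perm_obs = 400L,
                            n_catalog_obs = 200L, n_perm_boot = 100L,
                            n_catalog_boot = 50L, rho = 0.3, seed = 1L) {
  expr <- preprocess(st$expression)
  met <- preprocess(st$metabolites)
  net <- subset_network(build_metabolite_network(st$reactions),
                        rownames(met))
  infl <- influence_matrix(net, rho, metabolites = rownames(met))
  pw <- st$pathways
  gene_tab <- gsa_enrich(expr, st$labels, pw, n_perm = n_perm_obs,
                         n_catalog = n_catalog_obs, seed = seed + 1L)
  metab_tab <- netgsa_enrich(met, st$labels, infl, pw)
  gene_fn <- function(Y, cls, s)
    gsa_enrich(omics_matrix(Y, "gene"),
               class_labels(stats::setNames(cls, colnames(Y))), pw,
               n_perm = n_perm_boot, n_catalog = n_catalog_boot, seed = s)
  met_fn <- function(Y, cls, s)
    netgsa_enrich(omics_matrix(Y, "metabolite"),
                  class_labels(stats::setNames(cls, colnames(Y))), infl, pw,
                  estimate_components = FALSE)
  boot_gene <- suppressMessages(
    bootstrap_rankings(expr, st$labels, gene_fn, n_boot = n_boot,
                       seed = seed + 2L))
  boot_metab <- suppressMessages(
    bootstrap_rankings(met, st$labels, met_fn, n_boot = n_boot,
                       seed = seed + 3L))
  common <- intersect(boot_gene$pathway_id, boot_metab$pathway_id)
  combined <- suppressMessages(combine_layers(
    boot_gene[boot_gene$pathway_id %in% common, ],
    boot_metab[boot_metab$pathway_id %in% common, ]))
  graph <- build_pathway_graph(pw, net)
  list(expr = expr, met = met, net = net, infl = infl, gene_tab = gene_tab,
       metab_tab = metab_tab, boot_gene = boot_gene,
       boot_metab = boot_metab, combined = combined, graph = graph)
}

# Small synthetic pipeline input directory
write_planted_dir <- function(seed, delta = 2.5,
                              planted_id = "PW005") {
  cfg <- calibration_config(seed, planted = data.frame(
    pathway_id = planted_id, delta_gene = delta, delta_metab = delta))
  dir <- tempfile("study")
  write_study(generate_study(cfg), dir)
  dir
}
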