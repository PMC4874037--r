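#' Pipeline configuration
#'
#' Collects all input paths, tuning parameters and stage seeds for
#' [run_pipeline()]. Every source of randomness flows from the explicit
#' `seed` (stage seeds are fixed offsets of it); there is no wall-clock
#' seeding, so a run is fully determined by its configuration.
#'
#' @param expression,metabolites,labels,gene_gmt,metabolite_gmt,reactions
#'   paths to the pipeline inputs (TSV matrices, labels TSV, GMT
#'   memberships, reactions TSV), e.g. as written by [write_study()].
#' @param n_boot bootstrap resamples per layer (default 1000).
#' @param n_perm GSA label permutations (default 1000).
#' @param n_catalog GSA restandardization sets per size (default 500).
#' @param n_perm_boot,n_catalog_boot smaller GSA settings used inside the
#'   bootstrap, where only ranks are consumed.
#' @param B random networks for the permutation test (default 10000).
#' @param rho influence-matrix propagation strength (default 0.3).
#' @param s_floor rank-SD floor in the combined score (default 0.5).
#' @param alpha_outlier Grubbs nomination level (default 0.03).
#' @param top_frac enriched-neighbor labelling fraction (default 0.5).
#' @param min_genes,min_metabs pathway eligibility floors.
#' @param max_missing_frac preprocessing missingness filter.
#' @param log_transform_genes,log_transform_metabs apply `log2` during
#'   preprocessing (default off: inputs are assumed already on a log
#'   scale).
#' @param se_method metabolite-layer SE estimator (see [netgsa_enrich()]).
#' @param score_variant combined-score parenthesization (see
#'   [combined_score()]).
#' @param extra_nominated pathway ids to nominate in addition to the
#'   Grubbs-flagged ones.
#' @param n_swaps swap attempts per random network (default `10 * |E|`).
#' @param seed master seed.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, metabolites, labels, gene_gmt,
                            metabolite_gmt, reactions,
                            n_boot = 1000L, n_perm = 1000L,
                            n_catalog = 500L, n_perm_boot = 100L,
                            n_catalog_boot = 100L, B = 10000L, rho = 0.3,
                            s_floor = 0.5, alpha_outlier = 0.03,
                            top_frac = 0.5, min_genes = 5L, min_metabs = 3L,
                            max_missing_frac = 0.3,
                            log_transform_genes = FALSE,
                            log_transform_metabs = FALSE,
                            se_method = "profile",
                            score_variant = "reversed_over_sd",
                            extra_nominated = character(),
                            n_swaps = NULL, seed = 1L) {
  cfg <- as.list(environment())
  check_count(cfg$n_boot, "n_boot", min = 2L)
  check_count(cfg$n_perm, "n_perm", min = 100L)
  check_count(cfg$B, "B", min = 1L)
  check_fraction(cfg$top_frac, "top_frac")
  check_fraction(cfg$max_missing_frac, "max_missing_frac")
  if (cfg$rho < 0 || cfg$rho >= 1) fail("rho must be in [0, 1)")
  if (cfg$alpha_outlier <= 0 || cfg$alpha_outlier >= 1)
    fail("alpha_outlier must be in (0, 1)")
  if (cfg$s_floor <= 0) fail("s_floor must be positive")
  check_count(cfg$seed, "seed", min = 0L)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file must contain the input paths; any other field overrides a
#' [pipeline_config()] default.
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# fixed per-stage seed offsets from the master seed
stage_seeds <- function(seed) {
  list(gsa = seed + 101L, netgsa = seed + 202L, boot_gene = seed + 303L,
       boot_metab = seed + 404L, perm = seed + 505L)
}

#' Run the full integrative pipeline
#'
#' simulate-independent orchestration: read and preprocess both layers,
#' enrich genes (GSA) and metabolites (network mixed model), bootstrap both
#' rankings, combine them into the integrative score and nominate outlier
#' pathways, compute layer concordance, build the pathway-interaction
#' graph, and run the degree-preserving neighbor permutation test for the
#' nominated pathways. All stage outputs, a JSON manifest (config + seeds +
#' package version) and a human-readable summary are written to `out_dir`.
#' A stage failure writes a `FAILED` marker naming the stage and re-throws.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if absent).
#' @return invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("ipanet pipeline run\n", file = logf)
  log_line <- function(fmt, ...)
    cat(sprintf(paste0(fmt, "\n"), ...), file = logf, append = TRUE)
  seeds <- stage_seeds(config$seed)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(stage, conditionMessage(e)), file.path(out_dir, "FAILED"))
    fail("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "read_inputs"
    expr <- read_omics_matrix(config$expression, "gene")
    metab <- read_omics_matrix(config$metabolites, "metabolite")
    labels <- read_labels(config$labels)
    pw <- pathway_set(gene_sets = read_gmt(config$gene_gmt),
                      metabolite_sets = read_gmt(config$metabolite_gmt))
    reactions <- read_reactions(config$reactions)
    log_line("read_inputs: %d genes, %d metabolites, %d samples, %d pathways, %d reactions",
             nrow(expr), nrow(metab), ncol(expr), length(pw),
             nrow(reactions))

    stage <- "preprocess"
    expr <- preprocess(expr, config$max_missing_frac,
                       config$log_transform_genes)
    metab <- preprocess(metab, config$max_missing_frac,
                        config$log_transform_metabs)
    log_line("preprocess: %d genes, %d metabolites retained", nrow(expr),
             nrow(metab))

    stage <- "network"
    net <- build_metabolite_network(reactions)
    # metabolites filtered out during preprocessing cannot be modeled
    infl <- influence_matrix(subset_network(net, rownames(metab)),
                             config$rho, metabolites = rownames(metab))
    graph <- build_pathway_graph(pw, net)
    write_pathway_graph(graph, file.path(out_dir, "pathway_graph.tsv"))
    log_line("network: %d metabolite edges, %d pathway interactions",
             nrow(net$edges), nrow(graph$edges))

    stage <- "enrich_genes"
    gene_tab <- gsa_enrich(expr, labels, pw, n_perm = config$n_perm,
                           seed = seeds$gsa, n_catalog = config$n_catalog,
                           min_genes = config$min_genes)
    write_tsv(gene_tab, file.path(out_dir, "gene_enrichment.tsv"))

    stage <- "enrich_metabolites"
    metab_tab <- netgsa_enrich(metab, labels, infl, pw,
                               min_metabs = config$min_metabs,
                               se_method = config$se_method)
    write_tsv(metab_tab, file.path(out_dir, "metabolite_enrichment.tsv"))
    log_line("enrichment: %d gene-eligible, %d metabolite-eligible pathways",
             nrow(gene_tab), nrow(metab_tab))

    stage <- "bootstrap"
    common <- intersect(gene_tab$pathway_id, metab_tab$pathway_id)
    if (length(common) < 4L)
      fail("only %d pathway(s) eligible on both layers", length(common))
    gene_fn <- function(Y, cls, seed) {
      lab <- class_labels(stats::setNames(cls, colnames(Y)))
      gsa_enrich(omics_matrix(Y, "gene"), lab, pw,
                 n_perm = config$n_perm_boot, seed = seed,
                 n_catalog = config$n_catalog_boot,
                 min_genes = config$min_genes)
    }
    metab_fn <- function(Y, cls, seed) {
      lab <- class_labels(stats::setNames(cls, colnames(Y)))
      netgsa_enrich(omics_matrix(Y, "metabolite"), lab, infl, pw,
                    min_metabs = config$min_metabs,
                    se_method = config$se_method,
                    estimate_components = FALSE)
    }
    boot_gene <- bootstrap_rankings(expr, labels, gene_fn,
                                    n_boot = config$n_boot,
                                    seed = seeds$boot_gene)
    boot_metab <- bootstrap_rankings(metab, labels, metab_fn,
                                     n_boot = config$n_boot,
                                     seed = seeds$boot_metab)
    write_tsv(boot_gene, file.path(out_dir, "bootstrap_gene.tsv"))
    write_tsv(boot_metab, file.path(out_dir, "bootstrap_metabolite.tsv"))
    log_line("bootstrap: %d resamples per layer (%d + %d redraws)",
             config$n_boot, attr(boot_gene, "redraws"),
             attr(boot_metab, "redraws"))

    stage <- "integrate"
    combined <- combine_layers(
      boot_gene[boot_gene$pathway_id %in% common, ],
      boot_metab[boot_metab$pathway_id %in% common, ],
      s_floor = config$s_floor, alpha = config$alpha_outlier,
      variant = config$score_variant)
    write_tsv(combined, file.path(out_dir, "combined_scores.tsv"))
    conc <- concordance(gene_tab[gene_tab$pathway_id %in% common, ],
                        metab_tab[metab_tab$pathway_id %in% common, ])
    jsonlite::write_json(
      list(fraction = conc$fraction,
           sd_of_differences = conc$sd_of_differences),
      file.path(out_dir, "concordance.json"), auto_unbox = TRUE,
      digits = NA)
    nominated <- union(combined$pathway_id[combined$is_top],
                       config$extra_nominated)
    log_line("integrate: concordance %.3f, %d pathway(s) nominated",
             conc$fraction, length(nominated))

    stage <- "neighbors"
    perm <- NULL
    if (length(nominated)) {
      interacting <- setdiff(
        unique(unlist(lapply(nominated, graph_neighbors, graph = graph))),
        nominated)
      labs <- label_enriched(graph, interacting, gene_tab,
                             top_frac = config$top_frac)
      lab_path <- file.path(out_dir, "enrichment_labels.tsv")
      writeLines(sprintf("# provenance: %s", attr(labs, "provenance")),
                 lab_path)
      suppressWarnings(write.table(
        data.frame(pathway_id = names(labs), enriched = as.logical(labs)),
        lab_path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = TRUE, append = TRUE))
      perm <- permutation_test(graph, labs, nominated, B = config$B,
                               n_swaps = config$n_swaps, seed = seeds$perm)
      write_tsv(perm, file.path(out_dir, "permutation_test.tsv"))
      log_line("neighbors: %d interacting pathway(s), %d enriched label(s)",
               length(interacting), sum(labs))
    } else {
      log_line("neighbors: no pathway nominated, permutation test skipped")
    }

    stage <- "report"
    manifest <- list(config = unclass(config), stage_seeds = seeds,
                     package_version = as.character(packageVersion("ipanet")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    summary_lines <- c(
      sprintf("pathways scored: %d", nrow(combined)),
      sprintf("layer concordance: %.1f%%", 100 * conc$fraction),
      sprintf("nominated pathways: %s",
              if (length(nominated)) paste(nominated, collapse = ", ")
              else "(none)"),
      if (!is.null(perm))
        sprintf("smallest permutation P: %s (P_strict = %.4g)",
                attr(perm, "top"),
                min(perm$P_strict))
      else "permutation test not run")
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))

    invisible(list(out_dir = out_dir, gene_table = gene_tab,
                   metabolite_table = metab_tab, boot_gene = boot_gene,
                   boot_metab = boot_metab, combined = combined,
                   concordance = conc, graph = graph, nominated = nominated,
                   permutation = perm))
  }, error = on_fail)
}
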