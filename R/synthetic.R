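#' Configure a synthetic two-class multi-omics study
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' two-class tissue design (defaults: 16 benign vs 12 tumour samples),
#' 87 pathways with overlapping gene and metabolite membership arranged in a
#' ring (each pathway shares a fraction of its successor's members, which
#' keeps the pathway-interaction network connected), a substrate-product
#' metabolite reaction graph, planted enriched pathways with configurable
#' per-layer effect sizes, additive Gaussian noise on the log2 scale, and
#' completely-at-random metabolite missingness.
#'
#' @param n_class1 samples in class 1 ("benign"; default 16).
#' @param n_class2 samples in class 2 ("tumour"; default 12).
#' @param n_pathways number of pathways (default 87).
#' @param genes_per_pathway length-2 integer range of exclusive gene members
#'   per pathway.
#' @param metabolites_per_pathway length-2 integer range of exclusive
#'   metabolite members per pathway.
#' @param overlap_frac fraction of a successor pathway's members shared with
#'   its predecessor, in `[0, 1)`.
#' @param planted_pathways data.frame with columns `pathway_id`,
#'   `delta_gene`, `delta_metab` (effect sizes in units of `noise_sd`,
#'   additive on the log2 scale), or `NULL` for a null study.
#' @param noise_sd log2-scale Gaussian noise SD.
#' @param missing_frac_metab MCAR missingness rate for the metabolite matrix.
#' @param cross_pathway_reaction_rate expected number of reactions whose
#'   substrate and product lie in different pathways (Poisson).
#' @param seed RNG seed.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_class1 = 16, n_class2 = 12, n_pathways = 87,
                              genes_per_pathway = c(5L, 30L),
                              metabolites_per_pathway = c(3L, 15L),
                              overlap_frac = 0.25,
                              planted_pathways = NULL,
                              noise_sd = 1,
                              missing_frac_metab = 0.1,
                              cross_pathway_reaction_rate = 30,
                              seed = 1L) {
  cfg <- list(n_class1 = check_count(n_class1, "n_class1"),
              n_class2 = check_count(n_class2, "n_class2"),
              n_pathways = check_count(n_pathways, "n_pathways", min = 2L),
              genes_per_pathway = as.integer(genes_per_pathway),
              metabolites_per_pathway = as.integer(metabolites_per_pathway),
              overlap_frac = check_fraction(overlap_frac, "overlap_frac"),
              planted_pathways = planted_pathways,
              noise_sd = noise_sd,
              missing_frac_metab = check_fraction(missing_frac_metab,
                                                  "missing_frac_metab"),
              cross_pathway_reaction_rate = cross_pathway_reaction_rate,
              seed = check_count(seed, "seed", min = 0L))
  if (cfg$n_class1 + cfg$n_class2 < 4L)
    fail("need at least 4 samples in total")
  if (length(cfg$genes_per_pathway) != 2L || any(cfg$genes_per_pathway < 1L) ||
      diff(cfg$genes_per_pathway) < 0L)
    fail("genes_per_pathway must be an increasing range of counts >= 1")
  if (length(cfg$metabolites_per_pathway) != 2L ||
      any(cfg$metabolites_per_pathway < 1L) ||
      diff(cfg$metabolites_per_pathway) < 0L)
    fail("metabolites_per_pathway must be an increasing range of counts >= 1")
  if (!is.null(planted_pathways)) {
    need <- c("pathway_id", "delta_gene", "delta_metab")
    if (!is.data.frame(planted_pathways) ||
        !all(need %in% names(planted_pathways)))
      fail("planted_pathways must have columns %s", paste(need, collapse = ", "))
    if (any(planted_pathways$delta_gene < 0) ||
        any(planted_pathways$delta_metab < 0))
      fail("effect sizes must be >= 0")
    valid <- pathway_id_format(seq_len(cfg$n_pathways))
    bad <- setdiff(planted_pathways$pathway_id, valid)
    if (length(bad))
      fail("planted pathway id(s) outside 1..n_pathways: %s",
           paste(bad, collapse = ", "))
  }
  if (cfg$noise_sd <= 0) fail("noise_sd must be positive")
  structure(cfg, class = "simulation_config")
}

pathway_id_format <- function(j) sprintf("PW%03d", j)

# Ring membership: each pathway gets an exclusive block of features plus a
# shared slice borrowed from its ring successor.
ring_members <- function(n_pathways, size_range, overlap_frac, prefix) {
  sizes <- sample(seq(size_range[1L], size_range[2L]), n_pathways,
                  replace = TRUE)
  n_shared <- floor(overlap_frac * sizes)
  if (any(n_shared >= sizes))
    fail("overlap_frac %.2f leaves a pathway with no exclusive members",
         overlap_frac)
  stop_at <- cumsum(sizes)
  start_at <- stop_at - sizes + 1L
  ids <- sprintf("%s%05d", prefix, seq_len(sum(sizes)))
  own <- lapply(seq_len(n_pathways),
                function(j) ids[start_at[j]:stop_at[j]])
  members <- lapply(seq_len(n_pathways), function(j) {
    succ <- if (j == n_pathways) 1L else j + 1L
    c(own[[j]], head(own[[succ]], n_shared[succ]))
  })
  names(members) <- pathway_id_format(seq_len(n_pathways))
  list(members = members, own = own, all_ids = ids)
}

#' Generate a synthetic study
#'
#' Deterministic for a fixed seed. Member features of each planted pathway
#' have their class-2 mean shifted additively by `delta * noise_sd` on the
#' log2 scale; all other features are exchangeable across classes.
#' Within-pathway reactions chain each pathway's metabolite members into a
#' path; cross-pathway reactions are placed uniformly over ordered
#' metabolite pairs from distinct pathways at the configured Poisson rate.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_study`: list with `expression` and
#'   `metabolites` ([omics_matrix()]), `labels` ([class_labels()]),
#'   `pathways` ([pathway_set()]), `reactions` (data.frame), `truth`
#'   (planted table), and the `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  J <- config$n_pathways
  n1 <- config$n_class1
  n2 <- config$n_class2
  n <- n1 + n2
  sample_ids <- c(sprintf("Ben%02d", seq_len(n1)),
                  sprintf("PCa%02d", seq_len(n2)))
  cls <- class_labels(stats::setNames(rep(c(1L, 2L), c(n1, n2)), sample_ids),
                      class_names = c("Ben", "PCa"))

  genes <- ring_members(J, config$genes_per_pathway, config$overlap_frac, "G")
  metabs <- ring_members(J, config$metabolites_per_pathway,
                         config$overlap_frac, "M")
  pw <- pathway_set(gene_sets = genes$members,
                    metabolite_sets = metabs$members)

  planted <- config$planted_pathways %||%
    data.frame(pathway_id = character(), delta_gene = numeric(),
               delta_metab = numeric())

  simulate_layer <- function(all_ids, members, baseline, delta_col) {
    p <- length(all_ids)
    base <- rnorm(p, mean = baseline, sd = 1)
    m <- base + matrix(rnorm(p * n, sd = config$noise_sd), p, n)
    dimnames(m) <- list(all_ids, sample_ids)
    for (k in seq_len(nrow(planted))) {
      feats <- members[[planted$pathway_id[k]]]
      shift <- planted[[delta_col]][k] * config$noise_sd
      m[feats, cls == 2L] <- m[feats, cls == 2L] + shift
    }
    m
  }
  expr <- simulate_layer(genes$all_ids, genes$members, 8, "delta_gene")
  metab <- simulate_layer(metabs$all_ids, metabs$members, 10, "delta_metab")
  if (config$missing_frac_metab > 0) {
    mask <- matrix(runif(length(metab)) < config$missing_frac_metab,
                   nrow(metab), ncol(metab))
    metab[mask] <- NA_real_
  }

  # within-pathway chains connect each pathway's metabolites; borrowed
  # members make consecutive ring pathways interact
  sub <- prod <- character(0)
  for (j in seq_len(J)) {
    mm <- metabs$members[[j]]
    if (length(mm) >= 2L) {
      sub <- c(sub, mm[-length(mm)])
      prod <- c(prod, mm[-1L])
    }
  }
  n_cross <- rpois(1L, config$cross_pathway_reaction_rate)
  for (k in seq_len(n_cross)) {
    jj <- sample.int(J, 2L)
    a <- sample(metabs$own[[jj[1L]]], 1L)
    b <- sample(metabs$own[[jj[2L]]], 1L)
    sub <- c(sub, a)
    prod <- c(prod, b)
  }
  reactions <- data.frame(
    reaction_id = sprintf("RXN%05d", seq_along(sub)),
    substrates = sub, products = prod, stringsAsFactors = FALSE)

  structure(list(expression = omics_matrix(expr, "gene"),
                 metabolites = omics_matrix(metab, "metabolite"),
                 labels = cls,
                 pathways = pw,
                 reactions = reactions,
                 truth = planted,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d genes x %d samples, %d metabolites, %d pathways, %d planted\n",
    nrow(x$expression), ncol(x$expression), nrow(x$metabolites),
    length(x$pathways), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic study to the standard pipeline input files
#'
#' Writes `expression.tsv`, `metabolites.tsv` (empty cell = missing),
#' `labels.tsv`, `pathways_genes.gmt`, `pathways_metabolites.gmt`,
#' `reactions.tsv` and `truth.json` into `dir`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(study$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(study$metabolites, file.path(dir, "metabolites.tsv"))
  write_labels(study$labels, file.path(dir, "labels.tsv"))
  write_gmt(study$pathways$gene_members, file.path(dir, "pathways_genes.gmt"))
  write_gmt(study$pathways$metabolite_members,
            file.path(dir, "pathways_metabolites.gmt"))
  write_reactions(study$reactions, file.path(dir, "reactions.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
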