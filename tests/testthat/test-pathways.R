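rxn <- function(id, s, p)
  data.frame(reaction_id = id, substrates = s, products = p,
             stringsAsFactors = FALSE)

test_that("edges follow the substrate-product rule", {
  # A + B -> C gives A-C and B-C but never A-B
  net <- build_metabolite_network(rxn("r1", "A;B", "C"))
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(paste(net$edges$from, net$edges$to) %in%
                    c("A C", "B C")))
  # reversible pair collapses to a single undirected edge
  net2 <- build_metabolite_network(rbind(rxn("r1", "A", "B"),
                                         rxn("r2", "B", "A")))
  expect_equal(nrow(net2$edges), 1L)
  # A -> A: node present, no self-loop
  net3 <- build_metabolite_network(rxn("r1", "A", "A"))
  expect_identical(net3$nodes, "A")
  expect_equal(nrow(net3$edges), 0L)
})

test_that("degenerate and malformed reaction lists are handled", {
  empty <- build_metabolite_network(
    data.frame(reaction_id = character(), substrates = character(),
               products = character()))
  expect_equal(length(empty$nodes), 0L)
  expect_error(build_metabolite_network(rxn("rX", "", "B")), "rX")
  expect_lte(nrow(build_metabolite_network(
    rbind(rxn("r1", "A;B", "C;D"), rxn("r2", "A", "C")))$edges),
    2 * 2 + 1)  # sum over reactions of |S| * |P|
})

test_that("currency metabolite exclusion removes their edges", {
  net <- build_metabolite_network(rxn("r1", "A;H2O", "B"),
                                  exclude = "H2O")
  expect_false("H2O" %in% net$nodes)
  expect_equal(nrow(net$edges), 1L)
})

two_pathway_set <- function(mA, mB)
  pathway_set(gene_sets = list(X = "gX", Y = "gY"),
              metabolite_sets = list(X = mA, Y = mB))

test_that("pathway edges require cross-pathway molecular interactions", {
  # one cross reaction edge connects otherwise disjoint pathways
  pw <- two_pathway_set(c("A", "B"), c("C", "D"))
  net <- build_metabolite_network(rxn("r1", "A", "C"))
  g <- build_pathway_graph(pw, net)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(c(g$edges), c("X", "Y"))
  # shared membership alone creates no edge
  pw2 <- two_pathway_set(c("A", "S"), c("C", "S"))
  net2 <- build_metabolite_network(rxn("r1", "A", "S"))  # edge inside X
  g2 <- build_pathway_graph(pw2, net2)
  expect_equal(nrow(g2$edges), 1L)  # A-S touches S which is also in Y
  g3 <- build_pathway_graph(pw2, NULL)
  expect_equal(nrow(g3$edges), 0L)
  # a single-node graph has no edges
  g4 <- pathway_graph("X", NULL)
  expect_equal(length(g4$nodes), 1L)
  expect_equal(nrow(g4$edges), 0L)
})

test_that("gene links connect pathways and monotonicity holds", {
  pw <- two_pathway_set(c("A"), c("C"))
  g0 <- build_pathway_graph(pw, NULL,
                            extra_gene_links = cbind("gX", "gY"))
  expect_equal(nrow(g0$edges), 1L)
  # adding a reaction never removes a pathway edge
  net1 <- build_metabolite_network(rxn("r1", "A", "C"))
  net2 <- build_metabolite_network(rbind(rxn("r1", "A", "C"),
                                         rxn("r2", "C", "A")))
  e1 <- build_pathway_graph(pw, net1)$edges
  e2 <- build_pathway_graph(pw, net2)$edges
  expect_true(all(paste(e1[, 1], e1[, 2]) %in% paste(e2[, 1], e2[, 2])))
})

test_that("pathway graph construction is order-invariant", {
  st <- generate_study(calibration_config(13))
  net <- build_metabolite_network(st$reactions)
  g <- build_pathway_graph(st$pathways, net)
  # permute reaction rows: same canonical edge set
  net_perm <- build_metabolite_network(
    st$reactions[rev(seq_len(nrow(st$reactions))), ])
  g_perm <- build_pathway_graph(st$pathways, net_perm)
  expect_identical(g$edges, g_perm$edges)
  d <- graph_degree(g)
  expect_equal(sum(d), 2L * nrow(g$edges))
})

test_that("GMT files round-trip and reject duplicate pathway names", {
  sets <- list(P1 = c("g1", "g2", "g3"), P2 = c("g2", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
  writeLines(c("P1\tna\tg1", "P1\tna\tg2"), f)
  expect_error(read_gmt(f), "P1")
})

test_that("pathways without members are dropped with a warning", {
  expect_warning(
    pw <- pathway_set(gene_sets = list(P1 = "g1", P2 = "g2",
                                       P3 = character())),
    "P3")
  expect_equal(length(pw), 2L)
})
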