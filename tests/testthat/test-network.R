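star_graph <- function() {
  typed_graph(
    nodes = tibble::tibble(id = c("hub", "a", "b", "c"), role = "target"),
    edges = tibble::tibble(from = c("hub", "hub", "hub"), to = c("a", "b", "c"))
  )
}

test_that("typed_graph enforces simplicity and endpoint existence", {
  nodes <- tibble::tibble(id = c("a", "b"), role = "target")
  expect_error(typed_graph(nodes, tibble::tibble(from = "a", to = "a")), "self-loop")
  expect_error(typed_graph(nodes, tibble::tibble(from = "a", to = "z")), "endpoint")
  g <- typed_graph(nodes, tibble::tibble(from = c("a", "b"), to = c("b", "a")))
  expect_identical(nrow(g$edges), 1L) # duplicate undirected edge collapses
  expect_error(
    typed_graph(tibble::tibble(id = "a", role = "thing"), tibble::tibble()),
    "role")
})

test_that("degree sums to twice the edge count on random graphs", {
  set.seed(14)
  for (i in 1:25) {
    g <- random_typed_graph(sample(3:12, 1), p_edge = stats::runif(1, 0.2, 0.8))
    expect_identical(sum(graph_degree(g)), 2L * nrow(g$edges))
  }
})

test_that("betweenness matches closed forms on stars and paths", {
  b <- betweenness_centrality(star_graph())
  expect_equal(unname(b["hub"]), 1)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 0, 0))

  path <- typed_graph(
    nodes = tibble::tibble(id = c("a", "b", "c"), role = "target"),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  )
  expect_equal(unname(betweenness_centrality(path)["b"]), 1)

  tiny <- typed_graph(tibble::tibble(id = c("a", "b"), role = "target"),
                      tibble::tibble(from = "a", to = "b"))
  expect_equal(unname(betweenness_centrality(tiny)), c(0, 0))
})

test_that("betweenness equals the walk-counting oracle on random graphs", {
  set.seed(21)
  for (i in 1:40) {
    g <- random_typed_graph(sample(4:10, 1), p_edge = stats::runif(1, 0.15, 0.9))
    got <- betweenness_centrality(g)
    want <- betweenness_oracle(g$edges$from, g$edges$to, g$nodes$id)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("betweenness agrees with igraph including disconnected graphs", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:20) {
    g <- random_typed_graph(sample(5:25, 1), p_edge = stats::runif(1, 0.05, 0.5))
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes$id)
    want <- igraph::betweenness(ig, directed = FALSE, normalized = TRUE)
    got <- betweenness_centrality(g)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("compound-target network drops unlinked compounds and targets", {
  per_compound <- tibble::tibble(
    compound_id = c("c1", "c1", "c1", "c2", "c3"),
    gene = c("T1", "T2", "T3", "T2", "X9")
  )
  g <- build_compound_target_network(per_compound, c("T1", "T2", "T3"))
  # c3 maps only outside the therapeutic set and is omitted
  expect_identical(nrow(g$nodes), 5L)
  expect_identical(nrow(g$edges), 4L)
  expect_setequal(g$nodes$id[g$nodes$role == "compound"], c("c1", "c2"))

  empty <- build_compound_target_network(per_compound, "ZZZ")
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("compound-target graphs are bipartite with exact edge accounting", {
  s <- generate_study(small_study_config(seed = 4))
  ps <- screen_predictions(s$predictions)
  g <- build_compound_target_network(ps$per_compound, s$truth$planted_intersection)
  role_of <- stats::setNames(g$nodes$role, g$nodes$id)
  expect_true(all(role_of[g$edges$from] != role_of[g$edges$to]))
  smry <- summarize_network(g)
  expect_equal(smry$mean_degree_compound * smry$n_compound, smry$n_edges)
})

test_that("main-ingredient screen uses strict dual means over compounds", {
  # disjoint stars: degrees 1, 1, 10
  edges <- tibble::tibble(
    from = c("c1", "c2", rep("c3", 10)),
    to = c("t1", "t2", paste0("u", 1:10))
  )
  nodes <- tibble::tibble(
    id = c("c1", "c2", "c3", "t1", "t2", paste0("u", 1:10)),
    role = c(rep("compound", 3), rep("target", 12))
  )
  res <- screen_main_ingredients(typed_graph(nodes, edges))
  expect_equal(res$mean_degree, mean(c(1, 1, 10)))
  expect_true(all(res$table$id[res$table$degree > res$mean_degree] == "c3"))

  # identical compounds: nothing strictly exceeds the mean
  sym <- typed_graph(
    tibble::tibble(id = c("c1", "c2", "t1", "t2"),
                   role = c("compound", "compound", "target", "target")),
    tibble::tibble(from = c("c1", "c1", "c2", "c2"), to = c("t1", "t2", "t1", "t2"))
  )
  expect_identical(screen_main_ingredients(sym)$ingredients, character(0))
  expect_setequal(screen_main_ingredients(sym, strict = FALSE)$ingredients,
                  c("c1", "c2"))
})

test_that("main-ingredient screen is invariant under node relabeling", {
  s <- generate_study(small_study_config(seed = 8))
  ps <- screen_predictions(s$predictions)
  g <- build_compound_target_network(ps$per_compound, s$truth$planted_intersection)
  res1 <- screen_main_ingredients(g)
  relabel <- stats::setNames(paste0("z_", rev(g$nodes$id)), g$nodes$id)
  g2 <- typed_graph(
    tibble::tibble(id = unname(relabel[g$nodes$id]), role = g$nodes$role),
    tibble::tibble(from = unname(relabel[g$edges$from]),
                   to = unname(relabel[g$edges$to]))
  )
  res2 <- screen_main_ingredients(g2)
  expect_setequal(unname(relabel[res1$ingredients]), res2$ingredients)
  expect_equal(res1$mean_degree, res2$mean_degree)
  expect_equal(res1$mean_betweenness, res2$mean_betweenness)
})

test_that("PPI filtering is inclusive at the threshold and removes free genes", {
  ppi <- tibble::tibble(
    gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
    combined_score = c(0.95, 0.9, 0.89)
  )
  g <- build_ppi_network(ppi, c("A", "B", "C", "D", "E"))
  expect_identical(nrow(g$edges), 2L)
  expect_false("D" %in% g$nodes$id) # its only edge fell below the threshold
  expect_false("E" %in% g$nodes$id) # free gene removed
  expect_identical(nrow(build_ppi_network(ppi, letters, threshold = 1)$edges), 0L)
  expect_error(build_ppi_network(ppi, letters, threshold = 1.1))
})

test_that("PPI filtering rejects malformed rows and is monotone in threshold", {
  bad <- tibble::tibble(gene_a = "A", gene_b = "A", combined_score = 0.95)
  expect_error(build_ppi_network(bad, c("A")), "malformed.*1")
  set.seed(6)
  ppi <- tibble::tibble(
    gene_a = sample(paste0("G", 1:30), 150, replace = TRUE),
    gene_b = sample(paste0("G", 31:60), 150, replace = TRUE),
    combined_score = round(stats::runif(150), 3)
  )
  genes <- paste0("G", 1:60)
  prev_edges <- Inf; prev_nodes <- Inf
  for (thr in c(0.2, 0.5, 0.9, 0.99)) {
    g <- build_ppi_network(ppi, genes, thr)
    expect_lte(nrow(g$edges), prev_edges)
    expect_lte(nrow(g$nodes), prev_nodes)
    prev_edges <- nrow(g$edges); prev_nodes <- nrow(g$nodes)
  }
})

test_that("hub ranking breaks ties alphabetically and reports cut ties", {
  g <- typed_graph(
    tibble::tibble(id = c("A", "B", "C", "D"), role = "target"),
    tibble::tibble(from = c("A", "B", "C", "A", "B", "C"),
                   to = c("B", "C", "A", "D", "D", "D"))
  )
  # all four nodes have degree 3
  res <- hub_genes(g, k = 2)
  expect_identical(res$hubs$gene, c("A", "B"))
  expect_setequal(res$tie_overflow$gene, c("C", "D"))

  deg_distinct <- typed_graph(
    tibble::tibble(id = c("A", "B", "C"), role = "target"),
    tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"))
  )
  expect_identical(hub_genes(deg_distinct, k = 10)$hubs$gene, c("A", "B", "C"))
})

test_that("compound-target-pathway assembly keeps only pathway-annotated targets", {
  per_compound <- tibble::tibble(
    compound_id = c("c1", "c1", "c2"),
    gene = c("T1", "T2", "T3")
  )
  g <- build_compound_target_network(per_compound, c("T1", "T2", "T3"))
  membership <- tibble::tibble(pathway = c("p1", "p1"), gene = c("T1", "T2"))
  ctp <- build_ctp_network(g, membership, "p1")
  expect_setequal(ctp$nodes$id[ctp$nodes$role == "target"], c("T1", "T2"))
  expect_false("T3" %in% ctp$nodes$id)
  expect_false("c2" %in% ctp$nodes$id) # lost its only target
  expect_identical(nrow(build_ctp_network(g, membership, character(0))$nodes), 0L)
  expect_error(build_ctp_network(g, membership, "nope"), "absent")
})

test_that("network summary reports whole-graph and per-role mean degrees", {
  g <- star_graph()
  smry <- summarize_network(g)
  expect_equal(smry$mean_degree, 2 * 3 / 4)
  single <- typed_graph(tibble::tibble(id = "x", role = "target"),
                        tibble::tibble())
  expect_equal(summarize_network(single)$mean_degree, 0)
  expect_identical(glance(g), summarize_network(g))
  expect_identical(tidy(g), centrality(g))
})

test_that("graph writers emit readable GraphML and SIF", {
  g <- star_graph()
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  write_graphml(g, gml)
  write_sif(g, sif)
  expect_true(any(grepl("edge source", readLines(gml))))
  skip_if_not_installed("igraph")
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(as.integer(igraph::vcount(ig)), 4L)
  expect_equal(as.integer(igraph::ecount(ig)), 3L)
  expect_setequal(igraph::vertex_attr(ig, "role"), "target")
  sif_lines <- readLines(sif)
  expect_identical(length(sif_lines), 3L)
  expect_true(all(grepl("target-target", sif_lines)))
})
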