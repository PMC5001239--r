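edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  stratomics:::pair_key(el[, 1], el[, 2])
}

test_that("pearson_pairs matches hand computation and drops constants", {
  expr <- rbind(x = c(1, 2, 3), y = c(3, 2, 4), z = c(3, 5, 7))
  colnames(expr) <- paste0("s", 1:3)
  p <- pearson_pairs(expr)
  expect_equal(nrow(p), 3)  # no self-pairs
  expect_equal(p$r[p$a == "x" & p$b == "y"], 0.5)
  expect_equal(p$r[p$a == "x" & p$b == "z"], 1)  # z = 2x + 1
  expect_warning(p2 <- pearson_pairs(rbind(expr, w = c(1, 1, 1))),
                 "zero-variance")
  expect_false("w" %in% c(p2$a, p2$b))
  expect_error(pearson_pairs(expr[, 1:2]), class = "stratomics_input_error")
})

test_that("blockwise correlation equals the direct computation", {
  set.seed(14)
  expr <- matrix(rnorm(60 * 8), 60, 8,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  p1 <- pearson_pairs(expr, block = 7)
  p2 <- pearson_pairs(expr, block = 1000)
  k1 <- stratomics:::pair_key(p1$a, p1$b)
  k2 <- stratomics:::pair_key(p2$a, p2$b)
  expect_setequal(k1, k2)
  expect_equal(p1$r[order(k1)], p2$r[order(k2)], tolerance = 1e-12)
})

test_that("top-fraction selection applies ceiling and keeps cutoff ties", {
  pairs <- data.frame(a = paste0("a", 1:20), b = paste0("b", 1:20),
                      r = c(0.9, 0.8, 0.8, seq(0.0, 0.75, length.out = 17)))
  top <- top_fraction_pairs(pairs, 0.1)   # ceiling(2) but tie at 0.8
  expect_equal(nrow(top), 3)
  expect_equal(nrow(top_fraction_pairs(pairs, 1.0)), 20)
  # absolute mode ranks negative correlations too
  pairs$r[5] <- -0.95
  expect_true(any(top_fraction_pairs(pairs, 0.1, "absolute")$r < 0))
  expect_false(any(top_fraction_pairs(pairs, 0.1, "signed")$r < 0))
  expect_error(top_fraction_pairs(pairs, 0), class = "stratomics_config_error")
})

test_that("background network is the PPI/top-pairs intersection", {
  pairs <- data.frame(a = c("A", "B"), b = c("B", "C"), r = c(0.9, 0.8))
  ppi <- data.frame(gene_a = c("B", "C"), gene_b = c("C", "D"))
  g <- build_background(pairs, ppi)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("B", "C"))
  expect_warning(e <- build_background(pairs,
                                       data.frame(gene_a = "X",
                                                  gene_b = "Y")),
                 "empty")
  expect_equal(igraph::vcount(e), 0)
  # subset property on random inputs
  set.seed(8)
  for (i in 1:5) {
    nodes <- paste0("n", 1:15)
    pr <- t(combn(nodes, 2))
    pairs <- data.frame(a = pr[, 1], b = pr[, 2],
                        r = runif(nrow(pr), -1, 1))
    top <- top_fraction_pairs(pairs, 0.2)
    ppi <- data.frame(gene_a = sample(nodes, 30, TRUE),
                      gene_b = sample(nodes, 30, TRUE))
    ppi <- ppi[ppi$gene_a != ppi$gene_b, ]
    bg <- suppressWarnings(build_background(top, ppi))
    ek <- edge_keys(bg)
    expect_true(all(ek %in% stratomics:::pair_key(ppi$gene_a, ppi$gene_b)))
    expect_true(all(ek %in% stratomics:::pair_key(top$a, top$b)))
  }
})

test_that("projection induces subgraphs and attaches miRNA nodes", {
  pairs <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                      r = c(0.9, 0.8, 0.7))
  ppi <- data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"))
  bg <- build_background(pairs, ppi)
  sub <- project_subnetwork(bg, c("A", "B", "C"),
                            mirnas = c("m1", "m2"),
                            target_map = list(m1 = "C", m2 = "Z"),
                            direction = "down")
  expect_setequal(igraph::V(sub)$name, c("A", "B", "C", "m1"))
  expect_equal(sum(igraph::E(sub)$source == "mirna_target"), 1)
  # every gene-gene edge of the projection exists in the background
  gk <- edge_keys(sub)[igraph::E(sub)$source != "mirna_target"]
  expect_true(all(gk %in% edge_keys(bg)))
  empty <- project_subnetwork(bg, "nope")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("core network equals the closed neighborhood of the seeds", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C")), directed = FALSE)
  core <- core_network(g, "A")
  expect_setequal(igraph::V(core)$name, c("A", "B"))
  expect_true(igraph::V(core)$hyper_down[igraph::V(core)$name == "A"])
  expect_setequal(igraph::V(core_network(g, c("A", "B", "C")))$name,
                  c("A", "B", "C"))
  expect_warning(e <- core_network(g, "Z"), "no seed")
  expect_equal(igraph::vcount(e), 0)
  # oracle equivalence on random graphs + idempotence
  set.seed(4)
  for (i in 1:8) {
    n <- 12
    el <- t(combn(paste0("v", 1:n), 2))
    el <- el[runif(nrow(el)) < 0.2, , drop = FALSE]
    if (nrow(el) == 0) next
    gr <- igraph::graph_from_data_frame(as.data.frame(el),
                                        directed = FALSE)
    seeds <- sample(igraph::V(gr)$name, 2)
    core1 <- core_network(gr, seeds)
    # brute force closed neighborhood
    want <- unique(c(seeds, unlist(lapply(seeds, function(s) {
      unique(c(el[el[, 1] == s, 2], el[el[, 2] == s, 1]))
    }))))
    expect_setequal(igraph::V(core1)$name, intersect(want,
                                                     igraph::V(gr)$name))
    core2 <- core_network(core1, seeds)
    expect_setequal(igraph::V(core2)$name, igraph::V(core1)$name)
    expect_equal(igraph::ecount(core2), igraph::ecount(core1))
  }
})

test_that("degree filter is single-pass with k-core option", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  f <- filter_by_degree(star, 3)
  expect_identical(igraph::V(f)$name, "hub")  # leaves removed, hub kept
  clique <- igraph::make_full_graph(4)
  igraph::V(clique)$name <- paste0("c", 1:4)
  expect_equal(igraph::vcount(filter_by_degree(clique, 3)), 4)
  path <- igraph::make_ring(4, circular = FALSE)
  igraph::V(path)$name <- LETTERS[1:4]
  expect_equal(igraph::vcount(filter_by_degree(path, 3)), 0)
  # iterative k-core removes the hub too once leaves are gone
  expect_equal(igraph::vcount(filter_by_degree(star, 3, iterative = TRUE)),
               0)
})
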