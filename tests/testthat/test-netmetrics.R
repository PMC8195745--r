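test_that("degree and sign summaries reproduce the published worked examples", {
  # networks with the published node/edge/sign counts
  wheat <- sample_signed_network(573, 1462, 211, seed = 1,
                                 label = "wheat_IC_cleaned")
  ds <- degree_stats(wheat)
  expect_equal(ds$n_nodes, 573)
  expect_equal(ds$n_edges, 1673)
  expect_equal(round(ds$mean_degree, 1), 5.8)
  expect_equal(round(sign_ratio(wheat), 1), 6.9)
  pea <- sample_signed_network(451, 1112, 77, seed = 2,
                               label = "pea_IC_cleaned")
  expect_equal(round(degree_stats(pea)$mean_degree, 1), 5.3)
  expect_equal(round(sign_ratio(pea), 1), 14.4)
  # 0-edge network
  expect_equal(degree_stats(net())$mean_degree, 0)
})

test_that("betweenness matches hand-enumerated cases", {
  path3 <- net("A-B", "B-C")
  bw <- betweenness_stats(path3)
  expect_equal(unname(bw$node[c("A", "B", "C")]), c(0, 1, 0))
  tri <- net("A-B", "B-C", "A-C")
  expect_equal(unname(betweenness_stats(tri)$node), c(0, 0, 0))
  star <- net("C-L1", "C-L2", "C-L3", "C-L4")
  bws <- betweenness_stats(star)
  expect_equal(unname(bws$node["C"]), 6)   # all C(4,2) leaf pairs
  expect_equal(n_edges(net()), 0)
  expect_equal(betweenness_stats(net())$mean_node, 0)
})

test_that("betweenness equals brute-force enumeration on random graphs", {
  for (s in 1:25) {
    nn <- sample(4:12, 1)
    ne <- sample(3:min(14, choose(nn, 2)), 1)
    g <- random_net(sprintf("N%02d", 1:nn), ne, seed = 200 + s)
    bw <- betweenness_stats(g)
    oracle <- brute_betweenness(g)
    expect_equal(bw$node[names(oracle$node)], oracle$node, tolerance = 1e-9)
    key <- paste(g$edges$otu_a, g$edges$otu_b)
    expect_equal(unname(bw$edge), unname(oracle$edge[key]), tolerance = 1e-9)
  }
})

test_that("sign ratio flags the all-positive case as infinite", {
  allpos <- random_net(letters[1:8], 10, seed = 1)
  allpos$edges$weight <- abs(allpos$edges$weight)
  allpos <- signed_network(allpos$edges[, c("otu_a", "otu_b", "weight")])
  expect_true(is.infinite(sign_ratio(allpos)))
})

test_that("keystones are outstanding-degree nodes", {
  hub <- signed_network(data.frame(
    otu_a = "HUB", otu_b = sprintf("L%02d", 1:20), weight = 0.3))
  ring <- signed_network(data.frame(
    otu_a = sprintf("L%02d", 1:20), otu_b = sprintf("L%02d", c(2:20, 1)),
    weight = 0.3))
  both <- signed_network(rbind(hub$edges[, 1:3], ring$edges[, 1:3]))
  ks <- keystone_otus(both, k = 3)
  expect_identical(ks$otu_id, "HUB")
  expect_equal(ks$degree, 20)
  # regular graph: nobody exceeds mean + k SD
  expect_equal(nrow(keystone_otus(ring, k = 3)), 0)
  # k = 0 returns exactly the above-mean nodes (brute-force scan)
  deg <- table(c(both$edges$otu_a, both$edges$otu_b))
  expect_setequal(keystone_otus(both, k = 0)$otu_id,
                  names(deg)[deg > mean(deg)])
})

test_that("module detection separates disjoint cliques", {
  cl1 <- t(combn(c("a1", "a2", "a3", "a4"), 2))
  cl2 <- t(combn(c("b1", "b2", "b3", "b4"), 2))
  g <- signed_network(data.frame(otu_a = c(cl1[, 1], cl2[, 1]),
                                 otu_b = c(cl1[, 2], cl2[, 2]), weight = 0.4))
  mod <- detect_modules(g, seed = 1)
  expect_equal(mod$n_modules, 2)
  memb <- mod$membership
  expect_length(unique(memb[c("a1", "a2", "a3", "a4")]), 1)
  expect_length(unique(memb[c("b1", "b2", "b3", "b4")]), 1)
  # single edge: one module, modularity 0 by the direct formula
  single <- detect_modules(net("A-B"), seed = 1)
  expect_equal(single$modularity, 0)
  # empty network: empty partition
  expect_equal(detect_modules(net())$n_modules, 0)
})

test_that("taxon composition is a node-fraction distribution", {
  g <- net("A-B", "C-D")
  tax <- c(A = "Acidobacteria", B = "Acidobacteria", C = "Chloroflexi")
  comp <- taxon_composition(g, tax)
  expect_equal(sum(comp), 1)
  expect_equal(unname(comp["Acidobacteria"]), 0.5)
  expect_equal(unname(comp["Unassigned"]), 0.25)   # D missing from taxonomy
  one <- taxon_composition(net("A-B"), c(A = "X", B = "X"))
  expect_equal(unname(one["X"]), 1.0)
})

test_that("network comparison reports direction and delegates rank tests", {
  a <- net("H-L1", "H-L2", "H-L3", "H-L4", "H-L5")
  b <- net("X-Y", "Z-W")
  cmp <- compare_networks(a, b)
  expect_setequal(cmp$metric, c("degree", "node_betweenness", "edge_betweenness"))
  # identical networks: tied or p = 1
  same <- compare_networks(b, b)
  expect_true(all(same$p_value == 1 | same$tied))
  # forced ordering
  degrow <- cmp[cmp$metric == "degree", ]
  expect_equal(degrow$direction, "a > b")
  # p-values equal a direct call to the standard routine
  da <- as.numeric(table(c(a$edges$otu_a, a$edges$otu_b)))
  db <- as.numeric(table(c(b$edges$otu_a, b$edges$otu_b)))
  expect_equal(degrow$p_value,
               suppressWarnings(stats::wilcox.test(da, db, exact = FALSE)$p.value),
               tolerance = 1e-12)
})

test_that("metrics are invariant under node relabelling", {
  g <- random_net(sprintf("N%02d", 1:9), 12, seed = 77)
  perm <- withr::with_seed(7, sample(network_nodes(g)))
  names(perm) <- network_nodes(g)
  g2 <- signed_network(data.frame(otu_a = unname(perm[g$edges$otu_a]),
                                  otu_b = unname(perm[g$edges$otu_b]),
                                  weight = g$edges$weight))
  expect_equal(degree_stats(g2), degree_stats(g))
  expect_equal(sort(unname(betweenness_stats(g2)$node)),
               sort(unname(betweenness_stats(g)$node)))
  expect_equal(sign_ratio(g2), sign_ratio(g))
})

test_that("the metrics report is internally consistent", {
  g <- random_net(sprintf("N%02d", 1:10), 15, seed = 5)
  rep <- network_metrics(g)
  expect_equal(rep$n_edges, rep$n_positive + rep$n_negative)
  expect_equal(rep$mean_degree, 2 * rep$n_edges / rep$n_nodes)
  tf <- tempfile(fileext = ".json")
  write_metrics_json(rep, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$n_edges, rep$n_edges)
})
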