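test_that("seed subnetwork statistics match brute-force adjacency computation", {
  set.seed(40)
  g <- igraph::sample_gnp(25, 0.2)
  igraph::V(g)$name <- sprintf("p%03d", 1:25)
  ppi <- ppi_network(g)
  seeds <- sprintf("p%03d", sample(25, 10))
  out <- seed_subnetwork(ppi, seeds)

  A <- as.matrix(igraph::as_adjacency_matrix(g))
  idx <- match(seeds, igraph::V(g)$name)
  sub <- A[idx, idx]
  expect_equal(out$stats$n_direct_edges, sum(sub) / 2)
  expect_equal(out$stats$n_connected_seeds, sum(rowSums(sub) > 0))
  expect_equal(out$stats$mean_direct_degree,
               2 * (sum(sub) / 2) / sum(rowSums(sub) > 0))
  # indirect: non-seed neighbours shared with another seed
  nonseed <- setdiff(seq_len(25), idx)
  shared <- nonseed[colSums(A[idx, nonseed, drop = FALSE]) >= 2]
  indirect <- rowSums(A[idx, shared, drop = FALSE] > 0)
  expect_equal(out$stats$mean_indirect_connectivity, mean(indirect))
})

test_that("clique seeds and non-adjacent seeds give the expected degrees", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- sprintf("p%03d", 1:6)
  out <- seed_subnetwork(ppi_network(g), sprintf("p%03d", 1:6))
  expect_true(all(out$seed_degrees == 5))

  ring <- ring_graph(10)
  out2 <- seed_subnetwork(ring, c("p001", "p004", "p007"))
  expect_equal(out2$stats$n_direct_edges, 0)
  expect_equal(out2$stats$mean_direct_degree, 0)

  expect_message(seed_subnetwork(ring, c("p001", "nope", "p002")), "absent")
  expect_error(seed_subnetwork(ring, "nope"), "no seeds")
})

test_that("the 2E/V identity reproduces the reported connectivity arithmetic", {
  # 36 connected proteins with 48 direct interactions: mean degree 2.7
  ppi <- ring_graph(36, extra = 12)
  expect_equal(igraph::ecount(ppi$graph), 48)
  out <- seed_subnetwork(ppi, igraph::V(ppi$graph)$name)
  expect_equal(out$stats$n_direct_edges, 48)
  expect_equal(out$stats$n_connected_seeds, 36)
  expect_equal(round(out$stats$mean_direct_degree, 1), 2.7)
})

test_that("within-degree permutations preserve the degree multiset exactly", {
  set.seed(41)
  g <- igraph::sample_pa(200, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("p%03d", 1:200)
  deg <- igraph::degree(g)
  bin_members <- split(seq_len(200), deg)
  for (b in 1:50) {
    map <- agemodnet:::sample_degree_permutation(bin_members, 200)
    expect_true(all(sort(map) == 1:200))          # a permutation
    expect_identical(deg[map], setNames(deg, names(deg)[map])) # degree-preserving
    expect_true(all(deg[map] == deg))
  }
})

test_that("permutation test pins seeds in singleton bins and is deterministic", {
  # path graph: endpoint degrees 1, interior 2
  g <- igraph::make_ring(8, circular = FALSE)
  igraph::V(g)$name <- sprintf("p%03d", 1:8)
  ppi <- ppi_network(g)
  res1 <- within_degree_permutation_test(ppi, c("p001", "p004"), B = 100,
                                         seed = 7)
  res2 <- within_degree_permutation_test(ppi, c("p001", "p004"), B = 100,
                                         seed = 7)
  expect_identical(res1$network_p, res2$network_p)
  expect_true(all(res1$per_node_p >= 1 / 101 & res1$per_node_p <= 1))
})

test_that("random seeds give near-uniform per-node p-values", {
  set.seed(42)
  g <- igraph::sample_pa(300, m = 3, directed = FALSE)
  igraph::V(g)$name <- sprintf("p%03d", 1:300)
  ppi <- ppi_network(g)
  ps <- unlist(lapply(1:12, function(s) {
    seeds <- sprintf("p%03d", sample(300, 15))
    suppressMessages(within_degree_permutation_test(
      ppi, seeds, B = 200, degree_bins = "log2", seed = s))$per_node_p
  }))
  # no mass concentration at the significant end
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(mean(ps), 0.3)
})
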