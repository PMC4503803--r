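test_that("kernel MI is symmetric, non-negative and maximal for self-dependence", {
  set.seed(10)
  x <- rnorm(200); y <- rnorm(200)
  expect_lte(abs(mutual_information(x, y) - mutual_information(y, x)), 1e-12)
  for (rep in 1:5) {
    a <- rnorm(50); b <- 0.5 * a + rnorm(50)
    expect_gte(mutual_information(a, b), 0)
  }
  expect_gt(mutual_information(x, x), mutual_information(x, sample(x)))
  expect_warning(mi0 <- mutual_information(rep(1, 30), rnorm(30)), "constant")
  expect_equal(mi0, 0)
  expect_error(mutual_information(rnorm(10), rnorm(10)), ">= 20")
})

test_that("the binned fallback estimator tracks dependence like the kernel", {
  set.seed(15)
  x <- rnorm(2000); y <- 0.8 * x + 0.6 * rnorm(2000)
  z <- rnorm(2000)
  mi_dep <- mutual_information(x, y, estimator = "bins")
  mi_ind <- mutual_information(x, z, estimator = "bins")
  expect_gt(mi_dep, mi_ind)
  expect_gte(mi_ind, 0)
  expect_lt(mi_ind, 0.1)
  # agrees with the kernel estimate to first order on strong dependence
  expect_lt(abs(mi_dep - mutual_information(x, y)), 0.15)
})

test_that("MI threshold is monotone in p, reproducible, and guards the tail fit", {
  set.seed(11)
  st <- tiny_study(matrix(rnorm(40 * 60), 40, 60))
  t_mid <- mi_threshold(st, p_value = 0.5, seed = 3)
  t_small <- mi_threshold(st, p_value = 1e-7, seed = 3)
  expect_lt(t_mid, t_small)
  expect_gt(t_small, 0)
  expect_identical(as.numeric(mi_threshold(st, 1e-5, seed = 9)),
                   as.numeric(mi_threshold(st, 1e-5, seed = 9)))
  expect_error(mi_threshold(st, 1e-7, n_null = 500), ">= 1000")
  expect_error(mi_threshold(st, 0), "in \\(0, 1\\)")
})

test_that("the MI threshold calibrates edge retention on independent data", {
  # at p = 0.01 about 1% of independent gene pairs should clear the
  # extrapolated threshold; at p = 1e-4 a 40-gene null study has
  # essentially no edges
  fracs <- vapply(1:20, function(s) {
    withr::with_seed(800 + s, {
      st <- tiny_study(matrix(rnorm(40 * 100), 40, 100))
      thr <- mi_threshold(st, p_value = 0.01, seed = 900 + s)
      R <- agemodnet:::rank_matrix(st$values)
      kk <- agemodnet:::rank_kernel(100)
      M <- agemodnet:::cpp_mi_allpairs(kk$K0, kk$logm, t(R))
      mean(M[upper.tri(M)] >= thr)
    })
  }, numeric(1))
  expect_gte(mean(fracs), 0.003)
  expect_lte(mean(fracs), 0.03)

  edges <- vapply(1:10, function(s) {
    withr::with_seed(820 + s, {
      st <- tiny_study(matrix(rnorm(40 * 100), 40, 100))
      net <- build_mi_network(st, character(0), p_value = 1e-4,
                              seed = 930 + s)
      sum(net$mi[upper.tri(net$mi)] > 0)
    })
  }, numeric(1))
  expect_lte(mean(edges), 1)
})

test_that("DPI applies the triangle rule with TF protection", {
  m <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  m["x", "y"] <- m["y", "x"] <- 0.9
  m["y", "z"] <- m["z", "y"] <- 0.8
  m["x", "z"] <- m["z", "x"] <- 0.3

  # no TFs: weakest edge 0.3 < 0.72 is removed
  net <- mi_network(m, is_tf = c(FALSE, FALSE, FALSE))
  pruned <- apply_dpi(net, 0.1)
  expect_equal(pruned$mi["x", "z"], 0)
  expect_gt(pruned$mi["x", "y"], 0)
  expect_gt(pruned$mi["y", "z"], 0)

  # x is a TF and the min-defining edge (y,z) joins two non-TFs: retained
  net_tf <- mi_network(m, is_tf = c(TRUE, FALSE, FALSE))
  pruned_tf <- apply_dpi(net_tf, 0.1)
  expect_gt(pruned_tf$mi["x", "z"], 0)

  # tolerance 1 preserves all triplets
  expect_equal(apply_dpi(net, 1)$mi, net$mi)
})

test_that("DPI equals brute-force triangle enumeration and is monotone and idempotent", {
  set.seed(12)
  for (rep in 1:40) {
    g <- sample(4:15, 1)
    m <- matrix(0, g, g)
    idx <- which(upper.tri(m) & matrix(runif(g * g), g) < 0.6)
    m[idx] <- runif(length(idx), 0.1, 1)
    m <- m + t(m)
    dimnames(m) <- rep(list(sprintf("n%02d", 1:g)), 2)
    is_tf <- runif(g) < 0.3
    net <- mi_network(m, is_tf)
    pruned <- apply_dpi(net, 0.15)
    expect_identical(pruned$mi, dpi_brute(net$mi, 0.15, is_tf))

    # raising the tolerance never removes more edges
    loose <- apply_dpi(net, 0.5)
    expect_true(all(loose$mi[pruned$mi > 0] > 0))

    # a second application removes nothing
    expect_identical(apply_dpi(pruned, 0.15)$mi, pruned$mi)
  }
})

test_that("regulons are the TF neighbourhoods of the final network", {
  m <- matrix(0, 4, 4, dimnames = rep(list(c("tf1", "a", "b", "tf2")), 2))
  m["tf1", "a"] <- m["a", "tf1"] <- 0.5
  m["tf1", "b"] <- m["b", "tf1"] <- 0.4
  m["a", "b"] <- m["b", "a"] <- 0.3
  net <- mi_network(m, is_tf = c(TRUE, FALSE, FALSE, TRUE))
  regs <- extract_regulons(net)
  expect_named(regs, "tf1")
  expect_setequal(regs$tf1, c("a", "b"))
  expect_identical(attr(regs, "empty_regulon_tfs"), "tf2")
  expect_false("a" %in% names(regs))
})

test_that("bootstrap consensus keeps unanimous edges and guards the round count", {
  set.seed(13)
  n <- 60
  f <- rnorm(n)
  v <- rbind(tf = f + 0.1 * rnorm(n),
             t1 = 0.9 * f + 0.3 * rnorm(n),
             t2 = 0.9 * f + 0.3 * rnorm(n),
             bg1 = rnorm(n), bg2 = rnorm(n), bg3 = rnorm(n))
  colnames(v) <- sprintf("s%02d", 1:n)
  st <- expression_study(v, NULL)
  cons <- bootstrap_consensus(st, tf_list = "tf", rounds = 20,
                              p_value = 1e-4, seed = 14)
  sup <- cons$support
  unanimous <- which(sup == 20 & upper.tri(sup), arr.ind = TRUE)
  for (r in seq_len(nrow(unanimous)))
    expect_gt(cons$mi[unanimous[r, 1], unanimous[r, 2]], 0)
  expect_gt(cons$mi["tf", "t1"], 0)

  expect_error(bootstrap_consensus(st, "tf", rounds = 1), ">= 2")
  expect_error(bootstrap_consensus(st, "tf", rounds = 20000), "cost guard")
})

test_that("network building needs enough samples and reports missing TFs", {
  st <- tiny_study(matrix(rnorm(5 * 10), 5, 10))
  expect_error(build_mi_network(st, "g01"), ">= 20 samples")
  st2 <- tiny_study(matrix(rnorm(5 * 30), 5, 30))
  expect_message(build_mi_network(st2, c("g01", "nope"), p_value = 0.01),
                 "absent")
})
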