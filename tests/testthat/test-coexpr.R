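test_that("correlation_matrix matches hand-computed Pearson and flags degenerate input", {
  # duplicated gene and negated gene
  set.seed(1)
  x <- rnorm(6)
  st <- tiny_study(rbind(x, x, -x) + 0)
  r <- correlation_matrix(st)
  expect_equal(r["g01", "g02"], 1)
  expect_equal(r["g01", "g03"], -1)

  # 3 genes x 4 samples against the textbook formula evaluated by hand
  v <- rbind(c(1, 2, 3, 4),
             c(2, 1, 4, 3),
             c(5, 5, 2, 0))
  st2 <- tiny_study(v)
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  r2 <- correlation_matrix(st2)
  for (i in 1:3) for (j in 1:3)
    expect_equal(r2[i, j], if (i == j) 1 else pearson(v[i, ], v[j, ]),
                 tolerance = 1e-12)

  stc <- suppressWarnings(expression_study(
    matrix(c(1, 2, 3, 1, 1, 1), 2, byrow = TRUE,
           dimnames = list(c("a", "b"), c("s1", "s2", "s3")))))
  expect_named(list(stc), NULL, ignore.order = TRUE) # constant gene dropped at build
  expect_equal(stc$genes, "a")
})

test_that("soft power selection finds scale-free structure and applies the smallest-power rule", {
  # rank-1 adjacency with connectivity k_i ~ 1/i is exactly scale-free
  g <- 200
  ci <- (1:g)^-1
  sim <- sqrt(outer(ci, ci))
  diag(sim) <- 1
  fit <- agemodnet:::scale_free_fit(rowSums(sqrt(outer(ci, ci))) - ci)
  expect_gte(fit, 0.95)

  # smallest power whose fit reaches the target is returned
  set.seed(2)
  gen <- generate_expression(synth_config(n_genes = 400, n_samples = 60, seed = 8))
  sp <- pick_soft_power(correlation_matrix(gen$study), powers = 1:12,
                        fit_target = 0.8)
  first_ok <- sp$fit_table$power[which(sp$fit_table$fit >= 0.8)[1]]
  expect_identical(sp$power, first_ok)

  # unreachable target falls back to the argmax with a warning
  expect_warning(
    sp2 <- pick_soft_power(correlation_matrix(gen$study), powers = 1:3,
                           fit_target = 0.999),
    "never reached")
  expect_identical(sp2$power,
                   sp2$fit_table$power[which.max(sp2$fit_table$fit)])
})

test_that("TOM transform matches its formula on hand and brute-force cases", {
  # all-zero adjacency: off-diagonal TOM 0
  a0 <- matrix(0, 4, 4)
  t0 <- adjacency_to_tom(a0)
  expect_equal(t0, diag(4))

  # 3-node, all off-diagonal 0.5: TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5)
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  expect_equal(adjacency_to_tom(a)[1, 2], 0.5)

  # identical neighbour profiles with a_ij = 1 give maximal overlap
  a2 <- matrix(0, 4, 4)
  a2[1, 2] <- a2[2, 1] <- 1
  a2[1, 3] <- a2[3, 1] <- a2[2, 3] <- a2[3, 2] <- 1
  a2[1, 4] <- a2[4, 1] <- a2[2, 4] <- a2[4, 2] <- 1
  expect_equal(adjacency_to_tom(a2)[1, 2], 1)

  expect_error(adjacency_to_tom(matrix(2, 2, 2)), "\\[0, 1\\]")

  # brute-force triple-loop equality and invariants on random matrices
  set.seed(3)
  for (rep in 1:8) {
    a <- random_adjacency(sample(5:20, 1))
    tom <- adjacency_to_tom(a)
    expect_lt(max(abs(tom - tom_brute(a))), 1e-10)
  }
  for (rep in 1:30) {
    tom <- adjacency_to_tom(random_adjacency(sample(4:15, 1)))
    expect_lt(max(abs(tom - t(tom))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  }
})

test_that("module eigengene is the first PC, sign-oriented, and beats any single gene", {
  set.seed(4)
  # single-gene module: standardized profile up to norm
  st <- tiny_study(matrix(rnorm(40), 4, 10))
  e1 <- module_eigengene(st, "g01")
  prof <- as.numeric(scale(st$values["g01", ]))
  expect_equal(abs(cor(e1, prof)), 1, tolerance = 1e-12)

  # rank-1 block recovers the generating factor with correlation ~1
  f <- rnorm(30)
  load <- runif(12, 0.5, 2)
  block <- outer(load, f)
  st2 <- tiny_study(block + rnorm(length(block), sd = 1e-6))
  e2 <- module_eigengene(st2, st2$genes)
  expect_gte(abs(cor(e2, f)), 0.999)
  expect_equal(sum(e2^2), 1, tolerance = 1e-8)
  # orientation: mean correlation with members is non-negative
  expect_gte(mean(cor(t(st2$values), e2)), 0)

  # variance explained by the eigengene >= by any single gene's profile
  st3 <- tiny_study(matrix(rnorm(30 * 20), 30, 20))
  e3 <- module_eigengene(st3, st3$genes)
  xs <- t(scale(t(st3$values)))
  var_expl <- function(v) sum((xs %*% v / sqrt(sum(v^2)))^2)
  best_gene <- max(apply(xs, 1, var_expl))
  expect_gte(var_expl(e3) + 1e-8, best_gene)
})

test_that("module detection separates blocks, merges close eigengenes and is permutation-equivariant", {
  set.seed(5)
  n <- 30
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, g, noise) outer(rep(1, g), f) + matrix(rnorm(g * n, sd = noise), g)
  v <- rbind(block(f1, 20, 0.1), block(f2, 15, 0.1))
  st <- tiny_study(v)
  tom <- adjacency_to_tom(abs(correlation_matrix(st))^6)
  mods <- detect_modules(tom, st, min_size = 10)
  expect_equal(max(mods$labels), 2)
  expect_length(unique(mods$labels[1:20]), 1)
  expect_length(unique(mods$labels[21:35]), 1)

  # two blocks whose driving factors correlate at 0.95 are merged
  f3 <- 0.95 * f1 + sqrt(1 - 0.95^2) * rnorm(n)
  v2 <- rbind(block(f1, 20, 0.1), block(f3, 20, 0.1))
  st2 <- tiny_study(v2)
  tom2 <- adjacency_to_tom(abs(correlation_matrix(st2))^6)
  mods2 <- detect_modules(tom2, st2, min_size = 10, merge_height = 0.25)
  expect_equal(max(mods2$labels), 1)

  # permuting gene order permutes labels identically
  perm <- sample(nrow(v))
  stp <- expression_study(st$values[perm, ], NULL)
  tomp <- adjacency_to_tom(abs(correlation_matrix(stp))^6)
  modsp <- detect_modules(tomp, stp, min_size = 10)
  expect_identical(unname(modsp$labels[names(mods$labels)]),
                   unname(mods$labels))

  # fewer genes than min_size: everything unassigned, with a warning
  st_small <- tiny_study(matrix(rnorm(12), 3, 4))
  tom_small <- adjacency_to_tom(abs(correlation_matrix(st_small))^2)
  expect_warning(m0 <- detect_modules(tom_small, st_small, min_size = 10),
                 "fewer genes")
  expect_true(all(m0$labels == 0))
})

test_that("age selection applies the confounder-comparison rule", {
  set.seed(6)
  n <- 60
  age <- runif(n, 20, 70)
  # module 1 tracks age, module 2 tracks RIN, module 3 is noise
  f1 <- -scale(age) + 0.3 * rnorm(n)
  rin <- rnorm(n)
  f2 <- scale(rin) + 0.3 * rnorm(n)
  f3 <- rnorm(n)
  mk_block <- function(f) outer(rep(1, 12), as.numeric(f)) +
    matrix(rnorm(12 * n, sd = 0.2), 12)
  st <- tiny_study(rbind(mk_block(f1), mk_block(f2), mk_block(f3)),
                   age = age, RIN = rin)
  tom <- adjacency_to_tom(abs(correlation_matrix(st))^6)
  mods <- detect_modules(tom, st, min_size = 10)
  rep <- select_age_modules(mods, st$traits, alpha = 0.05, adjust = "none")
  tab <- rep$table
  age_mod <- tab$module[which.min(tab$p_age)]
  expect_true(tab$selected[tab$module == age_mod])
  # the RIN-driven module must not pass: its RIN p beats its age p
  rin_mod <- tab$module[which.min(tab$p_RIN)]
  expect_false(tab$selected[tab$module == rin_mod])

  # constant confounder is skipped with a warning
  st2 <- st; st2$traits$RIN <- 1
  expect_warning(select_age_modules(mods, st2$traits), "constant trait")
})

test_that("matched correlation stratifies on exact confounder values", {
  set.seed(7)
  n <- 40
  age <- runif(n, 20, 70)
  eig <- -as.numeric(scale(age))
  # constant confounder: single stratum equals the unstratified correlation
  out <- matched_correlation(eig, age, rep(1, n), min_group = 5)
  expect_equal(nrow(out), 1)
  expect_equal(out$r, cor(eig, age))

  # eigengene = -age exactly: every stratum correlation is -1
  conf <- sample(1:4, n, replace = TRUE)
  out2 <- matched_correlation(-age, age, conf, min_group = 5)
  expect_true(all(abs(out2$r + 1) < 1e-12))
  expect_equal(sum(out2$n), n)

  # no stratum large enough: empty result with a warning
  expect_warning(out3 <- matched_correlation(eig, age, seq_len(n), min_group = 5),
                 "min_group")
  expect_equal(nrow(out3), 0)
})
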