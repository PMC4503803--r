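# Small in-code fixtures shared across test files.

# A tiny expression study with named genes/samples from a value matrix.
tiny_study <- function(values, age = NULL, ...) {
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  traits <- NULL
  if (!is.null(age)) {
    traits <- data.frame(age = age, ..., row.names = colnames(values))
  }
  expression_study(values, traits)
}

# Random symmetric adjacency with entries in [0, 1] and zero diagonal.
random_adjacency <- function(g) {
  a <- matrix(runif(g * g), g, g)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", 1:g), sprintf("g%02d", 1:g))
  a
}

# Brute-force unsigned TOM by the defining triple loop.
tom_brute <- function(a) {
  g <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Brute-force DPI: independent triple-loop implementation of the triangle
# rule with TF protection, applied simultaneously.
dpi_brute <- function(m, eps, is_tf) {
  g <- nrow(m)
  rem <- matrix(FALSE, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j >= i || m[i, j] <= 0) next
    for (k in seq_len(g)) {
      if (k == i || k == j) next
      if (m[i, k] <= 0 || m[j, k] <= 0) next
      mn <- min(m[i, k], m[j, k])
      if (m[i, j] >= mn * (1 - eps)) next
      if (is_tf[i] || is_tf[j]) {
        exempt <- FALSE
        if (m[i, k] == mn && !is_tf[i] && !is_tf[k]) exempt <- TRUE
        if (m[j, k] == mn && !is_tf[j] && !is_tf[k]) exempt <- TRUE
        if (exempt) next
      }
      rem[i, j] <- rem[j, i] <- TRUE
      break
    }
  }
  out <- m
  out[rem] <- 0
  out
}

# Exhaustive hypergeometric upper tail from binomial coefficients only.
hyper_tail_brute <- function(k, module, regulon, universe) {
  xs <- k:min(module, regulon)
  sum(choose(module, xs) * choose(universe - module, regulon - xs)) /
    choose(universe, regulon)
}

# Brute-force per-base overlap between two 0-based half-open interval sets
# on one small chromosome.
overlap_bp_brute <- function(a, b, len) {
  cov_a <- logical(len)
  for (r in seq_len(nrow(a))) cov_a[(a[r, 1] + 1):a[r, 2]] <- TRUE
  cov_b <- logical(len)
  for (r in seq_len(nrow(b))) cov_b[(b[r, 1] + 1):b[r, 2]] <- TRUE
  sum(cov_a & cov_b)
}

# Cycle of n nodes plus chords: connected graph with a known edge count.
ring_graph <- function(n, extra = 0) {
  # cycle of n nodes plus `extra` chords: connected, known edge count
  el <- cbind(1:n, c(2:n, 1))
  if (extra > 0) {
    ch <- cbind(1:extra, 1:extra + n %/% 2)
    el <- rbind(el, ch)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- sprintf("p%03d", 1:n)
  ppi_network(igraph::simplify(g))
}

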