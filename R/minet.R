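#' Gaussian-kernel mutual information between two sample vectors
#'
#' Rank/copula transform to normal scores, then a plug-in estimate: the
#' average over sample points of the log ratio of the joint Gaussian-kernel
#' density to the product of the marginal kernel densities (Silverman
#' bandwidth per axis, leave-one-out sums). The estimate is clamped at zero.
#' Ties are broken at random, so set the RNG seed for exact reproducibility
#' on tied data.
#'
#' @param x,y numeric vectors of equal length >= 20.
#' @param estimator `"kernel"` (default) or `"bins"`, a faster plug-in
#'   estimate on an equal-frequency discretization.
#' @param n_bins number of marginal bins for the `"bins"` estimator;
#'   defaults to `floor(sqrt(n / 5))`.
#' @return mutual information estimate in nats (>= 0).
#' @export
mutual_information <- function(x, y, estimator = c("kernel", "bins"),
                               n_bins = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 20) stop("need >= 20 samples for a usable MI estimate")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (var(x) == 0 || var(y) == 0) {
    warning("constant vector: MI = 0")
    return(0)
  }
  if (estimator == "bins") {
    if (is.null(n_bins)) n_bins <- max(2, floor(sqrt(n / 5)))
    bx <- equal_freq_bins(x, n_bins)
    by <- equal_freq_bins(y, n_bins)
    tab <- table(bx, by) / n
    px <- rowSums(tab)
    py <- colSums(tab)
    pos <- tab > 0
    return(max(0, sum(tab[pos] * log(tab[pos] / outer(px, py)[pos]))))
  }
  s <- copula_scores(x)
  t <- copula_scores(y)
  h <- silverman_bw(n)
  cpp_mi_scores(s, t, h * sd(s), h * sd(t))
}

equal_freq_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "random")
  ceiling(r * n_bins / length(x))
}

silverman_bw <- function(n) 1.06 * n^(-1 / 5)

copula_scores <- function(x) {
  n <- length(x)
  qnorm(rank(x, ties.method = "random") / (n + 1))
}

# Shared machinery for study-wide MI: all genes share the same set of normal
# scores (ranks are a permutation of 1..n), so one kernel matrix serves every
# pair.  Returns list(K0, logm, scores).
rank_kernel <- function(n) {
  s <- qnorm(seq_len(n) / (n + 1))
  h <- silverman_bw(n) * sd(s)
  K0 <- cpp_kernel_matrix(s, h)
  list(K0 = K0, logm = log(rowSums(K0)), scores = s)
}

rank_matrix <- function(values) {
  t(apply(values, 1, rank, ties.method = "random"))
}

#' MI significance threshold from a permutation null
#'
#' Builds a null MI distribution from random gene pairs with one member's
#' samples permuted, fits an exponential to the right tail above the upper
#' decile, and inverts the fitted survival function at `p_value`. Extreme
#' thresholds (e.g. p = 1e-7) are therefore obtained by tail extrapolation
#' rather than by infeasibly many permutations.
#'
#' @param study an [expression_study()].
#' @param p_value probability of exceeding the threshold under independence.
#' @param n_null number of null pairs (>= 1000; the tail fit is unstable
#'   below that).
#' @param seed RNG seed.
#' @return threshold in nats (> 0), with attributes `null_mean` and
#'   `null_q90`.
#' @export
mi_threshold <- function(study, p_value = 1e-7, n_null = 1000, seed = NULL) {
  if (p_value <= 0 || p_value >= 1) stop("p_value must be in (0, 1)")
  if (n_null < 1000) stop("n_null must be >= 1000 for a stable tail fit")
  g <- length(study$genes)
  n <- length(study$samples)
  with_rng(seed, {
    R <- rank_matrix(study$values)
    kk <- rank_kernel(n)
    pairs <- cbind(sample.int(g, n_null, replace = TRUE),
                   sample.int(g, n_null, replace = TRUE))
    same <- pairs[, 1] == pairs[, 2]
    while (any(same)) {
      pairs[same, 2] <- sample.int(g, sum(same), replace = TRUE)
      same <- pairs[, 1] == pairs[, 2]
    }
    perms <- vapply(seq_len(n_null), function(i) sample.int(n), integer(n))
    null_mi <- cpp_mi_null(kk$K0, kk$logm, t(R), pairs, perms)
    threshold_from_null(null_mi, p_value)
  })
}

threshold_from_null <- function(null_mi, p_value) {
  q0 <- unname(quantile(null_mi, 0.9))
  if (p_value >= 0.1) {
    thr <- unname(quantile(null_mi, 1 - p_value))
  } else {
    excess <- null_mi[null_mi > q0] - q0
    lambda <- 1 / mean(excess)
    thr <- q0 + log(0.1 / p_value) / lambda
  }
  thr <- max(thr, .Machine$double.eps)
  attr(thr, "null_mean") <- mean(null_mi)
  attr(thr, "null_q90") <- q0
  thr
}

#' Data processing inequality pruning of an MI network
#'
#' For every gene triplet forming a triangle, the weakest edge is removed
#' when its MI falls below (1 - tolerance) times the smaller of the other
#' two MIs — in a Markov chain the indirect pair carries the least
#' information. TF protection: an edge incident to a TF survives when the
#' min-defining alternative edge of the triangle joins two non-TFs, so a
#' TF-target edge is never dropped in favour of an edge between two non-TFs.
#' All removals are applied simultaneously after scanning every triangle,
#' making the result independent of edge order; a second application removes
#' nothing.
#'
#' @param network an `mi_network`.
#' @param tolerance DPI tolerance in \[0, 1\]; 1 preserves all triplets.
#' @return the pruned `mi_network`.
#' @export
apply_dpi <- function(network, tolerance = network$params$dpi_tolerance %||% 0.1) {
  if (tolerance < 0 || tolerance > 1) stop("tolerance must be in [0, 1]")
  m <- network$mi
  if (nrow(m) > 0) {
    rem <- cpp_dpi(m, tolerance, network$is_tf)
    m[rem] <- 0
  }
  network$mi <- m
  network$params$dpi_tolerance <- tolerance
  network
}

#' Construct an mi_network object
#'
#' @param mi symmetric MI matrix (0 = absent edge) with gene dimnames.
#' @param is_tf logical vector flagging transcription factors.
#' @param params list of parameters used to build the network.
#' @return object of class `mi_network`.
#' @export
mi_network <- function(mi, is_tf, params = list()) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi),
            length(is_tf) == nrow(mi))
  diag(mi) <- 0
  structure(list(genes = rownames(mi), mi = mi, is_tf = is_tf,
                 params = params),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  ne <- sum(x$mi[upper.tri(x$mi)] > 0)
  cat(sprintf("mi_network: %d genes (%d TFs), %d edges\n",
              length(x$genes), sum(x$is_tf), ne))
  invisible(x)
}

#' Edge list of an MI network
#'
#' @param network an `mi_network`.
#' @return data.frame with `gene_a`, `gene_b`, `mi` (and `support` when the
#'   network is a bootstrap consensus).
#' @export
as_edge_list <- function(network) {
  idx <- which(upper.tri(network$mi) & network$mi > 0, arr.ind = TRUE)
  out <- data.frame(gene_a = network$genes[idx[, 1]],
                    gene_b = network$genes[idx[, 2]],
                    mi = network$mi[idx])
  if (!is.null(network$support)) out$support <- network$support[idx]
  out[order(-out$mi), , drop = FALSE]
}

#' Reverse-engineer an MI network ARACNE-style
#'
#' All-pairs Gaussian-kernel MI, removal of edges below the p-value-derived
#' MI threshold, then DPI pruning with TF protection.
#'
#' @param study an [expression_study()] with >= 20 samples.
#' @param tf_list character vector of TF gene ids (members absent from the
#'   study are reported and ignored).
#' @param p_value MI threshold p-value.
#' @param dpi_tolerance DPI tolerance.
#' @param n_null null pairs for the threshold fit.
#' @param seed RNG seed.
#' @return an `mi_network`.
#' @export
build_mi_network <- function(study, tf_list, p_value = 1e-7,
                             dpi_tolerance = 0.1, n_null = 1000,
                             seed = NULL) {
  n <- length(study$samples)
  if (n < 20) stop("MI network needs >= 20 samples")
  missing_tfs <- setdiff(tf_list, study$genes)
  if (length(missing_tfs) > 0)
    message(sprintf("%d TF(s) absent from the study ignored", length(missing_tfs)))
  is_tf <- study$genes %in% tf_list
  with_rng(seed, {
    R <- rank_matrix(study$values)
    kk <- rank_kernel(n)
    M <- cpp_mi_allpairs(kk$K0, kk$logm, t(R))
    dimnames(M) <- list(study$genes, study$genes)
    g <- length(study$genes)
    n_null_eff <- max(n_null, 1000)
    pairs <- cbind(sample.int(g, n_null_eff, replace = TRUE),
                   sample.int(g, n_null_eff, replace = TRUE))
    same <- pairs[, 1] == pairs[, 2]
    while (any(same)) {
      pairs[same, 2] <- sample.int(g, sum(same), replace = TRUE)
      same <- pairs[, 1] == pairs[, 2]
    }
    perms <- vapply(seq_len(n_null_eff), function(i) sample.int(n), integer(n))
    null_mi <- cpp_mi_null(kk$K0, kk$logm, t(R), pairs, perms)
    thr <- threshold_from_null(null_mi, p_value)
    M[M < thr] <- 0
    net <- mi_network(M, is_tf,
                      params = list(mi_pvalue = p_value,
                                    mi_threshold = as.numeric(thr),
                                    dpi_tolerance = dpi_tolerance,
                                    n_null = n_null_eff))
    apply_dpi(net, dpi_tolerance)
  })
}

#' Bootstrap consensus MI network
#'
#' Rebuilds the network on sample-bootstrap resamples and keeps edges whose
#' support count across rounds is significantly above the per-round mean
#' edge rate under a binomial null (BH-corrected at `alpha`). The consensus
#' edge MI is the mean MI over supporting rounds.
#'
#' @param study an [expression_study()].
#' @param tf_list character vector of TF gene ids.
#' @param rounds number of bootstrap rounds (2 to 10000).
#' @param p_value,dpi_tolerance,n_null per-round network parameters.
#' @param alpha BH level for consensus retention.
#' @param seed RNG seed.
#' @return an `mi_network` with a `support` matrix attached.
#' @export
bootstrap_consensus <- function(study, tf_list, rounds = 100,
                                p_value = 1e-7, dpi_tolerance = 0.1,
                                n_null = 1000, alpha = 0.05, seed = NULL) {
  if (rounds < 2) stop("rounds must be >= 2")
  if (rounds > 10000) stop("rounds > 10000 refused (cost guard)")
  g <- length(study$genes)
  with_rng(seed, {
    support <- matrix(0L, g, g, dimnames = list(study$genes, study$genes))
    mi_sum <- matrix(0, g, g, dimnames = list(study$genes, study$genes))
    n <- length(study$samples)
    for (r in seq_len(rounds)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_vals <- study$values[, idx, drop = FALSE]
      colnames(boot_vals) <- study$samples  # keep ids unique
      boot <- suppressWarnings(expression_study(boot_vals, NULL))
      net <- build_mi_network(boot, tf_list, p_value = p_value,
                              dpi_tolerance = dpi_tolerance, n_null = n_null)
      present <- net$mi > 0
      # resampling can drop zero-variance genes; align
      gi <- match(net$genes, study$genes)
      support[gi, gi] <- support[gi, gi] + present
      mi_sum[gi, gi] <- mi_sum[gi, gi] + net$mi
    }
    npairs <- g * (g - 1) / 2
    rate <- sum(support[upper.tri(support)]) / (rounds * npairs)
    up <- upper.tri(support)
    k <- support[up]
    pb <- pbinom(k - 1, rounds, rate, lower.tail = FALSE)
    qb <- p.adjust(pb, method = "BH")
    keep_up <- qb < alpha & k > 0
    keep <- matrix(FALSE, g, g)
    keep[up] <- keep_up
    keep <- keep | t(keep)
    mi <- ifelse(keep & support > 0, mi_sum / pmax(support, 1L), 0)
    dimnames(mi) <- dimnames(support)
    net <- mi_network(mi, study$genes %in% tf_list,
                      params = list(mi_pvalue = p_value,
                                    dpi_tolerance = dpi_tolerance,
                                    bootstrap_rounds = rounds,
                                    consensus_alpha = alpha,
                                    background_rate = rate))
    net$support <- support
    net
  })
}

#' Extract per-TF regulons from an MI network
#'
#' The regulon of a TF is the set of genes adjacent to it in the final
#' network. TFs with empty regulons are reported via the
#' `empty_regulon_tfs` attribute.
#'
#' @param network an `mi_network` with TF flags.
#' @return named list (class `regulon_set`) mapping each TF with a nonempty
#'   regulon to its target gene ids.
#' @export
extract_regulons <- function(network) {
  tfs <- network$genes[network$is_tf]
  regs <- lapply(setNames(tfs, tfs), function(tf) {
    nb <- network$genes[network$mi[tf, ] > 0]
    setdiff(nb, tf)
  })
  empty <- names(regs)[vapply(regs, length, integer(1)) == 0]
  regs <- regs[vapply(regs, length, integer(1)) > 0]
  class(regs) <- "regulon_set"
  attr(regs, "empty_regulon_tfs") <- empty
  regs
}

#' @export
print.regulon_set <- function(x, ...) {
  sizes <- vapply(x, length, integer(1))
  cat(sprintf("regulon_set: %d TFs with regulons (sizes %d-%d, median %g)\n",
              length(x), if (length(x)) min(sizes) else 0,
              if (length(x)) max(sizes) else 0,
              if (length(x)) median(sizes) else 0))
  invisible(x)
}
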