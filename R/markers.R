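#' Empirical cell-type marker enrichment of a module
#'
#' Compares the number of marker-panel genes in the module with the counts
#' obtained in B random gene sets of the same size drawn uniformly from the
#' universe. Fold enrichment is observed over the null median; the
#' empirical p uses the +1 permutation correction, so its floor is
#' 1 / (B + 1).
#'
#' @param module character vector of module gene ids (subset of universe).
#' @param panel character vector of marker gene ids (intersected with the
#'   universe: only expressed markers count).
#' @param universe character vector of all expressed genes.
#' @param B number of random gene sets (>= 100).
#' @param seed RNG seed.
#' @return object of class `enrichment_result`: observed count, null
#'   counts, null median/mean, fold, p_empirical, B, seed.
#' @export
marker_enrichment <- function(module, panel, universe, B = 1000,
                              seed = NULL) {
  if (B < 100) stop("B must be >= 100")
  if (length(module) > length(universe)) stop("module larger than universe")
  if (!all(module %in% universe)) stop("module must be a subset of the universe")
  panel <- intersect(panel, universe)
  observed <- length(intersect(module, panel))
  with_rng(seed, {
    null_counts <- vapply(seq_len(B), function(b)
      length(intersect(sample(universe, length(module)), panel)), integer(1))
    null_median <- median(null_counts)
    fold <- fold_enrichment(observed, null_median)
    p <- (sum(null_counts >= observed) + 1) / (B + 1)
    structure(list(observed = observed, null_counts = null_counts,
                   null_median = null_median, null_mean = mean(null_counts),
                   fold = fold, p_empirical = p, B = B, seed = seed),
              class = "enrichment_result")
  })
}

# observed / null_median with the conventions: 1 when both are zero,
# Inf when only the null median is zero.
fold_enrichment <- function(observed, null_median) {
  if (null_median == 0) {
    if (observed == 0) 1 else Inf
  } else observed / null_median
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: observed %d vs null median %g -> fold %.3g, empirical p = %.4g (B = %d)\n",
              x$observed, x$null_median, x$fold, x$p_empirical, x$B))
  invisible(x)
}

#' Age trend of a marker panel
#'
#' Per-gene Pearson correlation of expression with age for the expressed
#' panel genes, with the panel mean correlation and a two-sided one-sample
#' t-test of the per-gene correlations against zero. The analysis can be
#' restricted to subjects at or above `min_age` to probe late-life trends.
#'
#' @param study an [expression_study()] with an `age` trait.
#' @param panel character vector of marker gene ids.
#' @param min_age optional minimum age in years; at least 10 samples must
#'   remain.
#' @return object of class `trend_report`: list with `per_gene`
#'   (data.frame gene, r), `mean_r`, `p`, `n_samples`, `min_age`.
#' @export
marker_age_trend <- function(study, panel, min_age = NULL) {
  if (is.null(study$traits) || !"age" %in% colnames(study$traits))
    stop("study must carry an 'age' trait")
  keep <- rep(TRUE, length(study$samples))
  if (!is.null(min_age)) {
    keep <- study$traits$age >= min_age
    if (sum(keep) < 10) stop("fewer than 10 samples above min_age")
  }
  genes <- intersect(panel, study$genes)
  if (length(genes) == 0) stop("no panel genes expressed in the study")
  age <- study$traits$age[keep]
  rs <- apply(study$values[genes, keep, drop = FALSE], 1,
              function(x) if (var(x) == 0) NA_real_ else cor(x, age))
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stop("no panel genes with variance in the age window")
  p <- if (length(rs) >= 2) t.test(rs)$p.value else NA_real_
  structure(list(per_gene = data.frame(gene = names(rs), r = unname(rs)),
                 mean_r = mean(rs), p = p,
                 n_samples = sum(keep), min_age = min_age),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("trend_report: %d genes, mean r vs age = %.3f (p = %.3g, n = %d%s)\n",
              nrow(x$per_gene), x$mean_r, x$p, x$n_samples,
              if (is.null(x$min_age)) "" else sprintf(", age >= %g", x$min_age)))
  invisible(x)
}

#' Ordinary least-squares slope of y on x
#'
#' @param y dependent variable (e.g. a module eigengene).
#' @param x independent variable (e.g. age in years).
#' @return list with `slope`, `intercept`, `r` (Pearson), `p` (two-sided
#'   slope test).
#' @export
regression_slope <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(x) < 3) stop("need >= 3 points")
  if (var(x) == 0) stop("constant x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(x, y), p = sm$coefficients[2, 4])
}
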