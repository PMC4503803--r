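#' Construct an expression study
#'
#' The universal input container: a gene x sample matrix of normalized
#' expression (e.g. log-ratios) plus a per-sample trait table with `age`
#' (years) and zero or more confounders (RIN, pH, PMI). Genes with zero
#' variance are dropped with a warning.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param traits data.frame with one row per sample (rownames = sample ids)
#'   or NULL when no phenotype is available.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(values, traits = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  v <- apply(values, 1, var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    values <- values[v > 0, , drop = FALSE]
  }
  if (!is.null(traits)) {
    if (!all(colnames(values) %in% rownames(traits)))
      stop("traits missing rows for some samples")
    traits <- traits[colnames(values), , drop = FALSE]
  }
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, traits = traits),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples; traits: %s\n",
              length(x$genes), length(x$samples),
              if (is.null(x$traits)) "none" else
                paste(colnames(x$traits), collapse = ", ")))
  invisible(x)
}

#' Pairwise Pearson correlation matrix of all genes
#'
#' @param study an [expression_study()].
#' @return symmetric gene x gene matrix of Pearson correlations (diagonal 1).
#' @export
correlation_matrix <- function(study) {
  if (length(study$samples) < 3) stop("need >= 3 samples")
  v <- apply(study$values, 1, var)
  if (any(v == 0))
    stop(sprintf("zero-variance gene(s): %s",
                 paste(head(study$genes[v == 0], 5), collapse = ", ")))
  r <- cor(t(study$values))
  diag(r) <- 1
  r
}

#' Choose the soft-thresholding power for approximate scale-free topology
#'
#' For each candidate power beta, forms the adjacency |r|^beta, computes the
#' connectivity k_i = sum_j a_ij, and measures the scale-free fit index: the
#' R^2 of the regression of log10 connectivity density on log10 connectivity
#' over equal-count connectivity bins. Returns the smallest power whose fit
#' reaches `fit_target`, or the power of maximal fit with a warning.
#'
#' @param sim symmetric similarity (correlation) matrix.
#' @param powers ascending integer candidate powers.
#' @param fit_target required scale-free fit R^2.
#' @param n_bins number of equal-count connectivity bins.
#' @return list with `power` (the chosen beta) and `fit_table`
#'   (power, fit, mean_connectivity).
#' @export
pick_soft_power <- function(sim, powers = 1:20, fit_target = 0.85,
                            n_bins = 10) {
  stopifnot(length(powers) >= 1, !is.unsorted(powers))
  fits <- numeric(length(powers))
  meank <- numeric(length(powers))
  for (p in seq_along(powers)) {
    a <- abs(sim)^powers[p]
    diag(a) <- 0
    k <- rowSums(a)
    fits[p] <- scale_free_fit(k, n_bins)
    meank[p] <- mean(k)
  }
  tab <- data.frame(power = powers, fit = fits, mean_connectivity = meank)
  ok <- which(fits >= fit_target)
  if (length(ok) > 0) {
    power <- powers[ok[1]]
  } else {
    power <- powers[which.max(fits)]
    warning(sprintf("scale-free fit never reached %.2f; using power %d (fit %.2f)",
                    fit_target, power, max(fits)))
  }
  list(power = power, fit_table = tab)
}

# Scale-free fit index: R^2 of log10(density) on log10(k) over equal-count
# bins; density = bin count / bin width so the statistic is meaningful for
# equal-count binning.
scale_free_fit <- function(k, n_bins = 10) {
  if (var(k) == 0) stop("degenerate connectivity: all genes identical")
  br <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) stop("degenerate connectivity: too few distinct values")
  bin <- cut(k, br, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = length(br) - 1)
  width <- diff(br)
  keep <- cnt > 0
  dens <- cnt[keep] / width[keep]
  mids <- vapply(split(k, bin), mean, numeric(1))[keep]
  if (any(mids <= 0)) { pos <- mids > 0; mids <- mids[pos]; dens <- dens[pos] }
  if (length(mids) < 3) stop("degenerate connectivity distribution")
  fit <- lm(log10(dens) ~ log10(mids))
  summary(fit)$r.squared
}

#' Topological overlap matrix from an adjacency matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj and k_i = sum_u a_iu; the diagonal is set to 1.
#' Shared-neighbour information damps spurious pairwise associations;
#' 1 - TOM is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\] (the diagonal
#'   is zeroed internally).
#' @return the TOM matrix (symmetric, entries in \[0, 1\], diagonal 1).
#' @export
adjacency_to_tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-8)
    stop("adjacency must be symmetric")
  diag(a) <- 0
  if (min(a) < 0 || max(a) > 1) stop("adjacency entries must be in [0, 1]")
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Summary expression profile (eigengene) of a gene set
#'
#' First principal component of the gene-standardized member submatrix
#' across samples, unit norm, sign-oriented so that the mean correlation
#' with the member genes is non-negative.
#'
#' @param study an [expression_study()].
#' @param member_genes character vector of member gene ids.
#' @return named per-sample numeric vector of unit norm.
#' @export
module_eigengene <- function(study, member_genes) {
  member_genes <- intersect(member_genes, study$genes)
  if (length(member_genes) == 0) stop("empty module membership")
  x <- study$values[member_genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 1, nv = 1)
  eig <- sv$v[, 1]
  if (mean(sv$u[, 1]) < 0) eig <- -eig
  names(eig) <- study$samples
  eig
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on 1 - TOM, static branch cut at
#' `cut_height` (default: 0.995 times the maximum merge height, i.e. just
#' below the level where unclustered background genes join the tree — an
#' approximation of dynamic branch cutting), assignment of clusters smaller
#' than `min_size` to module 0 ("grey"/unassigned), then iterative merging
#' of modules whose eigengene dissimilarity (1 - correlation of eigengenes)
#' is below `merge_height`, recomputing eigengenes after every merge.
#' Final modules are labelled 1, 2, ... in decreasing size order.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param study the [expression_study()] the TOM was built from (for
#'   eigengene computation).
#' @param min_size minimum module size.
#' @param merge_height eigengene dissimilarity below which modules merge.
#' @param cut_height static tree cut height; NULL for the default
#'   0.995 * max(merge height).
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = unassigned), `eigengenes` (sample x module matrix),
#'   `params`.
#' @export
detect_modules <- function(tom, study, min_size = 10, merge_height = 0.25,
                           cut_height = NULL) {
  stopifnot(min_size >= 2)
  genes <- rownames(tom)
  if (is.null(genes)) stop("tom must carry gene dimnames")
  if (length(genes) < min_size) {
    warning("fewer genes than min_size: all genes unassigned")
    labels <- setNames(rep(0L, length(genes)), genes)
    return(structure(list(labels = labels,
                          eigengenes = matrix(nrow = length(study$samples), ncol = 0),
                          params = list(min_size = min_size,
                                        merge_height = merge_height,
                                        cut_height = NA)),
                     class = "module_assignment"))
  }
  diss <- 1 - tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height)) cut_height <- 0.995 * max(tree$height)
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- ifelse(raw %in% keep, match(raw, keep), 0L)
  names(labels) <- genes

  labels <- merge_modules(labels, study, merge_height)
  eig <- eigengene_matrix(labels, study)
  structure(list(labels = labels, eigengenes = eig,
                 params = list(min_size = min_size,
                               merge_height = merge_height,
                               cut_height = cut_height)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$labels[x$labels != 0])
  cat(sprintf("module_assignment: %d modules (sizes %s), %d unassigned of %d genes\n",
              length(tab), paste(as.integer(tab), collapse = ", "),
              sum(x$labels == 0), length(x$labels)))
  invisible(x)
}

# Per-gene module membership: correlation of the gene's profile with its
# own module's eigengene (NA for unassigned genes).
module_membership_r <- function(modules, study) {
  out <- rep(NA_real_, length(modules$labels))
  for (m in colnames(modules$eigengenes)) {
    idx <- which(modules$labels == as.integer(sub("M", "", m)))
    if (length(idx) == 0) next
    out[idx] <- as.numeric(cor(t(study$values[names(modules$labels)[idx], ,
                                              drop = FALSE]),
                               modules$eigengenes[, m]))
  }
  out
}

eigengene_matrix <- function(labels, study) {
  mods <- sort(unique(labels[labels != 0]))
  eig <- vapply(mods, function(m)
    module_eigengene(study, names(labels)[labels == m]),
    numeric(length(study$samples)))
  if (length(mods) == 0)
    return(matrix(numeric(0), nrow = length(study$samples), ncol = 0))
  colnames(eig) <- paste0("M", mods)
  rownames(eig) <- study$samples
  eig
}

# Iteratively merge the closest module pair while their eigengene
# dissimilarity is below merge_height; relabel by decreasing size.
merge_modules <- function(labels, study, merge_height) {
  repeat {
    mods <- sort(unique(labels[labels != 0]))
    if (length(mods) < 2) break
    eig <- vapply(mods, function(m)
      module_eigengene(study, names(labels)[labels == m]),
      numeric(length(study$samples)))
    d <- 1 - cor(eig)
    diag(d) <- Inf
    mn <- min(d)
    if (mn >= merge_height) break
    idx <- which(d == mn, arr.ind = TRUE)[1, ]
    a <- mods[min(idx)]; b <- mods[max(idx)]
    labels[labels == b] <- a
  }
  mods <- sort(unique(labels[labels != 0]))
  if (length(mods) > 0) {
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
    new_order <- mods[order(-sizes, mods)]
    relab <- labels
    for (i in seq_along(new_order)) relab[labels == new_order[i]] <- i
    labels <- relab
  }
  labels
}

#' Age-dependent module selection with confounder comparison
#'
#' For every module, correlates the eigengene with age and with each
#' confounder (Pearson, two-sided p). A module is selected when its
#' (optionally Bonferroni-adjusted across modules) age p-value is below
#' `alpha` and its raw age p-value is more significant than the p-value for
#' every available confounder. Matched-sample validation: for each
#' confounder, the eigengene-age correlation is recomputed within strata of
#' samples sharing the same recorded confounder value.
#'
#' @param modules a `module_assignment`.
#' @param traits per-sample trait data.frame with an `age` column.
#' @param alpha significance level for the age association.
#' @param adjust `"bonferroni"` (default) adjusts the age p-value for the
#'   number of tested modules before comparison with `alpha`; `"none"`
#'   applies the literal per-module rule.
#' @param spearman use Spearman instead of Pearson correlation.
#' @param min_group minimum stratum size for matched validation.
#' @return object of class `age_module_report`: list with `table`
#'   (per-module statistics and `selected` flag) and `matched` (per module,
#'   per confounder stratified correlations).
#' @export
select_age_modules <- function(modules, traits, alpha = 0.05,
                               adjust = c("bonferroni", "none"),
                               spearman = FALSE, min_group = 5) {
  adjust <- match.arg(adjust)
  if (!"age" %in% colnames(traits)) stop("traits must contain 'age'")
  eig <- modules$eigengenes
  if (ncol(eig) == 0) stop("no modules to test")
  traits <- traits[rownames(eig), , drop = FALSE]
  method <- if (spearman) "spearman" else "pearson"
  confs <- setdiff(colnames(traits), "age")
  usable <- character(0)
  for (cf in confs) {
    if (var(traits[[cf]]) == 0) {
      warning(sprintf("constant trait '%s' skipped", cf))
    } else usable <- c(usable, cf)
  }
  rows <- list()
  matched <- list()
  for (m in colnames(eig)) {
    ct <- suppressWarnings(cor.test(eig[, m], traits$age, method = method))
    row <- data.frame(module = m, n_genes = sum(modules$labels == as.integer(sub("M", "", m))),
                      r_age = unname(ct$estimate), p_age = ct$p.value)
    for (cf in usable) {
      cc <- suppressWarnings(cor.test(eig[, m], traits[[cf]], method = method))
      row[[paste0("r_", cf)]] <- unname(cc$estimate)
      row[[paste0("p_", cf)]] <- cc$p.value
    }
    rows[[m]] <- row
    matched[[m]] <- lapply(setNames(usable, usable), function(cf)
      suppressWarnings(matched_correlation(eig[, m], traits$age, traits[[cf]],
                                           min_group = min_group)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_age_adj <- if (adjust == "bonferroni")
    pmin(1, tab$p_age * nrow(tab)) else tab$p_age
  conf_ok <- rep(TRUE, nrow(tab))
  for (cf in usable)
    conf_ok <- conf_ok & (tab$p_age < tab[[paste0("p_", cf)]])
  tab$selected <- tab$p_age_adj < alpha & conf_ok
  structure(list(table = tab, matched = matched,
                 params = list(alpha = alpha, adjust = adjust,
                               method = method, min_group = min_group)),
            class = "age_module_report")
}

#' @export
print.age_module_report <- function(x, ...) {
  sel <- x$table$module[x$table$selected]
  cat(sprintf("age_module_report: %d modules tested, selected: %s\n",
              nrow(x$table),
              if (length(sel)) paste(sel, collapse = ", ") else "none"))
  invisible(x)
}

#' Eigengene-age correlation within confounder-matched strata
#'
#' Samples are grouped by identical recorded confounder value; within every
#' stratum of at least `min_group` samples the eigengene-age Pearson
#' correlation is recomputed. A confounder cannot drive an association that
#' persists when it is held fixed.
#'
#' @param eigengene per-sample eigengene vector.
#' @param age per-sample age vector.
#' @param confounder per-sample confounder vector (matched on exact value).
#' @param min_group minimum stratum size.
#' @return data.frame with `level`, `n`, `r` (one row per usable stratum);
#'   empty with a warning when no stratum is large enough.
#' @export
matched_correlation <- function(eigengene, age, confounder, min_group = 5) {
  stopifnot(length(eigengene) == length(age),
            length(age) == length(confounder))
  levels <- sort(unique(confounder))
  out <- list()
  for (lv in levels) {
    idx <- which(confounder == lv)
    if (length(idx) < min_group) next
    r <- if (var(age[idx]) == 0 || var(eigengene[idx]) == 0) NA_real_
         else cor(eigengene[idx], age[idx])
    out[[length(out) + 1]] <- data.frame(level = lv, n = length(idx), r = r)
  }
  if (length(out) == 0) {
    warning("no confounder stratum reaches min_group")
    return(data.frame(level = numeric(0), n = integer(0), r = numeric(0)))
  }
  do.call(rbind, out)
}
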