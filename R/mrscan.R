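#' One-sided Fisher / hypergeometric overlap p-value
#'
#' Probability of observing at least `overlap` genes in the intersection of
#' a regulon and a module when `regulon_size` genes are drawn without
#' replacement from a universe containing `module_size` module genes — the
#' upper tail of the hypergeometric distribution, i.e. the one-sided
#' ("greater") Fisher's exact test on the 2x2 membership table.
#'
#' @param overlap observed intersection size.
#' @param regulon_size regulon size (within the universe).
#' @param module_size module size (within the universe).
#' @param universe_size total genes in the universe.
#' @return p-value P(X >= overlap).
#' @export
fisher_overlap <- function(overlap, regulon_size, module_size, universe_size) {
  if (any(c(overlap, regulon_size, module_size, universe_size) < 0))
    stop("counts must be non-negative")
  if (regulon_size > universe_size || module_size > universe_size)
    stop("set sizes exceed universe")
  if (overlap > min(regulon_size, module_size))
    stop("overlap exceeds a set size")
  if (overlap < max(0, regulon_size + module_size - universe_size))
    stop("overlap below the minimum possible for these counts")
  phyper(overlap - 1, module_size, universe_size - module_size,
         regulon_size, lower.tail = FALSE)
}

#' Identify master regulators of a module
#'
#' Tests, for every TF with a nonempty regulon, whether the regulon's
#' intersection with the module is larger than expected by chance
#' (one-sided Fisher's exact test), Bonferroni-corrected for the number of
#' TFs tested in the network. Regulons and the module are intersected with
#' the universe (the genes of the network) before testing.
#'
#' @param regulons named list of TF -> target gene ids (a `regulon_set`).
#' @param module character vector of module gene ids.
#' @param universe character vector of all genes in the network.
#' @param alpha family-wise significance level.
#' @return data.frame of class `mr_result`, sorted by raw p: `tf`,
#'   `overlap`, `regulon_size`, `module_size`, `universe_size`, `p_raw`,
#'   `p_adj`, `is_mr`. The number of TFs tested is in attribute `n_tested`.
#' @export
identify_master_regulators <- function(regulons, module, universe,
                                       alpha = 0.05) {
  module <- intersect(module, universe)
  if (length(module) == 0) stop("module is empty within the universe")
  regs <- lapply(regulons, intersect, universe)
  sizes <- vapply(regs, length, integer(1))
  if (any(sizes == 0))
    message(sprintf("%d TF(s) with empty regulons excluded from testing",
                    sum(sizes == 0)))
  regs <- regs[sizes > 0]
  if (length(regs) == 0) stop("no testable regulons")
  n_tested <- length(regs)
  u <- length(universe)
  m <- length(module)
  rows <- lapply(names(regs), function(tf) {
    rs <- length(regs[[tf]])
    ov <- length(intersect(regs[[tf]], module))
    p <- fisher_overlap(ov, rs, m, u)
    data.frame(tf = tf, overlap = ov, regulon_size = rs, module_size = m,
               universe_size = u, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * n_tested)
  out$is_mr <- out$p_adj < alpha
  out <- out[order(out$p_raw, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  attr(out, "alpha") <- alpha
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Summarize master-regulator replication across datasets
#'
#' @param results named list (>= 2 entries) of `mr_result` tables, one per
#'   dataset.
#' @return list with `counts` (data.frame tf, n_replicated, datasets),
#'   `union`, `intersection` (TFs flagged in every dataset) and
#'   `per_dataset` MR counts.
#' @export
combine_across_datasets <- function(results) {
  if (length(results) < 2) stop("need >= 2 datasets")
  if (is.null(names(results)))
    names(results) <- paste0("dataset_", seq_along(results))
  mr_sets <- lapply(results, function(r) r$tf[r$is_mr])
  all_tfs <- sort(unique(unlist(mr_sets)))
  counts <- data.frame(
    tf = all_tfs,
    n_replicated = vapply(all_tfs, function(tf)
      sum(vapply(mr_sets, function(s) tf %in% s, logical(1))), integer(1)),
    datasets = vapply(all_tfs, function(tf)
      paste(names(mr_sets)[vapply(mr_sets, function(s) tf %in% s, logical(1))],
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_replicated, counts$tf), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       union = all_tfs,
       intersection = counts$tf[counts$n_replicated == length(results)],
       per_dataset = vapply(mr_sets, length, integer(1)))
}
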