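#' Strand-aware basal regulatory domains around gene TSSs
#'
#' For a plus-strand gene the domain is \[TSS - up, TSS + down) and for a
#' minus-strand gene \[TSS - down, TSS + up), in 0-based half-open
#' coordinates, clipped to the chromosome. Each gene keeps its own named
#' domain (domains of neighbouring genes may overlap).
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` ("+"/"-").
#' @param up,down extent upstream/downstream of the TSS in bp.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return GRanges with one range per gene (names = gene ids).
#' @export
basal_regulatory_domains <- function(annotation, up = 5000, down = 1000,
                                     chrom_lengths) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% colnames(annotation)))
  if (any(annotation$tss < 0)) stop("TSS must be >= 0")
  if (!all(annotation$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  unknown <- setdiff(unique(annotation$chrom), names(chrom_lengths))
  if (length(unknown) > 0)
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  len <- chrom_lengths[annotation$chrom]
  plus <- annotation$strand == "+"
  start0 <- ifelse(plus, annotation$tss - up, annotation$tss - down)
  end0 <- ifelse(plus, annotation$tss + down, annotation$tss + up)
  start0 <- pmax(start0, 0)
  end0 <- pmin(end0, len)
  keep <- end0 > start0
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom[keep],
    ranges = IRanges::IRanges(start = start0[keep] + 1L, end = end0[keep]),
    strand = annotation$strand[keep])
  names(gr) <- annotation$gene_id[keep]
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

# Flatten a GRanges to a per-chromosome list of merged numeric interval
# matrices (0-based half-open) for the fast randomization loop.
flatten_intervals <- function(gr) {
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  split_by <- split(red, GenomeInfoDb::seqnames(red))
  lapply(split_by, function(x)
    cbind(start = GenomicRanges::start(x) - 1, end = GenomicRanges::end(x)))
}

# Cumulative covered-bp lookup: C(x) = covered bp in [0, x) for one merged,
# sorted interval matrix.
coverage_lookup <- function(iv) {
  cum <- c(0, cumsum(iv[, "end"] - iv[, "start"]))
  function(x) {
    j <- findInterval(x, iv[, "start"])
    inside <- pmin(pmax(x - iv[pmax(j, 1), "start"], 0),
                   iv[pmax(j, 1), "end"] - iv[pmax(j, 1), "start"])
    ifelse(j == 0, 0, cum[pmax(j, 1)] + inside)
  }
}

#' Randomization test for ChIP-peak / target-interval overlap
#'
#' The observed statistic is the total nucleotide overlap between the peaks
#' and the (merged) target intervals, both first intersected with the
#' workspace. The null re-places every peak uniformly at random within the
#' workspace segments, preserving its length and never crossing a workspace
#' gap; the empirical p is (#\{null >= observed\} + 1) / (n_sim + 1) and
#' fold enrichment is observed over the null mean.
#'
#' @param peaks GRanges of ChIP peaks.
#' @param targets GRanges of target intervals (e.g. basal regulatory
#'   domains).
#' @param workspace GRanges of the admissible genomic space.
#' @param n_sim number of random placements (>= 100).
#' @param seed RNG seed.
#' @param statistic `"bp"` (total nucleotide overlap, default) or
#'   `"count"` (number of peaks overlapping a target).
#' @return object of class `overlap_test_result`: observed, expected (null
#'   mean), fold, p_empirical, n_sim, null vector, q_value (NA until filled
#'   by [adjust_pvalues()] across a batch of tests).
#' @export
interval_overlap_test <- function(peaks, targets, workspace, n_sim = 1000,
                                  seed = NULL, statistic = c("bp", "count")) {
  statistic <- match.arg(statistic)
  if (n_sim < 100) stop("n_sim must be >= 100")
  peaks <- GenomicRanges::intersect(GenomicRanges::reduce(peaks, ignore.strand = TRUE),
                                    GenomicRanges::reduce(workspace, ignore.strand = TRUE),
                                    ignore.strand = TRUE)
  targets_ws <- GenomicRanges::intersect(GenomicRanges::reduce(targets, ignore.strand = TRUE),
                                         GenomicRanges::reduce(workspace, ignore.strand = TRUE),
                                         ignore.strand = TRUE)
  ws <- flatten_intervals(workspace)
  tg <- flatten_intervals(targets_ws)
  pk <- flatten_intervals(peaks)

  lookups <- lapply(tg, coverage_lookup)
  obs_stat <- function(pk_list) {
    tot <- 0
    for (chr in names(pk_list)) {
      lk <- lookups[[chr]]
      if (is.null(lk)) next
      iv <- pk_list[[chr]]
      ov <- lk(iv[, "end"]) - lk(iv[, "start"])
      tot <- tot + if (statistic == "bp") sum(ov) else sum(ov > 0)
    }
    tot
  }
  observed <- obs_stat(pk)

  # workspace segments pooled across chromosomes for placement
  seg <- do.call(rbind, lapply(names(ws), function(chr)
    cbind(chr = match(chr, names(ws)), ws[[chr]])))
  seg_len <- seg[, "end"] - seg[, "start"]
  peak_lens <- unlist(lapply(pk, function(iv) iv[, "end"] - iv[, "start"]),
                      use.names = FALSE)
  if (length(peak_lens) == 0) stop("no peaks inside the workspace")
  if (max(peak_lens) > max(seg_len))
    stop("a peak is longer than every workspace segment")
  chr_names <- names(ws)

  null_stats <- with_rng(seed, {
    acc <- numeric(n_sim)
    for (L in unique(peak_lens)) {
      n_L <- sum(peak_lens == L)
      w <- pmax(seg_len - L + 1, 0)
      if (sum(w) == 0) stop("a peak is longer than every workspace segment")
      total <- n_L * n_sim
      si <- sample.int(nrow(seg), total, replace = TRUE, prob = w)
      st <- seg[si, "start"] + floor(runif(total) * w[si])
      ov <- numeric(total)
      for (ci in unique(seg[si, "chr"])) {
        sel <- seg[si, "chr"] == ci
        lk <- lookups[[chr_names[ci]]]
        if (is.null(lk)) { ov[sel] <- 0; next }
        ov[sel] <- lk(st[sel] + L) - lk(st[sel])
      }
      if (statistic == "count") ov <- as.numeric(ov > 0)
      acc <- acc + colSums(matrix(ov, nrow = n_L, ncol = n_sim))
    }
    acc
  })
  expected <- mean(null_stats)
  fold <- if (expected == 0) { if (observed == 0) 1 else Inf }
          else observed / expected
  p <- (sum(null_stats >= observed) + 1) / (n_sim + 1)
  structure(list(observed = observed, expected = expected, fold = fold,
                 p_empirical = p, n_sim = n_sim, null = null_stats,
                 statistic = statistic, q_value = NA_real_),
            class = "overlap_test_result")
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat(sprintf("overlap_test_result: observed %s %g vs expected %.1f -> fold %.3g, empirical p = %.4g (n_sim = %d)\n",
              x$statistic, x$observed, x$expected, x$fold, x$p_empirical,
              x$n_sim))
  invisible(x)
}

#' Benjamini-Hochberg adjustment of a p-value list
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method only "BH" is offered.
#' @return q-values in the original order.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  method <- match.arg(method, "BH")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
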