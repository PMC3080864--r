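#' Tail-enrichment ratio of two SNP classes
#'
#' Compares how often class-A SNPs fall in the lower tail of the rank
#' statistic relative to class-B SNPs:
#' \deqn{ratio = \frac{|A \cap tail(c)| / |A|}{|B \cap tail(c)| / |B|}},
#' with \eqn{tail(c) = \{q \le c\}}. Algebraically this equals the
#' tail-composition ratio \eqn{(|A \cap tail| / |B \cap tail|)} normalized by
#' the genome-wide composition \eqn{(|A| / |B|)}; a value of 1 means no
#' excess. SNPs with `NA` rank are ignored.
#'
#' @param q per-SNP rank statistics (e.g. minimum ranks).
#' @param class_a,class_b disjoint logical class indicators aligned with `q`.
#' @param cutoff tail cutoff in (0, 1); the analysis defaults are 0.05, 0.01
#'   and 0.005.
#' @return The ratio, with attributes `n_a`, `n_b`, `tail_a`, `tail_b` and
#'   `undefined` (`TRUE`, with value `NA`, when class B has no tail SNPs).
#' @export
tail_ratio <- function(q, class_a, class_b, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop_ecoscan("cutoff must lie in (0, 1)")
  if (any(class_a & class_b)) stop_ecoscan("classes must be disjoint")
  ok <- is.finite(q)
  a <- class_a & ok; b <- class_b & ok
  n_a <- sum(a); n_b <- sum(b)
  if (n_a == 0L || n_b == 0L) stop_ecoscan("empty SNP class")
  tail_a <- sum(a & q <= cutoff); tail_b <- sum(b & q <= cutoff)
  undefined <- tail_b == 0L
  ratio <- if (undefined) NA_real_ else (tail_a / n_a) / (tail_b / n_b)
  structure(ratio, n_a = n_a, n_b = n_b, tail_a = tail_a, tail_b = tail_b,
            undefined = undefined)
}

# per-genome-block class/tail counts used by the bootstrap
block_stats_ <- function(q, class_a, class_b, chrom, pos, block_size, cutoffs) {
  block <- factor(paste0(chrom, ":", pos %/% block_size))
  cols <- cbind(a_n = as.numeric(class_a), b_n = as.numeric(class_b))
  for (i in seq_along(cutoffs)) {
    cols <- cbind(cols,
                  as.numeric(class_a & q <= cutoffs[i]),
                  as.numeric(class_b & q <= cutoffs[i]))
    colnames(cols)[ncol(cols) - 1:0] <- paste0(c("a_t", "b_t"), i)
  }
  rowsum(cols, block)
}

ratios_from_totals_ <- function(tot, cutoffs) {
  vapply(seq_along(cutoffs), function(i) {
    ta <- tot[paste0("a_t", i)]; tb <- tot[paste0("b_t", i)]
    if (tot["a_n"] == 0 || tot["b_n"] == 0 || tb == 0) return(NA_real_)
    unname((ta / tot["a_n"]) / (tb / tot["b_n"]))
  }, 0)
}

#' Block-bootstrap significance of tail enrichment
#'
#' Observed tail ratios at each cutoff plus a genome block bootstrap that
#' respects linkage disequilibrium: the genome is cut into half-open
#' `block_size` (default 500 kb) windows per chromosome, and each replicate
#' resamples, with replacement from the occupied windows, a number of windows
#' equal to the spanned genome length divided by the window size, pooling
#' their SNPs with multiplicity and recomputing the ratios. An enrichment is
#' called significant (one-tailed) when at least 95% of replicates have a
#' ratio above 1; tiers `*`, `**`, `***` mark fractions of at least 0.95,
#' 0.975 and 0.99. Replicates with an undefined ratio (no class-B SNPs in
#' the tail) are counted as not enriched.
#'
#' @inheritParams tail_ratio
#' @param chrom,pos genome coordinates aligned with `q` (0-based positions).
#' @param cutoffs tail cutoffs (default `c(0.05, 0.01, 0.005)`).
#' @param block_size window size in bp (default 500000).
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @param comparison,rank_source labels recorded in the report.
#' @return An `enrichment_report` data frame (one row per cutoff) with the
#'   observed ratio, backing counts, fraction of replicates above 1, count of
#'   undefined replicates and significance tier; the replicate ratio matrix
#'   is attached as attribute `"replicates"`.
#' @export
block_bootstrap_enrichment <- function(q, class_a, class_b, chrom, pos,
                                       cutoffs = c(0.05, 0.01, 0.005),
                                       block_size = 500000L, replicates = 1000L,
                                       seed = NULL, comparison = "A:B",
                                       rank_source = "min_rank") {
  ok <- is.finite(q)
  q <- q[ok]; class_a <- class_a[ok]; class_b <- class_b[ok]
  chrom <- chrom[ok]; pos <- pos[ok]
  if (any(class_a & class_b)) stop_ecoscan("classes must be disjoint")
  if (sum(class_a) == 0L || sum(class_b) == 0L) stop_ecoscan("empty SNP class")
  bs <- block_stats_(q, class_a, class_b, chrom, pos, block_size, cutoffs)
  if (nrow(bs) < 1L) stop_ecoscan("no occupied genome blocks")
  spanned <- sum(tapply(pos, chrom, max) + 1)
  n_draw <- ceiling(spanned / block_size)
  observed <- ratios_from_totals_(colSums(bs), cutoffs)

  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(bs)
  reps <- matrix(NA_real_, replicates, length(cutoffs))
  for (r in seq_len(replicates)) {
    w <- tabulate(sample.int(nb, n_draw, replace = TRUE), nb)
    reps[r, ] <- ratios_from_totals_(colSums(bs * w), cutoffs)
  }
  frac <- colSums(reps > 1, na.rm = TRUE) / replicates
  n_undef <- colSums(is.na(reps))
  tier <- ifelse(frac >= 0.99, "***",
          ifelse(frac >= 0.975, "**",
          ifelse(frac >= 0.95, "*", "")))
  tot <- colSums(bs)
  out <- data.frame(
    comparison = comparison, rank_source = rank_source, cutoff = cutoffs,
    n_a = tot[["a_n"]], n_b = tot[["b_n"]],
    tail_a = vapply(seq_along(cutoffs), function(i) tot[[paste0("a_t", i)]], 0),
    tail_b = vapply(seq_along(cutoffs), function(i) tot[[paste0("b_t", i)]], 0),
    ratio = observed, boot_frac_gt1 = frac, n_undefined_replicates = n_undef,
    tier = tier, stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  class(out) <- c("enrichment_report", "data.frame")
  out
}

#' Genic and nonsynonymous tail enrichment of a ranked scan
#'
#' Convenience wrapper running [block_bootstrap_enrichment()] for the two
#' standard functional comparisons -- genic (including nonsynonymous) vs
#' nongenic and nonsynonymous vs nongenic -- on the minimum rank or a single
#' variable's ranks.
#'
#' @param ranks a `rank_table` ([rank_table()]).
#' @param annotations an `annotation_table` ([read_annotations()]).
#' @param source `"min_rank"` or one of the scan variables.
#' @param ... passed to [block_bootstrap_enrichment()].
#' @return An `enrichment_report` with both comparisons stacked.
#' @export
class_enrichment <- function(ranks, annotations, source = "min_rank", ...) {
  snps <- ranks$snps
  q <- if (source == "min_rank") snps$min_rank else ranks$q[, source]
  cls <- annotations$class[match(snps$snp_id, annotations$snp_id)]
  genic <- cls %in% c("genic", "nonsynonymous")
  ns <- cls %in% "nonsynonymous"
  nong <- cls %in% "nongenic"
  out <- rbind(
    block_bootstrap_enrichment(q, genic, nong, snps$chrom, snps$pos,
                               comparison = "genic:nongenic",
                               rank_source = source, ...),
    block_bootstrap_enrichment(q, ns, nong, snps$chrom, snps$pos,
                               comparison = "nonsynonymous:nongenic",
                               rank_source = source, ...))
  class(out) <- c("enrichment_report", "data.frame")
  out
}

#' Gene-set tail enrichment against the genic background
#'
#' For each gene set, compares the SNPs of the set's genes to all other genic
#' SNPs in the lower tail of the chosen rank statistic, with the same block
#' bootstrap as [block_bootstrap_enrichment()]. Sets mapping to no SNPs are
#' skipped with a warning; a set covering all genic SNPs leaves an empty
#' background and is an error.
#'
#' @inheritParams class_enrichment
#' @param gene_sets a `gene_set_collection` ([read_gene_sets()]) or named
#'   list of gene-id vectors.
#' @return An `enrichment_report` with one block of rows per gene set
#'   (`comparison` is the set name).
#' @export
gene_set_enrichment <- function(ranks, gene_sets, annotations,
                                source = "min_rank", ...) {
  snps <- ranks$snps
  q <- if (source == "min_rank") snps$min_rank else ranks$q[, source]
  hit <- match(snps$snp_id, annotations$snp_id)
  cls <- annotations$class[hit]
  gene <- annotations$gene_id[hit]
  genic <- cls %in% c("genic", "nonsynonymous") & !is.na(gene) & gene != ""
  out <- NULL
  for (nm in names(gene_sets)) {
    a <- genic & gene %in% gene_sets[[nm]]
    if (sum(a) == 0L) {
      warning(sprintf("gene set '%s' maps to no SNPs; skipped", nm))
      next
    }
    b <- genic & !a
    if (sum(b) == 0L)
      stop_ecoscan("gene set '%s' covers all genic SNPs; no background left", nm)
    rep_nm <- block_bootstrap_enrichment(q, a, b, snps$chrom, snps$pos,
                                         comparison = nm, rank_source = source,
                                         ...)
    out <- if (is.null(out)) rep_nm else rbind(out, rep_nm)
  }
  if (is.null(out)) stop_ecoscan("no gene set mapped to any SNP")
  class(out) <- c("enrichment_report", "data.frame")
  out
}
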