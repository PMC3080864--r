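#' Scan and rank a named population subset
#'
#' Runs the full scan + rank pipeline restricted to the populations of a
#' named subset of the panel (e.g. geographically restricted sets used to
#' catch region-restricted adaptation), re-estimating the covariance null on
#' the subset for every ascertainment panel before scanning. SNPs
#' monomorphic within the subset are excluded there. With
#' `subset = "worldwide"` this reproduces the worldwide analysis exactly.
#'
#' @param counts an [allele_counts()] object.
#' @param env an `environment_table`.
#' @param panel a [population_panel()] whose `subsets` define the sets.
#' @param subset subset name (default `"worldwide"`).
#' @param tau,n_controls,seed,min_controls passed to [climate_scan()].
#' @param binning_freqs,min_bin_size passed to [rank_table()].
#' @return List with elements `scan` (`scan_result`) and `ranks`
#'   (`rank_table`).
#' @export
subset_scan <- function(counts, env, panel, subset = "worldwide", tau = 1,
                        n_controls = 20000L, seed = NULL, min_controls = NULL,
                        binning_freqs = NULL, min_bin_size = 50L) {
  pops <- panel_subset(panel, subset)
  if (length(pops) < 3L)
    stop_ecoscan("population subset '%s' has fewer than 3 populations", subset)
  scan <- climate_scan(counts, env, populations = pops, tau = tau,
                       n_controls = n_controls, seed = seed,
                       min_controls = min_controls, population_set = subset)
  ranks <- rank_table(scan, binning_freqs = binning_freqs,
                      min_bin_size = min_bin_size)
  list(scan = scan, ranks = ranks)
}

#' Tail overlap between two analyses
#'
#' Counts SNPs falling in the lower tails of two rank-statistic vectors over
#' their shared SNP universe and compares the intersection to the expectation
#' under independent draws, `N * (|tail A|/N) * (|tail B|/N)`. Venn region
#' counts and the Spearman correlation of the two vectors are reported
#' alongside.
#'
#' @param rank_a,rank_b named numeric vectors of per-SNP rank statistics
#'   (e.g. [min_rank()] of two analyses); names are SNP ids.
#' @param cutoff tail cutoff.
#' @return An `overlap_report` list: `n` (shared universe size), `tail_a`,
#'   `tail_b`, `observed`, `expected`, `fold`, `venn` (counts for
#'   both/A-only/B-only/neither) and `spearman`.
#' @export
tail_overlap <- function(rank_a, rank_b, cutoff) {
  shared <- intersect(names(rank_a)[is.finite(rank_a)],
                      names(rank_b)[is.finite(rank_b)])
  if (!length(shared)) stop_ecoscan("empty shared SNP universe")
  a <- rank_a[shared]; b <- rank_b[shared]
  n <- length(shared)
  in_a <- a <= cutoff; in_b <- b <= cutoff
  observed <- sum(in_a & in_b)
  expected <- n * (sum(in_a) / n) * (sum(in_b) / n)
  structure(list(
    n = n, cutoff = cutoff, tail_a = sum(in_a), tail_b = sum(in_b),
    observed = observed, expected = expected,
    fold = if (expected > 0) observed / expected else NA_real_,
    venn = c(both = observed, a_only = sum(in_a & !in_b),
             b_only = sum(!in_a & in_b), neither = sum(!in_a & !in_b)),
    spearman = rank_correlation(a, b)), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "overlap_report: N = %d, cutoff = %g; observed = %d, expected = %.2f (fold %.2f), rho = %.3f\n",
    x$n, x$cutoff, x$observed, x$expected, x$fold, x$spearman))
  invisible(x)
}

#' Spearman correlation of two rank-statistic vectors
#'
#' @param rank_a,rank_b numeric vectors; if named, they are matched over the
#'   shared names first.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(rank_a, rank_b) {
  if (!is.null(names(rank_a)) && !is.null(names(rank_b))) {
    shared <- intersect(names(rank_a)[is.finite(rank_a)],
                        names(rank_b)[is.finite(rank_b)])
    if (!length(shared)) stop_ecoscan("empty shared SNP universe")
    rank_a <- rank_a[shared]; rank_b <- rank_b[shared]
  }
  stats::cor(rank_a, rank_b, method = "spearman", use = "complete.obs")
}

#' Pooled derived-allele frequencies over one region group
#'
#' Helper for frequency binning on a reference group (e.g. Europeans, for
#' comparison with GWAS hits discovered in European-ancestry cohorts).
#'
#' @param counts an [allele_counts()] object.
#' @param panel a [population_panel()].
#' @param regions region labels defining the group (default `"Europe"`).
#' @return Named per-SNP pooled frequency vector over the group.
#' @export
region_frequencies <- function(counts, panel, regions = "Europe") {
  pops <- panel$population[panel$region %in% regions]
  if (!length(pops)) stop_ecoscan("no populations in region(s): %s",
                                  paste(regions, collapse = ", "))
  sub <- align_populations(counts, pops)
  tot <- rowSums(sub$n)
  eps <- ifelse(tot > 0, rowSums(sub$k) / tot, NA_real_)
  stats::setNames(eps, counts$snps$snp_id)
}

#' Intersect climate-scan signals with a GWAS catalog
#'
#' Retains catalog SNPs that pass both filters: a transformed rank statistic
#' below `rank_cutoff` for at least one climate variable (ranks should be
#' computed with reference-group frequency binning, see
#' [region_frequencies()]) and a GWAS p-value below `p_cutoff`. One row is
#' emitted per (SNP, trait, population set) with the best variable (smallest
#' rank), its rank and log10 BF, and the annotated gene. Output order is
#' deterministic and independent of catalog row order.
#'
#' @param results a single `list(scan =, ranks =)` (as from [subset_scan()])
#'   or a named list of them, one per population set.
#' @param catalog a `gwas_catalog` ([read_gwas_catalog()]).
#' @param annotations optional `annotation_table` supplying `gene_id`.
#' @param rank_cutoff rank-statistic filter (default 5e-4, strict `<`).
#' @param p_cutoff GWAS p-value filter (default 1e-5, strict `<`).
#' @return Data frame of class `gwas_overlap_table`.
#' @export
gwas_overlap <- function(results, catalog, annotations = NULL,
                         rank_cutoff = 5e-4, p_cutoff = 1e-5) {
  if (!is.null(results$scan)) results <- list(worldwide = results)
  catalog <- catalog[catalog$p_value < p_cutoff, , drop = FALSE]
  rows <- list()
  for (set in names(results)) {
    res <- results[[set]]
    q <- res$ranks$q
    snp_ids <- res$ranks$snps$snp_id
    for (i in seq_len(nrow(catalog))) {
      snp <- catalog$snp_id[i]
      j <- match(snp, snp_ids)
      if (is.na(j)) next
      qs <- q[j, ]
      if (!any(is.finite(qs) & qs < rank_cutoff)) next
      best <- which.min(replace(qs, !is.finite(qs), Inf))
      gene <- if (is.null(annotations)) NA_character_ else {
        g <- annotations$gene_id[match(snp, annotations$snp_id)]
        if (length(g) == 0 || is.na(g)) NA_character_ else g
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, trait = catalog$trait[i], p_value = catalog$p_value[i],
        population_set = set, variable = res$ranks$variables[best],
        log10_bf = res$scan$bf[j, best], rank = qs[best], gene_id = gene,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), trait = character(),
               p_value = numeric(), population_set = character(),
               variable = character(), log10_bf = numeric(),
               rank = numeric(), gene_id = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$population_set, out$snp_id, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_overlap_table", "data.frame")
  out
}
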