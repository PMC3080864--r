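#' Assign SNPs to ascertainment x frequency bins
#'
#' Ranking is done within bins so that SNPs are only compared against SNPs
#' with similar discovery bias and allele frequency: one bin per combination
#' of ascertainment panel and derived-allele-frequency tenth (equal-width,
#' half-open `[j/10, (j+1)/10)`, frequency 1 capped into the top bin). With 3
#' panels and all 10 tenths occupied this yields 30 bins. Occupied bins with
#' fewer than `min_bin_size` SNPs are merged (recursively) into the adjacent
#' lower-frequency bin -- the lowest bin, if undersized, merges upward -- and
#' each merge is reported via `message()`.
#'
#' @param freq per-SNP binning frequency in `[0, 1]` (pooled global or, e.g.,
#'   European derived-allele frequency).
#' @param panel per-SNP ascertainment-panel label.
#' @param min_bin_size minimum SNPs per bin before merging (default 50).
#' @return Character vector of bin ids `"<panel>:f<j>"`, where `j` is the
#'   lowest frequency tenth merged into the bin.
#' @export
assign_bins <- function(freq, panel, min_bin_size = 50L) {
  if (any(!is.finite(freq) | freq < 0 | freq > 1))
    stop_ecoscan("binning frequencies must lie in [0, 1]")
  idx <- pmin(floor(freq * 10), 9L)
  out <- character(length(freq))
  for (p in unique(panel)) {
    sel <- panel == p
    map <- merge_bins_(idx[sel], min_bin_size, p)
    out[sel] <- sprintf("%s:f%d", p, map[as.character(idx[sel])])
  }
  out
}

# map each occupied decile index to the lowest index of its merged group
merge_bins_ <- function(idx, min_bin_size, panel_label) {
  tab <- table(idx)
  groups <- lapply(as.integer(names(tab)), function(j) j)
  counts <- as.integer(tab)
  repeat {
    small <- which(counts < min_bin_size)
    if (!length(small) || length(counts) == 1L) break
    g <- max(small)
    into <- if (g == 1L) 2L else g - 1L
    message(sprintf("panel %s: merging frequency bin %s (%d SNPs) into bin %s",
                    panel_label, min(groups[[g]]) / 10, counts[g],
                    min(groups[[into]]) / 10))
    groups[[into]] <- c(groups[[into]], groups[[g]])
    counts[into] <- counts[into] + counts[g]
    groups[[g]] <- NULL
    counts <- counts[-g]
  }
  map <- integer(0)
  for (g in groups) map[as.character(g)] <- min(g)
  map
}

#' Transformed rank statistic within one bin
#'
#' Converts the Bayes factors of one bin and one variable into the empirical
#' rank statistic ("empirical p-value") scaled to \eqn{(0, 1]}: SNPs are
#' sorted by decreasing BF (ties broken by ascending `snp_id` for
#' reproducibility) and the SNP at rank r of N receives q = r/N, so the
#' strongest SNP gets 1/N -- of order 1e-5 for genome-scale bins -- and the
#' weakest gets 1. Any strictly monotone transform of the BFs leaves q
#' unchanged.
#'
#' @param log10bf numeric vector of log10 Bayes factors in the bin.
#' @param snp_id tie-breaking ids (default: input order).
#' @return Numeric vector of rank statistics, aligned with the input.
#' @export
transformed_rank <- function(log10bf, snp_id = seq_along(log10bf)) {
  N <- length(log10bf)
  ord <- order(-log10bf, snp_id)
  q <- numeric(N)
  q[ord] <- seq_len(N) / N
  q
}

#' Rank table: binned empirical ranks and per-SNP minimum rank
#'
#' Applies [assign_bins()] and [transformed_rank()] to a scan result, per
#' (bin, variable), and computes for each SNP the minimum of its transformed
#' rank statistics across variables -- the single per-SNP summary used for
#' enrichment of climate signal as a whole. Excluded (monomorphic) SNPs carry
#' `NA` throughout.
#'
#' @param scan a `scan_result` from [climate_scan()].
#' @param binning_freqs optional per-SNP frequencies to bin on instead of the
#'   scan's pooled frequency (e.g. European frequencies for GWAS comparison);
#'   either aligned with the scan rows or named by `snp_id`.
#' @param min_bin_size passed to [assign_bins()].
#' @param binning label recorded in the result (default `"global"`).
#' @return A `rank_table`: list with `snps` (per-SNP table with `bin` and
#'   `min_rank`), `q` (SNP x variable rank matrix), `variables`,
#'   `population_set`, `binning`.
#' @export
rank_table <- function(scan, binning_freqs = NULL, min_bin_size = 50L,
                       binning = if (is.null(binning_freqs)) "global" else "custom") {
  snps <- scan$snps
  keep <- !snps$excluded & is.finite(snps$eps)
  freq <- if (is.null(binning_freqs)) {
    snps$eps
  } else if (!is.null(names(binning_freqs))) {
    unname(binning_freqs[snps$snp_id])
  } else {
    if (length(binning_freqs) != nrow(snps))
      stop_ecoscan("binning_freqs length does not match the scan")
    binning_freqs
  }
  keep <- keep & is.finite(freq)
  bin <- rep(NA_character_, nrow(snps))
  bin[keep] <- assign_bins(freq[keep], snps$panel[keep], min_bin_size)
  q <- matrix(NA_real_, nrow(snps), length(scan$variables),
              dimnames = dimnames(scan$bf))
  for (b in unique(bin[keep])) {
    rows <- which(!is.na(bin) & bin == b)
    for (v in scan$variables) {
      ok <- rows[is.finite(scan$bf[rows, v])]
      if (length(ok))
        q[ok, v] <- transformed_rank(scan$bf[ok, v], snps$snp_id[ok])
    }
  }
  snps$bin <- bin
  snps$min_rank <- row_mins(q)
  structure(list(snps = snps, q = q, variables = scan$variables,
                 population_set = scan$population_set, binning = binning),
            class = "rank_table")
}

#' @rdname rank_table
#' @param ranks a `rank_table`.
#' @return `min_rank`: named numeric vector of per-SNP minimum ranks.
#' @export
min_rank <- function(ranks) {
  stats::setNames(ranks$snps$min_rank, ranks$snps$snp_id)
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("rank_table: %d SNPs, %d bins, %d variables; set '%s', binning '%s'\n",
              nrow(x$snps), length(unique(stats::na.omit(x$snps$bin))),
              length(x$variables), x$population_set, x$binning))
  invisible(x)
}
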