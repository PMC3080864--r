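#' Population panel
#'
#' Describes the populations entering a scan: sample sizes in chromosomes
#' (2 x sampled individuals), a geographic region for each population, and
#' named population subsets (e.g. geographically restricted sets scanned with
#' a re-estimated covariance null).
#'
#' @param population character vector of unique population ids.
#' @param region character vector of region labels, one per population.
#' @param n_chromosomes integer vector of total chromosomes per population
#'   (each at least 2).
#' @param subsets named list of character vectors, each a nonempty subset of
#'   `population`. A `"worldwide"` subset holding all populations is always
#'   present.
#' @return A `population_panel`: a data frame with columns `population`,
#'   `region`, `n_chromosomes` and a `subsets` attribute.
#' @export
population_panel <- function(population, region, n_chromosomes, subsets = list()) {
  population <- as.character(population)
  if (anyDuplicated(population))
    stop_ecoscan("duplicate population ids: %s",
                 paste(unique(population[duplicated(population)]), collapse = ", "))
  if (length(region) != length(population) ||
      length(n_chromosomes) != length(population))
    stop_ecoscan("region and n_chromosomes must match population length")
  n_chromosomes <- as.integer(n_chromosomes)
  if (any(n_chromosomes < 2L)) stop_ecoscan("n_chromosomes must be >= 2")
  subsets <- c(list(worldwide = population), subsets)
  subsets <- subsets[!duplicated(names(subsets))]
  for (nm in names(subsets)) {
    s <- subsets[[nm]]
    if (length(s) == 0L) stop_ecoscan("subset '%s' is empty", nm)
    bad <- setdiff(s, population)
    if (length(bad))
      stop_ecoscan("subset '%s' names unknown populations: %s", nm,
                   paste(bad, collapse = ", "))
  }
  out <- data.frame(population = population, region = as.character(region),
                    n_chromosomes = n_chromosomes, stringsAsFactors = FALSE)
  attr(out, "subsets") <- subsets
  class(out) <- c("population_panel", "data.frame")
  out
}

#' Look up the populations of a named subset
#'
#' @param panel a [population_panel()].
#' @param subset subset name; `"worldwide"` returns all populations.
#' @return Character vector of population ids, in panel order.
#' @export
panel_subset <- function(panel, subset = "worldwide") {
  subsets <- attr(panel, "subsets")
  if (!subset %in% names(subsets))
    stop_ecoscan("unknown population subset '%s'", subset)
  intersect(panel$population, subsets[[subset]])
}

#' Allele-count matrix
#'
#' Per-SNP derived and total chromosome counts for every population, plus
#' genome coordinates and the ascertainment-panel label that stratifies all
#' downstream analyses.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos` (0-based),
#'   `panel`.
#' @param k integer matrix (SNP x population) of derived-allele counts.
#' @param n integer matrix (SNP x population) of total chromosome counts;
#'   reduced entries encode per-SNP missing genotypes.
#' @return An `allele_counts` object (list with elements `snps`, `k`, `n`,
#'   `populations`).
#' @export
allele_counts <- function(snps, k, n) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "panel")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop_ecoscan("snps table missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop_ecoscan("duplicate snp_id: %s",
                 paste(utils::head(unique(snps$snp_id[duplicated(snps$snp_id)]), 3), collapse = ", "))
  if (any(snps$pos < 0)) stop_ecoscan("positions must be non-negative (0-based)")
  k <- as.matrix(k); n <- as.matrix(n)
  if (!identical(dim(k), dim(n)) || nrow(k) != nrow(snps))
    stop_ecoscan("k and n must be SNP x population matrices matching the snps table")
  if (is.null(colnames(k)) || is.null(colnames(n)) || !identical(colnames(k), colnames(n)))
    stop_ecoscan("k and n must carry identical population column names")
  bad <- which(!is_whole(k) | !is_whole(n), arr.ind = TRUE)
  if (nrow(bad))
    stop_ecoscan("non-integer count at snp '%s', population '%s'",
                 snps$snp_id[bad[1, 1]], colnames(k)[bad[1, 2]])
  bad <- which(k < 0 | n < 0 | k > n, arr.ind = TRUE)
  if (nrow(bad))
    stop_ecoscan("invalid counts (need 0 <= k <= n) at snp '%s', population '%s'",
                 snps$snp_id[bad[1, 1]], colnames(k)[bad[1, 2]])
  rownames(k) <- rownames(n) <- snps$snp_id
  structure(list(snps = snps, k = k, n = n, populations = colnames(k)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d SNPs x %d populations; panels: %s\n",
              nrow(x$k), ncol(x$k),
              paste(sort(unique(x$snps$panel)), collapse = ", ")))
  invisible(x)
}

#' @export
print.population_panel <- function(x, ...) {
  cat(sprintf("population_panel: %d populations in %d regions; subsets: %s\n",
              nrow(x), length(unique(x$region)),
              paste(names(attr(x, "subsets")), collapse = ", ")))
  NextMethod()
}

# reorder count columns to the canonical panel order
align_populations <- function(counts, populations) {
  bad <- setdiff(populations, counts$populations)
  if (length(bad))
    stop_ecoscan("populations absent from allele counts: %s", paste(bad, collapse = ", "))
  counts$k <- counts$k[, populations, drop = FALSE]
  counts$n <- counts$n[, populations, drop = FALSE]
  counts$populations <- populations
  counts
}
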