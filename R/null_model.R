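#' Pooled derived-allele frequency
#'
#' Anchors the null model: the across-population pooled frequency
#' \eqn{\hat\epsilon = \sum_l k_l / \sum_l n_l}. SNPs that are monomorphic in
#' the analyzed population set (\eqn{\hat\epsilon \in \{0, 1\}}) are excluded
#' from covariance estimation, scanning and ranking.
#'
#' @param k derived counts: vector (one SNP) or SNP x population matrix.
#' @param n matching total chromosome counts.
#' @return Numeric vector of pooled frequencies.
#' @seealso [monomorphic_flags()]
#' @export
pooled_frequency <- function(k, n) {
  if (is.matrix(k)) {
    tot <- rowSums(n)
    if (any(tot <= 0)) stop_ecoscan("SNP with zero total chromosomes")
    unname(rowSums(k) / tot)
  } else {
    tot <- sum(n)
    if (tot <= 0) stop_ecoscan("zero total chromosomes")
    sum(k) / tot
  }
}

#' @rdname pooled_frequency
#' @param eps pooled frequencies.
#' @return `monomorphic_flags`: logical vector, `TRUE` where the SNP carries
#'   no variation in the population set.
#' @export
monomorphic_flags <- function(eps) !is.finite(eps) | eps <= 0 | eps >= 1

#' Standardized allele-frequency deviations
#'
#' The transform placing all SNPs on a common drift scale:
#' \eqn{y_l = (k_l/n_l - \hat\epsilon) / \sqrt{\hat\epsilon(1-\hat\epsilon)}}.
#' Populations with \eqn{n_l = 0} (per-SNP missingness) are masked with `NA`.
#'
#' @param k,n counts as in [pooled_frequency()].
#' @param eps pooled frequency per SNP (strictly inside (0,1)).
#' @return Matrix (or vector) of standardized deviations, `NA` where masked.
#' @export
standardize_frequencies <- function(k, n, eps = pooled_frequency(k, n)) {
  if (any(monomorphic_flags(eps)))
    stop_ecoscan("monomorphic SNP passed to standardize_frequencies")
  if (is.matrix(k)) {
    y <- (k / n - eps) / sqrt(eps * (1 - eps))
    y[n == 0] <- NA_real_
    y
  } else {
    y <- (k / n - eps) / sqrt(eps * (1 - eps))
    y[n == 0] <- NA_real_
    y
  }
}

#' Estimate the population-structure covariance null
#'
#' Moment estimator of the across-population covariance of standardized
#' allele frequencies, per ascertainment panel and population set, from a
#' (seeded) random subset of control SNPs: the raw moment matrix
#' \eqn{C = M^{-1} \sum y y^\top} (pairwise-complete over masked entries) is
#' corrected for binomial sampling noise, \eqn{\hat\Omega = C - D} with
#' \eqn{D_{ll} = 1/\bar n_l}, and projected to positive semi-definiteness by
#' flooring eigenvalues at `psd_floor_factor` times the mean positive
#' eigenvalue. Because allele orientation enters only through \eqn{y y^\top},
#' the estimate is invariant to flipping any subset of control SNPs.
#'
#' Note the estimand is identifiable only relative to the pooled-frequency
#' reference: the pooled \eqn{\hat\epsilon} absorbs the component of drift
#' shared by all populations, so \eqn{\hat\Omega} estimates the covariance of
#' deviations from the (sample-size-weighted) mean rather than from the
#' unobservable ancestral frequency. All downstream quantities use
#' \eqn{\hat\Omega} through the same transform, so this reference choice
#' cancels.
#'
#' @param counts an [allele_counts()] object.
#' @param panel_label ascertainment panel whose SNPs provide the controls.
#' @param populations population ids defining the set (default: all).
#' @param n_controls number of control SNPs to draw (default 20000, capped at
#'   availability).
#' @param seed seed for the control-SNP draw; `NULL` leaves the RNG alone.
#' @param min_controls required minimum, default `max(500, 5 L)`.
#' @param population_set label stored in the model.
#' @param psd_floor_factor relative eigenvalue floor.
#' @return A `covariance_model`: list with `omega` (L x L), `d` (sampling
#'   variances \eqn{1/\bar n_l}), `populations`, `panel`, `population_set`,
#'   `n_control_snps`.
#' @export
estimate_covariance <- function(counts, panel_label, populations = NULL,
                                n_controls = 20000L, seed = NULL,
                                min_controls = NULL,
                                population_set = "worldwide",
                                psd_floor_factor = 1e-6) {
  populations <- populations %||% counts$populations
  counts <- align_populations(counts, populations)
  L <- length(populations)
  idx <- which(counts$snps$panel == panel_label)
  if (!length(idx)) stop_ecoscan("no SNPs in panel '%s'", panel_label)
  k <- counts$k[idx, , drop = FALSE]
  n <- counts$n[idx, , drop = FALSE]
  eps <- pooled_frequency(k, n)
  poly <- !monomorphic_flags(eps)
  k <- k[poly, , drop = FALSE]; n <- n[poly, , drop = FALSE]; eps <- eps[poly]
  min_controls <- min_controls %||% max(500L, 5L * L)
  if (nrow(k) < min_controls)
    stop_ecoscan("panel '%s': %d polymorphic control SNPs available, need >= %d",
                 panel_label, nrow(k), min_controls)
  if (!is.null(seed)) set.seed(seed)
  m <- min(n_controls, nrow(k))
  take <- sort(sample.int(nrow(k), m))
  k <- k[take, , drop = FALSE]; n <- n[take, , drop = FALSE]; eps <- eps[take]

  y <- standardize_frequencies(k, n, eps)
  obs <- !is.na(y)
  if (any(colSums(obs) == 0L))
    stop_ecoscan("population with no observed control genotypes in panel '%s'", panel_label)
  y0 <- y; y0[!obs] <- 0
  pair_n <- crossprod(obs)         # per-pair complete counts
  C <- crossprod(y0) / pair_n
  nbar <- colSums(n * obs) / colSums(obs)
  d <- 1 / nbar
  omega <- C - diag(d, L)
  omega <- (omega + t(omega)) / 2
  eg <- eigen(omega, symmetric = TRUE)
  pos <- eg$values[eg$values > 0]
  floor_val <- psd_floor_factor * (if (length(pos)) mean(pos) else 1)
  vals <- pmax(eg$values, floor_val)
  omega <- eg$vectors %*% (vals * t(eg$vectors))
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- list(populations, populations)
  structure(list(omega = omega, d = stats::setNames(d, populations),
                 populations = populations, panel = panel_label,
                 population_set = population_set, n_control_snps = m,
                 psd_floor = floor_val),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf(
    "covariance_model: %d populations, panel '%s', set '%s', %d control SNPs\n",
    length(x$populations), x$panel, x$population_set, x$n_control_snps))
  invisible(x)
}
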