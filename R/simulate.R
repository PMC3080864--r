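#' Default climate variables of the generator
#'
#' Nine variables: absolute latitude, summer maximum and winter minimum
#' temperature, and summer/winter precipitation rate, relative humidity and
#' solar radiation. The generator draws each on a standardized scale and
#' maps it to plausible native units with a fixed affine transform (degrees,
#' degrees C, mm/day, %, W/m2); the scan standardizes variables again, so
#' these units are cosmetic.
#'
#' @return Character vector of variable names.
#' @export
climate_variables <- function() {
  c("abs_latitude", "summer_max_temp", "winter_min_temp",
    "summer_precip", "winter_precip", "summer_humidity", "winter_humidity",
    "summer_solar", "winter_solar")
}

variable_units_ <- function() {
  # offset + scale per variable, native-unit cosmetics only
  data.frame(
    variable = climate_variables(),
    offset = c(30, 28, 2, 3, 2.5, 60, 55, 240, 150),
    scale = c(18, 8, 18, 2.5, 2, 18, 20, 45, 60),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic-data generator
#'
#' Desk-scale defaults emulate the structure of a worldwide SNP-array
#' dataset: 60 populations in 7 regions with 16-160 chromosomes each, 3
#' ascertainment panels, 20,000 SNPs spaced every 150 kb over 22 chromosomes
#' (a 3-Gb-proportional genome), environment variables confounded with
#' population structure, and a configurable fraction of SNPs carrying a true
#' linear environmental effect, preferentially placed in genic and
#' nonsynonymous classes and in designated gene sets.
#'
#' @param n_populations number of populations (L).
#' @param region_names region labels; populations are split over them.
#' @param region_sizes optional integer vector summing to `n_populations`.
#' @param n_chrom_range range of per-population total chromosomes
#'   (2 x individuals; even values drawn uniformly).
#' @param panels named ascertainment-panel proportions.
#' @param n_snps number of SNPs.
#' @param fraction_effect fraction of SNPs with a true effect.
#' @param sigma_beta effect scale in units of the per-SNP drift standard
#'   deviation \eqn{\sqrt{\epsilon(1-\epsilon)\,\overline{diag \Omega}}}; the
#'   default 1 plants selective shifts on the order of the drift noise itself
#'   (larger values progressively clip against the frequency boundaries).
#' @param beta_kind `"normal"` (effects ~ N(0, sigma_beta^2) on the drift
#'   scale) or `"fixed"` (magnitude exactly `sigma_beta`, random sign).
#' @param rho structure-environment confounding in [0, 1]: each variable is
#'   `rho` x (a draw with covariance \eqn{\Omega_{true}}) + `(1-rho)` x
#'   independent noise.
#' @param spacing SNP spacing in bp; `n_chromosomes` chromosomes.
#' @param n_chromosomes number of chromosomes in the synthetic genome.
#' @param between_depth,within_depth mean root-to-tip drift depth of the
#'   region backbone tree and of the within-region subtrees (standardized
#'   frequency-variance units; within-region branches are shorter, so
#'   populations of a region are more correlated).
#' @param panel_eps_shapes per-panel Beta shape pairs for the ancestral
#'   frequency draw, mimicking panel-specific ascertainment toward common
#'   alleles.
#' @param eps_range ancestral frequencies are clamped to this interval
#'   (default [0.15, 0.85]): array SNPs are discovered in small panels and
#'   are overwhelmingly common, and keeping the anchor away from the
#'   boundaries keeps the Gaussian drift approximation (shared by generator
#'   and scan) from piling mass on the frequency bounds.
#' @param prop_genic,prop_ns marginal proportions of genic (including
#'   nonsynonymous) and nonsynonymous SNPs.
#' @param rr_genic,rr_ns relative enrichment of effect SNPs in the genic and
#'   nonsynonymous classes (1 = no planting).
#' @param snps_per_gene consecutive genic SNPs grouped into one gene.
#' @param n_gene_sets,genes_per_set gene-set collection dimensions.
#' @param n_enriched_sets,set_rr number of sets preferentially sampling
#'   genes that contain effect SNPs, and the sampling weight of such genes.
#' @param subset_regions named list mapping population subsets (e.g. AWE,
#'   AEA) to region groups.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_populations = 60L,
    region_names = c("subSaharanAfrica", "Europe", "MiddleEast", "WestAsia",
                     "EastAsia", "Oceania", "Americas"),
    region_sizes = NULL,
    n_chrom_range = c(16L, 160L),
    panels = c(P1 = 0.45, P2 = 0.35, P3 = 0.20),
    n_snps = 20000L,
    fraction_effect = 0.05,
    sigma_beta = 1,
    beta_kind = c("normal", "fixed"),
    rho = 0.5,
    spacing = 150000L,
    n_chromosomes = 22L,
    between_depth = 0.05,
    within_depth = 0.015,
    panel_eps_shapes = list(P1 = c(1.4, 1.4), P2 = c(2, 2), P3 = c(1.2, 2.2)),
    eps_range = c(0.15, 0.85),
    prop_genic = 0.45,
    prop_ns = 0.03,
    rr_genic = 1,
    rr_ns = 1,
    snps_per_gene = 5L,
    n_gene_sets = 14L,
    genes_per_set = 40L,
    n_enriched_sets = 2L,
    set_rr = 3,
    subset_regions = list(
      AWE = c("subSaharanAfrica", "Europe", "MiddleEast", "WestAsia"),
      AEA = c("subSaharanAfrica", "EastAsia", "Oceania"))) {
  beta_kind <- match.arg(beta_kind)
  cfg <- as.list(environment())
  if (cfg$n_populations < 3L) stop_ecoscan("need at least 3 populations")
  if (cfg$n_snps < 1L) stop_ecoscan("n_snps must be >= 1")
  for (f in c("fraction_effect", "rho"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_ecoscan("%s must lie in [0, 1]", f)
  if (cfg$prop_ns > cfg$prop_genic || cfg$prop_genic > 1)
    stop_ecoscan("need prop_ns <= prop_genic <= 1")
  if (abs(sum(cfg$panels) - 1) > 1e-8) stop_ecoscan("panel proportions must sum to 1")
  if (!identical(sort(names(cfg$panel_eps_shapes)), sort(names(cfg$panels))))
    stop_ecoscan("panel_eps_shapes must name the same panels as 'panels'")
  if (is.null(cfg$region_sizes)) {
    nr <- length(cfg$region_names)
    if (cfg$n_populations < nr)
      stop_ecoscan("n_populations (%d) below the %d configured regions",
                   cfg$n_populations, nr)
    cfg$region_sizes <- diff(round(seq(0, cfg$n_populations, length.out = nr + 1)))
  }
  if (sum(cfg$region_sizes) != cfg$n_populations || any(cfg$region_sizes < 1L))
    stop_ecoscan("region_sizes must be positive and sum to n_populations")
  class(cfg) <- "simulation_config"
  cfg
}

#' Shared-branch-length covariance of a phylogeny
#'
#' The drift covariance implied by a population tree: entry (i, j) is the
#' summed length of branches shared by the root-to-tip paths of populations
#' i and j (so a star tree gives a diagonal matrix). Thin wrapper over
#' [ape::vcv.phylo()].
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return Symmetric PSD matrix with tip labels as dimnames.
#' @export
tree_covariance <- function(tree) ape::vcv.phylo(tree)

# random ultrametric (coalescent) tree rescaled to the target root-to-tip
# depth; ultrametry keeps every population at the same total drift, as under
# a molecular clock
scaled_rtree_ <- function(n, mean_depth) {
  tree <- ape::rcoal(n)
  depth <- mean(diag(ape::vcv.phylo(tree)))
  tree$edge.length <- tree$edge.length * mean_depth / depth
  tree
}

#' Sample a tree-structured population covariance
#'
#' Draws a random bifurcating region backbone tree and, within each region, a
#' random subtree with shorter branches; the implied shared-branch covariance
#' (within-region blocks sit on top of the backbone covariance of their
#' region) is strictly positive definite and its clades coincide with the
#' region labels.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return List with `omega` (L x L true covariance), `panel`
#'   ([population_panel()] with worldwide/AWE/AEA subsets), `backbone` and
#'   `subtrees` (the generating `phylo` objects).
#' @export
sample_population_structure <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- config$region_names
  sizes <- config$region_sizes
  nr <- length(regions)
  backbone <- scaled_rtree_(nr, config$between_depth)
  backbone$tip.label <- regions[match(backbone$tip.label,
                                      paste0("t", seq_len(nr)))]
  # vcv in our fixed region order
  B <- tree_covariance(backbone)[regions, regions]

  L <- config$n_populations
  pops <- sprintf("pop%02d", seq_len(L))
  region_of <- rep(regions, sizes)
  omega <- matrix(0, L, L, dimnames = list(pops, pops))
  subtrees <- list()
  for (r in seq_len(nr)) {
    rows <- which(region_of == regions[r])
    m <- length(rows)
    if (m == 1L) {
      S <- matrix(config$within_depth, 1, 1)
    } else {
      sub <- scaled_rtree_(m, config$within_depth)
      subtrees[[regions[r]]] <- sub
      S <- tree_covariance(sub)[paste0("t", seq_len(m)), paste0("t", seq_len(m))]
    }
    omega[rows, rows] <- B[r, r] + S
  }
  for (r in seq_len(nr)) for (s in seq_len(nr)) {
    if (r == s) next
    omega[region_of == regions[r], region_of == regions[s]] <- B[r, s]
  }
  n_chrom <- 2L * sample(seq(config$n_chrom_range[1] %/% 2L,
                             config$n_chrom_range[2] %/% 2L), L, replace = TRUE)
  subsets <- lapply(config$subset_regions, function(rg) pops[region_of %in% rg])
  panel <- population_panel(pops, region_of, n_chrom, subsets)
  list(omega = omega, panel = panel, backbone = backbone, subtrees = subtrees)
}

#' Sample structure-confounded environmental variables
#'
#' Each variable is a convex mix of a spatially structured component (a draw
#' with covariance \eqn{\Omega_{true}}, normalized to unit average marginal
#' variance) and independent population-level noise, then mapped to native
#' units with a fixed per-variable affine transform. At `rho = 0` variables
#' are independent of structure; at `rho = 1` they cluster by clade, the
#' regime in which migration history masquerades as a climate gradient.
#'
#' @param panel a [population_panel()].
#' @param omega true population covariance ([sample_population_structure()]).
#' @param rho confounding weight in [0, 1].
#' @param seed RNG seed; `NULL` continues the current stream.
#' @param variables variable names (default the 9 of [climate_variables()]).
#' @return An `environment_table` data frame.
#' @export
sample_environment <- function(panel, omega, rho = 0.5, seed = NULL,
                               variables = climate_variables()) {
  if (rho < 0 || rho > 1) stop_ecoscan("rho must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(panel)
  R <- chol(omega / mean(diag(omega)))
  units <- variable_units_()
  env <- data.frame(population = panel$population, stringsAsFactors = FALSE)
  for (v in variables) {
    s <- drop(rnorm(L) %*% R)
    x <- rho * s + (1 - rho) * rnorm(L)
    u <- units[match(v, units$variable), ]
    if (is.na(u$offset)) u <- data.frame(offset = 0, scale = 1)
    env[[v]] <- u$offset + u$scale * x
  }
  class(env) <- c("environment_table", "data.frame")
  env
}

#' Simulate allele counts under the scan's own generative model
#'
#' The generative twin of the null/alternative pair the scan tests: for each
#' SNP an ancestral frequency \eqn{\epsilon} is drawn from a panel-specific
#' Beta (ascertainment mimic), latent population frequencies are multivariate
#' normal with mean \eqn{\epsilon + \beta z \sqrt{\epsilon(1-\epsilon)}}
#' (\eqn{\beta = 0} for null SNPs, z the standardized variable) and
#' covariance \eqn{\epsilon(1-\epsilon)\,\Omega_{true}}, clipped to
#' \eqn{[1/(2\bar n), 1 - 1/(2\bar n)]}, and observed counts are binomial
#' draws. Drift is modeled on the untransformed frequency scale with
#' clipping, mirroring the scan's approximation, so parameter recovery is a
#' meaningful end-to-end test; this is deliberately not a Wright-Fisher
#' simulator. Coordinates are laid out at `config$spacing` over
#' `config$n_chromosomes` chromosomes.
#'
#' @param panel,omega from [sample_population_structure()].
#' @param env from [sample_environment()] (standardized internally).
#' @param config a [simulation_config()].
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return List with `counts` ([allele_counts()]) and `truth` (a
#'   `truth_labels` data frame: per SNP the true effect flag, effect size on
#'   the drift-standardized scale, target variable and ancestral frequency).
#' @export
simulate_allele_counts <- function(panel, omega, env, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(panel); M <- config$n_snps
  pops <- panel$population
  z <- standardize_env(env, pops)
  vars <- colnames(z)

  panel_lab <- sample(names(config$panels), M, replace = TRUE,
                      prob = config$panels)
  eps <- numeric(M)
  for (p in names(config$panels)) {
    sel <- panel_lab == p
    sh <- config$panel_eps_shapes[[p]]
    eps[sel] <- stats::rbeta(sum(sel), sh[1], sh[2])
  }
  eps <- pmin(pmax(eps, config$eps_range[1]), config$eps_range[2])

  n_eff <- round(config$fraction_effect * M)
  eff_idx <- if (n_eff > 0) sort(sample.int(M, n_eff)) else integer(0)
  drift_sd <- sqrt(mean(diag(omega)))
  beta_std <- numeric(M)
  eff_var <- rep(NA_character_, M)
  if (n_eff > 0) {
    beta_std[eff_idx] <- switch(config$beta_kind,
      normal = stats::rnorm(n_eff, 0, config$sigma_beta * drift_sd),
      fixed = sample(c(-1, 1), n_eff, replace = TRUE) *
        config$sigma_beta * drift_sd)
    eff_var[eff_idx] <- sample(vars, n_eff, replace = TRUE)
  }

  G <- matrix(stats::rnorm(M * L), M, L) %*% chol(omega)
  if (n_eff > 0)
    G[eff_idx, ] <- G[eff_idx, ] +
      beta_std[eff_idx] * t(z[, eff_var[eff_idx], drop = FALSE])
  sv <- sqrt(eps * (1 - eps))
  x <- eps + sv * G

  nbar <- mean(panel$n_chromosomes)
  lo <- 1 / (2 * nbar)
  clipped <- x < lo | x > 1 - lo
  if (n_eff > 0) {
    # drift alone clips occasionally near the boundaries; flag only the
    # excess clipping attributable to the planted effects
    frac_eff <- mean(clipped[eff_idx, ])
    frac_null <- if (n_eff < M) mean(clipped[-eff_idx, ]) else 0
    if (frac_eff > frac_null + 0.10)
      warning(sprintf(
        "effect sizes so large that %.1f%% of effect-SNP frequencies (%d cells) were clipped (null baseline %.1f%%)",
        100 * frac_eff, sum(clipped[eff_idx, ]), 100 * frac_null))
  }
  theta <- pmin(pmax(x, lo), 1 - lo)
  nmat <- matrix(panel$n_chromosomes, M, L, byrow = TRUE)
  k <- matrix(stats::rbinom(M * L, as.vector(nmat), as.vector(theta)), M, L)
  colnames(k) <- colnames(nmat) <- pops

  sizes <- diff(round(seq(0, M, length.out = config$n_chromosomes + 1)))
  chrom <- rep(sprintf("chr%d", seq_along(sizes)), sizes)
  pos <- unlist(lapply(sizes, function(m) (seq_len(m) - 1) * config$spacing),
                use.names = FALSE)
  snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(M)), chrom = chrom,
                     pos = pos, panel = panel_lab, stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = snps$snp_id, chrom = chrom, pos = pos,
                      panel = panel_lab, eps_true = eps,
                      effect = beta_std != 0, beta_std = beta_std,
                      variable = eff_var, stringsAsFactors = FALSE)
  class(truth) <- c("truth_labels", "data.frame")
  list(counts = allele_counts(snps, k, nmat), truth = truth)
}

#' Assign functional annotations and gene sets with planted enrichment
#'
#' Each SNP gets a functional class (nongenic / genic / nonsynonymous) drawn
#' from the configured marginal proportions; for effect SNPs the genic and
#' nonsynonymous probabilities are multiplied by the configured relative
#' risks, planting the excess of functional effect SNPs that tail-enrichment
#' analyses should recover. Consecutive genic SNPs are grouped into genes
#' (keeping genes local on the genome, as the block bootstrap assumes), and
#' gene sets are sampled from the gene universe, with designated "enriched"
#' sets preferentially sampling genes that contain effect SNPs.
#'
#' @param truth a `truth_labels` table ([simulate_allele_counts()]).
#' @param config a [simulation_config()].
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return List with `annotations` (an `annotation_table`) and `gene_sets`
#'   (a `gene_set_collection`; attribute `"enriched"` names the planted
#'   sets).
#' @export
assign_annotations <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(truth)
  base <- c(nongenic = 1 - config$prop_genic,
            genic = config$prop_genic - config$prop_ns,
            nonsynonymous = config$prop_ns)
  wts <- base * c(1, config$rr_genic, config$rr_ns)
  cls <- character(M)
  null_idx <- which(!truth$effect)
  cls[null_idx] <- sample(names(base), length(null_idx), replace = TRUE,
                          prob = base)
  eff_idx <- which(truth$effect)
  if (length(eff_idx))
    cls[eff_idx] <- sample(names(base), length(eff_idx), replace = TRUE,
                           prob = wts / sum(wts))

  gene <- rep("", M)
  genic_rows <- which(cls != "nongenic")
  if (length(genic_rows)) {
    gene_index <- ceiling(seq_along(genic_rows) / config$snps_per_gene)
    gene[genic_rows] <- sprintf("g%05d", gene_index)
  }
  annotations <- data.frame(snp_id = truth$snp_id, class = cls,
                            gene_id = gene, stringsAsFactors = FALSE)
  class(annotations) <- c("annotation_table", "data.frame")

  all_genes <- unique(gene[gene != ""])
  effect_genes <- unique(gene[truth$effect & gene != ""])
  n_sets <- config$n_gene_sets
  size <- min(config$genes_per_set, max(1L, length(all_genes) - 1L))
  enriched <- character(0)
  if (config$n_enriched_sets > 0 && config$set_rr > 1 &&
      length(effect_genes) == 0L)
    stop_ecoscan("infeasible planting: enriched gene sets requested but no gene contains an effect SNP")
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  for (i in seq_len(n_sets)) {
    if (i <= config$n_enriched_sets) {
      w <- ifelse(all_genes %in% effect_genes, config$set_rr, 1)
      sets[[i]] <- sort(sample(all_genes, size, prob = w))
      enriched <- c(enriched, names(sets)[i])
    } else {
      sets[[i]] <- sort(sample(all_genes, size))
    }
  }
  attr(sets, "description") <- stats::setNames(
    ifelse(names(sets) %in% enriched, "planted_enriched", "background"),
    names(sets))
  attr(sets, "enriched") <- enriched
  class(sets) <- "gene_set_collection"
  list(annotations = annotations, gene_sets = sets)
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs [sample_population_structure()], [sample_environment()],
#' [simulate_allele_counts()] and [assign_annotations()] in sequence from a
#' single seed.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (mandatory; the generator is a pure function of
#'   (config, seed)).
#' @return List with `panel`, `omega`, `env`, `counts`, `truth`,
#'   `annotations`, `gene_sets`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed) {
  if (missing(seed)) stop_ecoscan("seed is mandatory")
  set.seed(seed)
  s <- sample_population_structure(config)
  env <- sample_environment(s$panel, s$omega, rho = config$rho)
  ac <- simulate_allele_counts(s$panel, s$omega, env, config)
  ann <- assign_annotations(ac$truth, config)
  list(panel = s$panel, omega = s$omega, env = env, counts = ac$counts,
       truth = ac$truth, annotations = ann$annotations,
       gene_sets = ann$gene_sets)
}
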