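test_that("tree covariance follows the shared-branch rule", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(unname(tree_covariance(star)), diag(1, 3))
  clade <- ape::read.tree(text = "((a:1,b:1):0.5,c:1.5);")
  V <- tree_covariance(clade)
  expect_equal(V["a", "b"], 0.5)
  expect_equal(V["a", "a"], 1.5)
  expect_equal(V["a", "c"], 0)
})

test_that("sampled population structure is PD, region-claded and seeded", {
  cfg <- small_config()
  s1 <- sample_population_structure(cfg, seed = 42)
  s2 <- sample_population_structure(cfg, seed = 42)
  expect_identical(s1$omega, s2$omega)
  expect_identical(s1$panel, s2$panel)

  expect_equal(s1$omega, t(s1$omega))
  expect_gt(min(eigen(s1$omega, symmetric = TRUE, only.values = TRUE)$values), 0)

  # populations of a region share more drift than populations across regions
  reg <- s1$panel$region
  same <- outer(reg, reg, "==") & !diag(TRUE, nrow(s1$panel))
  expect_gt(mean(s1$omega[same]), mean(s1$omega[!same & !diag(TRUE, nrow(s1$panel))]))

  subs <- attr(s1$panel, "subsets")
  expect_setequal(names(subs), c("worldwide", "AWE", "AEA"))
  expect_true(all(s1$panel$region[s1$panel$population %in% subs$AEA] %in%
                    c("subSaharanAfrica", "EastAsia", "Oceania")))
  expect_true(all(s1$panel$n_chromosomes >= 16 & s1$panel$n_chromosomes <= 160))
})

test_that("environment confounding behaves at its extremes", {
  cfg <- small_config()
  s <- sample_population_structure(cfg, seed = 7)
  L <- nrow(s$panel)
  pc1 <- eigen(s$omega, symmetric = TRUE)$vectors[, 1]

  # rho = 0: |cor| with the leading structure axis matches the independence
  # null band (oracle: independent normal pairs)
  set.seed(99)
  null_abs <- replicate(2000, abs(cor(rnorm(L), rnorm(L))))
  obs <- replicate(300, {
    e <- sample_environment(s$panel, s$omega, rho = 0)
    abs(cor(e$abs_latitude, pc1))
  })
  se <- sd(null_abs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - mean(null_abs)), 4 * se + 0.01)

  # rho = 1: values separate by the two deepest clades
  e1 <- sample_environment(s$panel, s$omega, rho = 1, seed = 5)
  strong <- replicate(50, {
    e <- sample_environment(s$panel, s$omega, rho = 1)
    abs(cor(e$abs_latitude, pc1))
  })
  expect_gt(mean(strong), mean(null_abs) + 4 * sd(null_abs) / sqrt(50))

  expect_identical(sample_environment(s$panel, s$omega, 0.5, seed = 3),
                   sample_environment(s$panel, s$omega, 0.5, seed = 3))
})

test_that("null allele counts reproduce the drift-plus-sampling variance", {
  L <- 40; cI <- 0.05; n <- 1000
  sim <- flat_sim(L, n_chrom = n, omega = diag(cI, L), M = 4000, seed = 21)
  eps <- pooled_frequency(sim$counts$k, sim$counts$n)
  keep <- !monomorphic_flags(eps)
  y <- standardize_frequencies(sim$counts$k[keep, ], sim$counts$n[keep, ],
                               eps[keep])
  v <- mean(apply(y, 1, var))
  expect_lt(abs(v - (cI + 1 / n)) / (cI + 1 / n), 0.05)
})

test_that("a strongly planted SNP correlates with its variable", {
  cfg <- simulation_config(n_populations = 30, n_snps = 400,
                           fraction_effect = 1 / 400, sigma_beta = 5,
                           beta_kind = "fixed", rho = 0.2,
                           n_enriched_sets = 0L)
  set.seed(12)
  s <- sample_population_structure(cfg)
  env <- sample_environment(s$panel, s$omega, rho = cfg$rho)
  sim <- suppressWarnings(simulate_allele_counts(s$panel, s$omega, env, cfg))
  i <- which(sim$truth$effect)
  expect_length(i, 1L)
  z <- standardize_env(env, s$panel$population)[, sim$truth$variable[i]]
  p_hat <- sim$counts$k[i, ] / sim$counts$n[i, ]
  expect_gt(abs(cor(p_hat, z, method = "spearman")), 0.8)
})

test_that("oversized effects trigger the clipping warning", {
  cfg <- simulation_config(n_populations = 20, n_snps = 200,
                           fraction_effect = 0.5, sigma_beta = 60,
                           beta_kind = "fixed", n_enriched_sets = 0L)
  set.seed(2)
  s <- sample_population_structure(cfg)
  env <- sample_environment(s$panel, s$omega, rho = cfg$rho)
  expect_warning(simulate_allele_counts(s$panel, s$omega, env, cfg),
                 "clipped")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config(n_snps = 500)
  a <- simulate_dataset(cfg, seed = 17)
  b <- simulate_dataset(cfg, seed = 17)
  expect_identical(a$counts$k, b$counts$k)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotations, b$annotations)
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
})

test_that("annotation planting respects class proportions and feasibility", {
  cfg <- small_config(n_snps = 6000, fraction_effect = 0.2)
  sim <- simulate_dataset(cfg, seed = 31)
  ann <- sim$annotations
  # relative risk 1: effect SNPs spread over classes like null SNPs
  tab <- table(ann$class, sim$truth$effect)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
  # marginal proportions near config within binomial noise
  p_genic <- mean(ann$class != "nongenic")
  expect_lt(abs(p_genic - cfg$prop_genic), 3 * sqrt(0.25 / cfg$n_snps) + 0.01)

  # NS proportion 0 removes the class entirely
  cfg0 <- small_config(n_snps = 500, prop_ns = 0)
  sim0 <- simulate_dataset(cfg0, seed = 4)
  expect_false(any(sim0$annotations$class == "nonsynonymous"))

  # planting an enriched set without effect SNPs is infeasible
  cfg_bad <- simulation_config(n_populations = 24, n_snps = 300,
                               fraction_effect = 0, n_enriched_sets = 1L)
  expect_error(simulate_dataset(cfg_bad, seed = 1), "infeasible planting")
})

test_that("enriched gene sets receive an excess of effect genes", {
  cfg <- simulation_config(n_populations = 24, n_snps = 6000,
                           fraction_effect = 0.1, set_rr = 8)
  sim <- simulate_dataset(cfg, seed = 8)
  effect_genes <- unique(sim$annotations$gene_id[
    sim$truth$effect & sim$annotations$gene_id != ""])
  enriched <- attr(sim$gene_sets, "enriched")
  frac_in <- function(nm) mean(sim$gene_sets[[nm]] %in% effect_genes)
  mean_enr <- mean(vapply(enriched, frac_in, 0))
  mean_bg <- mean(vapply(setdiff(names(sim$gene_sets), enriched), frac_in, 0))
  expect_gt(mean_enr, mean_bg)
})
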