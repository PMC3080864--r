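test_that("the worldwide subset scan is identical to the worldwide scan", {
  cfg <- small_config(n_snps = 2000)
  sim <- simulate_dataset(cfg, seed = 27)
  res <- quiet_subset_scan(sim$counts, sim$env, sim$panel, "worldwide",
                           seed = 27, n_controls = 2000)
  direct <- climate_scan(sim$counts, sim$env, tau = 1, n_controls = 2000, min_controls = 100,
                         seed = 27)
  expect_identical(res$scan$bf, direct$bf)
  expect_identical(res$ranks$q, quiet_rank_table(direct)$q)
})

test_that("subset scans re-estimate the covariance at subset size", {
  cfg <- small_config(n_snps = 2500)
  sim <- simulate_dataset(cfg, seed = 35)
  awe <- panel_subset(sim$panel, "AWE")
  res <- quiet_subset_scan(sim$counts, sim$env, sim$panel, "AWE",
                           seed = 35, n_controls = 2500)
  for (m in res$scan$models)
    expect_identical(dim(m$omega), c(length(awe), length(awe)))
  expect_error(
    subset_scan(sim$counts, sim$env, sim$panel, "nowhere"), "unknown")

  tiny <- population_panel(c("a", "b", "c", "d"), rep("r", 4), rep(10, 4),
                           subsets = list(pair = c("a", "b")))
  expect_error(subset_scan(sim$counts, sim$env, tiny, "pair"),
               "fewer than 3")
})

test_that("a region-restricted signal ranks higher in its own subset", {
  cfg <- small_config(n_snps = 2500, rho = 0.3)
  sim <- simulate_dataset(cfg, seed = 91)
  awe <- panel_subset(sim$panel, "AWE")
  aea <- panel_subset(sim$panel, "AEA")
  # plant a strong cline on winter_min_temp across AWE populations only
  z <- standardize_env(sim$env, awe)[, "winter_min_temp"]
  target <- sim$counts$snps$snp_id[100]
  n100 <- sim$counts$n[100, ]
  p <- rep(0.5, length(n100))
  names(p) <- sim$counts$populations
  p[awe] <- pmin(pmax(0.5 + 0.45 * z / max(abs(z)), 0.02), 0.98)
  set.seed(1)
  sim$counts$k[100, ] <- rbinom(length(p), n100, p)

  res_awe <- quiet_subset_scan(sim$counts, sim$env, sim$panel, "AWE",
                               seed = 91, n_controls = 2500)
  res_aea <- quiet_subset_scan(sim$counts, sim$env, sim$panel, "AEA",
                               seed = 91, n_controls = 2500)
  q_awe <- res_awe$ranks$q[target, "winter_min_temp"]
  q_aea <- res_aea$ranks$q[target, "winter_min_temp"]
  expect_lt(q_awe, 0.02)
  expect_lt(q_awe, q_aea)
  expect_gt(res_awe$scan$bf[target, "winter_min_temp"],
            res_aea$scan$bf[target, "winter_min_temp"] + 2)
})

test_that("tail overlap reports observed, expected and Venn counts", {
  q <- setNames(seq_len(10000) / 10000, paste0("s", 1:10000))
  # identical vectors: observed = tail size, fold = N / tail
  ov <- tail_overlap(q, q, cutoff = 0.01)
  expect_identical(ov$observed, 100L)
  expect_equal(ov$fold, 10000 / 100)
  expect_equal(ov$spearman, 1.0)
  expect_identical(unname(ov$venn["neither"]), 9900L)

  # independent tails of 100 in 10000: expected = 1
  set.seed(3)
  qb <- setNames(sample(q), names(q))
  ov2 <- tail_overlap(q, qb, cutoff = 0.01)
  expect_equal(ov2$expected, 1.0)

  # independent null ranks: observed stays within a Poisson band
  set.seed(8)
  obs <- replicate(100, {
    qa <- setNames(sample(2000) / 2000, paste0("s", 1:2000))
    qb <- setNames(sample(2000) / 2000, paste0("s", 1:2000))
    tail_overlap(qa, qb, cutoff = 0.05)$observed
  })
  lim <- qpois(c(0.005, 0.995), lambda = 2000 * 0.05 * 0.05)
  expect_lt(mean(obs < lim[1] | obs > lim[2]), 0.08)
  expect_equal(mean(obs), 5, tolerance = 0.25)
})

test_that("Spearman correlation matches hand computations", {
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1.0)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1.0)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  a <- setNames(c(0.1, 0.2, 0.9), c("x", "y", "z"))
  b <- setNames(c(0.9, 0.1, 0.3), c("z", "w", "x"))
  expect_equal(rank_correlation(a, b), rank_correlation(c(0.1, 0.9), c(0.3, 0.9)))
})

test_that("GWAS overlap applies both filters and ignores row order", {
  cfg <- small_config(n_snps = 2500, fraction_effect = 0.02,
                      sigma_beta = 5, beta_kind = "fixed")
  sim <- simulate_quiet(cfg, seed = 87)
  eu_freq <- region_frequencies(sim$counts, sim$panel, "Europe")
  scan <- climate_scan(sim$counts, sim$env, n_controls = 2500, min_controls = 100, seed = 87)
  ranks <- quiet_rank_table(scan, binning_freqs = eu_freq, binning = "european")
  res <- list(scan = scan, ranks = ranks)

  strong <- names(sort(min_rank(ranks)))[1:5]
  catalog <- data.frame(
    snp_id = c(strong, sim$counts$snps$snp_id[2001:2045]),
    trait = "trait_a",
    p_value = rep(c(1e-6, 1e-8, 2e-3), length.out = 50),
    stringsAsFactors = FALSE)
  class(catalog) <- c("gwas_catalog", "data.frame")

  got <- gwas_overlap(res, catalog, annotations = sim$annotations,
                      rank_cutoff = 5e-4, p_cutoff = 1e-5)
  # independent double-filter oracle
  expected <- character(0)
  for (i in seq_len(nrow(catalog))) {
    snp <- catalog$snp_id[i]
    if (catalog$p_value[i] >= 1e-5) next
    qs <- ranks$q[snp, ]
    if (any(is.finite(qs) & qs < 5e-4)) expected <- c(expected, snp)
  }
  expect_setequal(got$snp_id, expected)
  expect_true(all(got$rank < 5e-4) && all(got$p_value < 1e-5))

  shuffled <- catalog[sample(nrow(catalog)), ]
  expect_equal(gwas_overlap(res, shuffled, annotations = sim$annotations),
               got)
})

test_that("explicit rank/p boundaries behave per the filter definitions", {
  ranks <- structure(list(
    snps = data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                      pos = c(0, 100), panel = "P1", eps = 0.5,
                      excluded = FALSE, bin = "P1:f5",
                      min_rank = c(4e-4, 6e-4)),
    q = matrix(c(4e-4, 6e-4), 2, 1,
               dimnames = list(c("rs1", "rs2"), "temp")),
    variables = "temp", population_set = "worldwide", binning = "european"),
    class = "rank_table")
  scan <- structure(list(
    snps = ranks$snps,
    bf = matrix(c(9.1, 5.2), 2, 1, dimnames = list(c("rs1", "rs2"), "temp")),
    variables = "temp", population_set = "worldwide", tau = 1),
    class = "scan_result")
  catalog <- data.frame(snp_id = c("rs1", "rs2"), trait = "t",
                        p_value = c(1e-6, 1e-8))
  got <- gwas_overlap(list(scan = scan, ranks = ranks), catalog)
  expect_identical(got$snp_id, "rs1")   # rs2 fails the rank filter
  expect_equal(got$log10_bf, 9.1)
})
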