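test_that("tail ratios match hand counts and handle degenerate classes", {
  # |A| = 200 with 20 in tail, |B| = 400 with 20 in tail -> 0.10/0.05 = 2
  q <- c(runif(20, 0, 0.04), runif(180, 0.2, 1),
         runif(20, 0, 0.04), runif(380, 0.2, 1))
  a <- rep(c(TRUE, FALSE), c(200, 400))
  r <- tail_ratio(q, a, !a, cutoff = 0.05)
  expect_equal(as.numeric(r), 2.0)
  expect_identical(attr(r, "tail_a"), 20L)

  # duplicated SNPs in both classes: exact ratio 1 at any cutoff
  qq <- runif(100)
  r1 <- tail_ratio(c(qq, qq), rep(c(TRUE, FALSE), each = 100),
                   rep(c(FALSE, TRUE), each = 100), 0.2)
  expect_equal(as.numeric(r1), 1.0)

  # empty numerator tail -> 0; empty denominator tail -> undefined
  q2 <- c(0.5, 0.6, 0.01, 0.7)
  expect_equal(as.numeric(tail_ratio(q2, c(TRUE, TRUE, FALSE, FALSE),
                                     c(FALSE, FALSE, TRUE, TRUE), 0.05)), 0)
  r3 <- tail_ratio(q2, c(FALSE, FALSE, TRUE, TRUE),
                   c(TRUE, TRUE, FALSE, FALSE), 0.05)
  expect_true(is.na(r3) && attr(r3, "undefined"))
  expect_error(tail_ratio(q2, rep(FALSE, 4), rep(TRUE, 4), 0.05), "empty")
  expect_error(tail_ratio(q2, c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, FALSE, TRUE, TRUE), 0.05), "disjoint")
})

test_that("class-rate and tail-composition formulations coincide", {
  set.seed(14)
  for (i in 1:20) {
    q <- runif(500)
    a <- sample(c(TRUE, FALSE), 500, replace = TRUE)
    b <- !a
    r <- tail_ratio(q, a, b, 0.1)
    tail <- q <= 0.1
    composition <- (sum(a & tail) / sum(b & tail)) / (sum(a) / sum(b))
    expect_equal(as.numeric(r), composition)
  }
})

test_that("a single occupied block degenerates the bootstrap", {
  n <- 200
  # both classes represented at every cutoff so no replicate is undefined
  q <- c(0.001, 0.002, 0.004, 0.0045, 0.008, 0.009,
         seq(0.02, 1, length.out = n - 6))
  a <- rep(c(TRUE, FALSE), n / 2)
  rep1 <- block_bootstrap_enrichment(q, a, !a, chrom = rep("chr1", n),
                                     pos = seq(0, by = 100, length.out = n),
                                     replicates = 50, seed = 1)
  reps <- attr(rep1, "replicates")
  for (j in seq_along(rep1$cutoff))
    expect_true(all(reps[, j] == rep1$ratio[j]))
  expect_error(block_bootstrap_enrichment(
    q[1], a[1], !a[1], chrom = "chr1", pos = 0, seed = 1), "empty SNP class")
})

test_that("the bootstrap report is reproducible and internally consistent", {
  cfg <- small_config(n_snps = 3000, fraction_effect = 0.1,
                      rr_genic = 3, rr_ns = 3)
  sim <- simulate_dataset(cfg, seed = 52)
  res <- quiet_subset_scan(sim$counts, sim$env, sim$panel, seed = 52,
                           n_controls = 3000)
  er1 <- class_enrichment(res$ranks, sim$annotations, replicates = 300, seed = 9)
  er2 <- class_enrichment(res$ranks, sim$annotations, replicates = 300, seed = 9)
  expect_equal(as.data.frame(er1), as.data.frame(er2))
  expect_true(all(er1$boot_frac_gt1 >= 0 & er1$boot_frac_gt1 <= 1))
  expect_true(all(er1$tier[er1$boot_frac_gt1 >= 0.99] == "***"))
  # observed ratio recomputable from the backing counts
  expect_equal(er1$ratio,
               (er1$tail_a / er1$n_a) / (er1$tail_b / er1$n_b))
})

test_that("planted gene sets are enriched; degenerate sets error or skip", {
  cfg <- simulation_config(n_populations = 24, n_snps = 6000,
                           fraction_effect = 0.1, sigma_beta = 4,
                           beta_kind = "fixed", set_rr = 10,
                           rr_genic = 2, rr_ns = 2)
  sim <- simulate_quiet(cfg, seed = 71)
  res <- quiet_subset_scan(sim$counts, sim$env, sim$panel, seed = 71,
                           n_controls = 6000)
  planted <- attr(sim$gene_sets, "enriched")[1]
  gse <- gene_set_enrichment(res$ranks, sim$gene_sets[planted],
                             sim$annotations, replicates = 100, seed = 2)
  expect_true(all(gse$ratio > 1))

  # a set covering every genic SNP leaves no background
  all_genes <- unique(sim$annotations$gene_id[sim$annotations$gene_id != ""])
  expect_error(
    gene_set_enrichment(res$ranks, list(everything = all_genes),
                        sim$annotations, replicates = 10, seed = 1),
    "no background")

  # a set mapping to no SNPs is skipped (and alone, errors)
  expect_warning(
    expect_error(
      gene_set_enrichment(res$ranks, list(ghost = c("not_a_gene")),
                          sim$annotations, replicates = 10, seed = 1),
      "no gene set"),
    "skipped")

  # a set absent from the tail has ratio 0 at that cutoff
  qv <- res$ranks$snps$min_rank
  gene <- sim$annotations$gene_id[match(res$ranks$snps$snp_id,
                                        sim$annotations$snp_id)]
  outside <- unique(gene[gene != "" & qv > 0.2])
  outside <- setdiff(outside, gene[gene != "" & qv <= 0.05])
  gse0 <- gene_set_enrichment(res$ranks, list(coldset = outside[1:20]),
                              sim$annotations, cutoffs = 0.05,
                              replicates = 10, seed = 3)
  expect_equal(gse0$ratio, 0)
})

test_that("subsampled labels stay near ratio 1 (label-permutation null)", {
  set.seed(31)
  n <- 4000
  q <- runif(n)
  a <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
  rep1 <- block_bootstrap_enrichment(
    q, a, !a, chrom = rep(paste0("chr", 1:4), each = n / 4),
    pos = rep(seq(0, by = 150000, length.out = n / 4), 4),
    replicates = 400, seed = 8)
  expect_true(all(abs(rep1$ratio - 1) < 0.5))
  expect_true(all(rep1$tier %in% c("", "*", "**", "***")))
})
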