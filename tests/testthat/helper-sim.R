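# desk-scale config variants used across test files
small_config <- function(...) {
  args <- list(n_populations = 24L, n_snps = 3000L, n_enriched_sets = 0L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

# one-panel config with a handcrafted covariance, for estimator tests
flat_sim <- function(L, n_chrom, omega, M, seed, ...) {
  cfg <- simulation_config(n_populations = L, n_snps = M,
                           region_names = "r1", region_sizes = L,
                           panels = c(P1 = 1),
                           panel_eps_shapes = list(P1 = c(2, 2)),
                           fraction_effect = 0, n_enriched_sets = 0L, ...)
  panel <- population_panel(sprintf("pop%02d", seq_len(L)),
                            rep("r1", L), rep(n_chrom, L))
  set.seed(seed)
  env <- sample_environment(panel, omega, rho = 0)
  sim <- simulate_allele_counts(panel, omega, env, cfg)
  list(panel = panel, env = env, counts = sim$counts, truth = sim$truth,
       cfg = cfg)
}

# planted configs with effects well above the drift scale clip against the
# frequency boundaries by design; the generator's warning is expected there
simulate_quiet <- function(cfg, seed) suppressWarnings(simulate_dataset(cfg, seed))

quiet_rank_table <- function(...) suppressMessages(rank_table(...))
quiet_subset_scan <- function(..., min_controls = 100L)
  suppressMessages(subset_scan(..., min_controls = min_controls))
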