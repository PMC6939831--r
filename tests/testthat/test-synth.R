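test_that("the genotype generator is deterministic for a fixed seed", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 50000L), seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$dosages, b$dataset$dosages)
  expect_identical(a$dataset$sites, b$dataset$sites)
  expect_identical(a$truth$p_fw, b$truth$p_fw)
})

test_that("config validation rejects out-of-range rates and bad sweeps", {
  expect_error(sim_config(missing_rate = 1.5),
               class = "sweepscan_validation_error")
  expect_error(sim_config(n_freshwater = 1),
               class = "sweepscan_validation_error")
  expect_error(
    sim_config(chrom_lengths = c(chr1 = 1000L),
               sweeps = tibble::tibble(chrom = "chr1", start = 500L,
                                       end = 2000L)),
    class = "sweepscan_validation_error"
  )
})

test_that("realized missingness and drift match the configured model", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2200000L),
                    sweeps = tibble::tibble(chrom = character(),
                                            start = integer(),
                                            end = integer()),
                    missing_rate = 0.03, seed = 5)
  sim <- simulate_dataset(cfg)
  n_geno <- length(sim$dataset$dosages)
  p_hat <- mean(is.na(sim$dataset$dosages))
  se <- sqrt(0.03 * 0.97 / n_geno)
  expect_lt(abs(p_hat - 0.03), 3 * se)

  # per-site differentiation of the population frequencies themselves:
  # E[(p1-p2)^2] = 2 F p(1-p) under two independent Balding-Nichols draws
  expect_gt(nrow(sim$dataset$sites), 1e4)
  tr <- sim$truth
  realized <- mean((tr$p_mig - tr$p_fw)^2)
  expected <- mean(2 * cfg$background_fst * tr$p_anc * (1 - tr$p_anc))
  expect_lt(abs(realized / expected - 1), 0.3)
})

test_that("null configuration leaves sweep windows indistinguishable", {
  diffs <- sapply(1:10, function(seed) {
    cfg <- sim_config(
      chrom_lengths = c(chr1 = 200000L), n_migratory = 20,
      n_freshwater = 10, sweep_fst = 0.02, sweep_diversity_scale = 1,
      seed = seed)
    sim <- simulate_dataset(cfg)
    w <- scan_windows(filter_variants(sim$dataset), sim$grouping,
                      chrom_lengths = cfg$chrom_lengths)
    w <- w[w$eligible & !is.na(w$fst), ]
    in_sweep <- w$start >= cfg$sweeps$start[1] & w$end <= cfg$sweeps$end[1]
    mean(w$fst[in_sweep]) - mean(w$fst[!in_sweep])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 1e-3)
})

test_that("planted sweeps halve freshwater diversity inside the interval", {
  ratios <- sapply(1:10, function(seed) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 500000L), seed = seed)
    sim <- simulate_dataset(cfg)
    w <- scan_windows(filter_variants(sim$dataset), sim$grouping,
                      chrom_lengths = cfg$chrom_lengths)
    w <- w[w$eligible, ]
    in_sweep <- w$start >= cfg$sweeps$start[1] & w$end <= cfg$sweeps$end[1]
    mean(w$pi_fw[in_sweep]) / mean(w$pi_fw[!in_sweep])
  })
  expect_lt(mean(ratios), 0.5)
})

test_that("gene placement follows the block-tiling arithmetic", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 100000L), seed = 2)
  ann <- simulate_annotation(cfg, gene_length = 300, spacing = 5000)
  expect_equal(nrow(ann), floor(100000 / 5300))
  expect_true(all(ann$end - ann$start + 1 == 300))
  expect_true(all(vapply(ann$cds, function(cd) {
    sum(cd$end - cd$start + 1) %% 3 == 0
  }, logical(1))))
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))

  # a 25-kb sweep always contains at least one gene at 5-kb spacing
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 500000L), seed = 2)
  ann2 <- simulate_annotation(cfg2)
  hits <- genes_in_regions(cfg2$sweeps, ann2)
  expect_gte(nrow(hits), 1L)
})

test_that("noise-free otolith transects hit their pattern means exactly", {
  res <- simulate_otolith("resident", n_points = 40, noise_sd = 0, seed = 1)
  expect_true(all(res$sr_ca_ratio == 1.5))
  mig <- simulate_otolith("migratory", n_points = 40, noise_sd = 0, seed = 1)
  expect_true(all(mig$sr_ca_ratio %in% c(1.5, 5.0, 8.0)))
  expect_true(any(mig$sr_ca_ratio > 3))
  expect_identical(simulate_otolith("migratory", seed = 7),
                   simulate_otolith("migratory", seed = 7))
  expect_error(simulate_otolith("resident", n_points = 5),
               class = "sweepscan_validation_error")
})

test_that("qPCR generator encodes the effect as an RQ ratio", {
  ratio_for <- function(effect, seed) {
    q <- simulate_qpcr(n_per_group = 5, effect_log2 = effect, seed = seed)
    dd <- ddct_relative_expression(q)
    g <- dd$groups
    g$geo_mean_rq[g$group == "migratory"] /
      g$geo_mean_rq[g$group == "freshwater"]
  }
  null_ratios <- sapply(1:20, function(s) ratio_for(0, s))
  expect_true(all(null_ratios >= 0.5 & null_ratios <= 2))
  sig_ratios <- sapply(1:20, function(s) ratio_for(2, s))
  expect_true(all(sig_ratios >= 2 & sig_ratios <= 8))
  expect_identical(simulate_qpcr(seed = 3), simulate_qpcr(seed = 3))
})
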