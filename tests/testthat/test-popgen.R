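test_that("variant filter applies the missingness and MAF rules", {
  # 10 samples; site 1: 2 missing (20% > 10%); site 2: MAF 1/20 = 0.05;
  # site 3: MAF 4/20 = 0.2 -> only site 3 survives
  d <- cbind(
    c(NA, NA, rep(0L, 8)),
    c(1L, rep(0L, 9)),
    c(2L, 1L, 1L, rep(0L, 7))
  )
  fl <- filter_variants(make_ds(d))
  expect_equal(nrow(fl$sites), 1L)
  expect_equal(fl$sites$pos, 3L)
  cts <- attr(fl, "counts")
  expect_equal(cts$n_removed_missing, 1L)
  expect_equal(cts$n_removed_maf, 1L)

  # boundary: exactly 10% missing is kept, MAF exactly 0.10 is kept
  d2 <- cbind(c(NA, 1L, 1L, rep(0L, 7)))
  expect_equal(nrow(filter_variants(make_ds(d2))$sites), 1L)
  expect_warning(filter_variants(make_ds(cbind(rep(0L, 10)))),
                 "all sites removed")
})

test_that("site_pi matches allele-pair enumeration for all counts <= 60", {
  expect_equal(site_pi(2, 2), 2 * 2 * 2 / (4 * 3))
  expect_equal(site_pi(4, 0), 0)
  expect_equal(site_pi(1, 1), 1)
  expect_true(is.na(site_pi(1, 0)))
  for (n in 2:60) {
    for (alt in c(0L, 1L, n %/% 2, n - 1L, n)) {
      expect_equal(site_pi(n - alt, alt), oracle_site_pi(n - alt, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("window_pi is per-bp, linear in window length, label-symmetric", {
  d <- cbind(c(1L, 1L, 0L, 0L), c(2L, 2L, 0L, 0L))
  ds <- make_ds(d, pos = c(100L, 200L))
  win <- list(chrom = "chr1", start = 1L, end = 5000L)
  # site 1: (6,2) alleles -> pi = 2*6*2/(8*7); site 2: (4,4) -> 2*4*4/(8*7)
  expected <- (2 * 6 * 2 / 56 + 2 * 4 * 4 / 56) / 5000
  expect_equal(window_pi(ds, ds$sample_ids, win), expected)
  win2 <- list(chrom = "chr1", start = 1L, end = 10000L)
  expect_equal(window_pi(ds, ds$sample_ids, win2), expected / 2)
  expect_equal(window_pi(ds, ds$sample_ids,
                         list(chrom = "chr1", start = 1000L, end = 5000L)),
               0)
  # swapping ref/alt dosages leaves pi unchanged
  ds_swap <- make_ds(2L - d, pos = c(100L, 200L))
  expect_equal(window_pi(ds_swap, ds_swap$sample_ids, win), expected)
  # sample order irrelevant
  ds_perm <- make_ds(d[c(3, 1, 4, 2), ], pos = c(100L, 200L))
  expect_equal(window_pi(ds_perm, ds_perm$sample_ids, win), expected)
})

test_that("window_pi equals the enumeration oracle on random datasets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    m <- sample(5:50, 1)
    ds <- random_ds(n, m)
    grp_ids <- ds$sample_ids[seq_len(max(2, n %/% 2))]
    got <- window_pi(ds, grp_ids, list(chrom = "chr1", start = 1, end = m))
    want <- oracle_window_pi(ds, grp_ids, "chr1", 1, m)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Fst is 1 on fixed differences and 0-centered under panmixia", {
  d <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  ds <- make_ds(d)
  grp <- two_group_grouping(ds, 4)
  expect_equal(window_fst(ds, grp, list(chrom = "chr1", start = 1, end = 6)),
               1)
  expect_equal(window_fst(ds, grp, list(chrom = "chr1", start = 1, end = 6),
                          estimator = "hudson"), 1)

  # panmictic null: window values centered on zero
  set.seed(5)
  vals <- replicate(200, {
    p <- runif(8, 0.2, 0.8)
    d <- matrix(rbinom(20 * 8, 2, rep(p, each = 20)), nrow = 20)
    ds <- make_ds(d)
    window_fst(ds, two_group_grouping(ds, 10),
               list(chrom = "chr1", start = 1, end = 8))
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("Fst equals the scalar textbook oracle and is group-symmetric", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    m <- sample(3:20, 1)
    ds <- random_ds(n, m)
    grp <- two_group_grouping(ds, sample(2:(n - 2), 1))
    win <- list(chrom = "chr1", start = 1, end = m)
    got <- window_fst(ds, grp, win)
    want <- oracle_wc_fst(ds, grp, "chr1", 1, m)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
      # swapping group labels leaves theta unchanged
      grp_swapped <- grp
      grp_swapped$group <- ifelse(grp$group == "migratory",
                                  "freshwater", "migratory")
      expect_equal(window_fst(ds, grp_swapped, win), got,
                   tolerance = 1e-12)
    }
  }
})

test_that("ROD follows its defining identities and monotonicity", {
  expect_equal(rod(0.002, 0.002), 0)
  expect_equal(rod(0, 0.004), 1)
  expect_equal(rod(0.004, 0.002), -1)
  expect_true(is.na(rod(0.001, 0)))
  expect_error(rod(-0.1, 0.2), class = "sweepscan_validation_error")
  # antitone in pi_fw, isotone in pi_mig
  fw <- seq(0, 0.01, length.out = 20)
  expect_true(all(diff(rod(fw, 0.005)) < 0))
  mig <- seq(0.001, 0.01, length.out = 20)
  expect_true(all(diff(rod(0.004, mig)) > 0))
})

test_that("window tiling, partial flags and eligibility follow the rules", {
  d <- matrix(sample(0:2, 4 * 6, replace = TRUE), nrow = 4)
  ds <- make_ds(d, pos = c(10L, 20L, 30L, 5002L, 5003L, 11999L))
  grp <- two_group_grouping(ds, 2)
  w <- scan_windows(ds, grp, window_size = 5000, step = 5000,
                    chrom_lengths = c(chr1 = 12000))
  expect_equal(w$start, c(1L, 5001L, 10001L))
  expect_equal(w$end, c(5000L, 10000L, 12000L))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(w$n_sites, c(3L, 2L, 1L))
  expect_equal(w$eligible, c(TRUE, FALSE, FALSE))

  w2 <- scan_windows(ds, grp, window_size = 5000, step = 2500,
                     chrom_lengths = c(chr1 = 12000))
  expect_equal(nrow(w2), 5L)

  expect_error(scan_windows(ds, grp, window_size = 0),
               class = "sweepscan_validation_error")
})

test_that("scan_windows agrees with the single-window operations", {
  set.seed(31)
  ds <- random_ds(10, 40)
  ds$sites$pos <- sort(sample.int(2000, 40))
  ds <- genotype_dataset(ds$sample_ids, ds$sites, ds$dosages)
  grp <- two_group_grouping(ds, 6)
  w <- scan_windows(ds, grp, window_size = 500, step = 500,
                    chrom_lengths = c(chr1 = 2000))
  mig_ids <- grp$sample_id[grp$group == "migratory"]
  fw_ids <- grp$sample_id[grp$group == "freshwater"]
  for (k in seq_len(nrow(w))) {
    win <- list(chrom = w$chrom[k], start = w$start[k], end = w$end[k])
    expect_equal(w$pi_mig[k], window_pi(ds, mig_ids, win))
    expect_equal(w$pi_fw[k], window_pi(ds, fw_ids, win))
    expect_equal(w$fst[k], window_fst(ds, grp, win))
  }
})
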