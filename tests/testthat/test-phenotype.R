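test_that("water-type thresholds partition the ratio axis", {
  expect_equal(classify_water(2.5), "freshwater")
  expect_equal(classify_water(5.0), "brackish")
  expect_equal(classify_water(7.5), "seawater")
  # boundary values fall to the lower class per the <= rules
  expect_equal(classify_water(c(0, 3.0, 7.0)),
               c("freshwater", "freshwater", "brackish"))
  expect_error(classify_water(-1), class = "sweepscan_validation_error")
  ratios <- seq(0, 12, by = 0.1)
  expect_true(all(classify_water(ratios) %in%
                    c("freshwater", "brackish", "seawater")))
})

test_that("life-history calls need a sustained non-freshwater run", {
  constant <- tibble::tibble(distance_um = 1:20 * 10,
                             sr_ca_ratio = rep(1.5, 20))
  expect_equal(classify_life_history(constant), "resident")

  shift <- tibble::tibble(distance_um = 1:20 * 10,
                          sr_ca_ratio = rep(c(1.5, 5.0), each = 10))
  expect_equal(classify_life_history(shift), "migratory")

  spike <- constant
  spike$sr_ca_ratio[10] <- 5.0   # one isolated point: rejected as noise
  expect_equal(classify_life_history(spike), "resident")

  expect_error(classify_life_history(constant[1:5, ]),
               class = "sweepscan_validation_error")
})

test_that("synthetic transects are called perfectly at moderate noise", {
  for (pattern in c("resident", "migratory")) {
    calls <- sapply(1:25, function(seed) {
      classify_life_history(
        simulate_otolith(pattern, n_points = 60, noise_sd = 0.3,
                         seed = seed))
    })
    expect_true(all(calls == pattern))
  }
})

test_that("ddCt identities hold: worked example and calibrator centering", {
  q <- tibble::tibble(
    sample_id = c("m1", "m2", "f1", "f2"),
    group = c("migratory", "migratory", "freshwater", "freshwater"),
    gene = "g",
    ct_target = c(25, 25, 27.2, 26.8),
    ct_ref = c(15, 15, 15.1, 14.9)
  )
  # freshwater dCt = (12.1, 11.9), mean 12; migratory dCt = 10
  # ddCt = -2 -> RQ = 4
  dd <- ddct_relative_expression(q, calibrator_group = "freshwater")
  expect_equal(dd$samples$rq[dd$samples$group == "migratory"], c(4, 4))
  g <- dd$groups
  expect_equal(g$geo_mean_rq[g$group == "freshwater"], 1)

  # adding a constant to every target Ct preserves RQ ratios
  q2 <- q
  q2$ct_target <- q2$ct_target + 3
  dd2 <- ddct_relative_expression(q2, calibrator_group = "freshwater")
  r1 <- dd$groups$geo_mean_rq[dd$groups$group == "migratory"]
  r2 <- dd2$groups$geo_mean_rq[dd2$groups$group == "migratory"]
  expect_equal(r1, r2)

  q3 <- q
  q3$ct_target[1] <- NA
  expect_warning(ddct_relative_expression(q3, calibrator_group = "freshwater"),
                 "missing Ct")
})

test_that("the pooled t test matches stats::t.test and its conventions", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  res <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(res$p, 0.01)

  dg <- two_sample_t(c(2, 2), c(2, 2))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  dg2 <- two_sample_t(c(2, 2), c(5, 5))
  expect_true(dg2$degenerate)
  expect_equal(dg2$p, 0)

  set.seed(61)
  for (rep in 1:100) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    ours <- two_sample_t(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    ours_w <- two_sample_t(x, y, variant = "welch")
    ref_w <- stats::t.test(x, y)
    expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-10)
  }
})

test_that("DEG flags require both fold and significance", {
  expr <- tibble::tibble(
    gene_id = c("flat", "strong", "fold_only", "sig_only"),
    m1 = c(10, 100, 30, 10.2), m2 = c(11, 104, 10, 10.1),
    m3 = c(10, 98, 50, 10.15),
    f1 = c(10, 10, 20, 10.0), f2 = c(11, 10.5, 41, 9.9),
    f3 = c(10, 9.8, 29, 9.95)
  )
  grp <- tibble::tibble(
    sample_id = c("m1", "m2", "m3", "f1", "f2", "f3"),
    group = rep(c("migratory", "freshwater"), each = 3)
  )
  res <- call_deg(expr, grp)
  expect_false(res$flagged[res$gene_id == "flat"])
  expect_true(res$flagged[res$gene_id == "strong"])
  expect_false(res$flagged[res$gene_id == "fold_only"])  # p too large
  expect_false(res$flagged[res$gene_id == "sig_only"])   # fold ~ 1
  expect_equal(res$direction[res$gene_id == "strong"], "up")

  # invariance under group label swap and sample reordering
  grp_swap <- grp
  grp_swap$group <- ifelse(grp$group == "migratory",
                           "freshwater", "migratory")
  res_swap <- call_deg(expr, grp_swap)
  expect_equal(res_swap$flagged, res$flagged)
  expect_equal(res_swap$fold, res$fold)
  res_perm <- call_deg(expr[, c("gene_id", "f2", "m3", "f1", "m1",
                                "m2", "f3")], grp)
  expect_equal(res_perm$flagged, res$flagged)
  expect_equal(res_perm$fold, res$fold)
})
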