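test_that("fisher_exact reproduces enumeration on worked tables", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 2 / 6,
               tolerance = 1e-12)
  expect_message(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)),
               class = "sweepscan_validation_error")
})

test_that("fisher_exact is symmetric and matches stats::fisher.test", {
  set.seed(43)
  for (rep in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[, 2:1]), p, tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("codon-level calls distinguish synonymous from non-synonymous", {
  fx <- make_effect_fixture()
  syn <- classify_effect(list(chrom = "c1", pos = 10003, ref = "A",
                              alt = "C"), fx$ann, fx$seqs)
  expect_equal(syn$class, "coding_synonymous")   # GGA -> GGC, Gly = Gly
  expect_equal(syn$gene_id, "geneA")
  non <- classify_effect(list(chrom = "c1", pos = 10002, ref = "G",
                              alt = "A"), fx$ann, fx$seqs)
  expect_equal(non$class, "coding_nonsynonymous")  # GGA -> GAA, Gly -> Glu
})

test_that("minus-strand codons are read reverse-complemented", {
  fx <- make_effect_fixture()
  syn <- classify_effect(list(chrom = "c1", pos = 25298, ref = "T",
                              alt = "G"), fx$ann, fx$seqs)
  expect_equal(syn$class, "coding_synonymous")   # GGA -> GGC on the - strand
  expect_equal(syn$gene_id, "geneB")
  non <- classify_effect(list(chrom = "c1", pos = 25299, ref = "C",
                              alt = "T"), fx$ann, fx$seqs)
  expect_equal(non$class, "coding_nonsynonymous")  # GGA -> GAA
})

test_that("all six effect classes are reachable on the fixture", {
  fx <- make_effect_fixture()
  pick_alt <- function(pos) setdiff(c("A", "C", "G", "T"), fx$s[pos])[1]
  sites <- tibble::tibble(
    chrom = "c1",
    pos = c(10003L, 10002L, 10400L, 9000L, 11500L, 20000L),
    ref = fx$s[c(10003L, 10002L, 10400L, 9000L, 11500L, 20000L)],
    alt = c("C", "A", pick_alt(10400), pick_alt(9000), pick_alt(11500),
            pick_alt(20000))
  )
  got <- classify_effects(sites, fx$ann, fx$seqs)
  expect_equal(got$class,
               c("coding_synonymous", "coding_nonsynonymous", "intronic",
                 "upstream", "downstream", "intergenic"))
  expect_equal(got$gene_id[1:5], rep("geneA", 5))
  expect_true(is.na(got$gene_id[6]))
})

test_that("classifier rejects ref mismatches and out-of-frame genes", {
  fx <- make_effect_fixture()
  wrong_ref <- setdiff(c("A", "C", "G", "T"), fx$s[10003])[1]
  expect_error(
    classify_effect(list(chrom = "c1", pos = 10003, ref = wrong_ref,
                         alt = fx$s[10003]), fx$ann, fx$seqs),
    class = "sweepscan_validation_error"
  )
  bad_ann <- gene_annotation(tibble::tibble(
    gene_id = "gBad", chrom = "c1", start = 10001L, end = 10400L,
    strand = "+", cds = list(tibble::tibble(start = 10001L, end = 10400L))
  ))
  expect_warning(
    got <- classify_effect(list(chrom = "c1", pos = 10100, ref = fx$s[10100],
                                alt = setdiff(c("A", "C", "G", "T"),
                                              fx$s[10100])[1]),
                           bad_ann, fx$seqs),
    "multiple of 3"
  )
  expect_equal(got$class, "intergenic")  # the only gene was excluded
})

test_that("effect calls are invariant under genome reverse-complement", {
  fx <- make_effect_fixture()
  pos <- c(10003L, 10002L, 10400L, 9000L, 11500L, 20000L, 25298L, 25299L)
  alt <- vapply(seq_along(pos), function(i) {
    setdiff(c("A", "C", "G", "T"), fx$s[pos[i]])[1]
  }, character(1))
  alt[1] <- "C"; alt[2] <- "A"; alt[7] <- "G"; alt[8] <- "T"
  sites <- tibble::tibble(chrom = "c1", pos = pos, ref = fx$s[pos],
                          alt = alt)
  fwd <- classify_effects(sites, fx$ann, fx$seqs)
  flipped <- flip_fixture(fx$seqs, fx$ann, sites)
  rev <- classify_effects(flipped$sites, flipped$ann, flipped$seqs)
  expect_equal(rev$class, fwd$class)
  expect_equal(rev$gene_id, fwd$gene_id)
})

test_that("allele association scan flags fixed differences only", {
  d <- rbind(matrix(0L, 10, 3), matrix(2L, 10, 3))
  d[, 2] <- rep(c(0L, 2L), 10)        # same frequency in both groups
  d[, 3] <- 0L                        # monomorphic
  ds <- make_ds(d)
  grp <- two_group_grouping(ds, 10)
  res <- allele_assoc_scan(ds, grp)
  expect_lt(res$p[1], 1e-9)
  expect_true(res$significant[1])
  expect_equal(res$p[2], 1)
  expect_true(res$monomorphic[3])
  expect_equal(res$p[3], 1)
  expect_false(res$significant[3])
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("label permutation drives the flagged fraction to the null", {
  set.seed(47)
  ds <- random_ds(40, 60, missing_rate = 0)
  fracs <- sapply(1:20, function(i) {
    grp <- tibble::tibble(
      sample_id = ds$sample_ids,
      group = sample(rep(c("migratory", "freshwater"), c(30, 10)))
    )
    mean(allele_assoc_scan(ds, grp, alpha = 0.01)$significant)
  })
  # Fisher discreteness makes the test conservative: the realized rate
  # sits at or below the nominal alpha
  expect_lte(mean(fracs), 0.02)
})

test_that("enrichment picks the exact branch at small expected counts", {
  background <- sprintf("g%03d", 1:100)
  candidates <- background[1:10]
  term_map <- tibble::tibble(
    gene_id = c(background[1:5], background[11:15]),
    term = "T1"
  )
  res <- enrich_terms(candidates, background, term_map)
  expect_equal(res$branch, "fisher")  # min expected = 10*10/100 = 1 < 5
  expect_equal(res$k, 5L)
  expect_equal(res$p, oracle_fisher(matrix(c(5, 5, 5, 85), 2, byrow = TRUE)),
               tolerance = 1e-10)

  # identical frequency at large counts: chi-square branch, p ~ 1
  big_bg <- sprintf("h%04d", 1:1000)
  big_cand <- big_bg[1:400]
  members <- c(big_bg[1:200], big_bg[401:700])  # 50% in both sets
  res2 <- enrich_terms(big_cand, big_bg,
                       tibble::tibble(gene_id = members, term = "T2"))
  expect_equal(res2$branch, "chisq")
  expect_gt(res2$p, 0.9)

  expect_warning(
    enrich_terms(candidates, background,
                 tibble::tibble(gene_id = "absent", term = "T3")),
    "skipped"
  )
})

test_that("chi-square and exact branches agree at comfortable counts", {
  set.seed(53)
  for (rep in 1:20) {
    k <- sample(25:60, 1); K <- 100
    n <- sample(150:250, 1); N <- 500
    tab <- matrix(c(k, K - k, n - k, (N - K) - (n - k)), 2)
    if (any(tab < 0) || any(outer(rowSums(tab), colSums(tab)) / N < 20)) next
    p_chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    p_fis <- fisher_exact(tab)
    if (p_fis > 1e-4) {
      expect_lt(abs(p_chi - p_fis) / p_fis, 0.5)
    }
  }
})

test_that("enrichment p-values are near-uniform under a random null", {
  set.seed(59)
  bg <- sprintf("g%04d", 1:1000)
  ps <- unlist(lapply(1:5, function(i) {
    cand <- sample(bg, 300)
    term_map <- dplyr::bind_rows(lapply(1:40, function(t) {
      tibble::tibble(gene_id = sample(bg, 100),
                     term = sprintf("T%02d", t))
    }))
    enrich_terms(cand, bg, term_map)$p
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 1e-4)
})
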