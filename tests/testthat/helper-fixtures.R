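# Shared fixture builders. All fixtures are generated in code.

# genotype_dataset from a samples x sites dosage matrix; sites are laid out
# on one chromosome at the given positions (default 1, 2, ...).
make_ds <- function(dosages, chrom = "chr1", pos = NULL,
                    sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%02d", seq_len(nrow(dosages)))
  }
  refs <- rep(c("A", "C"), length.out = m)
  alts <- rep(c("G", "T"), length.out = m)
  genotype_dataset(
    sample_ids,
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   ref = refs, alt = alts),
    dosages
  )
}

two_group_grouping <- function(ds, n_first,
                               labels = c("migratory", "freshwater")) {
  tibble::tibble(
    sample_id = ds$sample_ids,
    group = rep(labels, c(n_first, length(ds$sample_ids) - n_first))
  )
}

# Random dataset for property tests: uniform dosages with missingness.
random_ds <- function(n_samples, n_sites, missing_rate = 0.1) {
  d <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
              nrow = n_samples)
  if (missing_rate > 0) {
    d[matrix(runif(length(d)) < missing_rate, nrow = n_samples)] <-
      NA_integer_
  }
  make_ds(d)
}

# Random unrooted binary tree with positive branch lengths, returned with
# its (additive) leaf distance matrix.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 2))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

write_temp_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("s1", "s2", "s3")) {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_line <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", "GT", gts),
        collapse = "\t")
}
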