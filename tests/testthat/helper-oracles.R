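# Independent oracles, kept deliberately naive: enumeration and scalar
# textbook formulas, never sharing code with the implementation.

# Probability two alleles drawn without replacement differ, by explicit
# enumeration of every allele pair.
oracle_site_pi <- function(ref_count, alt_count) {
  alleles <- c(rep(0L, ref_count), rep(1L, alt_count))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0L
  pairs <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pairs <- pairs + 1L
      if (alleles[i] != alleles[j]) diffs <- diffs + 1L
    }
  }
  diffs / pairs
}

# Window per-bp diversity for one group by allele-pair enumeration.
oracle_window_pi <- function(ds, group_ids, chrom, start, end) {
  idx <- match(group_ids, ds$sample_ids)
  total <- 0
  for (s in seq_len(nrow(ds$sites))) {
    if (ds$sites$chrom[s] != chrom) next
    if (ds$sites$pos[s] < start || ds$sites$pos[s] > end) next
    g <- ds$dosages[idx, s]
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    alt <- sum(g)
    ref <- 2L * length(g) - alt
    v <- oracle_site_pi(ref, alt)
    if (!is.na(v)) total <- total + v
  }
  total / (end - start + 1)
}

# Weir & Cockerham (1984) theta for one window, written as the published
# per-site variance components in scalar form (r = 2 populations).
oracle_wc_fst <- function(ds, grouping, chrom, start, end) {
  idx1 <- which(grouping$group[match(ds$sample_ids,
                                     grouping$sample_id)] == "migratory")
  idx2 <- setdiff(seq_along(ds$sample_ids), idx1)
  num <- 0
  den <- 0
  r <- 2
  for (s in seq_len(nrow(ds$sites))) {
    if (ds$sites$chrom[s] != chrom) next
    if (ds$sites$pos[s] < start || ds$sites$pos[s] > end) next
    g1 <- ds$dosages[idx1, s]; g1 <- g1[!is.na(g1)]
    g2 <- ds$dosages[idx2, s]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- sum(g1 == 1) / n1; h2 <- sum(g2 == 1) / n2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
      (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  min(num / den, 1)
}

# Two-sided Fisher p by full enumeration over fixed-margin tables with
# log-factorial point probabilities.
oracle_fisher <- function(tab) {
  r1 <- tab[1, 1] + tab[1, 2]
  r2 <- tab[2, 1] + tab[2, 2]
  c1 <- tab[1, 1] + tab[2, 1]
  N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  lp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- probs[support == tab[1, 1]]
  min(sum(probs[probs <= p_obs * (1 + 1e-12)]), 1)
}

# All-pairs interval overlap (brute force) for gene/region membership.
oracle_genes_in_regions <- function(regions, ann, min_overlap_bp = 1) {
  out <- character(0)
  for (i in seq_len(nrow(ann))) {
    for (j in seq_len(nrow(regions))) {
      if (ann$chrom[i] != regions$chrom[j]) next
      ov <- min(ann$end[i], regions$end[j]) -
        max(ann$start[i], regions$start[j]) + 1
      if (ov >= min_overlap_bp) out <- c(out, ann$gene_id[i])
    }
  }
  sort(unique(out))
}

# Reverse-complement a fixture genome and mirror all coordinates, strands
# and alleles; effect classes must be invariant under this flip.
flip_fixture <- function(seqs, ann, sites) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  lens <- vapply(seqs, nchar, integer(1))
  seqs2 <- vapply(seqs, rc, character(1))
  flip_pos <- function(chrom, p) lens[[chrom]] - p + 1L
  ann2 <- tibble::as_tibble(ann)
  for (i in seq_len(nrow(ann2))) {
    L <- lens[[ann2$chrom[i]]]
    s <- ann2$start[i]; e <- ann2$end[i]
    ann2$start[i] <- L - e + 1L
    ann2$end[i] <- L - s + 1L
    ann2$strand[i] <- if (ann2$strand[i] == "+") "-" else "+"
    cds <- ann2$cds[[i]]
    ann2$cds[[i]] <- tibble::tibble(
      start = L - cds$end + 1L, end = L - cds$start + 1L)
  }
  sites2 <- sites
  sites2$pos <- mapply(flip_pos, sites$chrom, sites$pos)
  sites2$ref <- unname(comp[sites$ref])
  sites2$alt <- unname(comp[sites$alt])
  list(seqs = seqs2, ann = gene_annotation(ann2), sites = sites2)
}
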