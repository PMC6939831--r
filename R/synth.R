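#' Simulation configuration for the two-population genotype generator
#'
#' Defaults mirror the study design the package targets: a partially
#' migratory cohort of 85 migratory and 11 freshwater-resident individuals,
#' two 500-kb chromosomes, background drift differentiation F = 0.02, and
#' one planted 25-kb sweep interval per chromosome in which the freshwater
#' group shows strong drift (F = 0.6) and a ten-fold loss of minor-allele
#' frequency.
#'
#' @param n_migratory,n_freshwater Diploid sample counts per group
#'   (each >= 2).
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param snp_density Expected SNPs per bp (default 1/200).
#' @param background_fst Balding-Nichols drift F per population outside
#'   sweeps.
#' @param sweeps Tibble with `chrom`, `start`, `end` (1-based inclusive)
#'   of planted sweep intervals; `NULL` places one centered 25-kb sweep
#'   per chromosome.
#' @param sweep_fst Freshwater drift F inside sweep intervals.
#' @param sweep_diversity_scale Multiplier applied to the freshwater
#'   minor-allele frequency inside sweeps (values < 1 push sites toward
#'   fixation).
#' @param missing_rate Per-genotype missing probability.
#' @param seed Integer seed governing all draws.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_migratory = 85, n_freshwater = 11,
                       chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                       snp_density = 1 / 200,
                       background_fst = 0.02,
                       sweeps = NULL,
                       sweep_fst = 0.6,
                       sweep_diversity_scale = 0.1,
                       missing_rate = 0.03,
                       seed = 1L) {
  if (is.null(sweeps)) {
    mid <- floor(chrom_lengths / 2)
    sweeps <- tibble(
      chrom = names(chrom_lengths),
      start = as.integer(mid - 12500L + 1L),
      end = as.integer(mid + 12500L)
    )
  }
  sweeps <- as_tibble(sweeps)
  cfg <- list(
    n_migratory = as.integer(n_migratory),
    n_freshwater = as.integer(n_freshwater),
    chrom_lengths = chrom_lengths, snp_density = snp_density,
    background_fst = background_fst, sweeps = sweeps,
    sweep_fst = sweep_fst,
    sweep_diversity_scale = sweep_diversity_scale,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  rates <- c(snp_density, background_fst, sweep_fst,
             sweep_diversity_scale, missing_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "sweepscan_validation_error")
  }
  if (cfg$n_migratory < 2 || cfg$n_freshwater < 2) {
    abort("each group needs at least 2 samples",
      class = "sweepscan_validation_error")
  }
  if (nrow(sweeps)) {
    ok <- sweeps$chrom %in% names(chrom_lengths) & sweeps$start >= 1 &
      sweeps$end <= chrom_lengths[sweeps$chrom] & sweeps$start <= sweeps$end
    if (any(!ok)) {
      abort("sweep intervals must lie within chromosome bounds",
        class = "sweepscan_validation_error")
    }
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw: population frequency around ancestral p with drift F.
rbalding_nichols <- function(n, p, f) {
  if (length(f) == 1) f <- rep(f, n)
  out <- numeric(n)
  drifted <- f > 0
  out[drifted] <- rbeta(sum(drifted),
                        p[drifted] * (1 - f[drifted]) / f[drifted],
                        (1 - p[drifted]) * (1 - f[drifted]) / f[drifted])
  out[!drifted] <- p[!drifted]
  out
}

in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[k] &
                    pos >= intervals$start[k] & pos <= intervals$end[k])
  }
  hit
}

#' Simulate a two-population genotype dataset with planted sweeps
#'
#' Sites are placed uniformly (then sorted and deduplicated) at the
#' configured density. Each site gets an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`; each population's frequency is drawn from the
#' Balding-Nichols distribution with its drift F (freshwater uses
#' `sweep_fst` inside sweep intervals). Inside sweeps the freshwater
#' minor-allele frequency is additionally multiplied by
#' `sweep_diversity_scale`, pushing sites toward fixation. Genotypes are
#' two Bernoulli allele draws; missingness is applied independently per
#' genotype. The whole draw sequence is governed by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a [genotype_dataset()]), `grouping`
#'   (tibble `sample_id`, `group`) and `truth` (list: configured sweep
#'   intervals, per-site ancestral and per-population frequencies, seed).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sites <- bind_rows(lapply(names(cfg$chrom_lengths), function(ch) {
    L <- cfg$chrom_lengths[[ch]]
    n_draw <- round(L * cfg$snp_density)
    pos <- sort(unique(sample.int(L, n_draw, replace = TRUE)))
    tibble(chrom = ch, pos = as.integer(pos))
  }))
  m <- nrow(sites)
  if (m == 0) {
    abort("no sites after deduplication", class = "sweepscan_validation_error")
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  p_anc <- runif(m, 0.05, 0.95)
  in_sweep <- in_intervals(sites$chrom, sites$pos, cfg$sweeps)
  p_mig <- rbalding_nichols(m, p_anc, rep(cfg$background_fst, m))
  f_fw <- ifelse(in_sweep, cfg$sweep_fst, cfg$background_fst)
  p_fw <- rbalding_nichols(m, p_anc, f_fw)
  scale_minor <- function(p, s) ifelse(p <= 0.5, p * s, 1 - (1 - p) * s)
  p_fw[in_sweep] <- scale_minor(p_fw[in_sweep], cfg$sweep_diversity_scale)

  n_mig <- cfg$n_migratory
  n_fw <- cfg$n_freshwater
  g_mig <- matrix(rbinom(n_mig * m, 2, rep(p_mig, each = n_mig)),
                  nrow = n_mig)
  g_fw <- matrix(rbinom(n_fw * m, 2, rep(p_fw, each = n_fw)), nrow = n_fw)
  dosages <- rbind(g_mig, g_fw)
  if (cfg$missing_rate > 0) {
    dosages[runif(length(dosages)) < cfg$missing_rate] <- NA_integer_
  }
  sample_ids <- c(sprintf("mig_%03d", seq_len(n_mig)),
                  sprintf("fw_%03d", seq_len(n_fw)))
  ds <- genotype_dataset(
    sample_ids,
    mutate(sites, ref = ref, alt = alt),
    dosages
  )
  grouping <- tibble(
    sample_id = sample_ids,
    group = rep(c("migratory", "freshwater"), c(n_mig, n_fw))
  )
  list(
    dataset = ds, grouping = grouping,
    truth = list(
      sweeps = cfg$sweeps, in_sweep = in_sweep,
      p_anc = p_anc, p_mig = p_mig, p_fw = p_fw, seed = cfg$seed
    )
  )
}

#' Simulate a reference genome consistent with a dataset
#'
#' Random uniform A/C/G/T sequence per chromosome with every variant
#' site's base forced to its ref allele, so effect classification
#' pre-conditions hold on simulated data.
#'
#' @param cfg A [sim_config()] (for chromosome lengths).
#' @param ds The simulated [genotype_dataset()].
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
simulate_reference <- function(cfg, ds, seed = cfg$seed + 1L) {
  set.seed(seed)
  seqs <- vapply(names(cfg$chrom_lengths), function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_lengths[[ch]],
                 replace = TRUE), collapse = "")
  }, character(1))
  for (ch in unique(ds$sites$chrom)) {
    sel <- ds$sites$chrom == ch
    s <- strsplit(seqs[[ch]], "")[[1]]
    s[ds$sites$pos[sel]] <- ds$sites$ref[sel]
    seqs[[ch]] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a gene annotation on the configured chromosomes
#'
#' Genes are tiled deterministically from position 1 in blocks of
#' `gene_length + spacing` bp, giving `floor(L / (gene_length + spacing))`
#' genes per chromosome — with the default 5-kb spacing at least one gene
#' overlaps any planted sweep interval of 25 kb. Each gene carries a single
#' CDS spanning its body (`gene_length` must be a multiple of 3); strands
#' are drawn at random under `seed`.
#'
#' @param cfg A [sim_config()].
#' @param gene_length Gene (and CDS) length in bp, multiple of 3.
#' @param spacing Gap between consecutive genes in bp.
#' @param seed Integer seed (strand draws).
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(cfg, gene_length = 300, spacing = 5000,
                                seed = cfg$seed) {
  if (gene_length %% 3 != 0) {
    abort("gene_length must be a multiple of 3",
      class = "sweepscan_validation_error")
  }
  set.seed(seed)
  period <- gene_length + spacing
  genes <- bind_rows(lapply(names(cfg$chrom_lengths), function(ch) {
    n_genes <- floor(cfg$chrom_lengths[[ch]] / period)
    if (n_genes == 0) return(NULL)
    start <- (seq_len(n_genes) - 1L) * period + 1L
    tibble(
      gene_id = sprintf("%s_g%04d", ch, seq_len(n_genes)),
      chrom = ch, start = as.integer(start),
      end = as.integer(start + gene_length - 1L)
    )
  }))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$cds <- lapply(seq_len(nrow(genes)), function(i) {
    tibble(start = genes$start[i], end = genes$end[i])
  })
  gene_annotation(genes)
}

#' Simulate an otolith Sr:Ca transect
#'
#' Resident fish accrete freshwater-level Sr:Ca (mean 1.5, in units of
#' Sr:Ca x 1000) from core to edge. Migratory fish show a freshwater core
#' (first 40% of points) followed by alternating brackish (mean 5.0) and
#' seawater (mean 8.0) segments. Gaussian noise of `noise_sd` is added and
#' values are clipped at zero.
#'
#' @param pattern `"resident"` or `"migratory"`.
#' @param n_points Number of transect points (>= 10), core to edge.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param step_um Spacing between points in micrometers.
#' @return Tibble of class `srca_transect` with `distance_um`,
#'   `sr_ca_ratio`.
#' @export
simulate_otolith <- function(pattern = c("resident", "migratory"),
                             n_points = 60, noise_sd = 0.2, seed = 1L,
                             step_um = 10) {
  pattern <- match.arg(pattern)
  if (n_points < 10) {
    abort("n_points must be >= 10", class = "sweepscan_validation_error")
  }
  set.seed(seed)
  if (pattern == "resident") {
    mu <- rep(1.5, n_points)
  } else {
    n_core <- ceiling(0.4 * n_points)
    n_rest <- n_points - n_core
    seg <- ceiling(n_rest / 4)
    marine <- rep(rep(c(5.0, 8.0), length.out = 4), each = seg)[seq_len(n_rest)]
    mu <- c(rep(1.5, n_core), marine)
  }
  ratio <- pmax(mu + rnorm(n_points, 0, noise_sd), 0)
  out <- tibble(
    distance_um = (seq_len(n_points) - 1) * step_um,
    sr_ca_ratio = ratio
  )
  class(out) <- c("srca_transect", class(out))
  attr(out, "pattern") <- pattern
  out
}

#' Simulate a qPCR Ct table for one target gene
#'
#' Reference-gene Ct is drawn as Normal(15, 0.2); the target Ct equals the
#' reference plus a baseline delta-Ct of `baseline_dct` cycles, minus
#' `effect_log2` cycles in the migratory group (one cycle = one doubling),
#' plus Normal(0, 0.3) noise — so the expected migratory/freshwater
#' relative-quantity ratio is `2^effect_log2`.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param effect_log2 Log2 expression increase in the migratory group.
#' @param seed Integer seed.
#' @param gene Target gene name.
#' @param baseline_dct Baseline target-minus-reference Ct offset in cycles.
#' @return Tibble with `sample_id`, `group`, `gene`, `ct_target`, `ct_ref`.
#' @export
simulate_qpcr <- function(n_per_group = 5, effect_log2 = 2, seed = 1L,
                          gene = "target", baseline_dct = 8) {
  if (n_per_group < 3) {
    abort("n_per_group must be >= 3", class = "sweepscan_validation_error")
  }
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("migratory", "freshwater"), each = n_per_group)
  ct_ref <- rnorm(n, 15, 0.2)
  ct_target <- ct_ref + baseline_dct -
    effect_log2 * (group == "migratory") + rnorm(n, 0, 0.3)
  tibble(
    sample_id = paste0(substr(group, 1, 3), "_", seq_len(n)),
    group = group, gene = gene,
    ct_target = ct_target, ct_ref = ct_ref
  )
}

#' Simulate a gene-to-term map
#'
#' Assigns each gene 1-3 terms from a pool of `n_terms`, for exercising
#' enrichment analysis on synthetic annotations.
#'
#' @param ann A [gene_annotation()].
#' @param n_terms Size of the term pool.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `term`.
#' @export
simulate_term_map <- function(ann, n_terms = 20, seed = 1L) {
  set.seed(seed)
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  bind_rows(lapply(ann$gene_id, function(g) {
    tibble(gene_id = g,
           term = sample(terms, sample.int(3, 1)))
  }))
}
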