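#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by point-probability ordering: the sum of hypergeometric
#' probabilities of every table with the observed margins whose point
#' probability is at most that of the observed table, with a 1e-12
#' relative slack absorbing floating-point ties.
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in `(0, 1]`. A table with a zero margin
#'   returns 1 by convention.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisher_exact <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2)) || any(t < 0) || any(t != round(t))) {
    abort("need a 2x2 table of non-negative integers",
      class = "sweepscan_validation_error")
  }
  r1 <- t[1, 1] + t[1, 2]
  r2 <- t[2, 1] + t[2, 2]
  c1 <- t[1, 1] + t[2, 1]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == sum(t)) {
    inform("fisher_exact: degenerate margin, p = 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- probs[match(t[1, 1], support)]
  min(sum(probs[probs <= p_obs * (1 + 1e-12)]), 1)
}

#' Per-SNP allele-frequency association scan between two groups
#'
#' Builds, for every site, the 2x2 table of (group) x (ref, alt) allele
#' counts from non-missing dosages and applies [fisher_exact()].
#' Benjamini-Hochberg q-values are reported alongside the raw p; the
#' `significant` flag follows the raw `p < alpha` rule.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping Tibble with `sample_id`, `group`.
#' @param sites Optional integer index of sites to test (default: all).
#' @param alpha Raw-p significance threshold (default 0.01).
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, the four allele
#'   counts, `monomorphic`, `p`, `q`, `significant`.
#' @export
allele_assoc_scan <- function(ds, grouping, sites = NULL, alpha = 0.01) {
  gi <- group_indices(ds, grouping)
  if (is.null(sites)) sites <- seq_len(nrow(ds$sites))
  d <- ds$dosages[, sites, drop = FALSE]
  g1 <- group_site_summary(d, gi$idx1)
  g2 <- group_site_summary(d, gi$idx2)
  mono <- (g1$alt_count + g2$alt_count) == 0 |
    (g1$ref_count + g2$ref_count) == 0
  p <- vapply(seq_along(sites), function(k) {
    if (mono[k]) return(1)
    suppressMessages(fisher_exact(matrix(
      c(g1$ref_count[k], g2$ref_count[k],
        g1$alt_count[k], g2$alt_count[k]), nrow = 2)))
  }, numeric(1))
  out <- ds$sites[sites, ]
  out[[paste0("ref_", gi$labels[1])]] <- g1$ref_count
  out[[paste0("alt_", gi$labels[1])]] <- g1$alt_count
  out[[paste0("ref_", gi$labels[2])]] <- g2$ref_count
  out[[paste0("alt_", gi$labels[2])]] <- g2$alt_count
  out$monomorphic <- mono
  out$p <- p
  out$q <- p.adjust(p, method = "BH")
  out$significant <- p < alpha
  out
}

#' Term enrichment of a candidate gene set
#'
#' For each term, tests whether the candidate set holds more term members
#' than expected from the background using the 2x2 table
#' (candidate, rest) x (has term, lacks term). When all expected cell
#' counts (`row x column / N`) are at least 5 a 1-df chi-square test
#' without continuity correction is used; otherwise the exact
#' [fisher_exact()] branch.
#'
#' @param candidates Character vector of candidate gene ids (subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Tibble with `gene_id`, `term` keyed on background genes.
#' @param alpha Raw-p flag threshold (default 0.05).
#' @return Tibble sorted by p: `term`, `k` (candidates with term),
#'   `K` (candidates), `n` (background with term), `N` (background),
#'   `branch` (`chisq` or `fisher`), `p`, `q`, `significant`.
#' @export
enrich_terms <- function(candidates, background, term_map, alpha = 0.05) {
  candidates <- unique(as.character(candidates))
  background <- unique(as.character(background))
  if (!all(candidates %in% background)) {
    abort("candidates must be a subset of the background",
      class = "sweepscan_validation_error")
  }
  term_map <- as_tibble(term_map)
  outside <- !term_map$gene_id %in% background
  if (any(outside)) {
    dropped <- unique(term_map$term[outside])
    term_map <- term_map[!outside, ]
    orphan <- setdiff(dropped, unique(term_map$term))
    if (length(orphan)) {
      warn(paste0("enrich_terms: terms with no background gene skipped: ",
                  paste(head(orphan, 5), collapse = ", ")))
    }
  }
  N <- length(background)
  K <- length(candidates)
  terms <- unique(term_map$term)
  res <- lapply(terms, function(tm) {
    members <- unique(term_map$gene_id[term_map$term == tm])
    n <- length(members)
    k <- sum(candidates %in% members)
    tab <- matrix(c(k, K - k, n - k, (N - K) - (n - k)), nrow = 2)
    expected <- outer(rowSums(tab), colSums(tab)) / N
    if (all(expected >= 5)) {
      branch <- "chisq"
      p <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
    } else {
      branch <- "fisher"
      p <- suppressMessages(fisher_exact(tab))
    }
    tibble(term = tm, k = k, K = K, n = n, N = N, branch = branch, p = p)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), branch = character(),
                  p = numeric(), q = numeric(), significant = logical()))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  arrange(out, .data$p)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Spliced coding sequence of one gene in 5'->3' transcript orientation.
gene_cdna <- function(gene_row, ref_seqs) {
  cds <- gene_row$cds[[1]]
  seq <- ref_seqs[[gene_row$chrom]]
  segs <- vapply(seq_len(nrow(cds)), function(k) {
    s <- substr(seq, cds$start[k], cds$end[k])
    if (gene_row$strand == "-") {
      s <- paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
    }
    s
  }, character(1))
  paste(segs, collapse = "")
}

# 0-based transcript offset of a genomic position inside a gene's CDS,
# or NA when the position is non-coding. cds rows are in transcription
# order (descending coordinates on the minus strand).
cdna_offset <- function(gene_row, pos) {
  cds <- gene_row$cds[[1]]
  off <- 0L
  for (k in seq_len(nrow(cds))) {
    if (pos >= cds$start[k] && pos <= cds$end[k]) {
      within <- if (gene_row$strand == "+") pos - cds$start[k]
        else cds$end[k] - pos
      return(off + within)
    }
    off <- off + (cds$end[k] - cds$start[k] + 1L)
  }
  NA_integer_
}

severity_rank <- c(
  coding_nonsynonymous = 1, coding_synonymous = 1, intronic = 2,
  upstream = 3, downstream = 3, intergenic = 4
)

#' Classify the functional effect of one variant
#'
#' A variant inside a CDS is translated with its ref and alt base swapped
#' into the containing codon (reverse-complemented on the minus strand,
#' codon phase from cumulative CDS length): equal amino acids give
#' `coding_synonymous`, different ones `coding_nonsynonymous`. A position
#' inside a gene body but outside its CDS is `intronic`; within `flank`
#' bp 5' of the gene start (strand-aware) `upstream`, within `flank` bp 3'
#' `downstream`; anything else `intergenic`. When several genes apply the
#' most severe class wins (coding > intronic > upstream/downstream >
#' intergenic), ties resolved by the nearest gene.
#'
#' @param variant List or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param ann A [gene_annotation()]. Genes whose total CDS length is not a
#'   multiple of 3 are excluded with a warning.
#' @param ref_seqs Named character vector of reference sequences
#'   ([read_fasta()]); the variant's ref base must match the reference.
#' @param flank Upstream/downstream flank in bp (default 5000).
#' @return Tibble with `class` (one of the six effect classes, `NA` when a
#'   codon contains an ambiguity base) and `gene_id` (`NA` for
#'   intergenic).
#' @export
classify_effect <- function(variant, ann, ref_seqs, flank = 5000) {
  classify_effects(
    tibble(chrom = as.character(variant[["chrom"]]),
           pos = as.integer(variant[["pos"]]),
           ref = toupper(as.character(variant[["ref"]])),
           alt = toupper(as.character(variant[["alt"]]))),
    ann, ref_seqs, flank)
}

#' Classify functional effects of a table of variants
#'
#' Vectorized driver behind [classify_effect()]; see that page for the
#' classification rules.
#'
#' @param sites Data frame with `chrom`, `pos`, `ref`, `alt` (or a
#'   [genotype_dataset()], whose site table is used).
#' @inheritParams classify_effect
#' @return `sites` with `class` and `gene_id` columns appended.
#' @export
classify_effects <- function(sites, ann, ref_seqs, flank = 5000) {
  if (inherits(sites, "genotype_dataset")) sites <- sites$sites
  sites <- as_tibble(sites)
  stopifnot(inherits(ann, "gene_annotation"))

  cds_len <- vapply(ann$cds, function(cd) {
    sum(cd$end - cd$start + 1L)
  }, integer(1))
  bad_frame <- cds_len > 0 & cds_len %% 3 != 0
  if (any(bad_frame)) {
    warn(paste0("classify_effects: CDS length not a multiple of 3, ",
                "genes excluded: ",
                paste(head(ann$gene_id[bad_frame], 5), collapse = ", ")))
    ann <- gene_annotation(as_tibble(ann)[!bad_frame, ])
  }

  ref_ok <- vapply(seq_len(nrow(sites)), function(i) {
    seq <- ref_seqs[[sites$chrom[i]]]
    !is.null(seq) && substr(seq, sites$pos[i], sites$pos[i]) == sites$ref[i]
  }, logical(1))
  if (any(!ref_ok)) {
    i <- which(!ref_ok)[1]
    abort(sprintf("ref base mismatch with reference at %s:%d",
                  sites$chrom[i], sites$pos[i]),
      class = "sweepscan_validation_error")
  }

  cdna_cache <- new.env(parent = emptyenv())
  get_cdna <- function(gi) {
    key <- ann$gene_id[gi]
    if (is.null(cdna_cache[[key]])) {
      cdna_cache[[key]] <- gene_cdna(ann[gi, ], ref_seqs)
    }
    cdna_cache[[key]]
  }

  classify_one <- function(i) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]
    same <- which(ann$chrom == chrom)
    calls <- list()
    for (gi in same) {
      g_start <- ann$start[gi]; g_end <- ann$end[gi]
      strand <- ann$strand[gi]
      if (pos >= g_start && pos <= g_end) {
        off <- cdna_offset(ann[gi, ], pos)
        if (is.na(off)) {
          calls[[length(calls) + 1]] <-
            list(class = "intronic", gene = ann$gene_id[gi], dist = 0)
        } else {
          cdna <- get_cdna(gi)
          codon_i <- off %/% 3L
          ref_codon <- substr(cdna, codon_i * 3L + 1L, codon_i * 3L + 3L)
          alt_base <- if (strand == "+") sites$alt[i] else
            COMPLEMENT[[sites$alt[i]]]
          alt_codon <- ref_codon
          substr(alt_codon, off %% 3L + 1L, off %% 3L + 1L) <- alt_base
          if (grepl("N", ref_codon) || grepl("N", alt_codon)) {
            warn(sprintf(
              "classify_effects: ambiguity base in codon at %s:%d, excluded",
              chrom, pos))
            return(list(class = NA_character_, gene = ann$gene_id[gi]))
          }
          cls <- if (translate_codon(ref_codon) ==
                       translate_codon(alt_codon)) {
            "coding_synonymous"
          } else "coding_nonsynonymous"
          calls[[length(calls) + 1]] <-
            list(class = cls, gene = ann$gene_id[gi], dist = 0)
        }
      } else {
        dist_start <- g_start - pos
        dist_end <- pos - g_end
        before <- pos < g_start && dist_start <= flank
        after <- pos > g_end && dist_end <= flank
        if (before || after) {
          cls <- if ((before && strand == "+") || (after && strand == "-")) {
            "upstream"
          } else "downstream"
          calls[[length(calls) + 1]] <-
            list(class = cls, gene = ann$gene_id[gi],
                 dist = max(dist_start, dist_end))
        }
      }
    }
    if (!length(calls)) {
      return(list(class = "intergenic", gene = NA_character_))
    }
    ranks <- vapply(calls, function(cl) severity_rank[[cl$class]], numeric(1))
    dists <- vapply(calls, function(cl) cl$dist, numeric(1))
    best <- order(ranks, dists)[1]
    calls[[best]][c("class", "gene")]
  }

  res <- lapply(seq_len(nrow(sites)), classify_one)
  sites$class <- vapply(res, function(r) r$class %||% NA_character_,
                        character(1))
  sites$gene_id <- vapply(res, function(r) r$gene %||% NA_character_,
                          character(1))
  sites
}
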