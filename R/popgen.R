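#' Filter variants on missingness and minor-allele frequency
#'
#' A site is kept when its missing-genotype fraction is at most
#' `max_missing` and its minor-allele frequency, computed from non-missing
#' dosages, is at least `min_maf`. Samples and site order are unchanged.
#'
#' @param ds A [genotype_dataset()].
#' @param max_missing Maximum tolerated missing fraction per site
#'   (default 0.10: sites with more than 10% missing data are excluded).
#' @param min_maf Minimum minor-allele frequency (default 0.10).
#' @return A filtered `genotype_dataset` with attribute `counts` holding
#'   `n_input`, `n_kept`, `n_removed_missing`, `n_removed_maf` (a site
#'   failing both rules counts under missingness).
#' @export
filter_variants <- function(ds, max_missing = 0.10, min_maf = 0.10) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- length(ds$sample_ids)
  n_missing <- colSums(is.na(ds$dosages))
  miss_frac <- n_missing / n
  n_called <- n - n_missing
  af <- ifelse(n_called > 0,
               colSums(ds$dosages, na.rm = TRUE) / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  fail_miss <- miss_frac > max_missing
  fail_maf <- !fail_miss & (is.na(maf) | maf < min_maf)
  keep <- !fail_miss & !fail_maf
  out <- subset_sites(ds, keep)
  attr(out, "counts") <- list(
    n_input = ncol(ds$dosages), n_kept = sum(keep),
    n_removed_missing = sum(fail_miss), n_removed_maf = sum(fail_maf)
  )
  if (!any(keep) && ncol(ds$dosages) > 0) {
    warn("filter_variants: all sites removed")
  }
  out
}

#' Per-site nucleotide diversity from allele counts
#'
#' The unbiased probability that two alleles sampled without replacement
#' from the site differ: `2 * ref * alt / (c * (c - 1))` with
#' `c = ref + alt`. Sites with fewer than two observed alleles cannot be
#' scored and return `NA` (callers skip them).
#'
#' @param ref_count,alt_count Non-negative allele counts (vectorized).
#' @return Numeric vector of per-site diversity values in `[0, 1]`.
#' @examples
#' site_pi(2, 2)  # 4 of the 6 allele pairs differ: 0.666...
#' @export
site_pi <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    abort("allele counts must be non-negative",
      class = "sweepscan_validation_error")
  }
  cc <- ref_count + alt_count
  ifelse(cc >= 2, 2 * ref_count * alt_count / (cc * (cc - 1)), NA_real_)
}

#' Reduction of diversity
#'
#' `ROD = 1 - pi_fw / pi_mig`: positive values flag diversity loss in the
#' freshwater group relative to the migratory group, the footprint of a
#' selective sweep. Undefined (`NA`) when `pi_mig` is zero.
#'
#' @param pi_fw,pi_mig Non-negative per-bp diversities (vectorized).
#' @return Numeric vector in `(-Inf, 1]`, `NA` where `pi_mig == 0`.
#' @export
rod <- function(pi_fw, pi_mig) {
  if (any(pi_fw < 0, na.rm = TRUE) || any(pi_mig < 0, na.rm = TRUE)) {
    abort("diversities must be non-negative",
      class = "sweepscan_validation_error")
  }
  ifelse(!is.na(pi_mig) & pi_mig > 0, 1 - pi_fw / pi_mig, NA_real_)
}

# Per-site summaries for one group: number of non-missing genotypes,
# alt-allele frequency, observed heterozygote fraction.
group_site_summary <- function(dosages, idx) {
  x <- dosages[idx, , drop = FALSE]
  n <- colSums(!is.na(x))
  alt <- colSums(x, na.rm = TRUE)
  list(
    n = n,
    p = ifelse(n > 0, alt / (2 * n), NA_real_),
    h = ifelse(n > 0, colSums(x == 1L, na.rm = TRUE) / n, NA_real_),
    ref_count = 2 * n - alt,
    alt_count = alt
  )
}

# Weir & Cockerham (1984) two-population variance components per site.
# Inputs are vectors over sites; returns a, b, c and a usability mask.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  inner <- pbar * (1 - pbar) - s2 / 2 - hbar / 4
  a <- nbar / nc * (s2 - inner / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, usable = usable)
}

# Hudson-style per-site numerator/denominator (allele-count based).
hudson_components <- function(n1, p1, n2, p2) {
  c1 <- 2 * n1
  c2 <- 2 * n2
  usable <- c1 >= 2 & c2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (c1 - 1) - p2 * (1 - p2) / (c2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den, usable = usable)
}

# Indices of sites falling in [start, end] on chrom (sites sorted by pos).
sites_in_window <- function(sites, chrom, start, end) {
  which(sites$chrom == chrom & sites$pos >= start & sites$pos <= end)
}

#' Per-bp nucleotide diversity of one group in one window
#'
#' Sums [site_pi()] over the window's variant sites, using allele counts
#' from the group's non-missing genotypes, and divides by the window length
#' in bp — so monomorphic and unobserved positions contribute zero. Sites
#' where the group has fewer than two observed alleles are skipped.
#'
#' @param ds A [genotype_dataset()].
#' @param group_samples Character vector of sample ids forming the group.
#' @param window List or vector with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return Per-bp diversity (numeric scalar).
#' @export
window_pi <- function(ds, group_samples, window) {
  idx <- match(group_samples, ds$sample_ids)
  if (anyNA(idx) || length(idx) == 0) {
    abort("group samples must be present in the dataset",
      class = "sweepscan_validation_error")
  }
  chrom <- as.character(window[["chrom"]])
  start <- as.numeric(window[["start"]])
  end <- as.numeric(window[["end"]])
  sel <- sites_in_window(ds$sites, chrom, start, end)
  if (!length(sel)) return(0)
  g <- group_site_summary(ds$dosages[, sel, drop = FALSE], idx)
  pis <- site_pi(g$ref_count, g$alt_count)
  sum(pis, na.rm = TRUE) / (end - start + 1)
}

#' Window Fst between two groups
#'
#' Weir & Cockerham (1984) variance components are computed per usable
#' site from each group's sample size, allele frequency and observed
#' heterozygosity; the window value is the ratio of averages
#' `sum(a) / sum(a + b + c)`. Values may be negative for undifferentiated
#' windows and are capped above at 1. A Hudson-style ratio-of-averages
#' estimator is available behind the same contract.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping Tibble with `sample_id`, `group` covering the dataset.
#' @param window List or vector with `chrom`, `start`, `end`.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return Fst (numeric scalar), `NA` when no usable site exists.
#' @export
window_fst <- function(ds, grouping, window, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  gi <- group_indices(ds, grouping)
  chrom <- as.character(window[["chrom"]])
  sel <- sites_in_window(ds$sites, chrom, as.numeric(window[["start"]]),
                         as.numeric(window[["end"]]))
  if (!length(sel)) return(NA_real_)
  d <- ds$dosages[, sel, drop = FALSE]
  g1 <- group_site_summary(d, gi$idx1)
  g2 <- group_site_summary(d, gi$idx2)
  if (estimator == "wc") {
    w <- wc_components(g1$n, g1$p, g1$h, g2$n, g2$p, g2$h)
    if (!any(w$usable)) return(NA_real_)
    num <- sum(w$a[w$usable])
    den <- sum((w$a + w$b + w$c)[w$usable])
    if (den == 0) return(NA_real_)
    min(num / den, 1)
  } else {
    h <- hudson_components(g1$n, g1$p, g2$n, g2$p)
    if (!any(h$usable)) return(NA_real_)
    den <- sum(h$den[h$usable])
    if (den == 0) return(NA_real_)
    min(sum(h$num[h$usable]) / den, 1)
  }
}

#' Genome-wide window scan of diversity, Fst and ROD
#'
#' Tiles each chromosome with windows of `window_size` bp starting at
#' position 1 in steps of `step` (the default `step = window_size` gives
#' non-overlapping windows), then computes for every window: the number of
#' variant sites, per-bp nucleotide diversity of the migratory and
#' freshwater groups, Weir-Cockerham Fst, and ROD. The final window of a
#' chromosome may be shorter than `window_size`; it is kept and flagged
#' `partial`. Windows with fewer than `min_sites` variants are flagged
#' ineligible — reported, but excluded from downstream thresholding.
#'
#' @param ds A filtered [genotype_dataset()].
#' @param grouping Tibble with `sample_id` and `group` (labels
#'   `migratory` / `freshwater`).
#' @param window_size,step Window length and stride in bp (default 5000
#'   non-overlapping).
#' @param min_sites Minimum variant sites for a window to enter
#'   thresholding.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   absent each chromosome extends to its last variant site.
#' @param estimator Fst estimator, `"wc"` or `"hudson"`.
#' @return A tibble of class `scan_windows` with columns `chrom`, `start`,
#'   `end`, `n_sites`, `n_skipped_fst`, `pi_mig`, `pi_fw`, `fst`, `rod`,
#'   `eligible`, `partial`. Undefined statistics are `NA`.
#' @export
scan_windows <- function(ds, grouping, window_size = 5000, step = window_size,
                         min_sites = 3, chrom_lengths = NULL,
                         estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  if (window_size <= 0 || step <= 0) {
    abort("window_size and step must be positive",
      class = "sweepscan_validation_error")
  }
  gi <- group_indices(ds, grouping)
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(ds$sites$chrom)

  g1 <- group_site_summary(ds$dosages, gi$idx1)
  g2 <- group_site_summary(ds$dosages, gi$idx2)
  pi1 <- site_pi(g1$ref_count, g1$alt_count)
  pi2 <- site_pi(g2$ref_count, g2$alt_count)
  if (estimator == "wc") {
    w <- wc_components(g1$n, g1$p, g1$h, g2$n, g2$p, g2$h)
    fst_num <- ifelse(w$usable, w$a, 0)
    fst_den <- ifelse(w$usable, w$a + w$b + w$c, 0)
    fst_usable <- w$usable
  } else {
    h <- hudson_components(g1$n, g1$p, g2$n, g2$p)
    fst_num <- ifelse(h$usable, h$num, 0)
    fst_den <- ifelse(h$usable, h$den, 0)
    fst_usable <- h$usable
  }

  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    on_chrom <- which(ds$sites$chrom == ch)
    pos <- ds$sites$pos[on_chrom]
    L <- if (!is.null(chrom_lengths)) as.numeric(chrom_lengths[[ch]]) else
      if (length(pos)) max(pos) else 0
    if (L < 1) next
    starts <- seq(1, L, by = step)
    ends <- pmin(starts + window_size - 1, L)
    # sites are position-sorted within chrom: locate by binary search
    lo <- findInterval(starts - 1, pos) + 1L
    hi <- findInterval(ends, pos)
    n_sites <- pmax(hi - lo + 1L, 0L)
    stat <- function(v, from, to) {
      if (to < from) 0 else sum(v[on_chrom[from:to]], na.rm = TRUE)
    }
    pi_mig <- pi_fw <- fst <- numeric(length(starts))
    n_skip <- integer(length(starts))
    for (k in seq_along(starts)) {
      if (n_sites[k] == 0) {
        pi_mig[k] <- 0; pi_fw[k] <- 0; fst[k] <- NA_real_
        next
      }
      len <- ends[k] - starts[k] + 1
      pi_mig[k] <- stat(pi1, lo[k], hi[k]) / len
      pi_fw[k] <- stat(pi2, lo[k], hi[k]) / len
      den <- stat(fst_den, lo[k], hi[k])
      n_usable <- sum(fst_usable[on_chrom[lo[k]:hi[k]]])
      n_skip[k] <- n_sites[k] - n_usable
      fst[k] <- if (n_usable == 0 || den == 0) NA_real_ else
        min(stat(fst_num, lo[k], hi[k]) / den, 1)
    }
    out[[ci]] <- tibble(
      chrom = ch, start = as.integer(starts), end = as.integer(ends),
      n_sites = as.integer(n_sites), n_skipped_fst = n_skip,
      pi_mig = pi_mig, pi_fw = pi_fw, fst = fst,
      rod = rod(pi_fw, pi_mig),
      eligible = n_sites >= min_sites,
      partial = (ends - starts + 1) < window_size
    )
  }
  res <- bind_rows(out)
  attr(res, "window_size") <- window_size
  attr(res, "step") <- step
  attr(res, "min_sites") <- min_sites
  attr(res, "groups") <- gi$labels
  class(res) <- c("scan_windows", class(res))
  res
}

#' Write a window-scan table as TSV
#'
#' Undefined statistics serialize as `NA`.
#'
#' @param windows A [scan_windows()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  readr::write_tsv(as_tibble(windows), path, na = "NA")
  invisible(path)
}
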