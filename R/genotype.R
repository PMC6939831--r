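#' Construct a genotype dataset
#'
#' The package's central genotype container: an ordered set of samples, an
#' ordered table of biallelic SNP sites, and a samples x sites matrix of
#' alt-allele dosages (0, 1, 2, or `NA` for a missing diploid genotype).
#'
#' Coordinates are 1-based inclusive throughout the package; conversion to
#' 0-based half-open happens only in BED I/O.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single upper-case bases, `ref != alt`); `pos` strictly
#'   increasing within each `chrom`.
#' @param dosages Integer matrix, `length(sample_ids)` rows by
#'   `nrow(sites)` columns, entries in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_dataset`.
#' @examples
#' gd <- genotype_dataset(
#'   c("s1", "s2"),
#'   tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G"),
#'   matrix(c(0L, 2L), nrow = 2)
#' )
#' glance(gd)
#' @export
genotype_dataset <- function(sample_ids, sites, dosages) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort("sample ids must be unique", class = "sweepscan_validation_error")
  }
  sites <- as_tibble(sites)
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(sites))) {
    abort("`sites` needs columns chrom, pos, ref, alt",
      class = "sweepscan_validation_error")
  }
  sites <- mutate(sites,
    chrom = as.character(.data$chrom), pos = as.integer(.data$pos),
    ref = toupper(as.character(.data$ref)),
    alt = toupper(as.character(.data$alt)))
  if (nrow(sites) > 0) {
    if (any(!sites$ref %in% c("A", "C", "G", "T")) ||
        any(!sites$alt %in% c("A", "C", "G", "T"))) {
      abort("ref/alt must be single bases in {A,C,G,T}",
        class = "sweepscan_validation_error")
    }
    if (any(sites$ref == sites$alt)) {
      abort("ref and alt alleles must differ",
        class = "sweepscan_validation_error")
    }
    ord_ok <- all(tapply(sites$pos, sites$chrom, function(p) {
      length(p) < 2 || all(diff(p) > 0)
    }))
    if (!ord_ok) {
      abort("positions must be strictly increasing within each chrom",
        class = "sweepscan_validation_error")
    }
  }
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(sites)) {
    abort("dosage matrix dimensions must match samples x sites",
      class = "sweepscan_validation_error")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && any(bad < 0L | bad > 2L)) {
    abort("dosages must be 0, 1, 2 or NA",
      class = "sweepscan_validation_error")
  }
  dimnames(dosages) <- list(sample_ids, NULL)
  structure(
    list(sample_ids = sample_ids, sites = sites, dosages = dosages),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d sites (%.1f%% missing)\n",
    length(x$sample_ids), nrow(x$sites),
    100 * mean(is.na(x$dosages))
  ))
  if (nrow(x$sites)) {
    chroms <- unique(x$sites$chrom)
    cat("  chroms:", paste(head(chroms, 5), collapse = ", "),
        if (length(chroms) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) {
  c(length(x$sample_ids), nrow(x$sites))
}

#' One-row summary of a genotype dataset
#'
#' @param x A [genotype_dataset()].
#' @param ... Unused.
#' @return A one-row tibble with sample, site, chromosome and missingness
#'   summaries.
#' @method glance genotype_dataset
#' @export
glance.genotype_dataset <- function(x, ...) {
  tibble(
    n_samples = length(x$sample_ids),
    n_sites = nrow(x$sites),
    n_chroms = length(unique(x$sites$chrom)),
    missing_rate = if (length(x$dosages)) mean(is.na(x$dosages)) else NA_real_
  )
}

#' Per-site tidy view of a genotype dataset
#'
#' @param x A [genotype_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per site: coordinates, alleles, number of
#'   called genotypes, alt-allele frequency and minor-allele frequency
#'   computed from non-missing dosages.
#' @method tidy genotype_dataset
#' @export
tidy.genotype_dataset <- function(x, ...) {
  n_called <- colSums(!is.na(x$dosages))
  alt_af <- colSums(x$dosages, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  alt_af[n_called == 0] <- NA_real_
  mutate(x$sites,
    n_called = as.integer(n_called),
    alt_af = alt_af,
    maf = pmin(alt_af, 1 - alt_af)
  )
}

#' Subset a genotype dataset by site index
#'
#' @param ds A [genotype_dataset()].
#' @param idx Integer or logical index over sites.
#' @return A `genotype_dataset` with the selected sites, samples unchanged.
#' @export
subset_sites <- function(ds, idx) {
  stopifnot(inherits(ds, "genotype_dataset"))
  genotype_dataset(ds$sample_ids, ds$sites[idx, , drop = FALSE],
                   ds$dosages[, idx, drop = FALSE])
}

# Validate a sample->group table against a dataset. Both labels must occur;
# every dataset sample must be covered.
check_grouping <- function(ds, grouping) {
  grouping <- as_tibble(grouping)
  if (!all(c("sample_id", "group") %in% names(grouping))) {
    abort("grouping needs columns sample_id, group",
      class = "sweepscan_validation_error")
  }
  grouping$group <- as.character(grouping$group)
  missing_samples <- setdiff(ds$sample_ids, grouping$sample_id)
  if (length(missing_samples)) {
    abort(paste0("grouping does not cover samples: ",
                 paste(head(missing_samples, 5), collapse = ", ")),
      class = "sweepscan_validation_error")
  }
  grouping <- grouping[match(ds$sample_ids, grouping$sample_id), ]
  if (length(unique(grouping$group)) < 2) {
    abort("grouping must contain at least two groups",
      class = "sweepscan_validation_error")
  }
  grouping
}

# Row indices of the two analysis groups, in the standard order
# (migratory, freshwater). Falls back to the first two labels encountered
# when the standard names are absent.
group_indices <- function(ds, grouping,
                          labels = c("migratory", "freshwater")) {
  grouping <- check_grouping(ds, grouping)
  present <- unique(grouping$group)
  if (!all(labels %in% present)) labels <- present[1:2]
  list(
    labels = labels,
    idx1 = which(grouping$group == labels[1]),
    idx2 = which(grouping$group == labels[2])
  )
}
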