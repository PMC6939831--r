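#' Read biallelic SNP genotypes from a VCF file
#'
#' Ingests only records with a single-base REF, a single-base ALT and a GT
#' entry in FORMAT; indels, multiallelic records and GT-less records are
#' skipped and counted. GT codes map to alt-allele dosages: `0/0` -> 0,
#' `0/1`/`1/0` -> 1, `1/1` -> 2, `./.` or `.` -> missing; phased `|`
#' separators are treated as `/`; half-calls such as `./1` are treated as
#' missing because the downstream estimators need an unambiguous dosage.
#'
#' @param path Path to a VCF v4.x text file.
#' @return A [genotype_dataset()] with attribute `counts`: a list with
#'   `n_data_lines`, `n_ingested` and `n_skipped` (skip + ingest always sum
#'   to the data-line count).
#' @export
read_vcf <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) {
      abort(paste0("malformed VCF header or body in ", path, ": ",
                   conditionMessage(e)),
        class = "sweepscan_format_error")
    }
  )
  fix <- v@fix
  gt <- v@gt
  n_lines <- nrow(fix)
  if (is.null(n_lines)) n_lines <- 0L
  if (n_lines == 0L) {
    abort("VCF contains no data lines", class = "sweepscan_format_error")
  }
  if (is.null(gt) || ncol(gt) < 2L) {
    abort("VCF carries no sample genotype columns",
      class = "sweepscan_format_error")
  }
  sample_ids <- colnames(gt)[-1]

  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  has_gt <- vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  keep <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & has_gt
  n_skipped <- sum(!keep)
  if (!any(keep)) {
    abort("no biallelic SNP records with GT found",
      class = "sweepscan_format_error")
  }

  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  ref <- ref[keep]
  alt <- alt[keep]
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate (chrom,pos) record: ", dup),
      class = "sweepscan_validation_error")
  }
  unsorted <- tapply(pos, chrom, function(p) length(p) > 1 && any(diff(p) <= 0))
  if (any(unlist(unsorted))) {
    abort("VCF records are not position-sorted within chromosome",
      class = "sweepscan_validation_error")
  }

  # GT is the first sub-field per VCF spec when present in FORMAT.
  # vcfR surfaces fully missing genotype fields as NA.
  gt_raw <- gt[keep, -1, drop = FALSE]
  gt_field <- matrix(gsub("|", "/", sub(":.*$", "", gt_raw), fixed = TRUE),
                     nrow = sum(keep), ncol = length(sample_ids))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "./." = NA_integer_, "." = NA_integer_,
           "./0" = NA_integer_, "0/." = NA_integer_,
           "./1" = NA_integer_, "1/." = NA_integer_)
  known <- is.na(gt_field) | gt_field %in% names(lut)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, , drop = TRUE]
    abort(sprintf(
      "non-diploid or unrecognized GT '%s' at %s:%d (sample %s)",
      gt_field[!known][1], chrom[bad[1]], pos[bad[1]], sample_ids[bad[2]]),
      class = "sweepscan_validation_error")
  }
  dos <- matrix(unname(lut[gt_field]), nrow = sum(keep),
                ncol = length(sample_ids))

  ds <- genotype_dataset(
    sample_ids,
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    t(dos)
  )
  attr(ds, "counts") <- list(
    n_data_lines = n_lines, n_ingested = sum(keep), n_skipped = n_skipped
  )
  if (n_skipped > 0) {
    inform(sprintf("read_vcf: skipped %d non-biallelic-SNP or GT-less record%s",
                   n_skipped, if (n_skipped == 1) "" else "s"))
  }
  ds
}

#' Write a genotype dataset as a minimal VCF
#'
#' Emits `##fileformat=VCFv4.2`, the `#CHROM` header and one GT-only record
#' per site. Re-reading a file written here and writing it again reproduces
#' the bytes exactly, so CHROM/POS/REF/ALT/GT content round-trips.
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  gt_code <- matrix("./.", nrow = nrow(ds$dosages), ncol = ncol(ds$dosages))
  gt_code[!is.na(ds$dosages) & ds$dosages == 0L] <- "0/0"
  gt_code[!is.na(ds$dosages) & ds$dosages == 1L] <- "0/1"
  gt_code[!is.na(ds$dosages) & ds$dosages == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$sample_ids), collapse = "\t")
  )
  body <- character(nrow(ds$sites))
  if (nrow(ds$sites)) {
    gt_rows <- apply(gt_code, 2, paste, collapse = "\t")
    body <- paste(ds$sites$chrom, ds$sites$pos, ".", ds$sites$ref,
                  ds$sites$alt, ".", ".", ".", "GT", gt_rows, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
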