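#' Read reference sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences, one per record,
#'   in file order; names are the header token before the first whitespace.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name: ", nm[duplicated(nm)][1]),
      class = "sweepscan_validation_error")
  }
  if (any(Biostrings::width(seqs) == 0)) {
    abort(paste0("empty FASTA record: ",
                 nm[Biostrings::width(seqs) == 0][1]),
      class = "sweepscan_validation_error")
  }
  setNames(toupper(as.character(seqs)), nm)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write genomic regions as BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention and sorted by (chrom, start). An empty region set
#' produces a file holding only a header comment.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) {
    writeLines("#chrom\tstart\tend", path)
    return(invisible(path))
  }
  regions <- arrange(regions, .data$chrom, .data$start)
  by_chrom <- split(regions, regions$chrom)
  overlapping <- any(vapply(by_chrom, function(r) {
    nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])
  }, logical(1)))
  if (overlapping) {
    warn("write_bed: overlapping intervals on the same chromosome")
  }
  name <- if ("name" %in% names(regions)) regions$name else
    paste0("region_", seq_len(nrow(regions)))
  writeLines(
    paste(regions$chrom, regions$start - 1L, regions$end, name, sep = "\t"),
    path
  )
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path Path to a BED file (comment lines starting with `#` ignored).
#' @return Tibble with `chrom`, `start`, `end` in the package's 1-based
#'   inclusive convention, plus `name` when a fourth column is present.
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)) + 1L,
    end = as.integer(vapply(parts, `[`, character(1), 3))
  )
  if (all(lengths(parts) >= 4)) {
    out$name <- vapply(parts, `[`, character(1), 4)
  }
  out
}
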