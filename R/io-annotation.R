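#' Construct a gene annotation table
#'
#' @param genes Data frame with columns `gene_id` (unique), `chrom`, `start`,
#'   `end` (1-based inclusive, `start <= end`), `strand` (`+` or `-`) and
#'   optionally `cds`, a list column of tibbles with `start`/`end` columns.
#'   CDS intervals must lie within the gene and be pairwise disjoint; they
#'   are stored in 5'->3' transcription order (descending coordinates on the
#'   minus strand).
#' @return A tibble of class `gene_annotation`.
#' @export
gene_annotation <- function(genes) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    abort("gene annotation needs gene_id, chrom, start, end, strand",
      class = "sweepscan_validation_error")
  }
  genes <- mutate(genes,
    gene_id = as.character(.data$gene_id),
    chrom = as.character(.data$chrom),
    start = as.integer(.data$start), end = as.integer(.data$end),
    strand = as.character(.data$strand))
  if (anyDuplicated(genes$gene_id)) {
    abort("gene ids must be unique", class = "sweepscan_validation_error")
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    abort(paste0("unknown strand: ",
                 genes$strand[!genes$strand %in% c("+", "-")][1]),
      class = "sweepscan_validation_error")
  }
  if (any(genes$start > genes$end)) {
    abort("gene start must be <= end", class = "sweepscan_validation_error")
  }
  if (!"cds" %in% names(genes)) {
    genes$cds <- rep(list(tibble(start = integer(), end = integer())),
                     nrow(genes))
  }
  for (i in seq_len(nrow(genes))) {
    cds <- as_tibble(genes$cds[[i]])
    if (nrow(cds) == 0) {
      genes$cds[[i]] <- tibble(start = integer(), end = integer())
      next
    }
    cds <- mutate(cds, start = as.integer(.data$start),
                  end = as.integer(.data$end))
    if (any(cds$start > cds$end) ||
        any(cds$start < genes$start[i]) || any(cds$end > genes$end[i])) {
      abort(paste0("CDS outside gene body for ", genes$gene_id[i]),
        class = "sweepscan_validation_error")
    }
    cds <- cds[order(cds$start), ]
    if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)])) {
      abort(paste0("overlapping CDS intervals in ", genes$gene_id[i]),
        class = "sweepscan_validation_error")
    }
    # 5'->3' transcription order: ascending on +, descending on -.
    if (genes$strand[i] == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
    genes$cds[[i]] <- cds
  }
  class(genes) <- c("gene_annotation", class(genes))
  genes
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 input uses `gene` features plus `CDS` features linked to their gene
#' through `Parent` (directly, or via an intermediate mRNA feature). BED6
#' input yields genes without CDS; its 0-based half-open coordinates are
#' converted to the package's 1-based inclusive convention.
#'
#' @param path Input file path.
#' @param fmt `"gff3"` or `"bed"`.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, fmt = c("gff3", "bed")) {
  fmt <- match.arg(fmt)
  if (fmt == "bed") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 6)) {
      abort("BED6 requires six columns", class = "sweepscan_format_error")
    }
    f <- function(k) vapply(parts, `[`, character(1), k)
    return(gene_annotation(tibble(
      gene_id = f(4), chrom = f(1),
      start = as.integer(f(2)) + 1L, end = as.integer(f(3)),
      strand = f(6)
    )))
  }

  g <- as.data.frame(rtracklayer::readGFF(path))
  g$type <- as.character(g$type)
  genes <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(genes)) {
    abort("GFF3 contains no gene features", class = "sweepscan_format_error")
  }
  gene_ids <- as.character(genes$ID)
  # Map transcript-level features to their parent gene so CDS may attach
  # through an mRNA layer.
  first_parent <- function(p) {
    if (is.list(p)) vapply(p, function(x) {
      if (length(x)) as.character(x[[1]]) else NA_character_
    }, character(1)) else as.character(p)
  }
  tx <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_to_gene <- setNames(first_parent(tx$Parent), as.character(tx$ID))

  cds <- g[g$type == "CDS", , drop = FALSE]
  ann <- tibble(
    gene_id = gene_ids,
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start), end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  cds_by_gene <- rep(list(tibble(start = integer(), end = integer())),
                     nrow(ann))
  if (nrow(cds)) {
    parent <- first_parent(cds$Parent)
    owner <- ifelse(parent %in% gene_ids, parent,
                    unname(tx_to_gene[parent]))
    if (any(is.na(owner)) || any(!owner %in% gene_ids)) {
      bad <- parent[is.na(owner) | !owner %in% gene_ids][1]
      abort(paste0("CDS Parent does not resolve to a gene: ", bad),
        class = "sweepscan_validation_error")
    }
    for (gid in unique(owner)) {
      sel <- owner == gid
      cds_by_gene[[match(gid, gene_ids)]] <-
        tibble(start = as.integer(cds$start[sel]),
               end = as.integer(cds$end[sel]))
    }
  }
  ann$cds <- cds_by_gene
  gene_annotation(ann)
}

#' Write a gene annotation as GFF3
#'
#' @param ann A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ann))) {
    lines <- c(lines, paste(
      ann$chrom[i], "sweepscan", "gene", ann$start[i], ann$end[i], ".",
      ann$strand[i], ".", paste0("ID=", ann$gene_id[i]), sep = "\t"))
    cds <- ann$cds[[i]]
    if (nrow(cds)) {
      cds <- cds[order(cds$start), ]
      lines <- c(lines, paste(
        ann$chrom[i], "sweepscan", "CDS", cds$start, cds$end, ".",
        ann$strand[i], "0", paste0("Parent=", ann$gene_id[i]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
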