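#' Empirical quantile threshold
#'
#' Linear interpolation between order statistics (the common "type 7"
#' rule). `NA` entries are dropped before computation; fewer than 20
#' defined values triggers a warning since the tail quantile is then
#' poorly determined.
#'
#' @param values Numeric vector.
#' @param q Quantile in `[0, 1]` (default 0.95, the top-5% rule).
#' @return The threshold (numeric scalar).
#' @examples
#' percentile_threshold(1:20)   # 19.05
#' percentile_threshold(1:100)  # 95.05: exactly 5 values exceed it
#' @export
percentile_threshold <- function(values, q = 0.95) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    abort("no defined values to threshold",
      class = "sweepscan_validation_error")
  }
  if (length(values) < 20) {
    warn(sprintf("percentile_threshold: only %d defined values",
                 length(values)))
  }
  unname(quantile(values, probs = q, type = 7, names = FALSE))
}

#' Select windows jointly exceeding Fst and ROD thresholds
#'
#' Keeps eligible windows with `fst > thr_fst` and `rod > thr_rod` — both
#' strictly, so a window sitting exactly on a threshold is not selected.
#' Windows with undefined ROD are never selected.
#'
#' @param stats A [scan_windows()] tibble.
#' @param thr_fst,thr_rod Finite selection thresholds.
#' @return The selected rows of `stats`.
#' @export
select_windows <- function(stats, thr_fst, thr_rod) {
  if (!is.finite(thr_fst) || !is.finite(thr_rod)) {
    abort("thresholds must be finite", class = "sweepscan_validation_error")
  }
  filter(as_tibble(stats),
    .data$eligible,
    !is.na(.data$fst), !is.na(.data$rod),
    .data$fst > thr_fst, .data$rod > thr_rod)
}

#' Merge selected windows into sweep regions
#'
#' Windows on the same chromosome whose gap is at most `max_gap` bp fuse
#' into one region carrying the member-window count and the member maxima
#' of Fst and ROD. With `max_gap = 0` only touching/adjacent windows merge,
#' so regions cover exactly the union of the selected windows.
#'
#' @param selected Selected-window tibble (as from [select_windows()]).
#' @param max_gap Maximum between-window gap in bp to bridge.
#' @return Tibble with `chrom`, `start`, `end`, `n_windows`, `max_fst`,
#'   `max_rod`.
#' @export
merge_windows <- function(selected, max_gap = 0) {
  selected <- arrange(as_tibble(selected), .data$chrom, .data$start)
  if (nrow(selected) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), max_fst = numeric(),
                  max_rod = numeric()))
  }
  gap <- c(Inf, ifelse(
    selected$chrom[-1] == selected$chrom[-nrow(selected)],
    selected$start[-1] - selected$end[-nrow(selected)] - 1, Inf))
  region_id <- cumsum(gap > max_gap)
  selected |>
    mutate(.region = region_id) |>
    group_by(.data$.region, .data$chrom) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(),
      max_fst = max(.data$fst), max_rod = max(.data$rod),
      .groups = "drop"
    ) |>
    select(!".region") |>
    arrange(.data$chrom, .data$start)
}

#' Candidate genes overlapping sweep regions
#'
#' @param regions Region tibble (`chrom`, `start`, `end`), e.g. from
#'   [merge_windows()].
#' @param ann A [gene_annotation()].
#' @param min_overlap_bp Minimum overlap in bp for a gene to count as
#'   inside a region (default 1).
#' @return Tibble with one row per candidate gene (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `regions` — a comma-separated list of the
#'   `chrom:start-end` regions it overlaps — and `n_regions`), sorted by
#'   chromosome and start.
#' @export
genes_in_regions <- function(regions, ann, min_overlap_bp = 1) {
  stopifnot(inherits(ann, "gene_annotation"))
  regions <- as_tibble(regions)
  hits <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    same <- regions[regions$chrom == ann$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    ov <- pmin(same$end, ann$end[i]) - pmax(same$start, ann$start[i]) + 1
    sel <- ov >= min_overlap_bp
    if (any(sel)) {
      hits[[i]] <- sprintf("%s:%d-%d", same$chrom[sel],
                           same$start[sel], same$end[sel])
    }
  }
  keep <- lengths(hits) > 0
  tibble(
    gene_id = ann$gene_id[keep], chrom = ann$chrom[keep],
    start = ann$start[keep], end = ann$end[keep],
    strand = ann$strand[keep],
    regions = vapply(hits[keep], paste, character(1), collapse = ","),
    n_regions = lengths(hits[keep])
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Full sweep call from a window scan
#'
#' Convenience wrapper: thresholds Fst and ROD at the `q` quantile over
#' eligible windows (both thresholds from the same window set), selects
#' windows jointly exceeding both, merges them into regions, and (when an
#' annotation is given) lists candidate genes.
#'
#' @param stats A [scan_windows()] tibble.
#' @param q Quantile for both thresholds (default 0.95).
#' @param max_gap Region merge gap in bp.
#' @param ann Optional [gene_annotation()].
#' @param min_overlap_bp Minimum gene/region overlap in bp.
#' @return List of class `sweep_call`: `thresholds` (named numeric),
#'   `selected` (window tibble), `regions`, and `genes` (or `NULL`).
#' @export
call_sweeps <- function(stats, q = 0.95, max_gap = 0, ann = NULL,
                        min_overlap_bp = 1) {
  eligible <- filter(as_tibble(stats), .data$eligible)
  thr_fst <- percentile_threshold(eligible$fst, q)
  thr_rod <- percentile_threshold(eligible$rod, q)
  selected <- select_windows(stats, thr_fst, thr_rod)
  regions <- merge_windows(selected, max_gap = max_gap)
  genes <- if (!is.null(ann)) {
    genes_in_regions(regions, ann, min_overlap_bp = min_overlap_bp)
  }
  structure(
    list(thresholds = c(fst = thr_fst, rod = thr_rod),
         selected = selected, regions = regions, genes = genes),
    class = "sweep_call"
  )
}

#' @export
print.sweep_call <- function(x, ...) {
  cat(sprintf(
    "<sweep_call> thresholds fst > %.4f, rod > %.4f; %d windows -> %d regions%s\n",
    x$thresholds[["fst"]], x$thresholds[["rod"]],
    nrow(x$selected), nrow(x$regions),
    if (!is.null(x$genes)) sprintf("; %d candidate genes", nrow(x$genes))
    else ""
  ))
  invisible(x)
}

#' @rdname call_sweeps
#' @param x A `sweep_call`.
#' @param ... Unused.
#' @method tidy sweep_call
#' @export
tidy.sweep_call <- function(x, ...) x$regions

#' @rdname call_sweeps
#' @method glance sweep_call
#' @export
glance.sweep_call <- function(x, ...) {
  tibble(
    thr_fst = x$thresholds[["fst"]], thr_rod = x$thresholds[["rod"]],
    n_selected = nrow(x$selected), n_regions = nrow(x$regions),
    n_genes = if (is.null(x$genes)) NA_integer_ else nrow(x$genes)
  )
}
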