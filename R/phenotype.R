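#' Classify water type from an otolith Sr:Ca ratio
#'
#' Thresholds follow the standard otolith-microchemistry reading:
#' freshwater at Sr:Ca (x1000) at most 3.0, brackish above 3.0 up to 7.0,
#' seawater above 7.0. Vectorized.
#'
#' @param ratio Non-negative Sr:Ca ratios (x1000).
#' @return Character vector in `{freshwater, brackish, seawater}`.
#' @export
classify_water <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) {
    abort("Sr:Ca ratios must be non-negative",
      class = "sweepscan_validation_error")
  }
  ifelse(ratio <= 3.0, "freshwater",
         ifelse(ratio <= 7.0, "brackish", "seawater"))
}

#' Call resident vs migratory life history from a Sr:Ca transect
#'
#' Ratios are smoothed with a 3-point running median, each point is
#' classified with [classify_water()], and the fish is called migratory
#' when any run of at least `min_run` consecutive non-freshwater points
#' exists — a constant freshwater signal reads as resident, while
#' alternating freshwater/brackish(/seawater) bands read as migratory.
#' The run-length rule rejects isolated noise spikes.
#'
#' @param transect Tibble with `distance_um` (strictly increasing) and
#'   `sr_ca_ratio`, at least 10 points.
#' @param min_run Minimum consecutive non-freshwater run (default 3).
#' @return `"resident"` or `"migratory"`.
#' @export
classify_life_history <- function(transect, min_run = 3) {
  transect <- as_tibble(transect)
  if (nrow(transect) < 10) {
    abort("transect needs at least 10 points",
      class = "sweepscan_validation_error")
  }
  if (any(diff(transect$distance_um) <= 0)) {
    abort("transect distances must be strictly increasing",
      class = "sweepscan_validation_error")
  }
  smoothed <- runmed(transect$sr_ca_ratio, 3, endrule = "median")
  marine <- classify_water(smoothed) != "freshwater"
  runs <- rle(marine)
  if (any(runs$values & runs$lengths >= min_run)) "migratory" else "resident"
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = ct_target - ct_ref`; `ddCt` subtracts the arithmetic
#' mean dCt of the calibrator group; relative quantity `RQ = 2^(-ddCt)`.
#' By construction the calibrator group's geometric-mean RQ is exactly 1.
#'
#' @param q Tibble with `sample_id`, `group`, `gene`, `ct_target`,
#'   `ct_ref` (Ct values in cycles; records with a missing Ct are dropped
#'   with a warning).
#' @param gene Target gene to analyse (default: the only gene present).
#' @param calibrator_group Group used as calibrator (default
#'   `"freshwater"`).
#' @return List of class `ddct_result`: `samples` (per-sample tibble with
#'   `dct`, `ddct`, `rq`) and `groups` (per-group tibble with `n`,
#'   `geo_mean_rq`).
#' @export
ddct_relative_expression <- function(q, gene = NULL,
                                     calibrator_group = "freshwater") {
  q <- as_tibble(q)
  if (is.null(gene)) {
    gene <- unique(q$gene)
    if (length(gene) != 1) {
      abort("multiple genes present; pick one with `gene`",
        class = "sweepscan_validation_error")
    }
  }
  q <- filter(q, .data$gene == !!gene)
  dropped <- !complete.cases(q[, c("ct_target", "ct_ref")])
  if (any(dropped)) {
    warn(sprintf("ddct: %d record(s) with missing Ct excluded",
                 sum(dropped)))
    q <- q[!dropped, ]
  }
  if (!any(q$group == calibrator_group)) {
    abort("calibrator group has no records for this gene",
      class = "sweepscan_validation_error")
  }
  q$dct <- q$ct_target - q$ct_ref
  cal_mean <- mean(q$dct[q$group == calibrator_group])
  q$ddct <- q$dct - cal_mean
  q$rq <- 2^(-q$ddct)
  groups <- q |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              geo_mean_rq = exp(mean(log(.data$rq))), .groups = "drop")
  structure(list(samples = q, groups = groups, gene = gene,
                 calibrator = calibrator_group),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> gene %s, calibrator %s\n", x$gene,
              x$calibrator))
  print(x$groups)
  invisible(x)
}

#' @rdname ddct_relative_expression
#' @param x A `ddct_result`.
#' @param ... Unused.
#' @method tidy ddct_result
#' @export
tidy.ddct_result <- function(x, ...) x$samples

#' @rdname ddct_relative_expression
#' @method glance ddct_result
#' @export
glance.ddct_result <- function(x, ...) {
  tidyr::pivot_wider(x$groups, names_from = "group",
                     values_from = c("n", "geo_mean_rq"))
}

#' Two-sample t test
#'
#' Pooled-variance Student t by default (two-sided p on n1 + n2 - 2 df),
#' with the Welch variant behind the same interface. Degenerate
#' zero-variance inputs are resolved by convention: equal means give
#' p = 1, unequal means p = 0, both flagged `degenerate`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return Tibble with `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 values",
      class = "sweepscan_validation_error")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(t = 0, df = length(x) + length(y) - 2, p = 1,
                    degenerate = TRUE))
    }
    return(tibble(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = 0, degenerate = TRUE))
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "student"))
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value, degenerate = FALSE)
}

#' Flag differentially expressed genes by fold change and t test
#'
#' Per gene, the fold change is the larger group mean divided by the
#' smaller (direction recorded), and the p-value comes from
#' [two_sample_t()] on `log2(x + 1)`-transformed values. A gene is
#' flagged when `p < alpha` and `fold > fold_thr` — both conditions
#' required.
#'
#' @param expr Expression table: first column `gene_id`, remaining columns
#'   one per sample.
#' @param grouping Tibble with `sample_id`, `group` covering the
#'   expression columns; both groups need >= 2 samples.
#' @param fold_thr Fold-change threshold (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @return Tibble with `gene_id`, per-group means, `fold`, `direction`
#'   (`up` = first group higher), `p`, `q`, `flagged`.
#' @export
call_deg <- function(expr, grouping, fold_thr = 2, alpha = 0.05,
                     variant = "student") {
  expr <- as_tibble(expr)
  grouping <- as_tibble(grouping)
  samples <- setdiff(names(expr), "gene_id")
  grouping <- grouping[match(samples, grouping$sample_id), ]
  if (anyNA(grouping$sample_id)) {
    abort("grouping must cover every expression column",
      class = "sweepscan_validation_error")
  }
  labels <- unique(grouping$group)
  if (length(labels) != 2) {
    abort("expression grouping must have exactly two groups",
      class = "sweepscan_validation_error")
  }
  idx1 <- which(grouping$group == labels[1])
  idx2 <- which(grouping$group == labels[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort("both groups need at least 2 samples",
      class = "sweepscan_validation_error")
  }
  mat <- as.matrix(expr[, samples])
  res <- lapply(seq_len(nrow(expr)), function(i) {
    v1 <- mat[i, idx1]
    v2 <- mat[i, idx2]
    m1 <- mean(v1); m2 <- mean(v2)
    all_zero <- all(c(v1, v2) == 0)
    fold <- if (all_zero) 1 else
      if (min(m1, m2) == 0) Inf else max(m1, m2) / min(m1, m2)
    tt <- two_sample_t(log2(v1 + 1), log2(v2 + 1), variant = variant)
    tibble(
      gene_id = expr$gene_id[i], mean_1 = m1, mean_2 = m2,
      fold = fold, direction = if (m1 >= m2) "up" else "down",
      p = tt$p, degenerate = tt$degenerate | all_zero,
      flagged = !all_zero & tt$p < alpha & fold > fold_thr
    )
  })
  out <- bind_rows(res)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", labels[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", labels[2])
  out$q <- p.adjust(out$p, method = "BH")
  out
}
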