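#' Pairwise 1-IBS genetic distances
#'
#' For each sample pair, over the sites where both genotypes are called,
#' the per-site distance is `|dosage_i - dosage_j| / 2` (the fraction of
#' allele mismatches between the two diploid genotypes); the pair distance
#' is the mean over those sites. Each pair is normalized by its own
#' non-missing site count — PLINK's "flat-missing" behaviour.
#'
#' @param ds A [genotype_dataset()] with at least two samples.
#' @return A symmetric numeric matrix in `[0, 1]` with zero diagonal,
#'   dimnames = sample ids.
#' @export
ibs_distance <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- length(ds$sample_ids)
  if (n < 2) {
    abort("need at least two samples", class = "sweepscan_validation_error")
  }
  X <- ds$dosages
  called <- !is.na(X)
  A0 <- called & X == 0L
  A1 <- called & X == 1L
  A2 <- called & X == 2L
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  storage.mode(called) <- "double"
  shared <- tcrossprod(called)
  # |di-dj| summed over shared sites: 1 for {0,1} and {1,2} pairs, 2 for {0,2}
  m01 <- tcrossprod(A0, A1)
  m12 <- tcrossprod(A1, A2)
  m02 <- tcrossprod(A0, A2)
  total <- (m01 + t(m01) + m12 + t(m12)) + 2 * (m02 + t(m02))
  if (any(shared[upper.tri(shared)] == 0)) {
    bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    abort(sprintf("samples %s and %s share no non-missing sites",
                  ds$sample_ids[bad[1]], ds$sample_ids[bad[2]]),
      class = "sweepscan_validation_error")
  }
  d <- total / (2 * shared)
  diag(d) <- 0
  dimnames(d) <- list(ds$sample_ids, ds$sample_ids)
  d
}

check_distance_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort("distance input must be a square matrix",
      class = "sweepscan_validation_error")
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    abort("distance matrix must be symmetric with zero diagonal",
      class = "sweepscan_validation_error")
  }
  D
}

nwk_quote <- function(x) {
  ifelse(grepl("^[A-Za-z0-9_.]+$", x),
         x, paste0("'", gsub("'", "''", x, fixed = TRUE), "'"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j`, with the standard branch-length and
#' distance-update formulas, ending in a degree-3 hub. Exact `Q` ties break
#' to the lowest (row, column) index pair. Negative branch lengths are
#' clamped to zero, the total clamped deficit being recorded on the result.
#'
#' @param D Square symmetric distance matrix (dimnames = leaf labels) or a
#'   `dist` object; at least 3 taxa.
#' @return An unrooted [ape::phylo] tree with attribute `clamped`
#'   (total branch length removed by clamping, 0 for additive input).
#' @export
neighbor_joining <- function(D) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) {
    abort("neighbor joining needs at least 3 taxa",
      class = "sweepscan_validation_error")
  }
  fmt <- function(x) sprintf("%.17g", x)
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- clamped - x
      0
    } else x
  }
  frag <- nwk_quote(rownames(D))
  Dm <- unname(D)
  while (nrow(Dm) > 3) {
    m <- nrow(Dm)
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- clamp(Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- clamp(Dm[i, j] - (Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",",
                       frag[j], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- (Dm[i, keep] + Dm[j, keep] - Dm[i, j]) / 2
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[keep], new_frag)
  }
  la <- clamp((Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2)
  lb <- clamp((Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2)
  lc <- clamp((Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2)
  txt <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = txt)
  if (clamped > 0) {
    inform(sprintf("neighbor_joining: clamped %.3g of negative branch length",
                   clamped))
  }
  attr(tree, "clamped") <- clamped
  tree
}

# Leaf labels below each node of a rooted ape tree (root = ntip + 1).
leaves_under <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  res <- vector("list", n_node)
  for (i in seq_len(n_tip)) res[[i]] <- tree$tip.label[i]
  # children appear after parents in postorder traversal
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

#' Two-group split at the longest internal edge
#'
#' Removes the internal edge of maximal length and returns the induced
#' leaf bipartition, smaller side first. Ties go to the edge whose smaller
#' side holds more leaves, then to the lexicographically smallest smaller
#' side. This operationalizes the visual two-cluster reading of an NJ tree
#' of a structured sample.
#'
#' @param tree An [ape::phylo] with at least 4 leaves and at least one
#'   internal edge.
#' @return List with sorted character vectors `smaller` and `larger`.
#' @export
split_by_longest_edge <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 4) {
    abort("need at least 4 leaves", class = "sweepscan_validation_error")
  }
  internal <- which(tree$edge[, 1] > n_tip & tree$edge[, 2] > n_tip)
  if (!length(internal)) {
    abort("tree has no internal edge (star topology)",
      class = "sweepscan_validation_error")
  }
  lu <- leaves_under(tree)
  len <- tree$edge.length[internal]
  cand <- internal[len == max(len)]
  pick_side <- function(e) {
    below <- sort(lu[[tree$edge[e, 2]]], method = "radix")
    above <- sort(setdiff(tree$tip.label, below), method = "radix")
    if (length(below) < length(above) ||
        (length(below) == length(above) &&
         paste(below, collapse = "\r") <= paste(above, collapse = "\r"))) {
      list(smaller = below, larger = above)
    } else {
      list(smaller = above, larger = below)
    }
  }
  sides <- lapply(cand, pick_side)
  sizes <- vapply(sides, function(s) length(s$smaller), integer(1))
  sides <- sides[sizes == max(sizes)]
  keys <- vapply(sides, function(s) paste(s$smaller, collapse = "\r"),
                 character(1))
  sides[[order(keys, method = "radix")[1]]]
}

#' Grouping table from an NJ tree split
#'
#' Labels the smaller side of [split_by_longest_edge()] as the freshwater
#' group and the larger side as migratory (the minority of a partially
#' migratory cohort being the resident fraction). Any user-supplied
#' grouping overrides this call downstream.
#'
#' @param tree An [ape::phylo].
#' @return Tibble with `sample_id`, `group`.
#' @export
tree_grouping <- function(tree) {
  s <- split_by_longest_edge(tree)
  tibble(
    sample_id = c(s$smaller, s$larger),
    group = rep(c("freshwater", "migratory"),
                c(length(s$smaller), length(s$larger)))
  )
}

#' Write a labeled square distance matrix as TSV
#'
#' @param D Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  df <- as_tibble(as.data.frame(D), rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}
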