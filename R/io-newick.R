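#' Serialize a phylogenetic tree as Newick text
#'
#' Output is deterministic: at every internal node children are ordered by
#' the lexicographically smallest leaf label they contain, branch lengths
#' are printed with a fixed number of decimal places, and labels containing
#' whitespace or punctuation are single-quoted (embedded quotes doubled).
#'
#' @param tree An [ape::phylo] object with non-negative edge lengths.
#' @param digits Decimal places for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2,C:3);")
#' write_newick(tr)
#' @export
write_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("edge lengths must be non-negative",
      class = "sweepscan_validation_error")
  }
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  quote_label <- function(x) {
    if (grepl("^[A-Za-z0-9_.]+$", x)) x
    else paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  }
  min_leaf <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    sort(vapply(tree$edge[kids[[as.character(node)]], 2], min_leaf,
                character(1)), method = "radix")[1]
  }
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) "" else
      paste0(":", sprintf(paste0("%.", digits, "f"), tree$edge.length[e]))
  }
  render <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    e <- kids[[as.character(node)]]
    e <- e[order(vapply(tree$edge[e, 2], min_leaf, character(1)),
                 method = "radix")]
    paste0("(", paste0(vapply(tree$edge[e, 2], render, character(1)),
                       vapply(e, fmt_len, character(1)), collapse = ","),
           ")")
  }
  paste0(render(root), ";")
}

#' Parse Newick text into a tree
#'
#' Thin wrapper over [ape::read.tree] so the package's round trip is
#' explicit in one place.
#'
#' @param text Newick string.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}
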