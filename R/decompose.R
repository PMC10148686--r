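# Backbone/query splitting by sequence length, centroid-edge decomposition of
# the backbone tree, and ensemble selection (disjoint / disjoint+bb / upp).

#' Split sequences into backbone and query sets by length
#'
#' Full-length sequences form the backbone; the rest become queries.  Two
#' policies are supported: `fraction` keeps sequences whose ungapped length
#' is within `fraction * median` of the median length, and `threshold` keeps
#' sequences at least `threshold` letters long (the policy used for curated
#' rRNA datasets, e.g. a 1250 nt cutoff for 23S).
#'
#' @param seqs named character vector of (possibly gapped) sequences.
#' @param fraction allowed relative deviation from the median ungapped length
#'   (default 0.25); ignored when `threshold` is given.
#' @param threshold absolute minimum ungapped length for backbone membership,
#'   or `NULL` to use the fraction policy.
#' @return list with elements `backbone` and `query`, each a character vector
#'   of ids.
#' @export
split_by_length <- function(seqs, fraction = 0.25, threshold = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to split")
  len <- nchar(degap(seqs))
  if (is.null(threshold)) {
    med <- stats::median(len)
    keep <- abs(len - med) <= fraction * med
  } else {
    keep <- len >= threshold
  }
  if (!any(keep)) {
    stop("no sequences qualify as backbone under this policy; ",
         "use a larger fraction or a lower threshold")
  }
  list(backbone = names(seqs)[keep], query = names(seqs)[!keep])
}

# leaf labels below the child node of every edge, as a list indexed by edge
edge_leaf_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  # postorder: children before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1L]; ch <- ord[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) below[[tree$edge[k, 2L]]])
}

# key for deterministic lexicographic comparison of label sets: joining the
# sorted labels with \1 (below any printable char) makes string order agree
# with elementwise order of the sorted vectors; radix sorting and key_less
# use C-locale byte order so results do not depend on the session locale
label_key <- function(labels) {
  paste(sort(labels, method = "radix"), collapse = "\1")
}

key_less_eq <- function(a, b) {
  sort(c(a, b), method = "radix")[1L] == a
}

#' Find the centroid edge of a tree
#'
#' The centroid edge is the edge whose removal splits the leaf set into the
#' two most balanced parts, i.e. it minimizes `max(|A|, |B|)` over the leaf
#' bipartition `(A, B)` induced by each edge.  Ties are broken
#' deterministically by the lexicographically smallest sorted label list of
#' the smaller side.  Branch lengths are ignored; multifurcations are fine.
#'
#' @param tree an [ape::phylo] tree with at least 2 leaves.
#' @return list with `A` (leaves below the chosen edge's child), `B` (the
#'   rest), `max_side`, and `edge` (row index into `tree$edge`).
#' @export
find_centroid_edge <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("cannot decompose a tree with fewer than 2 leaves")
  all_tips <- tree$tip.label
  sets <- edge_leaf_sets(tree)
  best <- NULL
  for (k in seq_along(sets)) {
    A <- sets[[k]]
    if (length(A) == 0L || length(A) == ntip) next  # degenerate bipartition
    B <- setdiff(all_tips, A)
    m <- max(length(A), length(B))
    small <- if (length(A) < length(B)) A
             else if (length(B) < length(A)) B
             else if (key_less_eq(label_key(A), label_key(B))) A else B
    key <- label_key(small)
    if (is.null(best) || m < best$max_side ||
        (m == best$max_side && key != best$key &&
           key_less_eq(key, best$key))) {
      best <- list(A = A, B = B, max_side = m, key = key, edge = k)
    }
  }
  if (is.null(best)) stop("tree has no internal bipartition to delete")
  best$key <- NULL
  best
}

#' Centroid-edge decomposition of a backbone tree
#'
#' Recursively deletes centroid edges until every subset has at most
#' `max_size` leaves.  Every intermediate subset is recorded, including the
#' full leaf set (level 0); the recursion's leaves are the `minimal` subsets,
#' which are pairwise disjoint and partition the full leaf set.
#'
#' @param tree an [ape::phylo] tree whose tip labels are the backbone ids.
#' @param max_size maximum size of a minimal subset (default 50).
#' @return an object of class `"decomposition"`: list of subset records
#'   (`ids`, `level`, `parent`, `minimal`) plus `max_size`.
#' @export
decompose_tree <- function(tree, max_size = 50L) {
  stopifnot(inherits(tree, "phylo"))
  if (max_size < 2L) stop("max_size must be at least 2")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  subsets <- list()
  recurse <- function(tips, level, parent) {
    idx <- length(subsets) + 1L
    minimal <- length(tips) <= max_size
    subsets[[idx]] <<- list(ids = tips, level = level, parent = parent,
                            minimal = minimal)
    if (minimal) {
      if (length(tips) == 1L) {
        warning("decomposition produced a single-sequence subset (",
                tips, "); its profile HMM is degenerate but well-defined")
      }
      return(invisible(NULL))
    }
    sub <- if (length(tips) == length(tree$tip.label)) tree
           else ape::keep.tip(tree, tips)
    split <- find_centroid_edge(sub)
    recurse(split$A, level + 1L, idx)
    recurse(split$B, level + 1L, idx)
  }
  recurse(tree$tip.label, 0L, NA_integer_)
  structure(list(subsets = subsets, max_size = max_size), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  sizes <- vapply(x$subsets, function(s) length(s$ids), integer(1))
  minimal <- vapply(x$subsets, `[[`, logical(1), "minimal")
  cat(sprintf("Centroid-edge decomposition: %d subsets (%d minimal), max_size %d\n",
              length(sizes), sum(minimal), x$max_size))
  cat("  minimal subset sizes:", paste(sizes[minimal], collapse = ", "), "\n")
  invisible(x)
}

#' Select the HMM ensemble from a decomposition
#'
#' @param dec a [decompose_tree()] result.
#' @param mode `"disjoint"` (minimal subsets only; the default ensemble),
#'   `"disjoint+bb"` (minimal subsets plus the full backbone set), or
#'   `"upp"` (every subset recorded by the decomposition, a hierarchical
#'   laminar family).
#' @return an object of class `"ensemble_spec"`: `mode`, `subsets` (list of
#'   id vectors) and `sizes` (sequence counts per subset, the weight priors).
#' @export
select_ensemble <- function(dec, mode = c("disjoint", "disjoint+bb", "upp")) {
  stopifnot(inherits(dec, "decomposition"))
  mode <- match.arg(mode)
  minimal <- Filter(function(s) s$minimal, dec$subsets)
  subsets <- switch(mode,
    "disjoint" = lapply(minimal, `[[`, "ids"),
    "disjoint+bb" = {
      full <- dec$subsets[[1L]]$ids
      mins <- lapply(minimal, `[[`, "ids")
      if (dec$subsets[[1L]]$minimal) mins else c(list(full), mins)
    },
    "upp" = lapply(dec$subsets, `[[`, "ids"))
  structure(list(mode = mode, subsets = subsets,
                 sizes = vapply(subsets, length, integer(1))),
            class = "ensemble_spec")
}
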