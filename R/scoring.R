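# Sum-of-pairs alignment error: SPFN / SPFP over pairwise letter homologies.

#' Enumerate pairwise homologies of an alignment
#'
#' A homology is an unordered pair of two uppercase letters in the same
#' column, identified by `(id, residue index)` where residue indices count
#' ungapped letters within each sequence.  Lowercase letters were emitted by
#' insertion states and yield no pairs.  With `restrict_to`, only pairs with
#' at least one member in the id set are returned (query-only scoring).
#'
#' @param aln an `"aln"` object.
#' @param restrict_to optional character vector of ids.
#' @return character vector of canonical pair keys
#'   (`"id1#res1|id2#res2"`, endpoints ordered by id).
#' @export
homology_pairs <- function(aln, restrict_to = NULL) {
  stopifnot(inherits(aln, "aln"))
  m <- aln_matrix(aln)
  ids <- rownames(m)
  # residue index of every cell (NA at gaps)
  res <- t(apply(m, 1L, function(r) {
    idx <- cumsum(r != GAP)
    idx[r == GAP] <- NA_integer_
    idx
  }))
  if (aln$L == 1L) res <- matrix(res, ncol = 1L)
  upper <- m != GAP & m == toupper(m)
  pairs <- character()
  for (j in seq_len(ncol(m))) {
    rows <- which(upper[, j])
    if (length(rows) < 2L) next
    ord <- rows[order(ids[rows], method = "radix")]
    ep <- paste0(ids[ord], "#", res[ord, j])
    cmb <- utils::combn(ep, 2L)
    keys <- paste(cmb[1L, ], cmb[2L, ], sep = "|")
    if (!is.null(restrict_to)) {
      keep <- ids[ord] %in% restrict_to
      incl <- utils::combn(keep, 2L)
      keys <- keys[incl[1L, ] | incl[2L, ]]
    }
    pairs <- c(pairs, keys)
  }
  pairs
}

#' Sum-of-pairs error between an estimated and a reference alignment
#'
#' SPFN is the fraction of reference homologies missing from the estimate;
#' SPFP is the fraction of estimated homologies absent from the reference.
#' With `restrict_to` (query-only mode) both sides are restricted to pairs
#' touching the given ids, the convention for comparing methods that share a
#' backbone alignment.  When one side has no homologies at all, the
#' corresponding rate is defined as 0.
#'
#' @param est estimated alignment (`"aln"`).
#' @param ref reference alignment (`"aln"`) over the same ids with identical
#'   ungapped sequences.
#' @param restrict_to optional id set for query-only scoring.
#' @return an object of class `"sp_score"`: `spfn`, `spfp`, `average`, and
#'   the raw counts `shared`, `ref_only`, `est_only`.
#' @export
sp_error <- function(est, ref, restrict_to = NULL) {
  stopifnot(inherits(est, "aln"), inherits(ref, "aln"))
  if (!setequal(names(est$rows), names(ref$rows))) {
    stop("estimated and reference alignments must contain the same ids")
  }
  ue <- toupper(degap(est$rows[names(ref$rows)]))
  ur <- toupper(degap(ref$rows))
  if (!identical(unname(ue), unname(ur))) {
    bad <- names(ref$rows)[ue != ur]
    stop("ungapped sequences differ between est and ref for: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  pe <- homology_pairs(est, restrict_to)
  pr <- homology_pairs(ref, restrict_to)
  shared <- length(intersect(pe, pr))
  ref_only <- length(setdiff(pr, pe))
  est_only <- length(setdiff(pe, pr))
  spfn <- if (shared + ref_only == 0L) 0 else ref_only / (shared + ref_only)
  spfp <- if (shared + est_only == 0L) 0 else est_only / (shared + est_only)
  structure(list(spfn = spfn, spfp = spfp, average = (spfn + spfp) / 2,
                 shared = shared, ref_only = ref_only, est_only = est_only),
            class = "sp_score")
}

#' @export
print.sp_score <- function(x, ...) {
  cat(sprintf("SPFN %.4f  SPFP %.4f  average %.4f  (shared %d, ref-only %d, est-only %d)\n",
              x$spfn, x$spfp, x$average, x$shared, x$ref_only, x$est_only))
  invisible(x)
}
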