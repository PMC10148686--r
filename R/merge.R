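# Transitivity merge: assemble the final MSA from the backbone alignment and
# per-query extended rows (match / insertion placements).

#' Construct an extended row (a query's placement against the backbone)
#'
#' An extended row records, for every letter of a query sequence, either a
#' match placement into a backbone column or an insertion placement anchored
#' after a backbone column (anchor 0 = before the first column).  Match
#' columns must be strictly increasing along the query and insertion anchors
#' must be compatible with the surrounding matches.
#'
#' @param id query id.
#' @param letters character vector, one query letter per element (ungapped).
#' @param type character vector over `"M"`/`"I"`, one per letter.
#' @param col integer vector: backbone column of each match placement, or the
#'   anchor column of each insertion placement (1-based; 0 = before-first).
#' @return an object of class `"extended_row"`.
#' @export
extended_row <- function(id, letters, type, col) {
  stopifnot(length(letters) == length(type), length(type) == length(col))
  if (!all(type %in% c("M", "I"))) stop("placement types must be 'M' or 'I'")
  mcols <- col[type == "M"]
  if (length(mcols) > 1L && any(diff(mcols) <= 0L)) {
    stop("match placements must use strictly increasing backbone columns")
  }
  structure(list(id = id, letters = letters,
                 placements = data.frame(type = type, col = as.integer(col))),
            class = "extended_row")
}

#' Merge extended rows into the backbone by transitivity
#'
#' Produces the final alignment: all backbone rows plus one row per query.
#' Backbone columns are preserved in order.  Each query's insertion segment
#' becomes a block of new columns placed immediately after its anchor column;
#' blocks of different queries at the same anchor are kept disjoint (insertion
#' letters are never homologous to anything) and ordered by query input
#' order.  Insertion letters are written lowercase, match letters uppercase.
#'
#' @param backbone an `"aln"` object.
#' @param rows list of [extended_row()] objects (possibly empty).
#' @return an `"aln"` object with `L + total insertions` columns.
#' @export
merge_extended <- function(backbone, rows = list()) {
  stopifnot(inherits(backbone, "aln"))
  if (length(rows) == 0L) return(backbone)
  qids <- vapply(rows, function(r) r$id, character(1))
  if (anyDuplicated(c(names(backbone$rows), qids))) {
    stop("query ids must be unique and distinct from backbone ids")
  }
  L <- backbone$L
  for (r in rows) {
    if (any(r$placements$col > L)) {
      stop("placement column beyond backbone length in query ", r$id)
    }
  }

  # per (anchor, query) insertion counts; queries keep input order
  nq <- length(rows)
  ins <- matrix(0L, nrow = L + 1L, ncol = nq)  # row a+1 = anchor a (0..L)
  for (j in seq_len(nq)) {
    p <- rows[[j]]$placements
    ic <- p$col[p$type == "I"]
    if (length(ic)) {
      tab <- table(ic)
      ins[as.integer(names(tab)) + 1L, j] <- as.integer(tab)
    }
  }

  # output column layout: [ins blocks @0][bb col 1][ins @1][bb col 2]...[ins @L]
  n_ins_at <- rowSums(ins)
  Lp <- L + sum(n_ins_at)
  # start position of query j's insertion block at anchor a (0-based offsets)
  block_start <- function(a, j) {
    before <- if (a > 0L) sum(n_ins_at[seq_len(a)]) + a else 0L
    before + (if (j > 1L) sum(ins[a + 1L, seq_len(j - 1L)]) else 0L) + 1L
  }
  bb_col_pos <- integer(L)  # output position of backbone column c
  for (c in seq_len(L)) bb_col_pos[c] <- cumsum(n_ins_at)[c] + c

  ids_out <- c(names(backbone$rows), qids)
  out <- matrix(GAP, nrow = length(ids_out), ncol = Lp,
                dimnames = list(ids_out, NULL))
  bbm <- aln_matrix(backbone)
  out[seq_len(nrow(bbm)), bb_col_pos] <- bbm

  for (j in seq_len(nq)) {
    r <- rows[[j]]
    p <- r$placements
    seen_at_anchor <- integer(L + 1L)
    for (i in seq_along(r$letters)) {
      if (p$type[i] == "M") {
        out[r$id, bb_col_pos[p$col[i]]] <- toupper(r$letters[i])
      } else {
        a <- p$col[i]
        seen_at_anchor[a + 1L] <- seen_at_anchor[a + 1L] + 1L
        pos <- block_start(a, j) + seen_at_anchor[a + 1L] - 1L
        out[r$id, pos] <- tolower(r$letters[i])
      }
    }
  }

  res <- apply(out, 1L, paste, collapse = "")
  new_alignment(res, alphabet = backbone$alphabet, rna_ids = backbone$rna_ids)
}
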