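# The merged HMM: a query-specific fusion of the ensemble of profile HMMs.
# Its topology is the exact union of the ensemble's transition edges mapped
# into backbone-column coordinates (so it can contain column-skipping edges a
# standard profile HMM lacks); its numeric parameters are adjusted-bitscore-
# weighted averages; entry/exit edges make the Viterbi alignment glocal.

#' Adjusted-bitscore weights of an ensemble for one query
#'
#' Turns the per-HMM bit scores `b_i` into a posterior-style probability that
#' each HMM generated the query: `w_i` is proportional to `2^(b_i) * s_i`,
#' where the prior of an HMM is proportional to its subset size `s_i`
#' (appropriate when the subsets are pairwise disjoint).  Computed stably in
#' the log2 domain.  For hierarchical (upp-mode) ensembles the same formula
#' is applied with each subset's own size; `prior = "uniform"` drops the size
#' factor instead.
#'
#' @param bitscores numeric vector of per-HMM bit scores.
#' @param sizes integer vector of subset sequence counts (the size prior).
#' @param prior `"size"` (default) or `"uniform"`.
#' @return an object of class `"query_weights"`: `w` (normalized weights
#'   summing to 1), `bitscores`, `sizes`.
#' @export
compute_adjusted_weights <- function(bitscores, sizes,
                                     prior = c("size", "uniform")) {
  prior <- match.arg(prior)
  stopifnot(length(bitscores) >= 1L, length(bitscores) == length(sizes),
            all(sizes >= 1))
  l <- bitscores + if (prior == "size") log2(sizes) else 0
  if (all(!is.finite(l))) {
    warning("all bit scores are -Inf; falling back to uniform weights")
    w <- rep(1 / length(l), length(l))
  } else {
    w <- 2^(l - max(l))
    w <- w / sum(w)
  }
  structure(list(w = w, bitscores = bitscores, sizes = sizes),
            class = "query_weights")
}

#' @export
print.query_weights <- function(x, ...) {
  cat(sprintf("Ensemble weights over %d HMMs (top weight %.3f on HMM %d)\n",
              length(x$w), max(x$w), which.max(x$w)))
  invisible(x)
}

#' Glocal bit score of a sequence against one profile HMM
#'
#' Like [bit_score()], but the HMM is first given glocal entry/exit edges
#' (via its singleton merged view and [add_glocal()]) so that a short
#' fragment is scored by how well it matches its best region of the model
#' rather than paying for a long delete chain through every unmatched
#' column.  This is the score [predict.ehmm()] feeds into the adjusted
#' weights: with plain global scores the weighting of fragments is dominated
#' by model length instead of sequence fit.
#'
#' @param hmm a [build_profile_hmm()] result.
#' @param seq sequence (character scalar) or letter vector.
#' @param entry_total,pexit glocal edge masses, see [add_glocal()].
#' @return bit score, a scalar.
#' @export
glocal_bit_score <- function(hmm, seq, entry_total = 0.1, pexit = 0.1) {
  g <- glocal_view(hmm, entry_total, pexit)
  letters <- seq_letters(seq)
  (ghmm_forward(g, letters) - null_log_prob(length(letters), hmm$alphabet)) /
    log(2)
}

# glocal singleton merged view of a profile HMM, as a ready-to-run ghmm
glocal_view <- function(hmm, entry_total = 0.1, pexit = 0.1) {
  w1 <- compute_adjusted_weights(0, hmm$size)
  m <- parameterize_merged(build_merged_topology(list(hmm)), list(hmm), w1)
  as_ghmm(add_glocal(m, entry_total = entry_total, pexit = pexit))
}

#' Union topology of an ensemble of profile HMMs
#'
#' Every ensemble HMM's states map into backbone coordinates (match/delete
#' states to their backbone column, insert states to their anchor column),
#' and the merged edge set is the union of the mapped per-HMM edge sets with
#' supporter bookkeeping.  A subset alignment that is entirely gapped across
#' some backbone columns contributes a transition that skips those columns,
#' which is what distinguishes the merged HMM from a standard profile HMM.
#'
#' @param hmms list of [build_profile_hmm()] results sharing the same
#'   backbone coordinate system.
#' @return an object of class `"merged_topology"`: `edge_long` (one row per
#'   (edge, supporter HMM) with that HMM's transition probability), `edges`
#'   (the deduplicated edge set), `match_cols`, `insert_anchors`, `S`, `L`.
#' @export
build_merged_topology <- function(hmms) {
  stopifnot(length(hmms) >= 1L,
            all(vapply(hmms, inherits, logical(1), "profile_hmm")))
  L <- hmms[[1L]]$L
  if (any(vapply(hmms, `[[`, integer(1), "L") != L)) {
    stop("ensemble HMMs disagree on backbone length")
  }
  if (any(vapply(hmms, function(h) max(h$match_cols), integer(1)) > L)) {
    stop("column map exceeds backbone length")
  }
  edge_long <- do.call(rbind, lapply(seq_along(hmms), function(i) {
    e <- hmms[[i]]$edges
    data.frame(from = e$from, to = e$to, hmm = i, prob = e$prob)
  }))
  edges <- unique(edge_long[, c("from", "to")])
  rownames(edges) <- NULL
  match_cols <- sort(unique(unlist(lapply(hmms, `[[`, "match_cols"))))
  anchors <- sort(unique(unlist(lapply(hmms, `[[`, "insert_anchors"))))
  structure(list(edge_long = edge_long, edges = edges,
                 match_cols = match_cols, insert_anchors = anchors,
                 S = length(match_cols), L = L,
                 alphabet = hmms[[1L]]$alphabet),
            class = "merged_topology")
}

#' @export
print.merged_topology <- function(x, ...) {
  cat(sprintf("Merged topology: %d match states over %d backbone columns, %d edges\n",
              x$S, x$L, nrow(x$edges)))
  invisible(x)
}

#' Query-specific parameters on the merged topology
#'
#' Each merged edge's raw value is the weighted sum of the transition
#' probabilities of the HMMs supporting that edge; each merged match (and
#' insert) state's raw emission values are the weighted sums over the HMMs
#' having that state.  Weights are used as-is (no re-normalization over
#' supporters); afterwards every state's outgoing edge values and every
#' emission distribution are renormalized to sum to 1.
#'
#' @param topology a [build_merged_topology()] result.
#' @param hmms the ensemble the topology was built from.
#' @param weights a [compute_adjusted_weights()] result for one query.
#' @return an object of class `"merged_hmm"` (glocal edges not yet added).
#' @export
parameterize_merged <- function(topology, hmms, weights) {
  stopifnot(inherits(topology, "merged_topology"),
            inherits(weights, "query_weights"),
            length(weights$w) == length(hmms))
  w <- weights$w
  el <- topology$edge_long
  key <- paste(el$from, el$to, sep = "\1")
  raw <- rowsum(w[el$hmm] * el$prob, key)
  first <- !duplicated(key)
  edges <- data.frame(from = el$from[first], to = el$to[first],
                      raw = raw[match(key[first], rownames(raw)), 1L])
  tot <- tapply(edges$raw, edges$from, sum)
  if (any(tot <= 0)) {
    stop("merged state with zero outgoing mass: ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  }
  edges$prob <- edges$raw / as.numeric(tot[edges$from])

  alpha <- core_alphabet(topology$alphabet)
  wavg_emit <- function(state_names, pick) {
    out <- matrix(0, nrow = length(state_names), ncol = length(alpha),
                  dimnames = list(state_names, alpha))
    for (s in state_names) {
      acc <- numeric(length(alpha))
      for (i in seq_along(hmms)) {
        tbl <- pick(hmms[[i]])
        if (s %in% rownames(tbl)) acc <- acc + w[i] * tbl[s, ]
      }
      if (sum(acc) <= 0) stop("merged emitting state ", s, " has zero mass")
      out[s, ] <- acc / sum(acc)
    }
    out
  }
  e_match <- wavg_emit(paste0("M", topology$match_cols),
                       function(h) h$e_match)
  e_insert <- wavg_emit(paste0("I", topology$insert_anchors),
                        function(h) h$e_insert)

  structure(list(edges = edges[, c("from", "to", "prob")],
                 e_match = e_match, e_insert = e_insert,
                 alphabet = topology$alphabet, L = topology$L,
                 S = topology$S, match_cols = topology$match_cols,
                 insert_anchors = topology$insert_anchors,
                 glocal = FALSE, weights = weights),
            class = "merged_hmm")
}

#' Add glocal entry and exit edges to a merged HMM
#'
#' To align an entire (possibly very short) query against a contiguous
#' region of the backbone without paying for long delete chains, the path
#' must be able to start at any match state and end at any match or delete
#' state.  A total entry mass of `entry_total` is divided equally over the
#' `S` match states (`pentry = entry_total / S` per entry edge) and an exit
#' edge of constant mass `pexit` is added from every match and delete state
#' to the end state; mass added to an already-existing edge accumulates.
#' All outgoing distributions are then renormalized to sum to 1.
#'
#' @param mhmm a [parameterize_merged()] result.
#' @param entry_total total pre-normalization entry mass (default 0.1).
#' @param pexit pre-normalization exit mass per state (default 0.1).
#' @return the merged HMM with glocal edges, renormalized.
#' @export
add_glocal <- function(mhmm, entry_total = 0.1, pexit = 0.1) {
  stopifnot(inherits(mhmm, "merged_hmm"), mhmm$S >= 1L)
  edges <- mhmm$edges
  names(edges)[names(edges) == "prob"] <- "raw"
  pentry <- entry_total / mhmm$S
  extra <- rbind(
    data.frame(from = "S", to = paste0("M", mhmm$match_cols), raw = pentry),
    data.frame(from = paste0("M", mhmm$match_cols), to = "E", raw = pexit))
  dcols <- sort(unique(as.integer(substring(
    grep("^D", unique(c(edges$from, edges$to)), value = TRUE), 2L))))
  if (length(dcols)) {
    extra <- rbind(extra,
                   data.frame(from = paste0("D", dcols), to = "E", raw = pexit))
  }
  all_e <- rbind(edges, extra)
  key <- paste(all_e$from, all_e$to, sep = "\1")
  raw <- rowsum(all_e$raw, key)
  first <- !duplicated(key)
  out <- data.frame(from = all_e$from[first], to = all_e$to[first],
                    raw = raw[match(key[first], rownames(raw)), 1L])
  tot <- tapply(out$raw, out$from, sum)
  out$prob <- out$raw / as.numeric(tot[out$from])
  mhmm$edges <- out[, c("from", "to", "prob")]
  mhmm$glocal <- TRUE
  mhmm$glocal_params <- list(entry_total = entry_total, pentry = pentry,
                             pexit = pexit)
  mhmm
}

#' @export
print.merged_hmm <- function(x, ...) {
  cat(sprintf("Merged HMM: %d match states, %d edges%s\n", x$S,
              nrow(x$edges), if (x$glocal) " (glocal)" else ""))
  invisible(x)
}

#' Align a query to the backbone through a merged HMM
#'
#' Runs the Viterbi algorithm over the (usually glocal) merged HMM in log
#' space.  Match states in the optimal path place query letters into their
#' backbone columns; insert states place letters between backbone columns.
#'
#' @param mhmm a merged HMM (after [add_glocal()], normally).
#' @param query query sequence (character scalar); gaps are ignored.
#' @param id id for the resulting row (default the name of `query`, or
#'   `"query"`).
#' @return an [extended_row()]; its `"logp"` attribute carries the Viterbi
#'   path log-probability.
#' @export
align_query <- function(mhmm, query, id = NULL) {
  stopifnot(inherits(mhmm, "merged_hmm"))
  id <- id %||% names(query) %||% "query"
  orig <- strsplit(degap(paste(query, collapse = "")), "")[[1]]
  if (length(orig) == 0L) stop("query must contain at least one letter")
  letters <- seq_letters(query)
  vit <- ghmm_viterbi(as_ghmm(mhmm), letters)
  if (!is.finite(vit$logp)) {
    stop("no finite-probability path for query ", id,
         "; was the model built without glocal edges?")
  }
  emit_states <- grep("^[MI]", vit$path, value = TRUE)
  stopifnot(length(emit_states) == length(orig))
  row <- extended_row(id, orig,
                      type = substr(emit_states, 1L, 1L),
                      col = as.integer(substring(emit_states, 2L)))
  attr(row, "logp") <- vit$logp
  row
}
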