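# Profile HMM construction from a sub-alignment (an internal replacement for
# hmmbuild).  States are named in backbone-column coordinates from the start:
# "M<c>" / "D<c>" are the match / delete states for backbone column c, "I<a>"
# is the insert state anchored after backbone column a (a = 0 means before
# the first column), "S" and "E" are start and end.  This makes the later
# union of ensembles a plain set union of identically-keyed edges.

state_name <- function(type, col) {
  if (type == "S") "S" else if (type == "E") "E" else paste0(type, col)
}

#' Call match columns of a sub-alignment
#'
#' A column receives a match state iff its fraction of non-gap characters
#' among the subset's rows is at least `symfrac` (the occupancy rule used by
#' hmmbuild).  Columns that are entirely gapped in the subset — a routine
#' occurrence for small subsets of a large backbone — are never match
#' columns; the resulting HMM then carries column-skipping transitions.
#'
#' @param sub a [induce_subalignment()] result (or any `"aln"`).
#' @param symfrac occupancy threshold in (0, 1]; default 0.5.
#' @return integer vector of backbone column indices (1-based), increasing.
#' @export
determine_match_columns <- function(sub, symfrac = 0.5) {
  stopifnot(inherits(sub, "aln"), symfrac > 0, symfrac <= 1)
  m <- aln_matrix(sub)
  occ <- colSums(m != GAP) / nrow(m)
  local <- which(occ >= symfrac)
  cols <- sub$backbone_columns %||% seq_len(ncol(m))
  as.integer(cols[local])
}

# allowed outgoing targets for every state of a profile HMM with match
# columns mc (full 9-transition topology: M/I/D each connect to M/I/D)
profile_allowed_edges <- function(mc) {
  S <- length(mc)
  anchors <- c(0L, mc)  # insert anchors for k = 0..S
  edges <- list()
  add <- function(from, to) edges[[length(edges) + 1L]] <<- c(from, to)
  nxt <- function(k) if (k == S) "E" else state_name("M", mc[k + 1L])
  for (k in 0:S) {
    from <- if (k == 0L) "S" else state_name("M", mc[k])
    add(from, nxt(k))
    add(from, state_name("I", anchors[k + 1L]))
    if (k < S) add(from, state_name("D", mc[k + 1L]))
  }
  for (k in 0:S) {
    from <- state_name("I", anchors[k + 1L])
    add(from, nxt(k))
    add(from, from)  # self loop
    if (k < S) add(from, state_name("D", mc[k + 1L]))
  }
  for (k in seq_len(S)) {
    from <- state_name("D", mc[k])
    add(from, nxt(k))
    add(from, state_name("I", anchors[k + 1L]))
    if (k < S) add(from, state_name("D", mc[k + 1L]))
  }
  do.call(rbind, lapply(edges, function(e) data.frame(from = e[1], to = e[2])))
}

#' Build a profile HMM from a sub-alignment
#'
#' Match states correspond to the match columns called by
#' [determine_match_columns()].  Each row of the sub-alignment is read off as
#' a state path (letter in a match column -> M, gap in a match column -> D,
#' letter in a non-match column -> I anchored at the preceding match column);
#' transition probabilities are pseudocount-smoothed path counts normalized
#' over the allowed outgoing edges, match emissions are pseudocount-smoothed
#' letter counts, and insert emissions are the uniform background.  Ambiguity
#' codes contribute no emission counts.
#'
#' @param sub a [induce_subalignment()] result (or plain `"aln"`).
#' @param symfrac match-column occupancy threshold (default 0.5).
#' @param pseudocount_emission additive smoothing weight for emission counts
#'   (default 1).
#' @param pseudocount_transition additive smoothing weight per allowed
#'   transition (default 0.1).
#' @return an object of class `"profile_hmm"`.
#' @export
build_profile_hmm <- function(sub, symfrac = 0.5, pseudocount_emission = 1,
                              pseudocount_transition = 0.1) {
  stopifnot(inherits(sub, "aln"))
  m <- aln_matrix(sub)
  L <- sub$L %||% ncol(m)
  bb_cols <- sub$backbone_columns %||% seq_len(ncol(m))
  mc <- determine_match_columns(sub, symfrac)
  if (length(mc) == 0L) {
    stop("no match columns at symfrac ", symfrac, ": degenerate model")
  }
  S <- length(mc)
  anchors <- c(0L, mc)
  alpha <- core_alphabet(sub$alphabet %||% guess_alphabet(sub$rows))
  A <- length(alpha)

  is_match_local <- bb_cols %in% mc
  match_of_col <- match(bb_cols, mc)  # local col -> match index k (or NA)

  # --- state paths and transition counts ---------------------------------
  allowed <- profile_allowed_edges(mc)
  counts <- stats::setNames(numeric(nrow(allowed)),
                            paste(allowed$from, allowed$to, sep = "\1"))
  bump <- function(from, to) {
    key <- paste(from, to, sep = "\1")
    if (is.na(counts[key])) {
      stop("observed transition ", from, " -> ", to, " is not an allowed edge")
    }
    counts[key] <<- counts[key] + 1
  }
  for (r in seq_len(nrow(m))) {
    prev <- "S"
    k <- 0L
    for (j in seq_len(ncol(m))) {
      ch <- m[r, j]
      if (is_match_local[j]) {
        k <- match_of_col[j]
        cur <- state_name(if (ch == GAP) "D" else "M", mc[k])
        bump(prev, cur)
        prev <- cur
      } else if (ch != GAP) {
        cur <- state_name("I", anchors[k + 1L])
        bump(prev, cur)
        prev <- cur
      }
    }
    bump(prev, "E")
  }

  allowed$count <- unname(counts)
  allowed$count <- allowed$count + pseudocount_transition
  tot <- tapply(allowed$count, allowed$from, sum)
  allowed$prob <- allowed$count / as.numeric(tot[allowed$from])

  # --- emissions ----------------------------------------------------------
  e_match <- matrix(0, nrow = S, ncol = A,
                    dimnames = list(paste0("M", mc), alpha))
  for (k in seq_len(S)) {
    j <- which(bb_cols == mc[k])
    col_letters <- toupper(m[, j])
    cnt <- table(factor(col_letters[col_letters %in% alpha], levels = alpha))
    e_match[k, ] <- (as.numeric(cnt) + pseudocount_emission) /
      (sum(cnt) + pseudocount_emission * A)
  }
  e_insert <- matrix(1 / A, nrow = S + 1L, ncol = A,
                     dimnames = list(paste0("I", anchors), alpha))

  structure(list(match_cols = mc, insert_anchors = anchors, L = L,
                 S_local = S,
                 edges = allowed[, c("from", "to", "prob")],
                 e_match = e_match, e_insert = e_insert,
                 alphabet = sub$alphabet %||% "dna",
                 size = nrow(m), ids = rownames(m)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM: %d match states over %d backbone columns, %d sequences (%s)\n",
              x$S_local, x$L, x$size, x$alphabet))
  skips <- sum(diff(x$match_cols) > 1L)
  if (skips) cat(sprintf("  %d backbone column gap(s) bridged by skip transitions\n", skips))
  invisible(x)
}

#' Forward log-probability of a sequence under a profile HMM
#'
#' Sum over all start-to-end state paths, computed in log space with
#' log-sum-exp accumulation.
#'
#' @param hmm a [build_profile_hmm()] result.
#' @param seq character scalar (a sequence) or character vector of letters.
#' @return log P(seq | hmm), a scalar.
#' @export
forward_log <- function(hmm, seq) {
  g <- as_ghmm(hmm)
  ghmm_forward(g, seq_letters(seq))
}

#' Viterbi decoding of a sequence against a profile HMM
#'
#' @inheritParams forward_log
#' @return list with `path` (character vector of state names, including `"S"`
#'   and `"E"`) and `logp` (the path's log probability).  Ties are broken
#'   deterministically, preferring match over delete over insert
#'   predecessors, then lower backbone columns.
#' @export
viterbi <- function(hmm, seq) {
  g <- as_ghmm(hmm)
  ghmm_viterbi(g, seq_letters(seq))
}

#' Null-model log probability of a sequence
#'
#' The null is an i.i.d. uniform background with a geometric length model:
#' residue probability `1/|A|` per letter and extension probability
#' `n/(n+1)` at sequence length `n`, mirroring the R-type null of common
#' profile HMM search tools.  Only score differences matter for ensemble
#' weighting, so the background is kept uniform.
#'
#' @param n sequence length in letters.
#' @param alphabet `"dna"` or `"protein"`.
#' @return log probability, natural log.
#' @export
null_log_prob <- function(n, alphabet = "dna") {
  A <- length(core_alphabet(alphabet))
  p <- n / (n + 1)
  n * log(1 / A) + n * log(p) + log(1 - p)
}

#' Bit score of a sequence against a profile HMM
#'
#' `(forward_log - null_log) / ln 2`: the log-odds of the model against the
#' i.i.d. null, in bits.  These are the raw scores that the adjusted-weight
#' calculation turns into per-HMM probabilities.
#'
#' @inheritParams forward_log
#' @return bit score, a scalar.
#' @export
bit_score <- function(hmm, seq) {
  letters <- seq_letters(seq)
  fl <- forward_log(hmm, letters)
  (fl - null_log_prob(length(letters), hmm$alphabet)) / log(2)
}

# normalize a query (string or letter vector) to uppercase letters, U -> T
seq_letters <- function(seq) {
  s <- toupper(chartr("Uu", "Tt", degap(paste(seq, collapse = ""))))
  if (nchar(s) == 0L) character() else strsplit(s, "")[[1]]
}
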