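# Independent oracles, deliberately implemented differently from the
# package's dynamic programming: exhaustive path recursion over the raw edge
# table, and a pairwise homology scanner.

# Forward (sum) or Viterbi (max) log-probability by memoized recursion over
# all Start -> End paths of a model given as an edge table plus emission
# distributions.  `edges` has columns from/to/prob (state-name strings);
# `emit` is a named list: state name -> named probability vector.
enum_log_score <- function(edges, emit, letters, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  n <- length(letters)
  out_edges <- split(seq_len(nrow(edges)), edges$from)
  memo <- new.env(parent = emptyenv())
  rec <- function(s, i) {
    key <- paste0(s, "@", i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    vals <- numeric()
    for (k in out_edges[[s]]) {
      t <- edges$to[k]
      p <- edges$prob[k]
      v <- if (t == "E") {
        if (i == n) p else 0
      } else if (substr(t, 1, 1) %in% c("M", "I")) {
        if (i < n) p * unname(emit[[t]][letters[i + 1]]) * rec(t, i + 1) else 0
      } else {  # silent delete state
        p * rec(t, i)
      }
      vals <- c(vals, v)
    }
    r <- if (length(vals) == 0) 0 else if (mode == "forward") sum(vals) else max(vals)
    memo[[key]] <- r
    r
  }
  log(rec("S", 0))
}

# emission list for a profile or merged HMM object
emit_list_of <- function(h) {
  tabs <- rbind(h$e_match, h$e_insert)
  out <- lapply(seq_len(nrow(tabs)), function(i) tabs[i, ])
  names(out) <- rownames(tabs)
  out
}

# oracle scores for a profile_hmm or merged_hmm on a letter vector
oracle_forward <- function(h, letters) {
  enum_log_score(h$edges, emit_list_of(h), letters, "forward")
}
oracle_viterbi <- function(h, letters) {
  enum_log_score(h$edges, emit_list_of(h), letters, "viterbi")
}

# brute-force homology pair set: iterate over row pairs and columns, a
# different traversal order from the package's column scan
brute_pairs <- function(aln, restrict_to = NULL) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  ids <- names(aln$rows)
  pairs <- character()
  for (a in seq_len(nrow(m))) {
    ra <- cumsum(m[a, ] != "-")
    for (b in seq_len(nrow(m))) {
      if (b <= a) next
      if (!is.null(restrict_to) &&
          !(ids[a] %in% restrict_to || ids[b] %in% restrict_to)) next
      rb <- cumsum(m[b, ] != "-")
      for (j in seq_len(ncol(m))) {
        ca <- m[a, j]; cb <- m[b, j]
        if (ca == "-" || cb == "-") next
        if (ca != toupper(ca) || cb != toupper(cb)) next
        ep <- sort(c(paste0(ids[a], "#", ra[j]), paste0(ids[b], "#", rb[j])),
                   method = "radix")
        pairs <- c(pairs, paste(ep, collapse = "|"))
      }
    }
  }
  pairs
}

# check that all outgoing-transition and emission distributions of a model
# (profile_hmm or merged_hmm) sum to 1 within tol
expect_normalized <- function(h, tol = 1e-9) {
  sums <- tapply(h$edges$prob, h$edges$from, sum)
  expect_true(all(abs(sums - 1) <= tol),
              label = paste("outgoing sums for", class(h)[1]))
  expect_true(all(abs(rowSums(h$e_match) - 1) <= tol))
  expect_true(all(abs(rowSums(h$e_insert) - 1) <= tol))
}
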