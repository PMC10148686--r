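# Fixture builders: random tiny sub-alignments / HMMs / ensembles, and the
# 20-taxon fragment-placement fixture shared by the end-to-end tests.

# random gapped sub-alignment over a backbone of L columns; guarantees at
# least one match column at symfrac 0.5
random_subaln <- function(n_rows = 2L, L = 4L, gap_prob = 0.3) {
  repeat {
    m <- matrix(sample(c("A", "C", "G", "T"), n_rows * L, replace = TRUE),
                nrow = n_rows)
    m[matrix(runif(n_rows * L) < gap_prob, nrow = n_rows)] <- "-"
    rows <- apply(m, 1L, paste, collapse = "")
    if (any(nchar(gsub("-", "", rows, fixed = TRUE)) == 0)) next
    names(rows) <- paste0("s", seq_len(n_rows))
    aln <- new_alignment(rows, alphabet = "dna")
    sub <- induce_subalignment(aln, names(rows))
    occ <- colSums(m != "-") / n_rows
    if (any(occ >= 0.5)) return(sub)
  }
}

random_tiny_hmm <- function(max_match = 4L) {
  repeat {
    sub <- random_subaln(n_rows = sample(1:3, 1), L = sample(2:5, 1))
    h <- try(build_profile_hmm(sub), silent = TRUE)
    if (inherits(h, "try-error")) next
    if (h$S_local <= max_match) return(h)
  }
}

# pair of HMMs over the same backbone coordinates (a tiny ensemble)
random_tiny_ensemble <- function(L = 5L, max_match = 4L) {
  repeat {
    m <- matrix(sample(c("A", "C", "G", "T"), 4L * L, replace = TRUE), nrow = 4L)
    m[matrix(runif(4L * L) < 0.35, nrow = 4L)] <- "-"
    rows <- apply(m, 1L, paste, collapse = "")
    if (any(nchar(gsub("-", "", rows, fixed = TRUE)) == 0)) next
    names(rows) <- paste0("s", 1:4)
    aln <- new_alignment(rows, alphabet = "dna")
    h1 <- try(build_profile_hmm(induce_subalignment(aln, c("s1", "s2"))),
              silent = TRUE)
    h2 <- try(build_profile_hmm(induce_subalignment(aln, c("s3", "s4"))),
              silent = TRUE)
    if (inherits(h1, "try-error") || inherits(h2, "try-error")) next
    if (h1$S_local > max_match || h2$S_local > max_match) next
    return(list(h1, h2))
  }
}

random_query <- function(min_len = 0L, max_len = 4L) {
  n <- sample(min_len:max_len, 1L)
  if (n == 0L) character() else sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# mask a backbone row down to the residue window [start, start+len-1]
# (used to build per-fragment reference rows from the true alignment)
fragment_reference_row <- function(src_row, start, len) {
  chars <- strsplit(src_row, "")[[1]]
  res <- cumsum(chars != "-")
  keep <- chars != "-" & res >= start & res <= start + len - 1
  chars[!keep] <- "-"
  paste(chars, collapse = "")
}

# 20-taxon simulated backbone with 10 held-in sequences fragmented at a
# target mean of 25% of the median length (sd scaled to the fixture's
# lengths); returns everything the placement tests need
placement_fixture <- function(sim_seed = 42, frag_seed = 7) {
  sim <- simulate_true_msa(n_taxa = 20, root_length = 120, sub_prob = 0.08,
                           indel_prob = 0.02, indel_mean = 3, seed = sim_seed)
  aln <- sim$alignment
  full <- gsub("-", "", aln$rows, fixed = TRUE)
  med <- stats::median(nchar(full))
  qids <- names(full)[1:10]
  fr <- make_fragments(full[qids], mean_fraction = 0.25,
                       sd = round(0.15 * 0.25 * med), fraction = 1,
                       seed = frag_seed)
  info <- attr(fr, "fragments")
  names(fr) <- paste0(qids, "_frag")
  ref_rows <- aln$rows
  for (i in seq_along(qids)) {
    ref_rows[[names(fr)[i]]] <-
      fragment_reference_row(aln$rows[[qids[i]]], info$start[i], info$length[i])
  }
  list(alignment = aln, tree = sim$tree, fragments = fr,
       reference = new_alignment(ref_rows), query_ids = names(fr))
}
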