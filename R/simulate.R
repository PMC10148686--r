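# Desk-scale synthetic data: a simple indel-aware sequence evolution
# simulator that tracks true column homologies, and the substring
# fragmentation protocol for producing high-fragmentary query sets.

#' Simulate a true multiple sequence alignment down a random tree
#'
#' Evolves a random root sequence down a random bifurcating tree.  On every
#' branch each site substitutes with probability `sub_prob`; a deletion
#' starts at a site with probability `indel_prob / 2` and removes a
#' geometric-length run (mean `indel_mean`), and an insertion of
#' geometric-length arises after a site with probability `indel_prob / 2`.
#' Every site carries a permanent identity, so the returned alignment is the
#' exact record of which letters are homologous; inserted sites are spliced
#' into a global column order next to their anchor.  The simulator is
#' deliberately simple (uniform substitutions, geometric indel lengths): it
#' provides enough signal for placement experiments, not a calibrated model
#' of any real evolutionary process.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param root_length root sequence length in letters.
#' @param sub_prob per-site substitution probability per branch.
#' @param indel_prob per-site probability per branch of starting an indel
#'   (split evenly between insertion and deletion).
#' @param indel_mean mean indel length (geometric).
#' @param seed random seed (required; the simulation is stochastic).
#' @return list with `alignment` (the true MSA, an `"aln"`, all uppercase)
#'   and `tree` (an [ape::phylo] with matching tip labels).
#' @export
simulate_true_msa <- function(n_taxa, root_length = 100L, sub_prob = 0.05,
                              indel_prob = 0.01, indel_mean = 3, seed) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  stopifnot(sub_prob >= 0, sub_prob <= 1, indel_prob >= 0, indel_prob <= 1,
            root_length >= 1L, indel_mean >= 1)
  if (missing(seed)) stop("a seed is required for simulation")
  set.seed(seed)
  alpha <- DNA_CORE

  tree <- ape::rtree(n_taxa)
  ntip <- n_taxa
  root <- ntip + 1L

  next_site <- root_length
  master <- seq_len(root_length)  # global left-to-right order of all sites
  geom_len <- function() 1L + stats::rgeom(1L, prob = 1 / indel_mean)

  evolve <- function(sites, letters) {
    n <- length(sites)
    if (n > 0L && sub_prob > 0) {
      hit <- which(stats::runif(n) < sub_prob)
      for (i in hit) {
        letters[i] <- sample(setdiff(alpha, letters[i]), 1L)
      }
    }
    if (n > 0L && indel_prob > 0) {
      # deletions: geometric run starting at each hit site
      del_start <- which(stats::runif(n) < indel_prob / 2)
      drop <- logical(n)
      for (i in del_start) {
        drop[i:min(n, i + geom_len() - 1L)] <- TRUE
      }
      sites <- sites[!drop]; letters <- letters[!drop]
      # insertions: after positions 0..n' (0 = before the first site)
      np <- length(sites)
      ins_at <- which(stats::runif(np + 1L) < indel_prob / 2) - 1L
      for (pos in rev(ins_at)) {
        len <- geom_len()
        new_ids <- next_site + seq_len(len)
        next_site <<- next_site + len
        new_letters <- sample(alpha, len, replace = TRUE)
        anchor_master <- if (pos == 0L) {
          if (np == 0L) 0L else match(sites[1L], master) - 1L
        } else match(sites[pos], master)
        master <<- append(master, new_ids, after = anchor_master)
        sites <- append(sites, new_ids, after = pos)
        letters <- append(letters, new_letters, after = pos)
        np <- length(sites)
      }
    }
    list(sites = sites, letters = letters)
  }

  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- list(sites = seq_len(root_length),
                       letters = sample(alpha, root_length, replace = TRUE))
  ord <- ape::reorder.phylo(tree, "cladewise")$edge  # parents before children
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1L]; ch <- ord[k, 2L]
    s <- seqs[[p]]
    seqs[[ch]] <- evolve(s$sites, s$letters)
  }

  leaf_sites <- lapply(seq_len(ntip), function(i) seqs[[i]])
  used <- sort(unique(unlist(lapply(leaf_sites, `[[`, "sites"))))
  cols <- master[master %in% used]  # all-gap columns dropped
  rows <- vapply(seq_len(ntip), function(i) {
    s <- leaf_sites[[i]]
    out <- rep(GAP, length(cols))
    out[match(s$sites, cols)] <- s$letters
    paste(out, collapse = "")
  }, character(1))
  names(rows) <- tree$tip.label
  list(alignment = new_alignment(rows, alphabet = "dna"), tree = tree)
}

#' Fragment sequences by substring trimming
#'
#' Emulates the high-fragmentary protocol: a selected fraction of the
#' sequences is trimmed (a prefix and a suffix are deleted) to a substring
#' whose target length is drawn from Normal(`mean_length`, `sd`), rounded
#' and clamped to `[1, full length]`, with a uniformly chosen start offset.
#' Unselected sequences are returned unchanged.  The high-fragmentary (HF)
#' condition of the experimental protocol corresponds to a target mean of
#' 25% of the median full length with sd 60; the ultra-high-fragmentary
#' (UHF) condition halves the target mean.
#'
#' @param seqs named character vector of ungapped sequences.
#' @param mean_length target mean fragment length in letters; if `NULL`,
#'   computed as `mean_fraction` of the median input length.
#' @param mean_fraction used only when `mean_length` is `NULL` (default
#'   0.25).
#' @param sd standard deviation of the target length (default 60).
#' @param fraction fraction of sequences to fragment (default 0.5).
#' @param seed random seed (required).
#' @return named character vector of sequences with a `"fragments"`
#'   attribute: a data frame with `id`, `fragmented`, `start`, `length`.
#' @export
make_fragments <- function(seqs, mean_length = NULL, mean_fraction = 0.25,
                           sd = 60, fraction = 0.5, seed) {
  if (missing(seed)) stop("a seed is required for fragmentation")
  if (any(grepl("-", seqs, fixed = TRUE))) stop("sequences must be ungapped")
  stopifnot(sd >= 0, fraction >= 0, fraction <= 1)
  set.seed(seed)
  lens <- nchar(seqs)
  if (is.null(mean_length)) mean_length <- mean_fraction * stats::median(lens)
  if (mean_length <= 0) stop("target mean length must be positive")
  n <- length(seqs)
  chosen <- sort(sample.int(n, round(fraction * n)))
  out <- seqs
  info <- data.frame(id = names(seqs), fragmented = FALSE,
                     start = 1L, length = lens)
  for (i in chosen) {
    len <- max(1L, min(lens[i], round(stats::rnorm(1L, mean_length, sd))))
    start <- sample.int(lens[i] - len + 1L, 1L)
    out[i] <- substr(seqs[i], start, start + len - 1L)
    info$fragmented[i] <- TRUE
    info$start[i] <- start
    info$length[i] <- len
  }
  attr(out, "fragments") <- info
  out
}
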