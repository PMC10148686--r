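# User-facing model interface: fit an ensemble-of-profile-HMMs
# representation of a backbone alignment, then place query sequences with
# query-specific merged HMMs.

#' Fit an ensemble-HMM representation of a backbone alignment
#'
#' Decomposes the backbone tree by centroid-edge deletions into subsets of at
#' most `max_subset_size` sequences, builds a profile HMM on the
#' sub-alignment induced by each ensemble subset, and precomputes the merged
#' union topology.  The fitted object is query-independent; per-query numeric
#' parameters are computed by [predict.ehmm()].
#'
#' @param backbone backbone alignment: an `"aln"` object or a path to an
#'   aligned FASTA file.
#' @param tree backbone tree: an [ape::phylo], a path to a newick file, or
#'   `NULL`.  The tree is only needed when the backbone has more than
#'   `max_subset_size` sequences (otherwise the decomposition is trivial);
#'   leaf labels must match the backbone ids exactly.
#' @param max_subset_size decomposition stopping size (default 50).
#' @param ensemble `"disjoint"` (default), `"disjoint+bb"`, or `"upp"`; see
#'   [select_ensemble()].
#' @param symfrac match-column occupancy threshold (default 0.5).
#' @param pseudocount_emission,pseudocount_transition smoothing weights for
#'   [build_profile_hmm()].
#' @param weight_prior `"size"` (default) or `"uniform"`; see
#'   [compute_adjusted_weights()].
#' @return an object of class `"ehmm"`.
#' @export
#' @examples
#' sim <- simulate_true_msa(n_taxa = 8, root_length = 40, seed = 1)
#' fit <- ehmm(sim$alignment, sim$tree, max_subset_size = 4)
#' fit
ehmm <- function(backbone, tree = NULL, max_subset_size = 50L,
                 ensemble = c("disjoint", "disjoint+bb", "upp"),
                 symfrac = 0.5, pseudocount_emission = 1,
                 pseudocount_transition = 0.1,
                 weight_prior = c("size", "uniform")) {
  ensemble <- match.arg(ensemble)
  weight_prior <- match.arg(weight_prior)
  if (is.character(backbone)) backbone <- read_fasta(backbone, as_alignment = TRUE)
  stopifnot(inherits(backbone, "aln"))
  if (is.character(tree)) tree <- ape::read.tree(tree)
  ids <- names(backbone$rows)

  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    if (!setequal(tree$tip.label, ids)) {
      stop("tree leaf labels do not match backbone sequence ids")
    }
    dec <- decompose_tree(tree, max_subset_size)
  } else if (length(ids) <= max_subset_size) {
    # single-subset decomposition; no tree required
    dec <- structure(list(subsets = list(list(ids = ids, level = 0L,
                                              parent = NA_integer_,
                                              minimal = TRUE)),
                          max_size = max_subset_size),
                     class = "decomposition")
  } else {
    stop("a backbone tree is required when the backbone has more than ",
         "max_subset_size sequences")
  }

  spec <- select_ensemble(dec, ensemble)
  hmms <- lapply(spec$subsets, function(subset_ids) {
    build_profile_hmm(induce_subalignment(backbone, subset_ids),
                      symfrac = symfrac,
                      pseudocount_emission = pseudocount_emission,
                      pseudocount_transition = pseudocount_transition)
  })
  topology <- build_merged_topology(hmms)
  structure(list(backbone = backbone, tree = tree, decomposition = dec,
                 ensemble = spec, hmms = hmms, topology = topology,
                 params = list(max_subset_size = max_subset_size,
                               symfrac = symfrac,
                               pseudocount_emission = pseudocount_emission,
                               pseudocount_transition = pseudocount_transition,
                               weight_prior = weight_prior)),
            class = "ehmm")
}

#' @export
print.ehmm <- function(x, ...) {
  cat(sprintf("Ensemble HMM fit: %d backbone sequences x %d columns, %s ensemble of %d HMM(s)\n",
              length(x$backbone$rows), x$backbone$L, x$ensemble$mode,
              length(x$hmms)))
  cat(sprintf("  merged topology: %d match states, %d edges\n",
              x$topology$S, nrow(x$topology$edges)))
  invisible(x)
}

#' @export
summary.ehmm <- function(object, ...) {
  sizes <- object$ensemble$sizes
  skips <- vapply(object$hmms, function(h) sum(diff(h$match_cols) > 1L),
                  integer(1))
  out <- list(n_backbone = length(object$backbone$rows),
              L = object$backbone$L,
              mode = object$ensemble$mode,
              subset_sizes = sizes,
              match_states = vapply(object$hmms, `[[`, integer(1), "S_local"),
              skip_edges = skips,
              merged_S = object$topology$S,
              merged_edges = nrow(object$topology$edges))
  class(out) <- "summary.ehmm"
  out
}

#' @export
print.summary.ehmm <- function(x, ...) {
  cat(sprintf("Ensemble HMM (%s) on %d sequences x %d columns\n",
              x$mode, x$n_backbone, x$L))
  cat("  subset sizes:   ", paste(x$subset_sizes, collapse = ", "), "\n")
  cat("  match states:   ", paste(x$match_states, collapse = ", "), "\n")
  cat("  columns skipped:", paste(x$skip_edges, collapse = ", "), "\n")
  cat(sprintf("  merged HMM: %d match states, %d edges\n",
              x$merged_S, x$merged_edges))
  invisible(x)
}

#' Align query sequences into the backbone of a fitted ensemble HMM
#'
#' For each query: score every ensemble HMM (forward bit score), convert the
#' scores into adjusted weights, parameterize the merged HMM with those
#' weights, add glocal entry/exit edges, run Viterbi, and read the optimal
#' path off as match/insertion placements.  All extended rows are then
#' merged into the backbone by transitivity.
#'
#' @param object an [ehmm()] fit.
#' @param queries named character vector of (unaligned) query sequences, a
#'   path to a FASTA file, or an `"aln"` whose rows are degapped first.
#' @param glocal add entry/exit edges (default `TRUE`); disable only to
#'   study the plain global alignment behaviour.
#' @param entry_total,pexit glocal edge masses, see [add_glocal()].
#' @param top_k if set, only the `top_k` HMMs by bit score are merged for
#'   each query (a speed knob; default uses the whole ensemble).
#' @param ... unused.
#' @return an object of class `c("ehmm_alignment", "aln")`: the merged
#'   alignment, with attributes `query_ids`, `weights` (per-query
#'   [compute_adjusted_weights()] results) and `logp` (per-query Viterbi
#'   path log-probabilities).
#' @export
predict.ehmm <- function(object, queries, glocal = TRUE, entry_total = 0.1,
                         pexit = 0.1, top_k = NULL, ...) {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
    queries <- read_fasta(queries)
  }
  if (inherits(queries, "aln")) queries <- degap(queries$rows)
  if (length(queries) == 0L) {
    warning("no query sequences; returning the backbone alignment unchanged")
    return(object$backbone)
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be named")
  }
  hmms <- object$hmms
  # each HMM is scored through its glocal view so that fragment scores
  # reflect sequence fit, not model length
  score_views <- lapply(hmms, glocal_view, entry_total = entry_total,
                        pexit = pexit)
  sizes <- object$ensemble$sizes
  prior <- object$params$weight_prior

  rows <- vector("list", length(queries))
  wts <- vector("list", length(queries))
  logp <- numeric(length(queries))
  for (qi in seq_along(queries)) {
    letters <- seq_letters(queries[[qi]])
    null_lp <- null_log_prob(length(letters), object$backbone$alphabet)
    b <- vapply(score_views, function(g) {
      (ghmm_forward(g, letters) - null_lp) / log(2)
    }, numeric(1))
    use <- seq_along(hmms)
    if (!is.null(top_k) && top_k < length(hmms)) {
      use <- order(b, decreasing = TRUE)[seq_len(top_k)]
    }
    w <- compute_adjusted_weights(b[use], sizes[use], prior = prior)
    topo <- if (length(use) == length(hmms)) object$topology
            else build_merged_topology(hmms[use])
    m <- parameterize_merged(topo, hmms[use], w)
    if (glocal) m <- add_glocal(m, entry_total = entry_total, pexit = pexit)
    row <- align_query(m, queries[[qi]], id = names(queries)[qi])
    rows[[qi]] <- row
    wts[[qi]] <- w
    logp[qi] <- attr(row, "logp")
  }
  out <- merge_extended(object$backbone, rows)
  attr(out, "query_ids") <- names(queries)
  attr(out, "weights") <- stats::setNames(wts, names(queries))
  attr(out, "logp") <- stats::setNames(logp, names(queries))
  class(out) <- c("ehmm_alignment", class(out))
  out
}

#' @export
print.ehmm_alignment <- function(x, ...) {
  qids <- attr(x, "query_ids")
  cat(sprintf("Merged alignment: %d sequences x %d columns (%d queries placed)\n",
              length(x$rows), x$L, length(qids)))
  NextMethod()
}

#' One-call pipeline: split, fit, and align
#'
#' Convenience wrapper around [split_by_length()], [ehmm()] and
#' [predict.ehmm()].  Either pass a ready backbone alignment plus unaligned
#' queries, or a single aligned FASTA (`sequences`) that is split by
#' ungapped length: the full-length rows keep their alignment and become the
#' backbone, the remaining rows are degapped and realigned as queries.
#'
#' @param backbone,tree,queries inputs as in [ehmm()] / [predict.ehmm()].
#' @param sequences alternative input: one aligned FASTA (path or `"aln"`)
#'   to be split by length.
#' @param split_fraction,split_threshold length-split policy, see
#'   [split_by_length()].
#' @param output optional path; when given, the merged alignment is also
#'   written there as FASTA.
#' @param ... passed on to [ehmm()] and [predict.ehmm()] (matched by name).
#' @return the merged alignment, as from [predict.ehmm()].
#' @export
align_sequences <- function(backbone = NULL, tree = NULL, queries = NULL,
                            sequences = NULL, split_fraction = 0.25,
                            split_threshold = NULL, output = NULL, ...) {
  if (!is.null(sequences)) {
    if (!is.null(backbone) || !is.null(queries)) {
      stop("give either 'sequences' or 'backbone'+'queries', not both")
    }
    if (is.character(sequences)) sequences <- read_fasta(sequences, as_alignment = TRUE)
    stopifnot(inherits(sequences, "aln"))
    sp <- split_by_length(sequences$rows, fraction = split_fraction,
                          threshold = split_threshold)
    backbone <- induce_subalignment(sequences, sp$backbone)
    class(backbone) <- "aln"
    queries <- degap(sequences$rows[sp$query])
  }
  dots <- list(...)
  fit_args <- dots[names(dots) %in% names(formals(ehmm))]
  fit <- do.call(ehmm, c(list(backbone = backbone, tree = tree), fit_args))
  pred_args <- dots[names(dots) %in% setdiff(names(formals(predict.ehmm)),
                                             c("object", "queries"))]
  out <- do.call(predict, c(list(object = fit, queries = queries), pred_args))
  if (!is.null(output)) write_fasta(out, output)
  out
}

#' Score an estimated alignment against a reference
#'
#' Thin wrapper over [sp_error()] accepting FASTA paths and an optional
#' query-id list for query-only error.
#'
#' @param est,ref alignments (`"aln"` objects or FASTA paths).
#' @param query_ids optional character vector of ids, or path to a file with
#'   one id per line.
#' @return an `"sp_score"` object.
#' @export
score_alignment <- function(est, ref, query_ids = NULL) {
  if (is.character(est)) est <- read_fasta(est, as_alignment = TRUE)
  if (is.character(ref)) ref <- read_fasta(ref, as_alignment = TRUE)
  if (is.character(query_ids) && length(query_ids) == 1L &&
      file.exists(query_ids)) {
    query_ids <- readLines(query_ids)
    query_ids <- query_ids[nzchar(query_ids)]
  }
  if (!is.null(query_ids)) {
    missing <- setdiff(query_ids, names(est$rows))
    if (length(missing)) {
      stop("query id(s) not present in the alignment: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  sp_error(est, ref, restrict_to = query_ids)
}
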