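# Generic HMM machinery shared by profile HMMs and merged HMMs: a state/edge
# container ("ghmm") plus forward and Viterbi dynamic programming in natural
# log space.  States are processed in backbone-column order so that silent
# (delete) chains, including column-skipping edges, propagate in one sweep
# per consumed letter.

parse_states <- function(names, L) {
  type <- substr(names, 1L, 1L)
  col <- suppressWarnings(as.integer(substring(names, 2L)))
  col[type == "S"] <- 0L
  col[type == "E"] <- L + 1L
  data.frame(name = names, type = type, col = col)
}

# Build the generic container from an edge table (state-name strings and
# probabilities) and emission matrices keyed by state name.
make_ghmm <- function(edges, emit_list, alphabet, L, match_cols) {
  nm <- unique(c("S", edges$from, edges$to, "E"))
  states <- parse_states(nm, L)
  A <- core_alphabet(alphabet)
  emit <- matrix(NA_real_, nrow = nrow(states), ncol = length(A),
                 dimnames = list(states$name, A))
  for (tbl in emit_list) {
    keep <- intersect(rownames(tbl), states$name)
    emit[keep, ] <- log(tbl[keep, , drop = FALSE])
  }
  from <- match(edges$from, states$name)
  to <- match(edges$to, states$name)
  bad <- edges$prob <= 0 | !is.finite(edges$prob)
  if (any(bad)) stop("non-positive or non-finite transition probability")
  g <- list(states = states,
            edges = data.frame(from = from, to = to, logp = log(edges$prob)),
            emit = emit, alphabet = alphabet, L = L, match_cols = match_cols)
  # check the column-advance invariant that the sweep order relies on
  fc <- states$col[from]; tc <- states$col[to]; tt <- states$type[to]
  if (any(tt %in% c("M", "D", "E") & fc >= tc)) {
    stop("edge into a match/delete state does not advance the backbone column")
  }
  if (any(tt == "I" & fc > tc)) {
    stop("edge into an insert state moves backwards along the backbone")
  }
  g <- ghmm_index(g)
  class(g) <- "ghmm"
  g
}

# precompute incoming-edge lists in deterministic tie-break order
# (prefer match over delete over insert predecessors, then lower columns)
ghmm_index <- function(g) {
  st <- g$states
  prio <- c(S = 0L, M = 1L, D = 2L, I = 3L, E = 4L)
  ord <- order(g$edges$to,
               prio[st$type[g$edges$from]],
               st$col[g$edges$from],
               st$name[g$edges$from],
               method = "radix")  # C-locale order: locale-independent ties
  e <- g$edges[ord, ]
  g$in_edges <- lapply(seq_len(nrow(st)), function(s) {
    sel <- e$to == s
    list(from = e$from[sel], logp = e$logp[sel])
  })
  g$start <- which(st$type == "S")
  g$end <- which(st$type == "E")
  g$emitting <- which(st$type %in% c("M", "I"))
  dstates <- which(st$type == "D")
  g$d_order <- dstates[order(st$col[dstates])]
  g
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# emission log-probabilities for one letter across all states; ambiguity
# codes emit the uniform background at every emitting state
emit_column <- function(g, letter) {
  A <- colnames(g$emit)
  j <- match(letter, A)
  if (is.na(j)) {
    out <- rep(log(1 / length(A)), nrow(g$emit))
    out[is.na(g$emit[, 1L])] <- NA_real_
    out
  } else {
    g$emit[, j]
  }
}

ghmm_dp <- function(g, letters, mode = c("viterbi", "forward")) {
  mode <- match.arg(mode)
  viterbi <- mode == "viterbi"
  n <- length(letters)
  nst <- nrow(g$states)
  V <- matrix(-Inf, nrow = nst, ncol = n + 1L)
  P <- if (viterbi) matrix(NA_integer_, nrow = nst, ncol = n + 1L)
  V[g$start, 1L] <- 0

  relax <- function(s, layer, base_layer, extra) {
    ie <- g$in_edges[[s]]
    if (length(ie$from) == 0L) return()
    vals <- V[ie$from, base_layer] + ie$logp
    if (viterbi) {
      k <- which.max(vals)
      if (vals[k] > -Inf) {
        V[s, layer] <<- vals[k] + extra
        P[s, layer] <<- ie$from[k]
      }
    } else {
      V[s, layer] <<- logsumexp(vals) + extra
    }
  }

  for (d in g$d_order) relax(d, 1L, 1L, 0)
  if (n > 0L) {
    for (i in 2L:(n + 1L)) {
      el <- emit_column(g, letters[i - 1L])
      for (s in g$emitting) relax(s, i, i - 1L, el[s])
      for (d in g$d_order) relax(d, i, i, 0)
    }
  }
  ieE <- g$in_edges[[g$end]]
  vals <- V[ieE$from, n + 1L] + ieE$logp
  if (length(vals) == 0L) vals <- -Inf
  if (viterbi) {
    k <- which.max(vals)
    logp <- unname(vals[k])
    if (!is.finite(logp)) return(list(path = NULL, logp = -Inf))
    # traceback
    path <- "E"
    cur <- ieE$from[k]
    layer <- n + 1L
    repeat {
      path <- c(g$states$name[cur], path)
      if (cur == g$start) break
      nxt <- P[cur, layer]
      if (g$states$type[cur] %in% c("M", "I")) layer <- layer - 1L
      cur <- nxt
    }
    list(path = path, logp = logp)
  } else {
    logsumexp(vals)
  }
}

ghmm_forward <- function(g, letters) ghmm_dp(g, letters, "forward")
ghmm_viterbi <- function(g, letters) ghmm_dp(g, letters, "viterbi")

# generic-container views -------------------------------------------------

as_ghmm <- function(x, ...) UseMethod("as_ghmm")

#' @export
as_ghmm.profile_hmm <- function(x, ...) {
  make_ghmm(x$edges, list(x$e_match, x$e_insert), x$alphabet, x$L,
            x$match_cols)
}

#' @export
as_ghmm.merged_hmm <- function(x, ...) {
  make_ghmm(x$edges, list(x$e_match, x$e_insert), x$alphabet, x$L,
            x$match_cols)
}
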