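test_that("adjusted weights follow the 2^b * s posterior formula", {
  w <- compute_adjusted_weights(rep(3.7, 4), rep(5L, 4))
  expect_equal(w$w, rep(0.25, 4))
  expect_equal(sum(w$w), 1, tolerance = 1e-12)

  # one extra bit doubles the odds
  w <- compute_adjusted_weights(c(11, 10), c(3L, 3L))
  expect_equal(w$w, c(2 / 3, 1 / 3), tolerance = 1e-12)

  # doubling the subset size doubles the prior
  w <- compute_adjusted_weights(c(4, 4), c(10L, 5L))
  expect_equal(w$w, c(2 / 3, 1 / 3), tolerance = 1e-12)

  # stability at extreme scores
  w <- compute_adjusted_weights(c(5000, 4999), c(1L, 1L))
  expect_equal(w$w, c(2 / 3, 1 / 3), tolerance = 1e-12)

  expect_warning(w <- compute_adjusted_weights(c(-Inf, -Inf), c(1L, 2L)),
                 "uniform")
  expect_equal(w$w, c(0.5, 0.5))
})

test_that("the merged topology is the exact union of mapped ensemble edges", {
  # singleton ensemble: isomorphic topology
  aln <- new_alignment(c(a = "ACG", b = "ATG"))
  h <- build_profile_hmm(induce_subalignment(aln, c("a", "b")))
  topo <- build_merged_topology(list(h))
  expect_setequal(paste(topo$edges$from, topo$edges$to),
                  paste(h$edges$from, h$edges$to))
  expect_equal(topo$S, h$S_local)

  # random ensembles: set-union oracle
  set.seed(601)
  for (rep in 1:10) {
    hmms <- random_tiny_ensemble()
    topo <- build_merged_topology(hmms)
    union_oracle <- unique(unlist(lapply(hmms, function(h) {
      paste(h$edges$from, h$edges$to)
    })))
    expect_setequal(paste(topo$edges$from, topo$edges$to), union_oracle)
  }
})

test_that("a subset gapped across interior columns contributes a skip edge", {
  # backbone fully occupied for rows a+b; rows c+d entirely gapped in col 3
  aln <- new_alignment(c(a = "ACGTA", b = "ATGCA",
                         c = "AC-TA", d = "AT-GA"))
  h_bb <- build_profile_hmm(induce_subalignment(aln, c("a", "b")))
  h_cd <- build_profile_hmm(induce_subalignment(aln, c("c", "d")))
  expect_equal(h_bb$match_cols, 1:5)
  expect_equal(h_cd$match_cols, c(1L, 2L, 4L, 5L))
  topo <- build_merged_topology(list(h_bb, h_cd))
  # the skip edge M2 -> M4 is absent from the backbone HMM but in the union
  expect_false(any(h_bb$edges$from == "M2" & h_bb$edges$to == "M4"))
  expect_true(any(topo$edges$from == "M2" & topo$edges$to == "M4"))
  expect_equal(topo$S, 5L)
})

test_that("parameterization degenerates correctly for singleton and identical ensembles", {
  aln <- new_alignment(c(a = "AC-G", b = "ATGG"))
  h <- build_profile_hmm(induce_subalignment(aln, c("a", "b")))
  topo <- build_merged_topology(list(h))
  m <- parameterize_merged(topo, list(h), compute_adjusted_weights(1, 2L))
  key <- function(e) paste(e$from, e$to)
  expect_equal(m$edges$prob[order(key(m$edges))],
               h$edges$prob[order(key(h$edges))], tolerance = 1e-12)
  expect_equal(m$e_match, h$e_match, tolerance = 1e-12)

  # two byte-identical HMMs under any weights reproduce the shared parameters
  aln2 <- new_alignment(c(x = "AC-G", y = "ATGG"))
  h2 <- build_profile_hmm(induce_subalignment(aln2, c("x", "y")))
  topo2 <- build_merged_topology(list(h, h2))
  for (b in list(c(0, 0), c(7, 2))) {
    m2 <- parameterize_merged(topo2, list(h, h2),
                              compute_adjusted_weights(b, c(2L, 2L)))
    expect_equal(m2$edges$prob[order(key(m2$edges))],
                 h$edges$prob[order(key(h$edges))], tolerance = 1e-12)
    expect_equal(m2$e_match, h$e_match, tolerance = 1e-12)
  }
})

test_that("merged parameters are weighted sums renormalized per state", {
  set.seed(602)
  for (rep in 1:8) {
    hmms <- random_tiny_ensemble()
    w <- compute_adjusted_weights(runif(2, -2, 2), c(2L, 2L))
    topo <- build_merged_topology(hmms)
    m <- parameterize_merged(topo, hmms, w)
    expect_normalized(m)
    # independent recomputation of every edge: weighted sum then renormalize
    lk1 <- paste(hmms[[1]]$edges$from, hmms[[1]]$edges$to)
    lk2 <- paste(hmms[[2]]$edges$from, hmms[[2]]$edges$to)
    raw <- function(from, to) {
      k <- paste(from, to)
      w$w[1] * sum(hmms[[1]]$edges$prob[lk1 == k]) +
        w$w[2] * sum(hmms[[2]]$edges$prob[lk2 == k])
    }
    for (i in sample(nrow(m$edges), min(10, nrow(m$edges)))) {
      from <- m$edges$from[i]
      sib <- m$edges$to[m$edges$from == from]
      denom <- sum(vapply(sib, function(t) raw(from, t), numeric(1)))
      expect_equal(m$edges$prob[i], raw(from, m$edges$to[i]) / denom,
                   tolerance = 1e-9)
    }
  }
})

test_that("glocal edges carry mass 0.1/S entry and 0.1 exit before renormalization", {
  set.seed(603)
  make_model_with_S <- function(S) {
    # a single ungapped sequence of length S gives exactly S match states
    rows <- c(x = paste(sample(c("A", "C", "G", "T"), S, replace = TRUE),
                        collapse = ""),
              y = paste(sample(c("A", "C", "G", "T"), S, replace = TRUE),
                        collapse = ""))
    h <- build_profile_hmm(induce_subalignment(new_alignment(rows), c("x", "y")))
    parameterize_merged(build_merged_topology(list(h)), list(h),
                        compute_adjusted_weights(0, 2L))
  }
  for (S in c(1L, 5L, 17L)) {
    m0 <- make_model_with_S(S)
    expect_equal(m0$S, S)
    m1 <- add_glocal(m0)
    expect_normalized(m1)
    expect_equal(m1$glocal_params$pentry, 0.1 / S)
    expect_equal(m1$glocal_params$pexit, 0.1)
    # oracle: manually add 0.1/S entry and 0.1 exit mass and renormalize
    e <- m0$edges
    add <- rbind(
      data.frame(from = "S", to = paste0("M", m0$match_cols), prob = 0.1 / S),
      data.frame(from = paste0("M", m0$match_cols), to = "E", prob = 0.1),
      data.frame(from = paste0("D", m0$match_cols), to = "E", prob = 0.1))
    dstates <- grep("^D", unique(c(e$from, e$to)), value = TRUE)
    add <- add[!(grepl("^D", add$from)) | add$from %in% dstates, ]
    all_e <- rbind(e, add)
    agg <- stats::aggregate(prob ~ from + to, all_e, sum)
    tot <- tapply(agg$prob, agg$from, sum)
    agg$prob <- agg$prob / as.numeric(tot[agg$from])
    key <- function(d) paste(d$from, d$to)
    agg <- agg[order(key(agg)), ]
    got <- m1$edges[order(key(m1$edges)), ]
    expect_equal(got$prob, agg$prob, tolerance = 1e-9)
    expect_equal(key(got), key(agg))
    # total pre-normalization entry mass is 0.1
    expect_equal(m1$glocal_params$pentry * S, 0.1)
  }
})

test_that("merged Viterbi scores match exhaustive enumeration, glocal on and off", {
  set.seed(604)
  for (rep in 1:10) {
    hmms <- random_tiny_ensemble()
    w <- compute_adjusted_weights(runif(2, -1, 1), c(2L, 2L))
    m <- parameterize_merged(build_merged_topology(hmms), hmms, w)
    for (glocal in c(FALSE, TRUE)) {
      mm <- if (glocal) add_glocal(m) else m
      q <- random_query(min_len = 1)
      r <- align_query(mm, paste(q, collapse = ""), id = "q")
      expect_equal(attr(r, "logp"), oracle_viterbi(mm, q), tolerance = 1e-9)
    }
  }
})

test_that("singleton ensemble without glocal reduces to plain profile Viterbi", {
  set.seed(605)
  for (rep in 1:5) {
    h <- random_tiny_hmm()
    m <- parameterize_merged(build_merged_topology(list(h)), list(h),
                             compute_adjusted_weights(0, h$size))
    q <- random_query(min_len = 1)
    v <- viterbi(h, q)
    r <- align_query(m, paste(q, collapse = ""), id = "q")
    expect_equal(attr(r, "logp"), v$logp, tolerance = 1e-12)
    emit_states <- grep("^[MI]", v$path, value = TRUE)
    expect_equal(paste0(r$placements$type, r$placements$col), emit_states)
  }
})

test_that("merged parameters converge to the dominant HMM's on its edges", {
  aln <- new_alignment(c(a = "ACGTA", b = "ATGCA", c = "AC-TA", d = "AT-GA"))
  h1 <- build_profile_hmm(induce_subalignment(aln, c("a", "b")))
  h2 <- build_profile_hmm(induce_subalignment(aln, c("c", "d")))
  # a large bit-score gap drives w_1 -> 1
  w <- compute_adjusted_weights(c(80, 0), c(2L, 2L))
  expect_gte(w$w[1], 1 - 1e-6)
  m <- parameterize_merged(build_merged_topology(list(h1, h2)), list(h1, h2), w)
  # on edges fully owned by h1's states, merged probabilities match h1
  h1_states <- unique(h1$edges$from)
  lk <- paste(h1$edges$from, h1$edges$to)
  for (i in which(m$edges$from %in% setdiff(h1_states, unique(h2$edges$from)))) {
    k <- paste(m$edges$from[i], m$edges$to[i])
    expect_equal(m$edges$prob[i], h1$edges$prob[lk == k], tolerance = 1e-5)
  }
})

test_that("glocal alignment beats global alignment on a short fragment", {
  aln <- new_alignment(c(x = "ACGTACGTTGCA", y = "ACGAACGTTGGA",
                         z = "TCGTACCTTGCA"))
  h <- build_profile_hmm(induce_subalignment(aln, c("x", "y", "z")))
  m <- parameterize_merged(build_merged_topology(list(h)), list(h),
                           compute_adjusted_weights(0, 3L))
  frag <- "ACGTT"  # interior fragment, 25-40% of the full length
  glocal_score <- attr(align_query(add_glocal(m), frag, id = "f"), "logp")
  global_score <- attr(align_query(m, frag, id = "f"), "logp")
  expect_gte(glocal_score, global_score)
})

test_that("an interior substring aligns to its column window without flanking deletions", {
  aln <- new_alignment(c(x = "ACGTACGTTGCA", y = "ACGAACGTTGGA",
                         z = "TCGTACCTTGCA"))
  h <- build_profile_hmm(induce_subalignment(aln, c("x", "y", "z")),
                         pseudocount_emission = 0.1,
                         pseudocount_transition = 0.1)
  m <- add_glocal(parameterize_merged(build_merged_topology(list(h)), list(h),
                                      compute_adjusted_weights(0, 3L)))
  # substring of x covering columns 4..9
  r <- align_query(m, substr("ACGTACGTTGCA", 4, 9), id = "f")
  expect_equal(r$placements$type, rep("M", 6))
  expect_equal(r$placements$col, 4:9)

  # single-letter query: exactly one placement
  r1 <- align_query(m, "A", id = "one")
  expect_equal(nrow(r1$placements), 1L)
})
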