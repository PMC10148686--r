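test_that("FASTA parsing handles shape, ids, and gap conventions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-G", ">b", "ACCG"), f)
  aln <- read_fasta(f, as_alignment = TRUE)
  expect_s3_class(aln, "aln")
  expect_equal(aln$L, 4L)
  expect_equal(names(aln$rows), c("a", "b"))

  writeLines(c(">a", "ACG", ">b", "AC"), f)
  expect_error(read_fasta(f, as_alignment = TRUE), "unequal lengths")
  seqs <- read_fasta(f)  # fine as unaligned sequences
  expect_equal(unname(nchar(seqs)), c(3L, 2L))

  writeLines(c(">a", "ACG", ">a", "ACT"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")

  writeLines(c(">dots", "A.C-G."), f)
  expect_equal(read_fasta(f)[["dots"]], "A-C-G-")
})

test_that("write/read round trip preserves rows, order, and case", {
  f <- withr::local_tempfile(fileext = ".fasta")
  aln <- new_alignment(c(q2 = "A-cGT", q1 = "ACc-T"))
  write_fasta(aln, f)
  back <- read_fasta(f, as_alignment = TRUE)
  expect_identical(back$rows, aln$rows)

  # backbone-only alignment: all letters stay uppercase
  bb <- new_alignment(c(a = "AC-G", b = "ACCG"))
  write_fasta(bb, f)
  txt <- paste(readLines(f), collapse = "")
  expect_false(grepl("[a-z][A-Z-]*$", gsub(">[ab]", "", txt)))
})

test_that("RNA input is normalized to T internally and restored on output", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r", "ACGU-U", ">d", "ACGT-T"), f)
  aln <- read_fasta(f, as_alignment = TRUE)
  expect_equal(unname(aln$rows["r"]), "ACGT-T")
  expect_equal(aln$rna_ids, "r")
  write_fasta(aln, f)
  out <- readLines(f)
  expect_equal(out[out != ""][2], "ACGU-U")
  expect_equal(out[out != ""][4], "ACGT-T")
})

test_that("induce_subalignment retains all columns with an identity map", {
  aln <- new_alignment(c(a = "A--G", b = "ACCG", c = "AC-G"))
  sub <- induce_subalignment(aln, c("a", "b", "c"))
  expect_identical(sub$rows, aln$rows)
  expect_equal(sub$backbone_columns, 1:4)

  one <- induce_subalignment(aln, "a")
  expect_equal(length(one$rows), 1L)
  expect_equal(one$backbone_columns, 1:4)  # all-gap columns kept here

  expect_error(induce_subalignment(aln, character()), "non-empty")
  expect_error(induce_subalignment(aln, c("a", "zz")), "unknown id")
})

test_that("merge_extended is the identity without queries and preserves L without insertions", {
  bb <- new_alignment(c(a = "ACGT", b = "AC-T"))
  expect_identical(merge_extended(bb, list()), bb)

  r <- extended_row("q", c("A", "C", "T"), c("M", "M", "M"), c(1L, 2L, 4L))
  out <- merge_extended(bb, list(r))
  expect_equal(out$L, 4L)
  expect_equal(unname(out$rows["q"]), "AC-T")
})

test_that("insertion segments of different queries stay in disjoint columns", {
  bb <- new_alignment(c(a = "ACGT", b = "ACTT"))
  q1 <- extended_row("q1", c("A", "C", "g", "G", "T"),
                     c("M", "M", "I", "M", "M"), c(1L, 2L, 2L, 3L, 4L))
  q2 <- extended_row("q2", c("A", "C", "t", "G", "T"),
                     c("M", "M", "I", "M", "M"), c(1L, 2L, 2L, 3L, 4L))
  out <- merge_extended(bb, list(q1, q2))
  expect_equal(out$L, 6L)  # L + 2 inserted letters
  m <- do.call(rbind, strsplit(out$rows, ""))
  ins_cols <- which(apply(m, 2, function(col) any(col %in% letters)))
  expect_equal(length(ins_cols), 2L)
  # the two inserted letters occupy different columns, never sharing one
  expect_equal(sum(m[, ins_cols[1]] != "-"), 1L)
  expect_equal(sum(m[, ins_cols[2]] != "-"), 1L)
  # and by the never-homologous rule they generate zero homology pairs
  expect_length(homology_pairs(out, restrict_to = c("q1", "q2")) |>
                  grep(pattern = "q1#3|q2#3", value = TRUE), 0L)
  # blocks ordered by query input order
  expect_lt(which(m["q1", ] == "g"), which(m["q2", ] == "t"))
})

test_that("restricting the merge to backbone rows reproduces the backbone", {
  set.seed(11)
  for (rep in 1:5) {
    sub <- random_subaln(n_rows = 3, L = 6, gap_prob = 0.25)
    bb <- new_alignment(sub$rows)
    n_ins <- 0L
    rows <- lapply(1:2, function(j) {
      n <- sample(2:4, 1)
      type <- sample(c("M", "I"), n, replace = TRUE, prob = c(0.7, 0.3))
      mcols <- sort(sample(seq_len(bb$L), sum(type == "M")))
      col <- integer(n)
      col[type == "M"] <- mcols
      last <- 0L
      for (i in seq_len(n)) {
        if (type[i] == "M") last <- col[i] else col[i] <- last
      }
      n_ins <<- n_ins + sum(type == "I")
      extended_row(paste0("q", j), sample(c("A", "C"), n, replace = TRUE),
                   type, col)
    })
    out <- merge_extended(bb, rows)
    expect_equal(out$L, bb$L + n_ins)  # column-count invariant
    m <- do.call(rbind, strsplit(out$rows[names(bb$rows)], ""))
    keep <- colSums(m != "-") > 0
    rebuilt <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    # transitivity conservation modulo columns that were all-gap already
    bbm <- do.call(rbind, strsplit(bb$rows, ""))
    bb_keep <- colSums(bbm != "-") > 0
    expect_identical(unname(rebuilt),
                     unname(apply(bbm[, bb_keep, drop = FALSE], 1, paste, collapse = "")))
  }
})

test_that("merge_extended rejects duplicate ids", {
  bb <- new_alignment(c(a = "ACGT"))
  r <- extended_row("a", "A", "M", 1L)
  expect_error(merge_extended(bb, list(r)), "unique")
})
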