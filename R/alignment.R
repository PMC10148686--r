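# Alignment data model and FASTA I/O.
#
# An alignment is stored as a named character vector of equal-length gapped
# strings plus an alphabet tag.  Case is meaningful on output: uppercase
# letters are backbone/match content that may be homologous to other letters,
# lowercase letters were emitted by insertion states and are never homologous
# to anything.  '-' is the only gap character internally; '.' is accepted on
# read and normalized.  RNA is mapped U->T internally and restored on output.

GAP <- "-"
DNA_CORE <- c("A", "C", "G", "T")
DNA_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
AA_CORE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIG <- c("X", "B", "Z", "J", "U", "O")

#' Construct an alignment object
#'
#' Builds the package's alignment container from a named character vector of
#' gapped sequences.  All rows must have identical length; `-` is the gap
#' character.  Uppercase letters are alignable content, lowercase letters mark
#' residues introduced by insertion states (never homologous to anything).
#'
#' @param rows named character vector of gapped strings, names are sequence
#'   ids (unique, non-empty).
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to guess from the letters.
#' @param rna_ids ids of rows that originally used RNA (U) lettering; their
#'   `T`s are turned back into `U`s by [write_fasta()].
#' @return an object of class `"aln"` with elements `rows`, `L` (number of
#'   columns), `alphabet` and `rna_ids`.
#' @seealso [read_fasta()], [write_fasta()], [induce_subalignment()]
#' @export
#' @examples
#' new_alignment(c(a = "AC-G", b = "ACCG"))
new_alignment <- function(rows, alphabet = NULL, rna_ids = character()) {
  if (length(rows) == 0L) stop("alignment must contain at least one row")
  ids <- names(rows)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all rows must be named with non-empty ids")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(range(lens), collapse = "-"), "): not a rectangular alignment")
  }
  if (is.null(alphabet)) alphabet <- guess_alphabet(rows)
  structure(list(rows = rows, L = unname(lens[1L]), alphabet = alphabet,
                 rna_ids = intersect(rna_ids, ids)),
            class = "aln")
}

guess_alphabet <- function(x) {
  letters <- unique(strsplit(paste(toupper(x), collapse = ""), "")[[1]])
  letters <- setdiff(letters, c(GAP, "."))
  if (length(letters) == 0L) return("dna")
  if (all(letters %in% c(DNA_CORE, DNA_AMBIG))) "dna" else "protein"
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns (%s)\n",
              length(x$rows), x$L, x$alphabet))
  show <- utils::head(x$rows, 6L)
  for (id in names(show)) {
    s <- show[[id]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", id, s))
  }
  if (length(x$rows) > 6L) cat(sprintf("  ... and %d more\n", length(x$rows) - 6L))
  invisible(x)
}

# character matrix view (rows x columns), preserving case
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- names(aln$rows)
  m
}

# degap a (vector of) gapped string(s)
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# symbols used for emission estimation / scoring
core_alphabet <- function(alphabet) {
  switch(alphabet, dna = DNA_CORE, protein = AA_CORE,
         stop("unknown alphabet: ", alphabet))
}

normalize_letters <- function(x) {
  # '.' is an alternative gap; U (RNA) maps to T for the numeric core
  x <- gsub(".", "-", x, fixed = TRUE)
  chartr("Uu", "Tt", x)
}

#' Read sequences or an alignment from a FASTA file
#'
#' Case is preserved on read.  `.` gaps are normalized to `-`.  RNA input
#' (containing `U`) is mapped to `T` internally; the affected ids are
#' remembered so that [write_fasta()] restores `U` on output.
#'
#' @param path path to a FASTA file.
#' @param as_alignment if `TRUE`, require equal-length records and return an
#'   [new_alignment()] object; otherwise return a named character vector of
#'   (possibly gapped) sequences.
#' @return an `"aln"` object or a named character vector.
#' @export
read_fasta <- function(path, as_alignment = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  # FASTA headers: id is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  rna <- grepl("U", toupper(seqs), fixed = TRUE) &
    !grepl("T", toupper(seqs), fixed = TRUE)
  seqs <- normalize_letters(seqs)
  if (as_alignment) {
    new_alignment(seqs, rna_ids = names(seqs)[rna])
  } else {
    attr(seqs, "rna_ids") <- names(seqs)[rna]
    seqs
  }
}

#' Write sequences or an alignment to a FASTA file
#'
#' Alignment rows are written as stored: uppercase for match-column letters,
#' lowercase for insertion-state letters, `-` for gaps.  Rows whose input was
#' RNA get their `T`s restored to `U`s.
#'
#' @param x an `"aln"` object or a named character vector of sequences.
#' @param path output file path.
#' @param width line-wrapping width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (inherits(x, "aln")) {
    rows <- x$rows
    rna_ids <- x$rna_ids
  } else {
    rows <- x
    rna_ids <- attr(x, "rna_ids") %||% character()
  }
  if (length(rna_ids)) {
    sel <- names(rows) %in% rna_ids
    rows[sel] <- chartr("Tt", "Uu", rows[sel])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(rows)) {
    writeLines(paste0(">", id), con)
    s <- rows[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Induce a sub-alignment on a subset of rows
#'
#' Restricts an alignment to the given ids.  All columns are retained —
#' columns that become entirely gapped in the subset are excluded later by
#' match-column calling, not here — so the local column coordinates coincide
#' with the parent backbone's column coordinates.
#'
#' @param aln an `"aln"` object.
#' @param ids non-empty subset of row ids.
#' @return an object of class `"subaln"`: an alignment plus
#'   `backbone_columns`, the (here identity) map from local columns to parent
#'   backbone columns (1-based).
#' @export
induce_subalignment <- function(aln, ids) {
  stopifnot(inherits(aln, "aln"))
  if (length(ids) == 0L) stop("ids must be a non-empty subset of row ids")
  missing <- setdiff(ids, names(aln$rows))
  if (length(missing)) stop("unknown id(s): ", paste(missing, collapse = ", "))
  sub <- new_alignment(aln$rows[ids], alphabet = aln$alphabet,
                       rna_ids = aln$rna_ids)
  sub$backbone_columns <- seq_len(aln$L)
  class(sub) <- c("subaln", "aln")
  sub
}
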