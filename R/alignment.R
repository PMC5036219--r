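# Aligned protein sequence sets: construction, file I/O, filtering and
# redundancy reduction. The container is deliberately light: identifiers,
# aligned rows (strings over the amino-acid alphabet plus 'X' and '-'),
# and the common column count.

#' Construct an aligned sequence set
#'
#' A rectangular protein alignment: every row has the same number of
#' columns, identifiers are unique, and residues are upper-case with
#' `.` normalised to `-`.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (same length as
#'   `ids`), using one-letter amino-acid codes, `X` for ambiguity and
#'   `-` (or `.`) for gaps.
#' @return An object of class `aligned_seqs` with elements `ids`,
#'   `seqs` and `n_columns`.
#' @examples
#' aln <- aligned_seqs(c("a", "b"), c("ACD-E", "ACDFE"))
#' aln$n_columns
#' @export
aligned_seqs <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(gsub(".", "-", as.character(seqs), fixed = TRUE))
  if (length(ids) != length(seqs))
    .stop2("`ids` and `seqs` must have the same length")
  if (length(seqs) == 0L) .stop2("empty alignment")
  if (anyDuplicated(ids))
    .stop2("duplicated identifiers: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    .stop2("ragged alignment: row ", bad, " ('", ids[bad], "') has ",
           w[bad], " columns, expected ", w[1L])
  }
  if (w[1L] == 0L) .stop2("alignment has zero columns")
  ok <- grepl(paste0("^[", paste(.AA20, collapse = ""), "X-]*$"), seqs)
  if (!all(ok))
    .stop2("invalid characters in row(s): ",
           paste(ids[!ok], collapse = ", "))
  structure(list(ids = ids, seqs = seqs, n_columns = w[1L]),
            class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("Aligned sequence set: ", length(x$ids), " sequences x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

# character matrix view (rows = sequences, cols = alignment columns)
.aln_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Read a protein multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm files into an [aligned_seqs] set.
#' Residues are upper-cased and `.` gaps normalised to `-`; ragged
#' FASTA input is rejected with the offending identifier.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA, default) or `"stockholm"`.
#' @return An [aligned_seqs] object.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stop2("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(ss) == 0L) .stop2("empty alignment file: ", path)
    aligned_seqs(names(ss), as.character(ss))
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    ss <- Biostrings::unmasked(ma)
    aligned_seqs(names(ss), as.character(ss))
  }
}

#' Write an alignment (or any sequence set) as FASTA
#'
#' @param x An [aligned_seqs] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "aligned_seqs"))
  writeLines(paste0(">", x$ids, "\n", x$seqs), path)
  invisible(path)
}

#' Remove incomplete sequences from an alignment
#'
#' Retains rows whose non-gap fraction is at least `min_coverage`;
#' input order is preserved. This is the incomplete-sequence filter
#' applied before consensus design.
#'
#' @param x An [aligned_seqs] object.
#' @param min_coverage Minimum non-gap fraction in (0, 1]; default 0.9.
#' @return A filtered [aligned_seqs] object.
#' @export
filter_incomplete <- function(x, min_coverage = 0.9) {
  stopifnot(inherits(x, "aligned_seqs"))
  if (!(min_coverage > 0 && min_coverage <= 1))
    .stop2("`min_coverage` must be in (0, 1]")
  n_gap <- nchar(gsub("[^-]", "", x$seqs))
  cov <- 1 - n_gap / x$n_columns
  keep <- cov >= min_coverage
  if (!any(keep)) .stop2("no sequences pass coverage threshold ", min_coverage)
  aligned_seqs(x$ids[keep], x$seqs[keep])
}

# Gap-excluded fractional identity between two residue vectors.
.pair_identity <- function(a, b) {
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (n == 0L) return(0)
  sum(a[both] == b[both]) / n
}

#' Greedy redundancy reduction of an alignment
#'
#' Deterministic greedy representative selection in input order: a row
#' is kept iff its gap-excluded pairwise identity to every previously
#' kept row is below `identity_threshold`. Idempotent.
#'
#' @param x An [aligned_seqs] object.
#' @param identity_threshold Identity in (0, 1) above which a sequence
#'   is considered redundant; default 0.9.
#' @return A reduced [aligned_seqs] object.
#' @export
reduce_redundancy <- function(x, identity_threshold = 0.9) {
  stopifnot(inherits(x, "aligned_seqs"))
  if (!(identity_threshold > 0 && identity_threshold < 1))
    .stop2("`identity_threshold` must be in (0, 1)")
  m <- .aln_matrix(x)
  kept <- integer(0)
  for (i in seq_along(x$ids)) {
    redundant <- FALSE
    for (j in kept) {
      if (.pair_identity(m[i, ], m[j, ]) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  aligned_seqs(x$ids[kept], x$seqs[kept])
}

#' Per-column residue counts of an alignment
#'
#' Tallies, for every alignment column, the occurrences of each of the
#' twenty amino acids, `X`, and the gap symbol. Counts in each column
#' sum to the number of rows.
#'
#' @param x An [aligned_seqs] object.
#' @return A `column_profiles` object: an integer matrix with one row
#'   per symbol (`A`..`Y`, `X`, `-`) and one column per alignment
#'   column.
#' @export
column_profiles <- function(x) {
  stopifnot(inherits(x, "aligned_seqs"))
  m <- .aln_matrix(x)
  symbols <- c(.AA20, "X", "-")
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = symbols))
    as.integer(tab)
  }, integer(length(symbols)))
  rownames(counts) <- symbols
  colnames(counts) <- seq_len(ncol(m))
  structure(counts, class = c("column_profiles", "matrix"))
}
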