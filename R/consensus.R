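# Consensus sequence construction ("most frequent residue per column")
# and comparison of a designed sequence against a reference serpin.

#' Build a consensus sequence from column profiles
#'
#' For every alignment column the most frequently observed residue is
#' selected. Columns in which the gap symbol is the strict plurality
#' symbol are dropped from the consensus (this is how a consensus
#' design can lose residues relative to family members); `X` counts as
#' ambiguity and never wins a column. Ties between residues are broken
#' by `tie_rule` and every tie is reported so it can be audited.
#'
#' @param profiles A `column_profiles` matrix from [column_profiles()],
#'   or an [aligned_seqs] object (profiled internally).
#' @param gap_rule `"drop"` (default): gap-plurality columns are
#'   removed from the consensus and listed in `dropped_columns`;
#'   `"never-drop"`: the best residue is used even where gaps dominate
#'   (an all-gap column is then an error).
#' @param tie_rule `"alphabetical"` (default) or `"random"`; with
#'   `"random"`, set a seed beforehand for reproducibility.
#' @return A `consensus_result` list: `consensus` (ungapped string),
#'   `per_column` (data frame with `column_index`, `winner`,
#'   `winner_fraction`, `runner_up_margin`), `dropped_columns`
#'   (integer vector), and `ties` (data frame of tied columns and the
#'   tied symbols).
#' @export
consensus <- function(profiles, gap_rule = c("drop", "never-drop"),
                      tie_rule = c("alphabetical", "random")) {
  gap_rule <- match.arg(gap_rule)
  tie_rule <- match.arg(tie_rule)
  if (inherits(profiles, "aligned_seqs")) profiles <- column_profiles(profiles)
  if (!inherits(profiles, "column_profiles"))
    .stop2("`profiles` must come from column_profiles()")
  counts <- unclass(profiles)
  n_col <- ncol(counts)
  n_row <- sum(counts[, 1L])
  res_rows <- .AA20                      # 'X' and '-' cannot win
  winners <- character(n_col)
  frac <- numeric(n_col)
  margin <- numeric(n_col)
  dropped <- integer(0)
  ties <- list()
  for (j in seq_len(n_col)) {
    rc <- counts[res_rows, j]
    gap_n <- counts["-", j]
    best <- max(rc)
    if (best == 0L) {
      if (gap_rule == "never-drop")
        .stop2("column ", j, " contains no residues and gap_rule forbids dropping")
      dropped <- c(dropped, j)
      winners[j] <- NA_character_
      next
    }
    if (gap_rule == "drop" && gap_n > best) {
      dropped <- c(dropped, j)
      winners[j] <- NA_character_
      next
    }
    tied <- res_rows[rc == best]
    if (length(tied) > 1L) {
      ties[[length(ties) + 1L]] <-
        data.frame(column_index = j,
                   tied = paste(tied, collapse = "/"),
                   stringsAsFactors = FALSE)
      winners[j] <- if (tie_rule == "alphabetical") sort(tied)[1L]
                    else sample(tied, 1L)
    } else {
      winners[j] <- tied
    }
    frac[j] <- best / n_row
    second <- if (length(rc) > 1L) sort(rc, decreasing = TRUE)[2L] else 0L
    margin[j] <- (best - second) / n_row
  }
  keep <- !is.na(winners)
  out <- list(
    consensus = paste(winners[keep], collapse = ""),
    per_column = data.frame(column_index = which(keep),
                            winner = winners[keep],
                            winner_fraction = frac[keep],
                            runner_up_margin = margin[keep],
                            stringsAsFactors = FALSE),
    dropped_columns = dropped,
    ties = if (length(ties)) do.call(rbind, ties)
           else data.frame(column_index = integer(0), tied = character(0)))
  class(out) <- "consensus_result"
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus sequence (", nchar(x$consensus), " aa; ",
      length(x$dropped_columns), " gap-plurality column(s) dropped; ",
      nrow(x$ties), " tie(s))\n", sep = "")
  invisible(x)
}

#' Write a consensus sequence as ungapped FASTA
#'
#' @param x A `consensus_result` from [consensus()].
#' @param path Output path.
#' @param id FASTA identifier line.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(x, path, id = "consensus") {
  stopifnot(inherits(x, "consensus_result"))
  writeLines(c(paste0(">", id), x$consensus), path)
  invisible(path)
}

#' Compare a designed sequence to a reference by global alignment
#'
#' Needleman-Wunsch global pairwise alignment (BLOSUM62, affine gaps)
#' of a consensus/designed sequence against a reference serpin.
#' Reports the number of residue differences (mismatched aligned pairs
#' plus inserted/deleted residues), percent identity with two
#' denominators (full alignment length, and the shorter sequence), the
#' indel positions, and a dual-numbering map in the convention
#' `<refAA><refPos><tgtAA>_<tgtPos>` (e.g. `Q105R_79`), so a residue
#' can be referred to in either numbering.
#'
#' @param target_seq Designed/consensus amino-acid sequence (ungapped).
#' @param reference_seq Reference amino-acid sequence (ungapped).
#' @param gap_open Gap opening penalty (default 10).
#' @param gap_extend Gap extension penalty (default 0.5).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @return A `reference_comparison` list: `n_differences`,
#'   `percent_identity` (alignment-length denominator),
#'   `percent_identity_shorter`, `indel_positions` (alignment columns
#'   containing a gap), and `numbering_map` (data frame with
#'   `reference_position`, `reference_residue`, `target_position`,
#'   `target_residue`, `label`).
#' @export
compare_to_reference <- function(target_seq, reference_seq,
                                 gap_open = 10, gap_extend = 0.5,
                                 matrix = "BLOSUM62") {
  target_seq <- toupper(as.character(target_seq))
  reference_seq <- toupper(as.character(reference_seq))
  if (nchar(target_seq) == 0L || nchar(reference_seq) == 0L)
    .stop2("sequences must be non-empty")
  pat <- paste0("^[", paste(.AA20, collapse = ""), "]+$")
  if (!grepl(pat, target_seq) || !grepl(pat, reference_seq))
    .stop2("sequences must contain only the 20 amino-acid letters")
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(target_seq),
    subject = Biostrings::AAString(reference_seq),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  tgt <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  ref <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  n_al <- length(tgt)
  gap_t <- tgt == "-"
  gap_r <- ref == "-"
  aligned <- !gap_t & !gap_r
  identities <- sum(aligned & tgt == ref)
  n_diff <- sum(aligned & tgt != ref) + sum(gap_t) + sum(gap_r)
  tgt_pos <- ifelse(gap_t, NA_integer_, cumsum(!gap_t))
  ref_pos <- ifelse(gap_r, NA_integer_, cumsum(!gap_r))
  lab <- ifelse(aligned,
                paste0(ref, ref_pos, tgt, "_", tgt_pos),
                ifelse(gap_t, paste0(ref, ref_pos, "del"),
                       paste0("ins", tgt, "_", tgt_pos)))
  out <- list(
    n_differences = n_diff,
    percent_identity = 100 * identities / n_al,
    percent_identity_shorter =
      100 * identities / min(nchar(target_seq), nchar(reference_seq)),
    indel_positions = which(gap_t | gap_r),
    numbering_map = data.frame(reference_position = ref_pos,
                               reference_residue = ref,
                               target_position = tgt_pos,
                               target_residue = tgt,
                               label = lab,
                               stringsAsFactors = FALSE))
  class(out) <- "reference_comparison"
  out
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat("Reference comparison: ", x$n_differences, " difference(s); ",
      sprintf("%.1f%%", x$percent_identity), " identity (alignment length), ",
      sprintf("%.1f%%", x$percent_identity_shorter), " (shorter sequence)\n",
      sep = "")
  invisible(x)
}
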