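#' Bisulfite-aware alignment scoring scheme
#'
#' Defaults: match +1, ref-C aligned to read-T ("converted") +1, mismatch -2,
#' gap -3, no end-gap discount (amplicons cover the full window). A converted
#' column must score as a full match, otherwise calls are biased toward
#' "methylated" in heavily converted reads.
#'
#' @param match,converted,mismatch,gap Integer column scores.
#' @return A named list used by [bisulfite_align()] and [call_methylation()].
#' @export
bisulfite_scoring <- function(match = 1L, converted = 1L,
                              mismatch = -2L, gap = -3L) {
  s <- list(match = as.integer(match), converted = as.integer(converted),
            mismatch = as.integer(mismatch), gap = as.integer(gap))
  if (any(vapply(s, is.na, logical(1)))) stop("scoring values must be integers")
  s
}

#' Global bisulfite-aware pairwise alignment
#'
#' Needleman-Wunsch global alignment of a bisulfite-converted read against its
#' untreated reference, under an asymmetric scheme where a reference C aligned
#' to a read T is a penalty-free "converted" column. Among equal-score
#' alignments the one with fewer gap columns is returned, with a fixed
#' traceback preference (substitution, then gap in the read, then gap in the
#' reference) so results are reproducible.
#'
#' @param ref_seq,read_seq Non-empty nucleotide strings (or `ref_region` /
#'   `bs_read` objects).
#' @param scoring A [bisulfite_scoring()] list.
#' @param mode `"c_strand"` (default): ref C vs read T is converted.
#'   `"g_strand"`: the mirrored rule (ref G vs read A) for reads sequenced
#'   from the opposite strand.
#' @return A `bs_alignment`: `ref_aln` and `read_aln` (equal-length gapped
#'   strings, gap `"-"`), `ops` (per column: `match`, `converted`, `mismatch`,
#'   `gap`), `score`, `n_gap`.
#' @examples
#' bisulfite_align("ACGT", "ATGT")$score # the C->T column is penalty-free
#' @export
bisulfite_align <- function(ref_seq, read_seq, scoring = bisulfite_scoring(),
                            mode = c("c_strand", "g_strand")) {
  mode <- match.arg(mode)
  if (inherits(ref_seq, "ref_region")) ref_seq <- ref_seq$sequence
  if (inherits(read_seq, "bs_read")) read_seq <- read_seq$sequence
  ref_seq <- toupper(as.character(ref_seq))
  read_seq <- toupper(as.character(read_seq))
  if (nchar(ref_seq) == 0L || nchar(read_seq) == 0L) {
    stop("input error: empty sequence", call. = FALSE)
  }
  conv <- if (mode == "c_strand") c("C", "T") else c("G", "A")
  r <- .nw_align_cpp(ref_seq, read_seq, scoring$match, scoring$converted,
                     scoring$mismatch, scoring$gap, conv[1], conv[2])
  ops <- chartr("MCXG", "mcxg", r$ops)
  ops <- strsplit(ops, "", fixed = TRUE)[[1]]
  ops <- c(m = "match", c = "converted", x = "mismatch", g = "gap")[ops]
  structure(list(ref_aln = r$ref_aln, read_aln = r$read_aln,
                 ops = unname(ops), score = r$score, n_gap = r$n_gap,
                 scoring = scoring, mode = mode),
            class = "bs_alignment")
}

#' @export
print.bs_alignment <- function(x, width = 60L, ...) {
  cat("<bs_alignment> score ", x$score, ", ", length(x$ops), " columns (",
      sum(x$ops == "converted"), " converted, ", sum(x$ops == "mismatch"),
      " mismatch, ", x$n_gap, " gap)\n", sep = "")
  n <- nchar(x$ref_aln)
  marks <- c(match = "|", converted = "*", mismatch = " ", gap = " ")[x$ops]
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    cat("ref  ", substr(x$ref_aln, s, e), "\n",
        "     ", paste(marks[s:e], collapse = ""), "\n",
        "read ", substr(x$read_aln, s, e), "\n", sep = "")
    if (e < n) cat("\n")
  }
  invisible(x)
}

# fraction of columns that are match or converted
alignment_identity <- function(aln) {
  mean(aln$ops %in% c("match", "converted"))
}
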