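#' Promoter reference window with upstream coordinates
#'
#' Constructs a `ref_region`: a promoter (sub)sequence addressed with 1-based
#' negative upstream coordinates. Position -1 is the base immediately 5' of the
#' start codon's A; positions decrease moving 5', so `upstream_start` (the
#' 5'-most base) is more negative than `upstream_end`.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param upstream_start Negative integer, coordinate of the 5'-most base.
#' @param upstream_end Negative integer, coordinate of the 3'-most base.
#' @param region_id Text label, e.g. `"Sdh3-1"`.
#' @param strand `"plus"` or `"minus"`, relative to the gene.
#' @return An object of class `ref_region` with fields `region_id`, `sequence`
#'   (uppercase), `upstream_start`, `upstream_end`, `strand`.
#' @examples
#' ref_region("ACGTACGT", -8, -1, region_id = "demo")
#' @export
ref_region <- function(sequence, upstream_start, upstream_end,
                       region_id = "region", strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  sequence <- toupper(as.character(sequence))
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("alphabet error: sequence contains non-{A,C,G,T,N} characters: '",
         substr(bad, 1L, 10L), "'", call. = FALSE)
  }
  upstream_start <- as.integer(upstream_start)
  upstream_end <- as.integer(upstream_end)
  if (is.na(upstream_start) || is.na(upstream_end) ||
      upstream_start >= 0L || upstream_end >= 0L || upstream_start > upstream_end) {
    stop("coordinate error: need upstream_start <= upstream_end < 0", call. = FALSE)
  }
  if (nchar(sequence) != upstream_end - upstream_start + 1L) {
    stop("coordinate error: window ", upstream_start, "..", upstream_end,
         " implies length ", upstream_end - upstream_start + 1L,
         " but sequence has ", nchar(sequence), call. = FALSE)
  }
  structure(
    list(region_id = region_id, sequence = sequence,
         upstream_start = upstream_start, upstream_end = upstream_end,
         strand = strand),
    class = "ref_region"
  )
}

#' @export
print.ref_region <- function(x, ...) {
  cat("<ref_region> ", x$region_id, "  window ", x$upstream_start, "..",
      x$upstream_end, " (", nchar(x$sequence), " nt, ", x$strand,
      " strand)\n", sep = "")
  s <- x$sequence
  if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

#' Load a promoter reference window from FASTA
#'
#' Reads one record from a FASTA file and attaches an upstream coordinate
#' window. If the record is exactly as long as the window it is used whole;
#' if longer, the record is assumed to end at position -1 (sequence immediately
#' upstream of the start codon) and the window is extracted as a sub-range.
#' Minus-strand requests return the reverse complement with coordinates
#' preserved.
#'
#' @param fasta_source Path to a FASTA file (multi-record, wrapped lines OK).
#' @param upstream_start,upstream_end Window coordinates, negative integers
#'   with `upstream_start <= upstream_end < 0` (e.g. -488 and -238).
#' @param strand `"plus"` (default) or `"minus"`.
#' @param record Record name or index to use when the file holds several
#'   (default: first).
#' @param region_id Label for the region; defaults to the FASTA record name.
#' @return A [ref_region].
#' @export
load_reference <- function(fasta_source, upstream_start, upstream_end,
                           strand = c("plus", "minus"), record = 1L,
                           region_id = NULL) {
  strand <- match.arg(strand)
  set <- tryCatch(Biostrings::readDNAStringSet(fasta_source),
                  error = function(e) stop("parse error: cannot read FASTA '",
                                           fasta_source, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) < 1L) stop("parse error: FASTA has no records", call. = FALSE)
  rec <- set[[record]]
  name <- names(set)[if (is.numeric(record)) record else match(record, names(set))]
  if (is.null(region_id)) region_id <- sub("\\s.*$", "", name)
  upstream_start <- as.integer(upstream_start)
  upstream_end <- as.integer(upstream_end)
  wlen <- upstream_end - upstream_start + 1L
  L <- length(rec)
  if (L == wlen) {
    seq <- as.character(rec)
  } else if (L >= -upstream_start) {
    # record ends at -1; position p maps to index L + p + 1
    seq <- as.character(Biostrings::subseq(rec, L + upstream_start + 1L,
                                           L + upstream_end + 1L))
  } else {
    stop("coordinate error: window ", upstream_start, "..", upstream_end,
         " outside record of length ", L, call. = FALSE)
  }
  if (strand == "minus") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  ref_region(seq, upstream_start, upstream_end, region_id = region_id,
             strand = strand)
}

# context of the cytosine at index i of seq (uppercase), given window length L.
# Returns one of "CG","CNG","CNN","edge". A class is assigned as soon as the
# bases it actually needs are present and unambiguous: CG needs only +1.
.classify_context <- function(seq, i, L = nchar(seq)) {
  b1 <- if (i + 1L <= L) substr(seq, i + 1L, i + 1L) else ""
  b2 <- if (i + 2L <= L) substr(seq, i + 2L, i + 2L) else ""
  if (b1 == "G") return("CG")
  if (b1 %in% c("A", "C", "T")) {
    if (b2 == "G") return("CNG")
    if (b2 %in% c("A", "C", "T")) return("CNN")
  }
  "edge"
}

#' Find and classify cytosine methylation sites
#'
#' Scans a promoter window for cytosines and classifies each into the plant
#' methylation contexts with priority CG > CNG > CNN: a site is CG iff the
#' next base is G; CNG iff the next base is A/C/T and the base after is G;
#' CNN otherwise. A cytosine whose required context bases lie beyond the
#' window 3' end or are N is marked `edge_excluded` and carries no class in
#' the counts.
#'
#' @param region A [ref_region].
#' @param both_strands If `TRUE`, also scan the reverse complement and report
#'   minus-strand sites (coordinates mirrored onto the same upstream axis).
#'   Default `FALSE`: only the provided strand is analyzed, matching
#'   single-strand amplicon sequencing.
#' @return A `site_map`: list with `region_id`, `sites` (data.frame with
#'   columns `position`, `context`, `trinucleotide`, `edge_excluded`,
#'   `strand`), and `counts` (named vector `CG`, `CNG`, `CNN`, `edge`).
#' @examples
#' r <- ref_region("CGACGACGTTAAAATACGAAAT", -22, -1)
#' find_cytosine_sites(r)$counts
#' @export
find_cytosine_sites <- function(region, both_strands = FALSE) {
  stopifnot(inherits(region, "ref_region"))
  scan1 <- function(seq, strand_label, positions) {
    L <- nchar(seq)
    idx <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
    if (length(idx) == 0L) {
      return(data.frame(position = integer(0), context = character(0),
                        trinucleotide = character(0),
                        edge_excluded = logical(0), strand = character(0),
                        stringsAsFactors = FALSE))
    }
    ctx <- vapply(idx, function(i) .classify_context(seq, i, L), character(1))
    tri <- vapply(idx, function(i) {
      t <- substr(seq, i, min(i + 2L, L))
      paste0(t, strrep("N", 3L - nchar(t)))
    }, character(1))
    data.frame(position = positions[idx],
               context = ifelse(ctx == "edge", NA_character_, ctx),
               trinucleotide = tri,
               edge_excluded = ctx == "edge",
               strand = strand_label,
               stringsAsFactors = FALSE)
  }
  positions <- seq.int(region$upstream_start, region$upstream_end)
  sites <- scan1(region$sequence, "+", positions)
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(region$sequence)))
    minus <- scan1(rc, "-", rev(positions))
    sites <- rbind(sites, minus)
    sites <- sites[order(sites$position, sites$strand), , drop = FALSE]
  }
  rownames(sites) <- NULL
  counts <- c(CG = sum(sites$context == "CG", na.rm = TRUE),
              CNG = sum(sites$context == "CNG", na.rm = TRUE),
              CNN = sum(sites$context == "CNN", na.rm = TRUE),
              edge = sum(sites$edge_excluded))
  structure(list(region_id = region$region_id, sites = sites, counts = counts),
            class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat("<site_map> ", x$region_id, ": ", x$counts[["CG"]], " CG, ",
      x$counts[["CNG"]], " CNG, ", x$counts[["CNN"]], " CNN",
      if (x$counts[["edge"]] > 0)
        paste0(" (+", x$counts[["edge"]], " edge-excluded)") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.site_map <- function(object, ...) {
  print(object)
  s <- object$sites[!object$sites$edge_excluded, , drop = FALSE]
  if (nrow(s)) print(utils::head(s, 10L))
  invisible(object)
}

# countable (non-edge-excluded) site positions, in window order
countable_positions <- function(sitemap, strand = "+") {
  s <- sitemap$sites
  s$position[!s$edge_excluded & s$strand == strand]
}

site_contexts <- function(sitemap, strand = "+") {
  s <- sitemap$sites
  stats::setNames(s$context[!s$edge_excluded & s$strand == strand],
                  s$position[!s$edge_excluded & s$strand == strand])
}

#' Write a site map as TSV
#'
#' Columns: `region_id`, `position`, `context` (`.` for edge-excluded),
#' `trinucleotide`, `edge_excluded`.
#'
#' @param sitemap A `site_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sitemap_tsv <- function(sitemap, path) {
  d <- sitemap$sites
  out <- data.frame(region_id = sitemap$region_id,
                    position = d$position,
                    context = ifelse(is.na(d$context), ".", d$context),
                    trinucleotide = d$trinucleotide,
                    edge_excluded = d$edge_excluded,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a site map in BED-like form
#'
#' Converts upstream promoter coordinates to 0-based half-open intervals on a
#' forward axis where the 5'-most window base is 0. The offset between the two
#' coordinate systems is recorded in a `track` header comment.
#'
#' @param sitemap A `site_map`.
#' @param region The [ref_region] the map was built from.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sitemap_bed <- function(sitemap, region, path) {
  d <- sitemap$sites
  start0 <- d$position - region$upstream_start # 0-based
  lines <- c(
    sprintf("# offset: bed_start = promoter_position - (%d)",
            region$upstream_start),
    sprintf("%s\t%d\t%d\t%s\t0\t%s",
            sitemap$region_id, start0, start0 + 1L,
            ifelse(is.na(d$context), "edge", d$context), d$strand)
  )
  writeLines(lines, path)
  invisible(path)
}
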