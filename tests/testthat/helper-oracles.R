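# Independent oracles and small generators used across the suite.

# Brute-force per-position context classifier: explicit if/else on the raw
# string, no shared code with find_cytosine_sites(). Returns a data.frame of
# 1-based indices and classes ("CG","CNG","CNN","edge") for every C.
brute_classify <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (i in seq_len(n)) {
    if (substr(seq, i, i) != "C") next
    b1 <- if (i + 1 <= n) substr(seq, i + 1, i + 1) else NA
    b2 <- if (i + 2 <= n) substr(seq, i + 2, i + 2) else NA
    cls <- if (!is.na(b1) && b1 == "G") {
      "CG"
    } else if (!is.na(b1) && b1 %in% c("A", "C", "T")) {
      if (!is.na(b2) && b2 == "G") "CNG"
      else if (!is.na(b2) && b2 %in% c("A", "C", "T")) "CNN"
      else "edge"
    } else {
      "edge"
    }
    out[[length(out) + 1]] <- data.frame(index = i, class = cls,
                                         stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(index = integer(0), class = character(0)))
  }
  do.call(rbind, out)
}

# Exhaustive enumeration of all monotone global alignments; returns the
# maximum total score. Plain recursion, no DP sharing with the implementation.
enum_align_score <- function(a, b, match = 1, converted = 1, mismatch = -2,
                             gap = -3, conv = c("C", "T")) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  sub <- function(x, y) {
    if (x == y && x != "N") match
    else if (x == conv[1] && y == conv[2]) converted
    else mismatch
  }
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j - 1) + sub(av[i], bv[j]))
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# region + sitemap + planted state in one step, for round-trip style tests
random_truth <- function(len = 60, gc = 0.5, p = c(0.5, 0.5, 0.5),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region <- ref_region(random_dna(len, gc), -len, -1L, region_id = "rnd")
  sitemap <- find_cytosine_sites(region)
  state <- plant_methylation(sitemap, p[1], p[2], p[3])
  list(region = region, sitemap = sitemap, state = state)
}

table1_counts_path <- function() {
  system.file("extdata", "table1_counts.tsv", package = "bsamplicon",
              mustWork = TRUE)
}

oligos_path <- function() {
  system.file("extdata", "dnmt_substrate_oligos.fasta",
              package = "bsamplicon", mustWork = TRUE)
}
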