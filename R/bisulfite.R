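#' Planted methylation state
#'
#' A binary methylation status for every countable (non-edge-excluded) site of
#' a site map, used as simulation truth.
#'
#' @param sitemap A `site_map`.
#' @param status Character vector over `"methylated"`/`"unmethylated"`, either
#'   named by site position or in site order.
#' @return A `meth_state`: list with `region_id` and `status` (named by
#'   position).
#' @export
meth_state <- function(sitemap, status) {
  pos <- countable_positions(sitemap)
  if (is.null(names(status))) {
    if (length(status) != length(pos)) {
      stop("status length ", length(status), " != ", length(pos), " sites")
    }
    names(status) <- pos
  }
  if (!setequal(names(status), as.character(pos))) {
    stop("status positions do not match the site map's countable sites")
  }
  status <- status[as.character(pos)]
  if (!all(status %in% c("methylated", "unmethylated"))) {
    stop("status values must be 'methylated' or 'unmethylated'")
  }
  structure(list(region_id = sitemap$region_id, status = status),
            class = "meth_state")
}

#' Simulate bisulfite conversion of a reference window
#'
#' Applies the bisulfite conversion model to a reference sequence given a
#' planted per-site methylation state: each cytosine at an unmethylated site,
#' and each edge-excluded cytosine, is converted C->T independently with
#' probability `efficiency`; methylated cytosines are fully protected (any
#' inappropriate conversion of methylated C is part of `error_rate`).
#' Independent per-base sequencing errors are applied afterwards at
#' `error_rate`, uniform over the three other bases. Deterministic under
#' `seed`.
#'
#' @param region A [ref_region].
#' @param sitemap Its `site_map`.
#' @param state A [meth_state] covering all countable sites.
#' @param efficiency Conversion efficiency in `[0,1]`.
#' @param error_rate Per-base sequencing error rate in `[0,1]`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param read_id Label for the read.
#' @return A `bs_read`: list with `read_id`, `sequence`, `provenance`
#'   (`"simulated"`), `conversion_efficiency_used`, `error_rate_used`,
#'   `rng_seed`.
#' @export
convert_in_silico <- function(region, sitemap, state, efficiency = 0.85,
                              error_rate = 0, seed = NULL,
                              read_id = paste0(region$region_id, "_bs")) {
  stopifnot(inherits(region, "ref_region"), inherits(sitemap, "site_map"))
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1) {
    stop("parameter error: efficiency must be in [0,1]", call. = FALSE)
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("parameter error: error_rate must be in [0,1]", call. = FALSE)
  }
  if (inherits(state, "meth_state")) state <- state$status
  pos_all <- seq.int(region$upstream_start, region$upstream_end)
  bases <- strsplit(region$sequence, "", fixed = TRUE)[[1]]

  sites <- sitemap$sites[sitemap$sites$strand == "+", , drop = FALSE]
  countable <- sites$position[!sites$edge_excluded]
  if (!setequal(names(state), as.character(countable))) {
    stop("state does not cover the site map's countable sites", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  # cytosines eligible for conversion: unmethylated sites + edge-excluded Cs
  unmeth_pos <- as.integer(names(state)[state == "unmethylated"])
  edge_pos <- sites$position[sites$edge_excluded]
  conv_idx <- match(c(unmeth_pos, edge_pos), pos_all)
  if (length(conv_idx)) {
    hit <- stats::runif(length(conv_idx)) < efficiency
    bases[conv_idx[hit]] <- "T"
  }
  if (error_rate > 0) {
    err <- which(stats::runif(length(bases)) < error_rate)
    if (length(err)) {
      others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))
      bases[err] <- vapply(bases[err],
                           function(b) sample(others[[b]], 1L), character(1))
    }
  }
  structure(list(read_id = read_id, sequence = paste(bases, collapse = ""),
                 provenance = "simulated",
                 conversion_efficiency_used = efficiency,
                 error_rate_used = error_rate,
                 rng_seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "bs_read")
}

#' @export
print.bs_read <- function(x, ...) {
  cat("<bs_read> ", x$read_id, " (", nchar(x$sequence), " nt, ",
      x$provenance, ")\n", sep = "")
  if (x$provenance == "simulated") {
    cat("  efficiency ", x$conversion_efficiency_used, ", error rate ",
        x$error_rate_used, ", seed ", x$rng_seed, "\n", sep = "")
  }
  invisible(x)
}

#' Call per-site methylation from a bisulfite-converted read
#'
#' Aligns the converted amplicon to its untreated reference with
#' [bisulfite_align()] and reads off methylation status at every countable
#' site: an aligned read C means the cytosine was protected (methylated), an
#' aligned T means it was converted (unmethylated), a gap or any other base
#' gives `no_call`. The bisulfite conversion rate is estimated over reference
#' cytosines in the same alignment.
#'
#' @param region A [ref_region].
#' @param sitemap Its `site_map`.
#' @param read A `bs_read`, FASTA path, or plain sequence string.
#' @param sample Sample label, e.g. `"day 1"`.
#' @param scoring A [bisulfite_scoring()] list.
#' @param mode Passed to [bisulfite_align()].
#' @param conversion_denominator `"all_c"` (default): the rate's denominator
#'   is every aligned reference cytosine, methylated sites included.
#'   `"non_site_c"`: only cytosines that are not countable sites. Both values
#'   are stored; the switch selects which one `conversion_rate_percent`
#'   reports.
#' @param min_identity Alignment-quality guard: error if fewer than this
#'   fraction of alignment columns are match/converted (default 0.5, against
#'   a wrong amplicon).
#' @return A `bs_callset`: `region_id`, `sample`, `calls` (data.frame
#'   `position`, `context`, `status`, `evidence_base`),
#'   `conversion_rate_percent`, `conversion_rate_all_c`,
#'   `conversion_rate_non_site_c`, `alignment`.
#' @export
call_methylation <- function(region, sitemap, read, sample = "sample",
                             scoring = bisulfite_scoring(),
                             mode = c("c_strand", "g_strand"),
                             conversion_denominator = c("all_c", "non_site_c"),
                             min_identity = 0.5) {
  mode <- match.arg(mode)
  conversion_denominator <- match.arg(conversion_denominator)
  stopifnot(inherits(region, "ref_region"), inherits(sitemap, "site_map"))
  if (is.character(read) && length(read) == 1L && file.exists(read)) {
    set <- Biostrings::readDNAStringSet(read)
    read <- as.character(set[[1L]])
  } else if (inherits(read, "bs_read")) {
    read <- read$sequence
  }
  aln <- bisulfite_align(region$sequence, read, scoring = scoring, mode = mode)
  ident <- alignment_identity(aln)
  if (ident < min_identity) {
    stop("alignment-quality error: identity ", sprintf("%.1f%%", 100 * ident),
         " below guard ", sprintf("%.0f%%", 100 * min_identity),
         " (score ", aln$score, "); wrong amplicon?", call. = FALSE)
  }
  ra <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  da <- strsplit(aln$read_aln, "", fixed = TRUE)[[1]]
  # map reference positions to alignment columns
  ref_cols <- which(ra != "-")
  pos_all <- seq.int(region$upstream_start, region$upstream_end)

  contexts <- site_contexts(sitemap)
  pos <- as.integer(names(contexts))
  col <- ref_cols[match(pos, pos_all)]
  ev <- da[col]
  status <- ifelse(ev == "C", "methylated",
                   ifelse(ev == "T", "unmethylated", "no_call"))
  calls <- data.frame(position = pos, context = unname(contexts),
                      status = status, evidence_base = ev,
                      stringsAsFactors = FALSE)

  # conversion rate over reference cytosines aligned to a non-gap base
  is_c <- ra == "C"
  ref_pos_at_col <- rep(NA_integer_, length(ra))
  ref_pos_at_col[ref_cols] <- pos_all
  aligned <- is_c & da != "-"
  converted <- aligned & da == "T"
  rate_all <- if (sum(aligned) > 0) 100 * sum(converted) / sum(aligned) else NA_real_
  non_site <- aligned & !(ref_pos_at_col %in% pos)
  rate_non_site <- if (sum(non_site) > 0) {
    100 * sum(converted & non_site) / sum(non_site)
  } else NA_real_
  rate <- if (conversion_denominator == "all_c") rate_all else rate_non_site

  structure(list(region_id = region$region_id, sample = sample, calls = calls,
                 conversion_rate_percent = rate,
                 conversion_rate_all_c = rate_all,
                 conversion_rate_non_site_c = rate_non_site,
                 conversion_denominator = conversion_denominator,
                 alignment = aln),
            class = "bs_callset")
}

#' @export
print.bs_callset <- function(x, ...) {
  tab <- table(factor(x$calls$status,
                      c("methylated", "unmethylated", "no_call")))
  cat("<bs_callset> ", x$region_id, " / ", x$sample, ": ",
      tab[["methylated"]], " methylated, ", tab[["unmethylated"]],
      " unmethylated, ", tab[["no_call"]], " no_call; conversion ",
      if (is.na(x$conversion_rate_percent)) "NA" else
        sprintf("%.1f%%", x$conversion_rate_percent),
      " (", x$conversion_denominator, ")\n", sep = "")
  invisible(x)
}

#' Bisulfite conversion rate of a call set
#'
#' @param callset A `bs_callset` from [call_methylation()].
#' @return The stored conversion rate as a percentage rounded half-up to one
#'   decimal.
#' @export
conversion_rate <- function(callset) {
  stopifnot(inherits(callset, "bs_callset"))
  round_half_up(callset$conversion_rate_percent, 1L)
}

#' Write a call set as TSV
#'
#' Columns: `region_id`, `sample`, `position`, `context`, `status`,
#' `evidence_base`; the conversion rate is recorded in a header comment.
#'
#' @param callset A `bs_callset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_callset_tsv <- function(callset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# conversion_rate_percent=%.6f denominator=%s",
                     callset$conversion_rate_percent,
                     callset$conversion_denominator), con)
  d <- data.frame(region_id = callset$region_id, sample = callset$sample,
                  callset$calls, stringsAsFactors = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call set written by [write_callset_tsv()]
#'
#' @param path TSV path.
#' @return A `bs_callset` (without the alignment).
#' @export
read_callset_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- NA_real_
  denom <- "all_c"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("conversion_rate_percent=([0-9.NAa]+)", first))[[1]]
    if (length(m) == 2L) rate <- suppressWarnings(as.numeric(m[2]))
    m <- regmatches(first, regexec("denominator=(\\S+)", first))[[1]]
    if (length(m) == 2L) denom <- m[2]
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  structure(list(region_id = d$region_id[1], sample = as.character(d$sample[1]),
                 calls = d[, c("position", "context", "status",
                               "evidence_base")],
                 conversion_rate_percent = rate,
                 conversion_rate_all_c = if (denom == "all_c") rate else NA_real_,
                 conversion_rate_non_site_c = if (denom == "non_site_c") rate else NA_real_,
                 conversion_denominator = denom, alignment = NULL),
            class = "bs_callset")
}
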