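#' Round half-up
#'
#' Rounds with ties going away from zero (half-up), the convention used for
#' all reported percentages: 56.25 rounds to 56.3, where banker's rounding
#' would give 56.2.
#'
#' @param x Numeric vector (non-negative in all reporting uses).
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percent methylation from site and unmethylated counts
#'
#' `100 * (n_sites - n_unmethylated) / n_sites`, rounded half-up to one
#' decimal — the per-context "Methylation (%)" statistic of a promoter
#' summary table.
#'
#' @param n_sites Number of countable sites in the context class (> 0).
#' @param n_unmethylated Number of those called unmethylated.
#' @return Percentage in `[0, 100]`, one decimal.
#' @examples
#' methylation_percent(7, 4)   # 42.9
#' methylation_percent(48, 21) # 56.3 (half-up from 56.25)
#' @export
methylation_percent <- function(n_sites, n_unmethylated) {
  if (any(n_sites == 0)) {
    stop("undefined-percentage error: n_sites is 0", call. = FALSE)
  }
  if (any(n_unmethylated < 0 | n_unmethylated > n_sites)) {
    stop("need 0 <= n_unmethylated <= n_sites", call. = FALSE)
  }
  round_half_up(100 * (n_sites - n_unmethylated) / n_sites, 1L)
}

#' Per-context summary of a call set
#'
#' Tallies sites, unmethylated calls and percent methylation for each context
#' class (CG, CNG, CNN). `no_call` sites are excluded from both numerator and
#' denominator and reported in their own column; a class with zero countable
#' sites is omitted with a notice.
#'
#' @param callset A `bs_callset`.
#' @param sitemap The matching `site_map`.
#' @return A data.frame of class `meth_class_summary` with columns
#'   `region_id`, `sample`, `context`, `n_sites`, `n_unmethylated`,
#'   `n_no_call`, `percent_methylated`.
#' @export
summarize_callset <- function(callset, sitemap) {
  stopifnot(inherits(callset, "bs_callset"), inherits(sitemap, "site_map"))
  contexts <- site_contexts(sitemap)
  if (!setequal(callset$calls$position, as.integer(names(contexts)))) {
    stop("callset positions do not match the site map", call. = FALSE)
  }
  rows <- lapply(c("CG", "CNG", "CNN"), function(cl) {
    calls <- callset$calls[callset$calls$context == cl, , drop = FALSE]
    n_nc <- sum(calls$status == "no_call")
    n <- nrow(calls) - n_nc
    if (nrow(calls) == 0L) {
      message("context ", cl, " has no countable sites in ",
              callset$region_id, "; omitted")
      return(NULL)
    }
    if (n == 0L) {
      message("context ", cl, " has only no_call sites in ",
              callset$region_id, "/", callset$sample, "; omitted")
      return(NULL)
    }
    u <- sum(calls$status == "unmethylated")
    data.frame(region_id = callset$region_id, sample = callset$sample,
               context = cl, n_sites = n, n_unmethylated = u,
               n_no_call = n_nc,
               percent_methylated = methylation_percent(n, u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("meth_class_summary", "data.frame")
  out
}

#' Distribution of unmethylated cytosines across context classes
#'
#' For one sample, the percentage of all unmethylated cytosines falling in
#' CG, CNG and CNN: `100 * n_unmethylated_class / total unmethylated`,
#' half-up to one decimal. The three values sum to 100 within 0.2 rounding
#' slack.
#'
#' @param summaries A `meth_class_summary` (one sample) or data.frame with
#'   columns `context` and `n_unmethylated`.
#' @return Named numeric vector `c(CG=, CNG=, CNN=)` of percentages.
#' @examples
#' unmethylated_distribution(data.frame(
#'   context = c("CG", "CNG", "CNN"), n_unmethylated = c(4, 1, 6)))
#' @export
unmethylated_distribution <- function(summaries) {
  u <- stats::setNames(rep(0, 3), c("CG", "CNG", "CNN"))
  got <- tapply(summaries$n_unmethylated, summaries$context, sum)
  u[names(got)] <- got
  tot <- sum(u)
  if (tot == 0) {
    stop("undefined-distribution error: no unmethylated sites", call. = FALSE)
  }
  round_half_up(100 * u / tot, 1L)
}

#' Classify a three-day methylation trajectory
#'
#' Maps the ordered status triple of one site across the three sampled days
#' (1, 4, 8) to a temporal pattern label: constant methylation, constant
#' absence, a wave (methylated on the first and last day only), its opposite
#' (methylated only on the middle day), `incomplete` when any day is
#' `no_call`, and `other` for the remaining trajectories.
#'
#' @param statuses Character vector of length 3 over
#'   `methylated`/`unmethylated`/`no_call`, in day order.
#' @return One of `always_methylated`, `always_unmethylated`, `wave_like`,
#'   `opposite`, `incomplete`, `other`.
#' @examples
#' classify_temporal_pattern(c("methylated", "unmethylated", "methylated"))
#' @export
classify_temporal_pattern <- function(statuses) {
  if (length(statuses) != 3L) {
    stop("exactly three ordered day statuses required", call. = FALSE)
  }
  ok <- c("methylated", "unmethylated", "no_call")
  if (!all(statuses %in% ok)) {
    stop("statuses must be in {", paste(ok, collapse = ", "), "}",
         call. = FALSE)
  }
  if (any(statuses == "no_call")) return("incomplete")
  key <- paste(ifelse(statuses == "methylated", "M", "U"), collapse = "")
  switch(key,
         MMM = "always_methylated",
         UUU = "always_unmethylated",
         MUM = "wave_like",
         UMU = "opposite",
         "other")
}

#' Temporal pattern table across a three-sample time course
#'
#' @param callsets List of exactly three `bs_callset`s in day order
#'   (days 1, 4, 8).
#' @param sitemap The shared `site_map`.
#' @return Data.frame with `position`, `context`, one status column per
#'   sample, and `pattern`.
#' @export
temporal_patterns <- function(callsets, sitemap) {
  if (length(callsets) != 3L) {
    stop("the temporal classifier requires exactly three ordered samples",
         call. = FALSE)
  }
  .check_consistent(callsets, sitemap)
  labels <- vapply(callsets, function(cs) cs$sample, character(1))
  base <- callsets[[1]]$calls[, c("position", "context")]
  status <- sapply(callsets, function(cs) {
    cs$calls$status[match(base$position, cs$calls$position)]
  })
  colnames(status) <- make.names(labels, unique = TRUE)
  pattern <- apply(status, 1L, classify_temporal_pattern)
  cbind(base, as.data.frame(status, stringsAsFactors = FALSE),
        pattern = pattern)
}

#' Methyltransferase activity shares
#'
#' Converts per-context DNA methyltransferase activities (e.g. CG-, CNG- and
#' CNN-specific activity in umol product per minute) into percentage shares
#' of the total: `100 * a_i / sum(a)`, half-up to one decimal.
#'
#' @param activities Non-negative numeric vector, optionally named by context;
#'   at least one value > 0.
#' @return Percent shares, same names, summing to 100 within 0.2.
#' @export
class_activity_shares <- function(activities) {
  if (any(is.na(activities)) || any(activities < 0)) {
    stop("activities must be non-negative numbers", call. = FALSE)
  }
  tot <- sum(activities)
  if (tot == 0) stop("undefined-share error: all activities are zero",
                     call. = FALSE)
  round_half_up(100 * activities / tot, 1L)
}

.check_consistent <- function(callsets, sitemap) {
  pos <- sort(as.integer(names(site_contexts(sitemap))))
  for (cs in callsets) {
    if (!inherits(cs, "bs_callset")) stop("expected bs_callset objects")
    if (cs$region_id != sitemap$region_id ||
        !identical(sort(cs$calls$position), pos)) {
      stop("consistency error: callset '", cs$sample,
           "' does not match the site map", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a per-context methylation summary table across samples
#'
#' Assembles the full quantitative summary of a bisulfite time course — per
#' context class and sample: number of sites, number unmethylated, percent
#' methylation, plus the bisulfite conversion rate row — as a tidy long
#' data.frame with TSV and aligned-text renderings.
#'
#' @param callsets Named list of `bs_callset`s, one per sample, in day order.
#' @param sitemap The shared `site_map`.
#' @return A `meth_table1` object: list with `long` (data.frame), `samples`,
#'   `region_id`.
#' @export
build_table1 <- function(callsets, sitemap) {
  if (length(callsets) < 1L) stop("need at least one sample", call. = FALSE)
  .check_consistent(callsets, sitemap)
  long <- do.call(rbind, lapply(callsets, summarize_callset,
                                sitemap = sitemap))
  rownames(long) <- NULL
  conv <- data.frame(
    region_id = sitemap$region_id,
    sample = vapply(callsets, function(cs) cs$sample, character(1)),
    conversion_rate_percent = vapply(callsets, conversion_rate, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(long = long, conversion = conv,
                 samples = conv$sample, region_id = sitemap$region_id),
            class = "meth_table1")
}

#' Build the summary table from printed counts (summary-only mode)
#'
#' Accepts a count table (e.g. transcribed from a published table) instead of
#' sequences, with columns `region_id`, `sample`, `context`, `n_sites`,
#' `n_unmethylated` and optionally `conversion_rate_percent`, and computes
#' the percent-methylation cells.
#'
#' @param counts Data.frame or TSV path with the columns above.
#' @return A `meth_table1`.
#' @export
table1_from_counts <- function(counts) {
  if (is.character(counts)) {
    counts <- utils::read.table(counts, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  need <- c("region_id", "sample", "context", "n_sites", "n_unmethylated")
  if (!all(need %in% names(counts))) {
    stop("counts need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  long <- counts[, need]
  long$n_no_call <- 0L
  long$percent_methylated <- methylation_percent(long$n_sites,
                                                 long$n_unmethylated)
  class(long) <- c("meth_class_summary", "data.frame")
  samples <- unique(long$sample)
  conv <- NULL
  if ("conversion_rate_percent" %in% names(counts)) {
    conv <- unique(counts[, c("region_id", "sample",
                              "conversion_rate_percent")])
    rownames(conv) <- NULL
  }
  structure(list(long = long, conversion = conv, samples = samples,
                 region_id = paste(unique(long$region_id), collapse = ",")),
            class = "meth_table1")
}

#' @export
format.meth_table1 <- function(x, ...) {
  long <- x$long
  out <- character(0)
  for (rid in unique(long$region_id)) {
    d <- long[long$region_id == rid, , drop = FALSE]
    out <- c(out, paste0("Region ", rid))
    hdr <- sprintf("  %-28s %s", "", paste(sprintf("%8s", x$samples),
                                           collapse = " "))
    out <- c(out, hdr)
    for (cl in intersect(c("CG", "CNG", "CNN"), unique(d$context))) {
      dd <- d[d$context == cl, , drop = FALSE]
      dd <- dd[match(x$samples, dd$sample), , drop = FALSE]
      out <- c(out,
        sprintf("  %-28s %s", paste0("Number of ", cl),
                paste(sprintf("%8d", dd$n_sites), collapse = " ")),
        sprintf("  %-28s %s", paste0("Number of unmethylated ", cl),
                paste(sprintf("%8d", dd$n_unmethylated), collapse = " ")),
        sprintf("  %-28s %s", "Methylation (%)",
                paste(sprintf("%8.1f", dd$percent_methylated),
                      collapse = " ")))
    }
    if (!is.null(x$conversion)) {
      cv <- x$conversion
      if ("region_id" %in% names(cv)) cv <- cv[cv$region_id == rid, ,
                                               drop = FALSE]
      cc <- cv[match(x$samples, cv$sample), , drop = FALSE]
      out <- c(out, sprintf("  %-28s %s", "Bisulfite conversion (%)",
                            paste(sprintf("%8.1f",
                                          cc$conversion_rate_percent),
                                  collapse = " ")))
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.meth_table1 <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a summary table as TSV
#'
#' Long layout, one row per region/sample/context; conversion rates appended
#' as `context = "conversion"` rows when present. Percentages are written at
#' one decimal (presentation layer); full precision stays in the object.
#'
#' @param table1 A `meth_table1`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table1_tsv <- function(table1, path) {
  d <- table1$long
  d$percent_methylated <- sprintf("%.1f", d$percent_methylated)
  if (!is.null(table1$conversion)) {
    conv <- data.frame(region_id = table1$conversion$region_id,
                       sample = table1$conversion$sample,
                       context = "conversion", n_sites = NA, n_unmethylated = NA,
                       n_no_call = NA,
                       percent_methylated = sprintf(
                         "%.1f", table1$conversion$conversion_rate_percent),
                       stringsAsFactors = FALSE)
    d <- rbind(d, conv)
  }
  d[is.na(d)] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stacked-bar plot of the unmethylated-cytosine distribution
#'
#' Cosmetic helper: one stacked bar per sample showing the percent of
#' unmethylated cytosines in each context class.
#'
#' @param table1 A `meth_table1`.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_unmethylated_distribution <- function(table1, ...) {
  m <- sapply(table1$samples, function(s) {
    unmethylated_distribution(table1$long[table1$long$sample == s, ,
                                          drop = FALSE])
  })
  graphics::barplot(m, legend.text = rownames(m),
                    ylab = "% of unmethylated cytosines", ...)
}
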