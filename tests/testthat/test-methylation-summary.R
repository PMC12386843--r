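test_that("methylation_percent reproduces printed-table arithmetic", {
  expect_equal(methylation_percent(7, 4), 42.9)
  expect_equal(methylation_percent(48, 21), 56.3) # half-up from 56.25
  expect_equal(methylation_percent(5, 0), 100.0)
  expect_equal(methylation_percent(12, 12), 0.0)
  expect_error(methylation_percent(0, 0), "undefined-percentage")
  expect_error(methylation_percent(5, 6), "n_unmethylated")
})

test_that("rounding is half-up, not banker's", {
  expect_equal(round_half_up(56.25), 56.3)
  expect_equal(round_half_up(0.05), 0.1)
  expect_equal(round_half_up(33 + 1 / 3), 33.3)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("summarize_callset tallies match a brute-force count", {
  set.seed(116)
  for (i in 1:25) {
    tr <- random_truth(len = sample(60:140, 1))
    read <- convert_in_silico(tr$region, tr$sitemap, tr$state, 0.9, 0,
                              seed = i)
    cs <- call_methylation(tr$region, tr$sitemap, read, sample = "s")
    sumry <- summarize_callset(cs, tr$sitemap)
    for (cl in sumry$context) {
      rows <- cs$calls[cs$calls$context == cl, ]
      n_nc <- sum(rows$status == "no_call")
      expect_equal(sumry$n_sites[sumry$context == cl], nrow(rows) - n_nc)
      expect_equal(sumry$n_unmethylated[sumry$context == cl],
                   sum(rows$status == "unmethylated"))
    }
    # tally conservation across classes
    expect_equal(sum(sumry$n_sites) + sum(sumry$n_no_call),
                 length(countable_positions(tr$sitemap)))
    expect_equal(sum(sumry$n_unmethylated),
                 sum(cs$calls$status == "unmethylated"))
    # percent complementarity within one-decimal rounding
    pm <- 100 * (sumry$n_sites - sumry$n_unmethylated) / sumry$n_sites
    pu <- 100 * sumry$n_unmethylated / sumry$n_sites
    expect_true(all(abs((100 - round_half_up(pu)) -
                          sumry$percent_methylated) <= 0.1))
    expect_equal(sumry$percent_methylated, round_half_up(pm))
  }
})

test_that("unmethylated_distribution normalizes and matches arithmetic", {
  d <- unmethylated_distribution(data.frame(
    context = c("CG", "CNG", "CNN"), n_unmethylated = c(4, 1, 6)))
  expect_equal(unname(d), c(36.4, 9.1, 54.5))
  expect_equal(unname(unmethylated_distribution(data.frame(
    context = c("CG", "CNG", "CNN"), n_unmethylated = c(0, 0, 5)))),
    c(0, 0, 100))
  expect_equal(unname(unmethylated_distribution(data.frame(
    context = c("CG", "CNG", "CNN"), n_unmethylated = c(3, 3, 3)))),
    c(33.3, 33.3, 33.3))
  expect_error(unmethylated_distribution(data.frame(
    context = c("CG", "CNG", "CNN"), n_unmethylated = c(0, 0, 0))),
    "undefined-distribution")

  set.seed(117)
  for (i in 1:300) {
    u <- stats::rpois(3, 5)
    if (sum(u) == 0) next
    d <- unmethylated_distribution(data.frame(
      context = c("CG", "CNG", "CNN"), n_unmethylated = u))
    expect_lt(abs(sum(d) - 100), 0.2)
    expect_equal(unname(d), round_half_up(100 * u / sum(u)))
  }
})

test_that("temporal pattern labels cover all 27 status triples", {
  st <- c("methylated", "unmethylated", "no_call")
  grid <- expand.grid(d1 = st, d4 = st, d8 = st, stringsAsFactors = FALSE)
  labels <- apply(grid, 1, classify_temporal_pattern)
  expect_equal(length(labels), 27L)
  valid <- c("always_methylated", "always_unmethylated", "wave_like",
             "opposite", "incomplete", "other")
  expect_true(all(labels %in% valid))
  # any no_call wins
  expect_true(all(labels[apply(grid, 1, function(r)
    any(r == "no_call"))] == "incomplete"))
  expect_equal(classify_temporal_pattern(
    c("methylated", "unmethylated", "methylated")), "wave_like")
  expect_equal(classify_temporal_pattern(
    c("unmethylated", "methylated", "unmethylated")), "opposite")
  expect_equal(classify_temporal_pattern(rep("methylated", 3)),
               "always_methylated")
  expect_equal(classify_temporal_pattern(rep("unmethylated", 3)),
               "always_unmethylated")
  expect_equal(classify_temporal_pattern(
    c("methylated", "methylated", "unmethylated")), "other")
  expect_error(classify_temporal_pattern(c("methylated", "methylated")),
               "three")
})

test_that("temporal_patterns tracks positions across three callsets", {
  tr <- random_truth(len = 80, seed = 118)
  css <- lapply(1:3, function(i) {
    st <- plant_methylation(tr$sitemap, 0.5, 0.5, 0.5, seed = 300 + i)
    rd <- convert_in_silico(tr$region, tr$sitemap, st, 1, 0, seed = 400 + i)
    call_methylation(tr$region, tr$sitemap, rd, sample = paste("day", i))
  })
  pat <- temporal_patterns(css, tr$sitemap)
  expect_equal(nrow(pat), length(countable_positions(tr$sitemap)))
  expect_true(all(pat$pattern %in% c("always_methylated",
                                     "always_unmethylated", "wave_like",
                                     "opposite", "incomplete", "other")))
  # identical callsets give only always_* labels
  pat2 <- temporal_patterns(css[c(1, 1, 1)], tr$sitemap)
  expect_true(all(pat2$pattern %in% c("always_methylated",
                                      "always_unmethylated")))
  expect_error(temporal_patterns(css[1:2], tr$sitemap), "three")
})

test_that("activity shares divide correctly and normalize", {
  expect_equal(unname(class_activity_shares(c(2, 2, 2))),
               c(33.3, 33.3, 33.3))
  expect_equal(unname(class_activity_shares(c(0, 0, 7))), c(0, 0, 100))
  expect_error(class_activity_shares(c(0, 0, 0)), "undefined-share")
  expect_error(class_activity_shares(c(-1, 2, 3)), "non-negative")
  set.seed(119)
  for (i in 1:300) {
    a <- stats::runif(3, 0.01, 10)
    s <- class_activity_shares(a)
    expect_lt(abs(sum(s) - 100), 0.2)
    expect_equal(unname(s), round_half_up(100 * a / sum(a)))
  }
})

test_that("build_table1 lays out counts, percents and conversion rates", {
  tr <- random_truth(len = 120, seed = 120)
  css <- lapply(1:3, function(i) {
    st <- plant_methylation(tr$sitemap, 1, 1, 1, seed = i)
    rd <- convert_in_silico(tr$region, tr$sitemap, st, 1, 0, seed = i)
    call_methylation(tr$region, tr$sitemap, rd, sample = paste("day", i))
  })
  names(css) <- sapply(css, `[[`, "sample")
  tab <- build_table1(css, tr$sitemap)
  # all-methylated samples: every percent cell 100.0, identical columns
  expect_true(all(tab$long$percent_methylated == 100.0))
  expect_true(all(tab$long$n_unmethylated == 0L))
  txt <- format(tab)
  expect_match(txt, "Methylation \\(%\\)")
  expect_match(txt, "Bisulfite conversion")

  tsv <- tempfile(fileext = ".tsv")
  write_table1_tsv(tab, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_true("conversion" %in% back$context)

  # a callset for a different region is rejected
  other <- random_truth(len = 50, seed = 121)
  rd <- convert_in_silico(other$region, other$sitemap, other$state, 1, 0,
                          seed = 1)
  cs_bad <- call_methylation(other$region, other$sitemap, rd, sample = "x")
  expect_error(build_table1(c(css[1:2], list(x = cs_bad)), tr$sitemap),
               "consistency error")
})

test_that("summary-only mode reproduces percent columns from printed counts", {
  tab <- table1_from_counts(table1_counts_path())
  long <- tab$long
  sdh4_d1 <- long[long$region_id == "Sdh4" & long$sample == "day 1", ]
  expect_equal(sdh4_d1$percent_methylated[match(c("CG", "CNG", "CNN"),
                                                sdh4_d1$context)],
               c(71.4, 58.3, 62.8))
  expect_equal(nrow(long), 27L)
  txt <- format(tab)
  expect_match(txt, "Sdh3-1")
})
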