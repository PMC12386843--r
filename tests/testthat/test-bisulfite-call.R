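test_that("complete conversion and full protection behave as limits", {
  tr <- random_truth(len = 50, seed = 106)
  sm <- tr$sitemap
  all_u <- meth_state(sm, rep("unmethylated", length(countable_positions(sm))))
  all_m <- meth_state(sm, rep("methylated", length(countable_positions(sm))))

  r_u <- convert_in_silico(tr$region, sm, all_u, efficiency = 1,
                           error_rate = 0, seed = 1)
  expect_false(grepl("C", r_u$sequence)) # every C becomes T

  r_m <- convert_in_silico(tr$region, sm, all_m, efficiency = 1,
                           error_rate = 0, seed = 1)
  # unchanged except edge-excluded Cs, which convert
  edge_pos <- sm$sites$position[sm$sites$edge_excluded]
  expected <- strsplit(tr$region$sequence, "")[[1]]
  expected[edge_pos + 51L] <- "T"
  expect_equal(r_m$sequence, paste(expected, collapse = ""))
})

test_that("conversion counts follow the binomial model", {
  tr <- random_truth(len = 200, gc = 0.5, seed = 107)
  sm <- tr$sitemap
  n_u <- length(countable_positions(sm))
  all_u <- meth_state(sm, rep("unmethylated", n_u))
  n_c <- n_u + sum(sm$sites$edge_excluded)
  eff <- 0.85
  fracs <- vapply(1:400, function(s) {
    r <- convert_in_silico(tr$region, sm, all_u, efficiency = eff,
                           error_rate = 0, seed = s)
    1 - lengths(regmatches(r$sequence, gregexpr("C", r$sequence))) / n_c
  }, numeric(1))
  se <- sqrt(eff * (1 - eff) / (n_c * 400))
  expect_lt(abs(mean(fracs) - eff), 3 * se)
})

test_that("simulated reads are byte-identical under the same seed", {
  tr <- random_truth(len = 80, seed = 108)
  r1 <- convert_in_silico(tr$region, tr$sitemap, tr$state, 0.8, 0.01,
                          seed = 99)
  r2 <- convert_in_silico(tr$region, tr$sitemap, tr$state, 0.8, 0.01,
                          seed = 99)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(r1$rng_seed, 99L)
  expect_equal(r1$provenance, "simulated")
})

test_that("parameters outside [0,1] are rejected", {
  tr <- random_truth(len = 40, seed = 109)
  expect_error(convert_in_silico(tr$region, tr$sitemap, tr$state,
                                 efficiency = 1.2), "parameter error")
  expect_error(convert_in_silico(tr$region, tr$sitemap, tr$state,
                                 error_rate = -0.1), "parameter error")
})

test_that("an untreated read calls all sites methylated at conversion 0", {
  tr <- random_truth(len = 60, seed = 110)
  cs <- call_methylation(tr$region, tr$sitemap, tr$region$sequence,
                         sample = "untreated")
  expect_true(all(cs$calls$status == "methylated"))
  expect_equal(conversion_rate(cs), 0)
})

test_that("a fully converted read calls all sites unmethylated at 100%", {
  tr <- random_truth(len = 60, seed = 111)
  read <- gsub("C", "T", tr$region$sequence)
  cs <- call_methylation(tr$region, tr$sitemap, read, sample = "converted")
  expect_true(all(cs$calls$status == "unmethylated"))
  expect_equal(conversion_rate(cs), 100)
})

test_that("calling recovers the planted state exactly at perfect conversion", {
  for (s in 1:30) {
    tr <- random_truth(len = sample(40:90, 1), seed = 1000 + s)
    read <- convert_in_silico(tr$region, tr$sitemap, tr$state, efficiency = 1,
                              error_rate = 0, seed = 2000 + s)
    cs <- call_methylation(tr$region, tr$sitemap, read)
    got <- stats::setNames(cs$calls$status, cs$calls$position)
    expect_identical(got[names(tr$state$status)], tr$state$status)
  }
})

test_that("gaps and foreign bases give no_call", {
  region <- ref_region("AACGTACGTAACGTACGTAA", -20, -1)
  sm <- find_cytosine_sites(region)
  # delete one site's base entirely: -18 (C of the first ACG)
  read <- paste0(substr(region$sequence, 1, 2), substr(region$sequence, 4, 20))
  cs <- call_methylation(region, sm, read)
  expect_equal(cs$calls$status[cs$calls$position == -18], "no_call")
  other <- cs$calls$status[cs$calls$position != -18]
  expect_true(all(other == "methylated"))
})

test_that("a wrong amplicon fails the alignment-quality guard", {
  region <- ref_region(strrep("ACGT", 15), -60, -1)
  sm <- find_cytosine_sites(region)
  foreign <- strrep("G", 60)
  expect_error(call_methylation(region, sm, foreign),
               "alignment-quality error.*score")
})

test_that("conversion rate definitions are bounded and monotone", {
  tr <- random_truth(len = 150, gc = 0.5, seed = 113)
  sm <- tr$sitemap
  n <- length(countable_positions(sm))
  rates <- vapply(c(0.1, 0.5, 0.9), function(p_meth) {
    set.seed(114)
    st <- plant_methylation(sm, p_meth, p_meth, p_meth)
    mean(vapply(1:40, function(s) {
      rd <- convert_in_silico(tr$region, sm, st, efficiency = 0.85,
                              error_rate = 0, seed = s)
      call_methylation(tr$region, sm, rd)$conversion_rate_percent
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(rates >= 0 & rates <= 100))
  # more planted methylation -> fewer convertible Cs -> lower expected rate
  expect_true(all(diff(rates) < 0))

  # with ~50% methylated sites the rate sits strictly between the all-
  # methylated and all-unmethylated bounds at the same efficiency
  mid <- rates[2]
  lo <- 100 * 0.85 * sum(sm$sites$edge_excluded) /
    (n + sum(sm$sites$edge_excluded))
  expect_gt(mid, lo)
  expect_lt(mid, 85)
})

test_that("callsets round-trip through TSV", {
  tr <- random_truth(len = 60, seed = 115)
  read <- convert_in_silico(tr$region, tr$sitemap, tr$state, 1, 0, seed = 3)
  cs <- call_methylation(tr$region, tr$sitemap, read, sample = "day 1")
  tsv <- tempfile(fileext = ".tsv")
  write_callset_tsv(cs, tsv)
  back <- read_callset_tsv(tsv)
  expect_equal(back$sample, "day 1")
  expect_equal(back$calls$status, cs$calls$status)
  expect_equal(back$conversion_rate_percent, cs$conversion_rate_percent,
               tolerance = 1e-6)
})
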