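---
title: "Calling promoter cytosine methylation from bisulfite amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling promoter cytosine methylation from bisulfite amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamplicon)
```

## The problem

Amplicon bisulfite sequencing is the classic assay for locus-specific DNA
methylation. Genomic DNA is treated with sodium bisulfite, which deaminates
unmethylated cytosine to uracil (read as thymine after PCR) while
5-methylcytosine is protected. Sequencing the amplicon and comparing it with
the untreated reference therefore turns methylation into a substitution
signal: a reference C that stays C was methylated, a reference C read as T
was not.

In plants, cytosine methylation occurs in three sequence contexts with
distinct maintenance machinery: the symmetric contexts CG (maintained by
MET1-class methyltransferases) and CNG (chromomethylases, N being A, C or
T), and the asymmetric context CNN (de novo RdDM-type methylation). A
promoter methylation study therefore reports, per context class: the number
of sites in the analyzed window, how many were unmethylated at each sampled
time point, and the resulting percent methylation, along with the bisulfite
conversion rate as a technical control. `bsamplicon` implements this whole
workflow — for real amplicon sequences supplied as FASTA, for published
count tables (summary-only mode), and for fully synthetic data.

## Coordinates and site classification

Promoter windows are addressed with 1-based negative upstream coordinates:
position −1 is the base immediately 5′ of the start codon's A, and positions
decrease moving 5′, so a window written −488…−238 has its 5′-most base at
−488. `load_reference()` attaches such a window to a FASTA record, either
using the record whole or extracting the window from a longer upstream
sequence assumed to end at −1.

Classification priority is CG > CNG > CNN, applied per cytosine from the two
bases 3′ of it: a C followed by G is CG regardless of what follows; a C
followed by A/C/T and then G is CNG; a C followed by two bases neither of
which completes those patterns is CNN. In the overlapping motif CCG, the
first C is consequently CNG and the second is CG. A cytosine is
*edge-excluded* when a base its classification actually needs is missing
(beyond the window's 3′ end) or is N — so a C at the second-to-last position
whose +1 base is G is still a CG site, since CG needs only one following
base, while the same C followed by A would be edge-excluded. Edge-excluded
cytosines are reported but never counted in class totals, and they behave
like unmethylated cytosines during conversion (nothing protects them).

```{r}
oligo <- ref_region("AAACCGAACCGAAAAACCG", -19, -1, region_id = "CNG_oligo")
find_cytosine_sites(oligo)$counts
```

## The conversion model

`convert_in_silico()` formalizes bisulfite chemistry as a Bernoulli model:
each cytosine at an unmethylated site (and each edge-excluded cytosine)
converts C→T independently with probability equal to the conversion
efficiency; methylated cytosines are fully protected. Inappropriate
conversion of methylated cytosine, PCR misincorporation and Sanger
base-calling errors are folded into a single independent per-base error rate
applied afterwards, uniform over the three other bases. Keeping the two
noise sources separate makes their effects distinguishable in tests:
efficiency only touches convertible cytosines, error touches every base.

Defaults follow the study conditions the package emulates: conversion
efficiency 0.85 (amplicon bisulfite runs commonly report 78–88%), error rate
0 (a consensus Sanger read is effectively error-free at this scale).

## Bisulfite-aware alignment

Calls are read off a global Needleman–Wunsch alignment with an asymmetric
substitution rule: a reference C aligned to a read T scores as a full match
and is tagged `converted`. This is essential — under a standard scorer every
converted cytosine is a mismatch, so heavily converted (i.e. unmethylated)
amplicons align worse and calls are biased toward "methylated". Default
scores are match +1, converted +1, mismatch −2, gap −3, with no end-gap
discount because amplicons cover the full window; all four are free
parameters of `bisulfite_scoring()`.

Tie-breaking is deterministic: among equal-score alignments the one with
fewer gap columns wins, and the traceback prefers substitution over a gap in
the read over a gap in the reference, so repeated runs are byte-identical.
Only the amplicon's C strand is analyzed by default, matching single-primer
Sanger practice; `mode = "g_strand"` applies the mirrored rule (ref G : read
A) for reads from the opposite strand.

```{r}
print(bisulfite_align("ACGTTCGA", "ATGTTTGA"))
```

## Calling and the conversion rate

`call_methylation()` guards against a wrong amplicon (error if fewer than
50% of alignment columns are match/converted), then assigns per-site status:
read C → methylated, read T → unmethylated, gap or any other base →
`no_call`. `no_call` sites are excluded from both numerator and denominator
of every percentage and reported separately; no imputation is attempted.

The bisulfite conversion rate is the percentage of aligned reference
cytosines read as T. Two denominators are implemented and labelled, because
the definition behind published "conversion of DNA (%)" rows is often not
stated: the default counts **all** reference cytosines (methylated sites
included), which is consistent with published values in the 78–88% range
sitting well below plausible chemistry efficiency; the alternative
(`conversion_denominator = "non_site_c"`) counts only cytosines outside
countable sites. Both values are stored on every call set.

Note the raw called-methylation fraction is biased upward under incomplete
conversion: a site is called methylated when it is methylated *or* when it
is unmethylated but escaped conversion, so its expectation is
$(1-e) + p\,e$ for planted methylation probability $p$ and efficiency $e$.
The package's estimator for recovery analyses inverts this map,
$\hat p = (\hat f - (1-e))/e$; confidence intervals are Clopper–Pearson
intervals of $\hat f$ with endpoints transformed the same way.

## Summaries

`summarize_callset()` produces the per-context block (sites, unmethylated,
percent methylated); `build_table1()` assembles the full multi-day layout
with the conversion-rate row, and `table1_from_counts()` computes the same
report from a printed count table without sequences. All percentages round
half-up to one decimal — required for count-consistent arithmetic like
27/48 = 56.25 → 56.3, where banker's rounding would disagree with published
tables.

`unmethylated_distribution()` reports what share of all unmethylated
cytosines falls in each context. Note one published first-day distribution
(12.5/12.5/75.0) cannot be reconciled with its own table's unmethylated
counts (4/1/6 → 36.4/9.1/54.5) nor with the site totals; the function
implements the defined formula and the discrepancy is simply documented
here. Similarly, three published percent cells (75.5, 77.7, 75.6) disagree
with their own printed counts (75.0, 77.8, 72.2); the package reproduces the
24 self-consistent cells exactly and flags these three.

`classify_temporal_pattern()` labels a site's status triple over a
three-day course (days 1, 4, 8): always methylated/unmethylated, `wave_like`
(methylated first and last day only), `opposite` (methylated the middle day
only), `incomplete` (any `no_call`), `other` for the remaining trajectories.
`class_activity_shares()` turns per-context methyltransferase activities
into percentage shares of the total.

## The synthetic generator

`simulate_timecourse()` produces a complete testable study: an i.i.d. random
promoter window (default 250 nt, GC 0.45 — plant-promoter-like composition,
deliberately without dinucleotide structure), per-day planted Bernoulli
methylation states, and converted reads. Defaults plant day-1 probabilities
0.429 (CG), 0.833 (CNG), 0.833 (CNN) with the later days following the same
promoter's published counts, at efficiency 0.85. Every stage derives its own
seed from the master seed (region: +1000; state for sample *i*: +2000+*i*;
read: +3000+*i*), so any stage regenerates independently and
`write_fixture_bundle()` manifests are sufficient for byte-identical
re-execution; bundle files carry md5 checksums that `read_fixture_bundle()`
verifies.

What passing tests on this generator do show: the classifier, aligner,
caller and summaries are mutually consistent, recover planted truth exactly
at efficiency 1, and recover planted parameters within binomial error at
efficiency 0.85. What they do not show: robustness to real Sanger
chromatogram noise, PCR bias, clone-sampling heterogeneity, or non-i.i.d.
promoter composition — none of which the generator models.

```{r}
bundle <- simulate_timecourse(sim_config(length = 200, seed = 7))
cs <- call_methylation(bundle$region, bundle$sitemap, bundle$reads[["day 1"]],
                       sample = "day 1")
summarize_callset(cs, bundle$sitemap)
```

## Numerical and design choices

* **Rounding**: half-up to one decimal at the presentation layer only; full
  precision is retained inside objects.
* **Statistical problem sizes**: recovery properties use windows large
  enough for ≥ 200 sites per context (3600 nt at GC 0.6) and 200 seeded
  replicates — enough for 3-standard-error binomial checks while keeping a
  full run in a few minutes; routine examples use 40–250 nt windows.
* **Consensus model**: one read per sample with binary site status, matching
  Sanger consensus practice. Per-site methylation *fractions* from multiple
  clones are out of scope.
* **Degenerate inputs**: zero sites → empty map, not an error; zero
  countable sites in a class → the class is omitted from summaries with a
  notice; a zero denominator in any percentage raises a typed error rather
  than returning NaN.
* **Alignment scores are integers**; there are no floating-point ties.

## Limitations

No chromatogram (AB1) parsing, no short-read (FASTQ/BAM) bisulfite mapping,
no paired-end or quality-score logic, no statistical testing across days.
The aligner is quadratic in sequence length — intended for amplicon-scale
windows (≤ a few kb), not genome scans.
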