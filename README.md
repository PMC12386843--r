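# bsamplicon

Locus-specific DNA methylation analysis from amplicon bisulfite sequencing,
for plant promoter windows.

Bisulfite treatment deaminates unmethylated cytosine to uracil (read as
thymine after PCR) while 5-methylcytosine is protected, so methylation
becomes a substitution signal: comparing a sequenced amplicon with its
untreated reference, a reference C still read as C was methylated, a
reference C read as T was not. Plant genomes methylate cytosine in three
contexts with distinct maintenance enzymes — the symmetric CG and CNG
(N ∈ {A, C, T}) contexts and the asymmetric CNN context — and promoter
studies report, per context class *k* and time point, the number of sites
*n<sub>k</sub>*, the number unmethylated *u<sub>k</sub>*, and

&nbsp;&nbsp;&nbsp;&nbsp;methylation % = 100 · (n<sub>k</sub> − u<sub>k</sub>) / n<sub>k</sub>

together with the bisulfite conversion rate (% of reference cytosines read
as T) as a technical control. `bsamplicon` is for researchers running that
workflow: it classifies cytosines into CG/CNG/CNN with the standard
CG > CNG > CNN priority, aligns converted amplicons to the reference with a
bisulfite-aware Needleman–Wunsch scorer (ref-C : read-T is a penalty-free
"converted" match), calls per-site methylation, estimates conversion rates,
summarizes germination time courses (per-context tables,
unmethylated-cytosine distributions, temporal pattern labels such as
*wave-like* and *opposite*, methyltransferase activity shares), and ships a
seeded in-silico bisulfite simulator so the whole pipeline is testable
without any sequence download.

## Worked example

Simulate a three-day germination time course over a synthetic 250-nt
promoter window (day-1 methylation probabilities 0.429/0.833/0.833 for
CG/CNG/CNN, bisulfite efficiency 0.85), call each day's read, and build the
summary table:

```r
library(bsamplicon)

bundle <- simulate_timecourse(sim_config(seed = 7))
bundle$sitemap
#> <site_map> synthetic_promoter: 16 CG, 8 CNG, 34 CNN (+1 edge-excluded)

callsets <- setNames(lapply(names(bundle$reads), function(s)
  call_methylation(bundle$region, bundle$sitemap, bundle$reads[[s]],
                   sample = s)), names(bundle$reads))
build_table1(callsets, bundle$sitemap)
#> Region synthetic_promoter
#>                                   day 1    day 4    day 8
#>   Number of CG                       16       16       16
#>   Number of unmethylated CG           8        6       13
#>   Methylation (%)                  50.0     62.5     18.8
#>   Number of CNG                       8        8        8
#>   Number of unmethylated CNG          1        3        3
#>   Methylation (%)                  87.5     62.5     62.5
#>   Number of CNN                      34       34       34
#>   Number of unmethylated CNN          4        5        8
#>   Methylation (%)                  88.2     85.3     76.5
#>   Bisulfite conversion (%)         23.7     25.4     40.7
```

Reading the output: the window contains 16 CG, 8 CNG and 34 CNN sites (one
cytosine near the 3′ edge lacks the context bases needed for a class and is
excluded). On day 1, 8 of 16 CG sites were read as T and called
unmethylated, giving 50.0% CG methylation; CG methylation collapses by day 8
(18.8%) while CNG/CNN change less — the site counts stay fixed because they
are a property of the reference, only the calls move. The conversion row is
computed over *all* reference cytosines (methylated ones included), so at
efficiency 0.85 it tracks the unmethylated fraction of the window rather
than the chemistry alone; raw per-call fractions can be corrected for
incomplete conversion as described in the vignette.

The distribution of unmethylated cytosines across contexts on day 1:

```r
unmethylated_distribution(summarize_callset(callsets[["day 1"]], bundle$sitemap))
#>   CG  CNG  CNN
#> 61.5  7.7 30.8
```

i.e. of the 13 unmethylated cytosines, 61.5% lie in CG context. A published
count table can be summarized without sequences via
`table1_from_counts()` — see `inst/extdata/table1_counts.tsv` for the
expected columns.

A thin command-line wrapper with subcommands `sites`, `simulate`, `call`
and `summarize` is installed at `inst/cli/bsamplicon`
(`system.file("cli", "bsamplicon", package = "bsamplicon")`).

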