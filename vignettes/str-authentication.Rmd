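---
title: "STR profile authentication: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STR profile authentication: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strauth)
```

## The problem

A continuous cell line is authenticated by genotyping a panel of short tandem
repeat (STR) loci and comparing the resulting profile against reference
databases. An STR allele is the number of repeat units at the locus; partial
repeats are written as microvariants (`20.3` = 20 repeats plus 3 extra
bases). `strauth` works with the 19-locus CellCheck mouse panel: 18 autosomal
markers and one X-linked marker, each with a published "known allele range"
(the span of repeat counts observed at that site) and a multiplex PCR primer
pair whose reverse primer carries the fixed `GTTTCTT` PIGtail tag.

```{r}
head(cellcheck_panel()[, 1:4])
```

## The genotype model

A genotype is a **set** of distinct alleles at one marker:

* a homozygous locus prints one value and counts one allele;
* a heterozygous locus prints two values and counts two;
* three or more values indicate an amplified locus; each distinct allele
  counts toward the totals, and allele calling flags the marker
  `multi_allelic`.

Set semantics are a substantive choice, not a convenience. The worked
example's scores only reproduce when a homozygous locus contributes a single
allele to the totals and a tri-allelic locus contributes three; counting
homozygotes twice (multiset semantics) changes every denominator. Alleles
compare as exact tokens, so a microvariant is never a match for its integral
neighbour: at marker 7-1, allele `27` shares nothing with `26.2,27.2`.

An untyped marker and a typed-but-empty one cannot be distinguished in the
tabular interchange formats, so both map to the empty genotype; comparisons
then exclude that marker under the default mode.

## Percent-match statistics

With `s` shared alleles and allele totals `n_q` (query) and `n_r` (reference)
over the selected markers:

* **Tanabe**: `100 * 2s / (n_q + n_r)` — symmetric;
* **Masters vs query**: `100 * s / n_q`;
* **Masters vs reference**: `100 * s / n_r` — the two Masters variants are
  dual under swapping the profiles.

Marker modes: `non_empty_both` (default) uses markers typed in both profiles;
`query_markers` uses all markers typed in the query (reference gaps then
depress the score); `all_panel` uses all 19. The default mode is what makes
the worked example reproduce: marker 9-2 is typed in the query profile but
absent from every reference column, and all six verifiable published scores
agree only when it is excluded pairwise.

Scores are rounded half-up to 2 decimals for reporting (base R's
round-half-to-even would print `80.9` where published tables print `80.95` →
`81.0`); the raw value is kept alongside. A comparison with zero usable
markers raises a `strauth_degenerate_comparison` error rather than returning
0%: a silent zero would be indistinguishable from strong evidence of
non-identity.

## Database search

`str_search()` scores the query against every reference, then filters:
retained hits need a score at or above `score_filter` (default 70%) and at
least `min_markers` usable markers (default 8). Results are ranked by score
descending with ties broken by reference name ascending — published tables
list tied scores in a fixed order but state no rule, and lexicographic
ordering is reproducible. Excluded references are reported with the reason;
authentication audits need the negative evidence. The score filter is applied
to the rounded (reported) score so that the filter and the printed numbers
never disagree.

```{r}
report <- str_search(colgfp_profile(), table3_profiles(include_query = FALSE))
report$results
```

### The DC2.4 discrepancy

The published search reported 78.05% for DC2.4, but recomputing from DC2.4's
published allele column gives 15 shared alleles of 20 + 20, i.e. **75.00%**.
The live database entry at search time evidently differed from the table
snapshot. The package does not force the published value: DC2.4 is excluded
from the exact-reproduction checks and the recomputed 75.00 is asserted
instead. The other six published scores (82.93, 80.00, 78.05, 76.92, 76.19,
73.17) reproduce exactly, as does their ranking.

## Allele calling

`call_marker()` and `call_profile()` convert peak tables — `(marker, allele,
height in RFU)` triples, alleles already binned to repeat tokens — into
genotypes. A peak is called when its height reaches `rfu_threshold` (default
100 RFU, the assay's stated detection level); a height exactly at the
threshold is included, reading "set to 100" as a pass level. Duplicate allele
tokens merge keeping the highest peak. More than `max_alleles_expected`
(default 2, diploid) survivors flag `multi_allelic`; no survivors flag
`no_signal`; sub-threshold peaks are counted in QC but never called. A single
global threshold is used: whether the commercial assay applies per-marker
thresholds or stutter filters is not public, and fragment-size calibration,
stutter and pull-up modelling are out of scope — peaks arrive pre-binned.

## The synthetic-data generator

`generate_profile()` draws, per marker, one allele (two with probability
`het_prob`) uniformly over the whole repeat counts in the marker's known
range, attaching a 1–3-base microvariant with probability
`microvariant_prob` and clipping into range. Defaults `het_prob = 0.2` and
`microvariant_prob = 0.15` sit near the rates visible in the packaged
profiles (2 of 19 markers heterozygous in the reference line; 3 of its 20
alleles microvariant) — plausible for laboratory mouse lines with substantial
inbred ancestry. Uniform allele sampling is deliberately non-biological: no
population allele frequencies exist for this panel, so generated profiles are
panel-conformant but not frequency-realistic, and passing tests demonstrate
algorithmic correctness, not calibration against real mouse populations.

`mutate_profile()` models culture drift: each allele is lost with
`dropout_rate` (markers may become empty) and, if kept, shifted ±1 repeat
with `shift_rate`, preserving any microvariant suffix and clipping to the
marker range. Deleting `k` alleles from an identical `n`-allele copy gives a
Tanabe score of `100·2(n−k)/(2n−k)`, the closed form the tests check against
brute force.

`generate_peak_table()` emits one peak per allele with height drawn
log-uniformly in `[2, 100] × threshold`, so noise-free calling at the default
threshold is unambiguous (every true peak ≥ 2× threshold). A contaminating
profile contributes its alleles with heights scaled by
`contaminant_fraction`: below fraction 0.5 the minor peaks can fall under the
detection threshold, while detectable fractions surface as `multi_allelic`
flags — the qualitative signature of a cell-line mixture. No stutter,
pull-up, or electrophoresis noise is modelled.

All generators are deterministic in their configuration: equal `sim_config`
values (including `seed`) produce bitwise-equal output.

## Numerical and design choices

* Marker labels are opaque strings; typographic en-dashes in printed tables
  (`1–1`) normalize to ASCII hyphens on input.
* Allele display order is ascending by (repeats, microvariant); storage is
  order-free, and duplicate tokens collapse on parse.
* The profile CSV dialect (`marker` column plus one column per line,
  comma-separated alleles inside quoted cells) is written bit-exactly
  (UTF-8, LF), so write → read is an identity on genotype sets.
* Problem sizes in the test suite — 200 synthetic pairs for the
  oracle-equivalence check, 100 seeds for the calling round trip, 1,000
  drifted profiles for dropout-rate recovery, drift closed form up to
  n = 40 alleles — are chosen to exercise the combinatorics thoroughly while
  keeping the default run fast.

## Limitations

* No probabilistic match interpretation (likelihood ratios, allele
  frequencies); the percent-match statistics are purely combinatorial.
* No interspecies-contamination caller: the upstream assay claims sensitivity
  to 5% interspecies contamination, but no mechanism is public.
* No in-silico PCR or amplicon-size prediction from the panel primers.
* The search operates on local profile files only; it does not query online
  databases.
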