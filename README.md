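# strauth

Short tandem repeat (STR) profile authentication for mouse cell lines.

Misidentified and cross-contaminated cell lines are a persistent source of
invalid results in biomedical research, and STR profiling is the accepted way
to verify a line's identity: genotype a panel of polymorphic microsatellite
loci and compare the resulting allele sets against reference profiles.
`strauth` implements that workflow for the 19-marker CellCheck mouse panel:

* a genotype model for STR alleles, including microvariants (partial repeats
  such as `20.3`), with set-valued genotypes per marker;
* percent-match statistics between profiles — the Tanabe score and both
  Masters variants — over a selectable marker subset;
* ranked database search with score and minimum-marker filters, reporting
  exclusions as well as hits;
* allele calling from electropherogram peak tables at a relative fluorescence
  unit (RFU) detection threshold, with QC flags for silent and multi-allelic
  loci;
* a synthetic-data generator for panel-conformant profiles, genetic drift
  (allele dropout and repeat shifts) and contaminated peak tables.

The package ships the published reference profile of the immortalized mouse
hepatic stellate cell line **Col-GFP HSC** (Cellosaurus `CVCL_B7MI`) and the
comparison table of its closest database matches as plain-text fixtures, and
reproduces the published percent-match values exactly.

## The statistic

For a questioned profile *q* and a reference profile *r*, compared over a
marker set *M* (by default the markers typed in **both** profiles), with
`s` = number of shared alleles, `n_q` and `n_r` = distinct-allele totals of
each profile over *M*:

```
Tanabe:                % match = 100 * 2s / (n_q + n_r)
Masters (vs query):    % match = 100 * s / n_q
Masters (vs reference):% match = 100 * s / n_r
```

Genotypes are sets: a homozygous marker contributes one allele, a tri-allelic
(amplified) marker three. Microvariant alleles never match their integral
neighbours (`27` ≠ `27.2` ≠ `26.2`). Scores are reported rounded half-up to
two decimals; a comparison with zero usable markers is an error, not a 0%
score.

## Worked example

```r
library(strauth)

report <- str_search(colgfp_profile(), table3_profiles(include_query = FALSE))
report$results
#>            reference accession shared n_query n_reference n_markers score
#> 1               AT-3 CVCL_VR89     17      20          21        18 82.93
#> 2 YUMMER1.7-H2B-GFP5 CVCL_A2AY     16      20          20        18 80.00
#> 3                MS1 CVCL_6502     16      20          21        18 78.05
#> 4            YUMM1.7 CVCL_JK16     15      20          19        18 76.92
#> 5            MCA-205 CVCL_VR90     16      20          22        18 76.19
#> 6              DC2.4 CVCL_I409     15      20          20        18 75.00
#> 7             MLTC-1 CVCL_3544     15      20          21        18 73.17
```

Each row is one reference: AT-3 shares 17 of its alleles with the query over
the 18 markers typed in both profiles; with 20 query and 21 reference alleles
that gives a Tanabe score of `200 * 17 / 41 = 82.93%`. All seven references
clear the default 70% score filter and 8-marker minimum, so none are
excluded. The top score of 82.93% is still far from the ~100% expected of the
same line, confirming the query profile is distinct from every database
entry. (The published score for DC2.4 was 78.05%, but its published allele
column computes to 75.00%; the database entry evidently changed between the
search and the table snapshot — see the vignette.)

The same search from a shell:

```sh
Rscript inst/cli/strauth fixtures --out fixtures/
Rscript inst/cli/strauth search --query fixtures/colgfp_profile.csv \
    --db fixtures/table3_profiles.csv
```

which prints the marker-by-marker comparison table with a `% match` footer
row. Other subcommands: `score` (pairwise scores), `call` (peak table →
profile at a 100-RFU threshold), `simulate profile|drift|peaks` (synthetic
data).

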