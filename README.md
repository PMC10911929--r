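# coamplikon

Oncogene amplicons in cancer genomes rarely contain the oncogene alone.
High-level amplification of a driver such as *MYCN* typically carries a 1–3 Mb
region with several neighboring **passenger genes** (*DDX1*, *NBAS*,
*FAM49A*, ...) along for the ride. Although passengers do not drive the tumor,
their constitutive overexpression can rewire cell physiology and create
**collateral dependencies** — therapeutic vulnerabilities present only in cells
where the passenger is coamplified with the oncogene.

`coamplikon` implements the computational screen for such vulnerabilities,
for analysts working with array/sequencing copy-number segment data and
genome-scale CRISPR dependency screens (DepMap-style CERES scores):

1. **Amplicon calling.** Segments with log2 ratio at or above a
   platform-specific cutoff (Affymetrix/NimbleGen 1.5, Agilent 2, Illumina
   0.7; configurable) are called high-level amplified; log2 ratio < −2 is a
   homozygous deletion. Each gene inherits the status of the overlapping
   segment with the largest base-pair overlap; amplified segments split by
   probe gaps ≤ 10 kb are merged into amplicon intervals whose members are
   partitioned into oncogenes and passengers.
2. **Cohort summaries.** Per-oncogene amplification frequency, mean passenger
   load, coamplification incidence, per-passenger coamplification fractions
   and upset-style passenger-combination counts.
3. **Differential dependency screen.** Cell lines are stratified as
   *coamplified* (CN(oncogene) ≥ 2 and CN(passenger) ≥ 2) versus
   *oncogene-only* (CN(passenger) < 2); for every gene *g* the screen reports

   Δ(g) = median dep(g | coamp) − median dep(g | oncogene-only)

   with a Wilcoxon rank-sum p-value (exact when the smaller arm has ≤ 10
   lines and no ties; tie-corrected normal approximation otherwise) and
   Benjamini–Hochberg q-values. Negative Δ at small p marks candidate
   collateral dependencies.
4. **Downstream analyses.** Pearson correlation of passenger copy number with
   dependency or drug response, hypergeometric over-representation and
   preranked permutation enrichment (ES/NES/p/q), and nomination of
   candidate disordered protein regions by polynomial modeling of
   per-residue disorder tracks.
5. **Synthetic cohorts.** A fully seeded generator plants oncogene-anchored
   amplicons, platform noise, dosage-driven expression and collateral
   dependency shifts, returning complete ground truth for recovery testing.

## Worked example

```r
library(coamplikon)

cohort <- simulate_cohort(simulation_config(seed = 7))
calls  <- merge_amplified_intervals(gene_level_calls(cohort$segments, cohort$annotation))
comp   <- classify_passengers(calls)
summarize_cohort(comp, "GENE010")
#> coamplification summary for GENE010
#>   amplified: 85 / 200 samples (frequency 0.425)
#>   mean passenger count: 3.024; coamp incidence: 1.000
#>   top passenger fractions among amplified samples:
#>     GENE011      0.824
#>     GENE009      0.612
#>     ...
```

85 of 200 simulated tumors amplify the oncogene (the generator's default rate
is 0.43), and the adjacent passenger `GENE009` rides on 61% of those amplicons
(target 0.58). Stratifying the simulated cell lines and screening the
dependency matrix:

```r
groups <- classify_cell_lines(cohort$line_cn, "GENE010", "GENE009")
screen <- coamp_screen(cohort$dependency, groups)
screen
#> coamp_screen: GENE009-GENE010 coamplified (n=8) vs GENE010-only (n=6)
#>   50 gene(s) tested, 0 skipped (group size < 3)
#>   top genes by nominal p:
#>     gene median_diff      p_value    q_value n_coamp n_onc_only
#>  GENE016  -0.9721072 0.0006660007 0.01110001       8          6
#>  GENE022  -0.9412040 0.0006660007 0.01110001       8          6
#>  GENE026  -1.2792240 0.0006660007 0.01110001       8          6
#>  GENE048   0.3392840 0.0079920080 0.09990010       8          6
#>  GENE024  -0.4132725 0.0199800200 0.19980020       8          6
```

The three genes with median dependency shifts near −1 and the smallest
attainable exact p (0.00067 for an 8-vs-6 split) are exactly the planted
collateral targets; `plot(screen)` draws the corresponding volcano.
`truth_report(cohort, calls, groups, screen)` confirms perfect recovery of
amplification calls, coamplification calls and group labels on this cohort.

A thin command-line wrapper over the same functions ships in
`inst/scripts/coamplikon.R` (subcommands `simulate`, `call`, `summarize`,
`screen`, `correlate`, `enrich`, `disorder`), and `run_pipeline()` executes
call → summarize → screen from files, writing TSV outputs plus a JSON
manifest (version, parameters, seed, input digests).

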