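# varcascade

Family-based rare-variant discovery for small families sequenced by
whole-exome sequencing (WES), built for the setting where only a handful of
affected relatives are available — here, two families segregating
bisphosphonate-associated atypical femur fractures (AFF): a sequenced
proband from a mother–daughter family (sample `1-b`) and an affected sister
pair (`2-a`, `2-b`).

With so few genomes, discovery rests on transparent filtering rather than
statistical association. `varcascade` implements that filtering as
auditable cascades over annotated variant calls:

- **Ingestion** — multi-sample VCF v4.x plus an ANNOVAR-style annotation
  table (gene, region class, exonic function, per-database per-population
  allele frequencies, SIFT/PolyPhen2/CADD/GERP++ scores). Multiallelic
  records are decomposed into per-ALT biallelic variants with genotype
  recoding: for ALT allele *k*, a diploid genotype *a/b* is `het` when
  exactly one of *a, b* equals *k*, `homalt` when both do. Upstream QC
  removes calls with quality-by-depth QD < 5 and non-PASS VQSR verdicts.
- **Filter cascades** — consequence classes (UTR, exonic nonsynonymous,
  splicing, stopgain/stoploss, exonic indels; synonymous and intronic are
  always excluded), a population-frequency rule (pass iff every in-scope
  (database, population) cell has frequency < 0.005 or is absent from the
  database; missingness is explicit, never coerced to 0), and a
  candidate-gene panel of genes previously implicated in AFF. Every cascade
  returns a flowchart-style report of per-step survivor counts.
- **Inheritance models** — carrier-pattern selection (proband carrier
  and/or both sisters carriers), dominant (both sisters `0/1`), recessive
  homozygous (both sisters `1/1`), and compound-heterozygote detection
  (all unordered pairs of same-gene variants heterozygous in both sisters,
  flagged phase-unknown since trans configuration cannot be verified
  without parents), plus cross-family gene overlap (genes where the proband
  carries a *different* qualifying variant than the sisters).
- **Prioritization** — damage partition (truncating, or phred-scaled
  CADD > 30), gene-set intersection against GMT-format pathways with
  gene-family expansion (e.g. a TRAF4 variant surfaced through TRAF2/TRAF6
  pathway membership), and CADD phred-to-percentile conversion
  (`100 * 10^(-score/10)`).
- **Synthetic data** — a generator that plants variants with fully known
  truth (survivors plus single-step failures) and emits VCF + annotation +
  cohort + truth files, used to validate the whole pipeline end to end.

## Worked example

The package ships a small example dataset with the two published candidate
variants (a PLOD2 missense carried by the proband, a TMEM25 missense shared
by the sisters):

```r
library(varcascade)

ext <- function(f) system.file("extdata", f, package = "varcascade")
data <- load_dataset(ext("table3.vcf"), ext("table3_annotations.tsv"),
                     ext("cohort.tsv"))
data$variants[, c("key", "gene", "freq_gnomad_wes_ALL", "cadd_phred")]
#>                  key   gene freq_gnomad_wes_ALL cadd_phred
#> 1  chr3:145799628T>A  PLOD2            3.99e-06      10.78
#> 2 chr11:118402939G>A TMEM25            1.00e-04      15.48
```

A fuller demonstration runs fixture R1 — those two variants planted among
twelve decoys, each violating exactly one cascade step — through the
candidate cascade:

```r
dir <- tempfile(); paths <- simulate_dataset(dir, fixture = "R1")
data <- load_dataset(paths$vcf, paths$annotations, paths$cohort)
panel <- read_gene_panel(ext("candidate_panel.txt"))
res <- candidate_cascade(qc_filter(data$variants), panel)
res$report
#> Filtering step                                                                                  n
#> Total number of variants                                                                        14
#> All variants in candidate genes                                                                 11
#> Selecting UTR, exonic nonsynonymous + splice variants (excluding intronic + exonic synonymous)  9
#> Variants with gnomAD WES and WGS frequency below threshold                                      7
#> Additional filtering with 1000 Genomes frequency below threshold                                5
#> Filtering out variants only carried by one of the affected sisters                              2
res$variants$key
#> [1] "chr3:145799628T>A"  "chr11:118402939G>A"
```

Each report row is a filter step with its survivor count: 14 planted
variants shrink to the two true candidates, and every decoy exits at the
step it was designed to fail. CADD percentiles contextualize the scores:

```r
cadd_percentile(10)         # 10  -> among the 10% most deleterious substitutions
round(cadd_percentile(15))  # 3   -> among the 3% most deleterious
```

A command-line wrapper over the same functions lives at
`inst/cli/varcascade.R` (`run`, `simulate`, `report` subcommands).

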