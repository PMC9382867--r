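---
title: "Family-based rare-variant filtering: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant filtering: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcascade)
```

## The setting and the procedure

`varcascade` targets the smallest useful unit of family genetics: a few
affected relatives with whole-exome data and no controls. The cohort shape
it encodes is two families — a sequenced proband `1-b` whose affected
mother was never sequenced, and an affected sister pair `2-a`/`2-b`. With
two or three genomes there is no power for association, so discovery is a
deterministic filtering argument, and the package's job is to make that
argument auditable: every cascade returns the ordered list of filter steps
with survivor counts, the same shape as the flowchart tables such studies
publish.

The procedure has four layers.

**Upstream QC.** Variant calling and VQSR are upstream of this package;
their verdicts arrive in the VCF `FILTER` column and the `INFO/QD`
(quality-by-depth) tag. QC removes variants with `QD < qd_min` (strict
inequality; a variant at exactly the threshold is retained) and, by
default, variants whose `FILTER` is not the literal `PASS`. A `.`
(unfiltered) FILTER is treated as non-PASS: in a pipeline whose calls
always carry VQSR verdicts, an unfiltered record indicates an upstream
anomaly. A missing QD tag, by contrast, is retained with a warning tally —
the rule removes *low* QD, and absence of the tag is not evidence of low
quality.

**Multiallelic decomposition.** Sites with several ALT alleles are split
into per-allele biallelic variants before any filtering. For ALT allele
*k*, genotype *a/b* recodes to `het` iff exactly one of *a, b* equals *k*,
`homalt` iff both do, and `homref` otherwise; any `.` allele makes the call
`missing`. Phase separators (`/`, `|`) are equivalent throughout — all
genotype logic is unphased. Split variants keep a `from_multiallelic` flag
and are run through identical model logic but reported in a separate output
section, because their allele frequencies and annotations are less
reliable and the source analysis treated them separately. Splitting
conserves allele observations (the test suite verifies `het + 2·homalt`
bookkeeping against exhaustive genotype enumeration for up to four ALT
alleles). Variant keys are taken verbatim from the VCF after splitting; no
left-alignment or trimming is performed, so annotation tables must be keyed
identically — indel normalization is out of scope and callers lifting
annotations from other pipelines should normalize upstream.

**Filters.** Three orthogonal predicates compose into cascades:

- *Consequence.* The `(region class, exonic function)` pair maps to a
  consequence token; the `CANDIDATE` preset retains UTR5/UTR3, exonic
  nonsynonymous, splicing, stopgain, stoploss and exonic indels, while the
  `UNBIASED` preset drops the UTRs. Synonymous and intronic variants are
  never retained by either preset. The two presets reflect the two stated
  filter definitions in the source analysis; where its flowchart and
  methods text disagreed on UTRs in the unbiased arm, the methods text
  (no UTR) was followed, and the preset is a plain argument the caller can
  override.
- *Frequency.* A variant passes iff *every* in-scope
  (database, population) cell — databases gnomAD exomes, gnomAD genomes,
  1000 Genomes; populations `ALL` and optionally `EAS` — has frequency
  strictly below the threshold (default 0.005), or is missing. Missingness
  is explicit (`NA`, parsed from `.`/empty cells) and passes by default
  ("rare or not present in the database"); it is never coerced to zero, and
  a missing cell can never satisfy a `<` comparison by accident. The
  East Asian stratum participates in the unbiased cascades because the
  families are of East Asian ancestry and a variant common in that stratum
  is a poor Mendelian candidate regardless of its global frequency.
- *Panel.* The candidate cascade first restricts to a gene panel (exact
  symbol match after upper-casing; alias resolution is deliberately not
  attempted, as alias maps are database-version dependent). The shipped
  panel contains genes from monogenic bone disorders with reported AFFs
  plus genes named by prior AFF sequencing and candidate-gene studies; it
  is a plain text file and fully user-replaceable.

**Inheritance models.** On the filtered set: the candidate carrier rule
keeps variants carried by the proband and/or by both sisters (dropping
single-sister variants); the dominant model requires strict heterozygosity
in both sisters (a homozygote is not `0/1`); the recessive model requires
`1/1` in both; compound-heterozygote detection emits all unordered pairs
of same-gene variants het in both sisters. Without parental genotypes the
trans configuration of a pair cannot be verified, so every pair carries an
explicit `phase_unknown` flag rather than a guessed phase. A missing
genotype fails every required-genotype predicate — conservative, and
consistent with how the unavailable mother was handled in the source
study. Cross-family overlap reports genes where the proband carries at
least one qualifying variant whose key differs from every shared variant
of the sisters in that gene; an identical key is excluded because shared
identity is not independent evidence.

One cohort ambiguity is resolved explicitly: the candidate carrier rule is
stated in terms of the first family's affected members, but only `1-b` was
ever sequenced, and the published genotype table reports `1-b`. The
implementation therefore uses `1-b` for that rule.

## Prioritization

The dominant model on two siblings leaves hundreds of candidates, so two
prioritization routes are provided. The damage partition selects
truncating variants (stopgain, stoploss, frameshift indels; splicing
variants only behind an opt-in flag, since truncation via splice
disruption is not certain and the class definition is genuinely
underdetermined) and variants with phred-scaled CADD strictly above 30.
CADD percentiles follow from the phred definition: a score *s* places a
substitution among the `100·10^(−s/10)` percent most deleterious — 10 maps
to 10%, 15 to about 3%.

Gene-set intersection consumes GMT-format files. Because a causal gene may
be absent from a curated pathway while its close paralogue is present, an
optional gene-family map adds family-level hits: an input gene is flagged
when any member of its family belongs to the pathway. This mirrors the
manual step by which a TRAF4 variant was surfaced through TRAF2/TRAF6
membership in the osteoclast differentiation pathway. Family expansion
requires an explicit map; a prefix heuristic (strip trailing digits)
exists behind an opt-in flag but is off by default because symbol prefixes
are an unreliable proxy for homology. The shipped pathway files are small
synthetic stand-ins assembled for testing — clearly labelled
non-authoritative in the file name — since pathway databases are versioned
resources a reproducible package should not silently pin.

## The synthetic-data generator

The study's exomes were never deposited, so validation runs on synthetic
data with planted truth. A roster assigns every variant an intended fate:
`survives_all`, or failure of exactly one cascade step
(`fails_qc`, `fails_panel`, `fails_consequence`, `fails_frequency`,
`fails_carrier_pattern`), or `multiallelic_demo` (emitted pairwise as
two-ALT records). Field values are drawn conditionally on the fate —
survivors draw frequencies in `[0, 0.0049]` or missing, QD in `[5, 60]`
and carrier-satisfying genotype triples; each failure mode perturbs
exactly the fields of its step. The closed-form truth table
(`roster_truth_table()`) states each entry's expected membership in every
cascade step's output, so a pipeline run over the emitted files can be
checked exactly. The default mixture plants roughly a third survivors with
every failure mode represented; generation is driven by one integer seed
through a single PRNG stream, with global RNG state restored.

Three fixed fixtures recapitulate the worked examples end to end: R1 (the
two published candidate variants among twelve single-fault decoys; the
candidate cascade must end with exactly those two keys), R2 (one shared
homozygote plus het–het pairs in three genes against non-shared,
single-shared and too-frequent decoy pairs), and R3 (shared-het variants
across seven genes with proband counterparts in exactly four, one
identical-key gene that must be excluded, and one frequency-failing
decoy). Fixture positions and genes are fixed constants on contigs not
used elsewhere, so fixture outputs are byte-stable.

What the generator does *not* emulate: read-level artifacts, genotyping
error, linkage between sites, realistic allele-frequency spectra, or
annotation disagreement between databases. Passing tests therefore
demonstrate that the filtering logic is faithful to its rules — not that
those rules are robust to noisy real-world annotation, which is a property
of the upstream calling and annotation stack.

## Numerical and interface choices

- Frequencies, scores and QD parse `.` and empty cells as `NA`; a present
  frequency outside `[0, 1]` is a fatal data error, never clamped.
- All thresholds are strict inequalities as stated in their rules:
  frequency `< 0.005`, QD removal `< 5`, high-CADD `> 30`. Boundary values
  (0.005, QD 5, CADD 30) fall on the retained/not-selected side
  accordingly, and the tests pin each boundary.
- Variant tables are ordered deterministically (chromosome rank, position,
  ref, alt) after every join and in every written report, so repeated runs
  are byte-identical.
- Genotypes with one missing allele (`0/.`) are classified `missing` —
  flagged, not guessed.
- A half-open question in the interface: annotation tables are joined on
  exact `(chrom, pos, ref, alt)` keys after chromosome-prefix
  normalization (`chr` prefix by default, toggleable), with duplicate keys
  fatal and unannotated variants excluded but counted and reported.

## Problem sizes

The validation suite runs rosters of 60–500 variants (20 seeds for
planted-truth recovery, exhaustive 64-triple genotype tables, and
exhaustive diploid-genotype enumeration at up to four ALT alleles), which
exercises every code path in seconds on a single core. The cascades are
linear in the number of variants and the compound-het step is quadratic
only within genes, so the same code runs comfortably at whole-exome scale
(tens of thousands of variants).

## Known limitations

- No indel normalization or liftover; annotation joins assume identically
  normalized keys.
- No pedigree likelihoods, kinship checks or phasing — the models are
  deliberately the simple genotype predicates of the desk analysis.
- Compound-het pairs are phase-unknown by construction; a cis pair is
  indistinguishable from a trans pair without parental data.
- The shipped panel and pathway files are starting points, not authorities;
  both are plain text and expected to be replaced by the user's own
  curation.
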