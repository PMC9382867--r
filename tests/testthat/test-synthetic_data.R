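test_that("random rosters are reproducible and honor degenerate mixtures", {
  a <- generate_random_roster(100, seed = 7)
  b <- generate_random_roster(100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_random_roster(100, seed = 8)))
  # global RNG state is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_random_roster(50, seed = 99)); after <- runif(3)
  expect_identical(before, after)
  # zero weight on frequency failures: no cell reaches the threshold
  w <- c(survives_all = 0.5, fails_consequence = 0.1, fails_frequency = 0,
         fails_panel = 0.1, fails_carrier_pattern = 0.2, fails_qc = 0.1,
         multiallelic_demo = 0)
  r <- generate_random_roster(200, seed = 3, config = roster_config(w))
  freqs <- unlist(r[, grep("^freq_", names(r))])
  expect_true(all(is.na(freqs) | freqs < 0.005))
  expect_error(roster_config(c(w[-1], bogus = 0.5)), "must name exactly")
  expect_error(roster_config(w * 2), "sum to 1")
})

test_that("fixture R1 recapitulates the candidate-cascade worked example", {
  roster <- build_fixture_R1()
  expect_gte(nrow(roster) - 2L, 10L)           # at least ten decoys
  data <- ingest_roster(roster, "R1")
  v <- suppressMessages(qc_filter(data$variants))
  panel <- read_gene_panel(shipped("candidate_panel.txt"))
  res <- candidate_cascade(v, panel)
  expect_equal(res$report$count[[1L]], nrow(roster))
  expect_equal(res$report$count[[nrow(res$report)]], 2L)
  expect_setequal(res$variants$key,
                  c("chr3:145799628T>A", "chr11:118402939G>A"))
  expect_setequal(res$variants$gene, c("PLOD2", "TMEM25"))
  # single-sister decoys are eliminated exactly at the carrier-pattern step
  n <- nrow(res$report)
  single_sister <- sum(roster$fate == "fails_carrier_pattern")
  expect_equal(res$report$count[[n - 1L]] - res$report$count[[n]],
               single_sister)
})

test_that("fixture R2 recapitulates the recessive and compound-het findings", {
  data <- ingest_roster(build_fixture_R2(), "R2")
  v <- suppressMessages(qc_filter(data$variants))
  res <- recessive_cascade(v)
  expect_equal(nrow(res$variants), 1L)
  expect_equal(res$variants$gene, "MANF")
  expect_equal(sort(unique(res$compound_het$gene)),
               c("GSX2", "SYNPO2L", "TTN"))
  expect_equal(nrow(res$compound_het), 3L)     # one pair per gene
  # the decoy gene with a single shared het never forms a pair
  expect_false("SORCS1" %in% res$compound_het$gene)
  expect_false("APH1B" %in% res$compound_het$gene)
})

test_that("fixture R3 recapitulates the cross-family gene overlap", {
  data <- ingest_roster(build_fixture_R3(), "R3")
  v <- suppressMessages(qc_filter(data$variants))
  dom <- dominant_cascade(v)
  pre <- consequence_filter(v, consequence_preset("UNBIASED"))
  pre <- frequency_filter(pre, frequency_rule(populations = c("ALL", "EAS")))
  proband <- pre[pre[["gt_1-b"]] %in% c("het", "homalt"), , drop = FALSE]
  overlap <- cross_family_gene_overlap(dom$variants, proband)
  expect_equal(overlap, c("ANKS3", "FAN1", "IL2RG", "TTN"))
  expect_false("EPHA10" %in% overlap)          # identical key: excluded
  expect_false("SORCS1" %in% overlap)          # no proband variant
})

test_that("emitted datasets round-trip exactly through the ingestion path", {
  rosters <- list(R1 = build_fixture_R1(), R2 = build_fixture_R2(),
                  R3 = build_fixture_R3(),
                  random = generate_random_roster(120, seed = 5))
  for (nm in names(rosters)) {
    roster <- rosters[[nm]]
    data <- ingest_roster(roster, nm)
    got <- data$variants
    expect_equal(nrow(got), nrow(roster), label = nm)
    ord <- match(got$key, roster$key)
    expect_false(anyNA(ord), label = nm)
    for (col in c("gene", "region_class", "exonic_function", "hgvs", "dbsnp",
                  FREQ_COLS, "sift", "polyphen2_hvar", "cadd_phred", "gerp",
                  "qd", "filter_field", "gt_1-b", "gt_2-a", "gt_2-b")) {
      expect_equal(got[[col]], roster[[col]][ord], label = paste(nm, col))
    }
    expect_equal(got$from_multiallelic, roster$n_alt[ord] > 1L, label = nm)
  }
})

test_that("emitted VCFs are grammatical and multiallelic sites emit as multi-ALT records", {
  dir <- withr::local_tempdir()
  w <- c(survives_all = 0.5, fails_consequence = 0, fails_frequency = 0,
         fails_panel = 0, fails_carrier_pattern = 0, fails_qc = 0,
         multiallelic_demo = 0.5)
  roster <- generate_random_roster(60, seed = 13, config = roster_config(w))
  paths <- emit_roster(roster, dir, "multi")
  lines <- readLines(paths$vcf)
  expect_equal(lines[[1L]], "##fileformat=VCFv4.2")
  header <- grep("^#CHROM", lines, value = TRUE)
  expect_length(header, 1L)
  expect_equal(strsplit(header, "\t")[[1L]][1:9],
               c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT"))
  body <- lines[!startsWith(lines, "#")]
  expect_true(all(lengths(strsplit(body, "\t")) == 12L))
  # each triallelic roster pair collapses to one record with two ALT alleles
  n_multi_rows <- sum(roster$n_alt > 1L)
  alts <- vapply(strsplit(body, "\t"), `[[`, character(1), 5L)
  expect_equal(sum(lengths(strsplit(alts, ",")) == 2L), n_multi_rows / 2L)
  # and ingestion splits them back into flagged biallelic skeletons
  data <- suppressMessages(load_dataset(paths$vcf, paths$annotations, paths$cohort))
  expect_equal(sum(data$variants$from_multiallelic), n_multi_rows)
})

test_that("planted truth is recovered by the cascade across seeds", {
  panel <- read_gene_panel(shipped("candidate_panel.txt"))
  for (seed in 1:20) {
    roster <- generate_random_roster(80, seed = seed)
    truth <- roster_truth_table(roster)
    data <- ingest_roster(roster, paste0("seed", seed))
    v <- suppressMessages(qc_filter(data$variants))
    bi <- v[!v$from_multiallelic, , drop = FALSE]
    res <- candidate_cascade(bi, panel)
    expect_setequal(res$variants$key, truth$key[truth$survives])
    # intended-fate labels are consistent with the closed-form step flags
    for (i in seq_len(nrow(truth))) {
      fate <- truth$fate[i]
      flags <- truth[i, c("pass_qc", "in_panel", "pass_consequence",
                          "pass_gnomad", "pass_kg1000", "pass_carrier")]
      if (fate == "multiallelic_demo") {
        expect_true(truth$is_multiallelic[i] && !truth$survives[i])
      } else if (fate == "survives_all") {
        expect_true(all(unlist(flags)), label = paste("seed", seed, "row", i))
      } else {
        expect_equal(sum(!unlist(flags)), 1L,
                     label = paste("seed", seed, "row", i, fate))
      }
    }
  }
})
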