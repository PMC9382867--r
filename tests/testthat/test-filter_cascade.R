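test_that("consequence presets retain and exclude the documented class table", {
  cases <- list(
    # region, exonic_function, in CANDIDATE, in UNBIASED
    list("exonic", "nonsynonymous_SNV", TRUE, TRUE),
    list("exonic", "stopgain", TRUE, TRUE),
    list("exonic", "stoploss", TRUE, TRUE),
    list("exonic", "frameshift_indel", TRUE, TRUE),
    list("exonic", "nonframeshift_indel", TRUE, TRUE),
    list("splicing", "none", TRUE, TRUE),
    list("UTR5", "none", TRUE, FALSE),
    list("UTR3", "none", TRUE, FALSE),
    list("exonic", "synonymous_SNV", FALSE, FALSE),
    list("exonic", "unknown", FALSE, FALSE),
    list("intronic", "none", FALSE, FALSE),
    list("intergenic", "none", FALSE, FALSE)
  )
  for (cs in cases) {
    v <- variant_row(1, region = cs[[1]], exfun = cs[[2]])
    got_c <- nrow(consequence_filter(v, consequence_preset("CANDIDATE"))) == 1L
    got_u <- nrow(consequence_filter(v, consequence_preset("UNBIASED"))) == 1L
    expect_equal(got_c, cs[[3]], label = paste(cs[[1]], cs[[2]], "CANDIDATE"))
    expect_equal(got_u, cs[[4]], label = paste(cs[[1]], cs[[2]], "UNBIASED"))
  }
  expect_warning(
    consequence_filter(variant_row(1, region = "weird")),
    "unrecognized region class"
  )
})

test_that("frequency rule: strict threshold, explicit missingness, scoped cells", {
  at <- function(freq) variant_table(variant_row(1, freq = freq))
  rule <- frequency_rule(0.005, c("gnomad_wes", "gnomad_wgs"), "ALL")
  expect_equal(nrow(frequency_filter(at(c(freq_gnomad_wes_ALL = 0.0049)), rule)), 1L)
  expect_equal(nrow(frequency_filter(at(c(freq_gnomad_wes_ALL = 0.005)), rule)), 0L)
  # all cells missing: "not present in the database" passes
  expect_equal(nrow(frequency_filter(at(numeric(0)), rule)), 1L)
  # a missing value never compares as below threshold when missing must fail
  strict <- frequency_rule(0.005, "gnomad_wes", "ALL", missing_passes = FALSE)
  expect_equal(nrow(frequency_filter(at(numeric(0)), strict)), 0L)
  # out-of-scope cells are ignored
  expect_equal(nrow(frequency_filter(at(c(freq_kg1000_ALL = 0.9)), rule)), 1L)
  # EAS-stratum scope catches subpopulation-frequent variants
  eas <- frequency_rule(0.005, "gnomad_wes", c("ALL", "EAS"))
  expect_equal(nrow(frequency_filter(at(c(freq_gnomad_wes_EAS = 0.01)), eas)), 0L)
  # a frequency outside [0,1] is a fatal data error
  expect_error(frequency_filter(at(c(freq_gnomad_wes_ALL = 1.2)),
                                frequency_rule(0.005, "gnomad_wes", "ALL")),
               "outside \\[0,1\\]")
  expect_error(frequency_rule(threshold = 0), "must lie in")
})

test_that("published candidate variants pass the unbiased frequency rule", {
  plod2 <- variant_row(145799628, chrom = "chr3", ref = "T", alt = "A",
                       freq = c(freq_gnomad_wes_ALL = 3.99e-06,
                                freq_gnomad_wes_SAS = 0,
                                freq_gnomad_wes_EAS = 5.44e-05))
  rule <- frequency_rule(0.005, databases = c("gnomad_wes", "gnomad_wgs", "kg1000"),
                         populations = c("ALL", "EAS"))
  expect_equal(nrow(frequency_filter(plod2, rule)), 1L)
})

test_that("candidate panel filter matches case-insensitively and validates input", {
  v <- variant_table(
    variant_row(1, gene = "PLOD2"),
    variant_row(2, gene = "Plod2"),
    variant_row(3, gene = "TRAF4")
  )
  panel <- read_gene_panel(shipped("candidate_panel.txt"))
  out <- candidate_gene_filter(v, panel)
  expect_equal(out$pos, c(1L, 2L))
  expect_error(candidate_gene_filter(v, character(0)), "non-empty")
  expect_equal(nrow(candidate_gene_filter(v, "NOSUCHGENE")), 0L)
})

test_that("cascades report monotone counts, start at the input size, handle empty input", {
  v <- variant_table(variant_row(1), variant_row(2), variant_row(3))
  res <- run_cascade(v, list(identity_step = function(x) x))
  expect_equal(res$report$count, c(3L, 3L))
  empty <- run_cascade(v[0, ], list(
    a = function(x) x,
    b = function(x) x[x$pos > 1e9, , drop = FALSE]
  ))
  expect_equal(empty$report$count, c(0L, 0L, 0L))
  expect_error(run_cascade(v, list()), "at least one step")

  for (seed in c(11, 12, 13)) {
    roster <- generate_random_roster(150, seed)
    res <- candidate_cascade(roster, read_gene_panel(shipped("candidate_panel.txt")))
    expect_false(is.unsorted(rev(res$report$count)))
    expect_equal(res$report$count[[1L]], nrow(roster))
  }
})

test_that("filters are idempotent and consequence/frequency filters commute", {
  for (seed in c(21, 22)) {
    v <- generate_random_roster(120, seed)
    cons <- function(x) consequence_filter(x, consequence_preset("CANDIDATE"))
    freq <- function(x) frequency_filter(x, frequency_rule())
    pan <- function(x) candidate_gene_filter(x, read_gene_panel(shipped("candidate_panel.txt")))
    carr <- function(x) carrier_pattern_filter(x)
    for (f in list(cons, freq, pan, carr)) {
      once <- f(v)
      expect_equal(f(once)$key, once$key)
    }
    expect_setequal(freq(cons(v))$key, cons(freq(v))$key)
  }
})

test_that("retained sets equal naive per-variant predicate re-evaluation", {
  panel <- read_gene_panel(shipped("candidate_panel.txt"))
  for (seed in c(31, 32, 33)) {
    roster <- generate_random_roster(200, seed)
    bi <- roster[roster$n_alt == 1L, , drop = FALSE]
    res <- candidate_cascade(bi, panel)
    expected <- vapply(seq_len(nrow(bi)), function(i)
      oracle_candidate_pass(bi[i, , drop = FALSE], panel), logical(1))
    expect_setequal(res$variants$key, bi$key[expected])
  }
})
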