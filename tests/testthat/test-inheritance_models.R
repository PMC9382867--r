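# The three selection rules are asserted over every genotype-code triple
# (1-b, 2-a, 2-b): 4^3 = 64 cases, against predicates restated from the
# rule definitions.

all_triples <- function() {
  codes <- c("homref", "het", "homalt", "missing")
  grid <- expand.grid(p = codes, a = codes, b = codes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    variant_row(i, gt = c(grid$p[i], grid$a[i], grid$b[i])))
  list(grid = grid, variants = do.call(rbind, rows))
}

test_that("carrier-pattern rule over all 64 genotype triples", {
  tt <- all_triples()
  out <- carrier_pattern_filter(tt$variants)
  carrier <- function(x) x %in% c("het", "homalt")
  expected <- carrier(tt$grid$p) | (carrier(tt$grid$a) & carrier(tt$grid$b))
  expect_setequal(out$pos, which(expected))
  # the published genotype patterns
  keep1 <- carrier_pattern_filter(variant_row(1, gt = c("het", "homref", "homref")))
  keep2 <- carrier_pattern_filter(variant_row(2, gt = c("homref", "het", "het")))
  drop1 <- carrier_pattern_filter(variant_row(3, gt = c("homref", "het", "homref")))
  expect_equal(c(nrow(keep1), nrow(keep2), nrow(drop1)), c(1L, 1L, 0L))
  # missing genotypes are tallied
  expect_gt(attr(carrier_pattern_filter(
    variant_row(4, gt = c("missing", "het", "het"))), "n_missing"), 0L)
})

test_that("dominant and recessive models over all 64 genotype triples", {
  tt <- all_triples()
  dom <- dominant_model(tt$variants)
  expect_setequal(dom$pos, which(tt$grid$a == "het" & tt$grid$b == "het"))
  rec <- recessive_hom(tt$variants)
  expect_setequal(rec$pos, which(tt$grid$a == "homalt" & tt$grid$b == "homalt"))
  # proband genotype is irrelevant to the dominant model
  expect_equal(nrow(dominant_model(
    variant_row(1, gt = c("homalt", "het", "het")))), 1L)
  # homalt is not "0/1": strict heterozygosity
  expect_equal(nrow(dominant_model(
    variant_row(1, gt = c("homref", "het", "homalt")))), 0L)
  # a missing genotype fails the predicate, never imputed
  expect_equal(nrow(dominant_model(
    variant_row(1, gt = c("homref", "missing", "het")))), 0L)
  # dominant and recessive outputs are disjoint; dominant is a subset of the
  # carrier-pattern output
  expect_length(intersect(dom$key, rec$key), 0L)
  expect_true(all(dom$key %in% carrier_pattern_filter(tt$variants)$key))
  expect_equal(nrow(recessive_hom(tt$variants[0, ])), 0L)
})

test_that("compound-heterozygote detection equals exhaustive pair enumeration", {
  # minimal positive case and the C(3,2) enumeration
  g <- variant_table(
    variant_row(1, gene = "GSX2"),
    variant_row(2, gene = "GSX2"),
    variant_row(3, gene = "GSX2")
  )
  pairs <- compound_het(g)
  expect_equal(nrow(pairs), 3L)              # all unordered pairs
  expect_true(all(pairs$phase_unknown))      # trans-configuration unverifiable
  expect_true(all(pairs$key1 != pairs$key2))
  # a gene with one shared and one unshared het contributes nothing
  solo <- variant_table(
    variant_row(4, gene = "SORCS1"),
    variant_row(5, gene = "SORCS1", gt = c("homref", "het", "homref"))
  )
  expect_equal(nrow(compound_het(solo)), 0L)

  # randomized equivalence with the brute-force oracle
  genes <- c("G1", "G2", "G3", "G4", "G5", "G6")
  codes <- c("homref", "het", "homalt")
  for (seed in c(41, 42, 43)) {
    set.seed(seed)
    n <- 400
    rows <- lapply(seq_len(n), function(i)
      variant_row(i, gene = sample(genes, 1),
                  gt = c(sample(codes, 1), sample(codes, 1), sample(codes, 1))))
    v <- do.call(rbind, rows)
    got <- compound_het(v)
    exp <- oracle_compound_het(v)
    expect_equal(got[c("gene", "key1", "key2")], exp, ignore_attr = TRUE)
  }
})

test_that("cross-family overlap requires a different variant key in the proband", {
  shared <- variant_table(
    variant_row(10, gene = "TTN"),
    variant_row(20, gene = "FAN1"),
    variant_row(30, gene = "EPHA10", gt = c("het", "het", "het"))
  )
  proband <- variant_table(
    variant_row(11, gene = "TTN", gt = c("het", "homref", "homref")),
    variant_row(30, gene = "EPHA10", gt = c("het", "het", "het")),
    variant_row(40, gene = "ANKS3", gt = c("het", "homref", "homref"))
  )
  # TTN: different key -> in; EPHA10: identical key only -> out;
  # FAN1: no proband variant -> out; ANKS3: not shared by the pair -> out
  expect_equal(cross_family_gene_overlap(shared, proband), "TTN")
})
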