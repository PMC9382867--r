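# Carrier-pattern, dominant, recessive-homozygous and compound-heterozygous
# selection rules over the two-family cohort, plus cross-family gene overlap.
#
# A sample is a "carrier" of a variant iff its genotype code is het or
# homalt. A missing genotype fails every required-genotype predicate: it is
# counted, never imputed.

#' Candidate carrier-pattern filter
#'
#' Retains a variant iff the family-1 proband is a carrier, or both members
#' of the family-2 affected pair are carriers. Variants carried by exactly
#' one member of the pair (and not by the proband) are dropped. Missing
#' genotypes count as non-carrier and are tallied in the `n_missing`
#' attribute.
#'
#' @param variants Variant table with per-sample genotype codes.
#' @param proband Proband sample id (default `"1-b"`).
#' @param pair Affected-pair sample ids (default `c("2-a", "2-b")`).
#' @return Filtered variant table.
#' @export
carrier_pattern_filter <- function(variants, proband = "1-b",
                                   pair = c("2-a", "2-b")) {
  stopifnot(length(pair) == 2L)
  p <- sample_codes(variants, proband)
  a <- sample_codes(variants, pair[[1L]])
  b <- sample_codes(variants, pair[[2L]])
  n_missing <- sum(p == "missing" | a == "missing" | b == "missing")
  keep <- is_carrier(p) | (is_carrier(a) & is_carrier(b))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  out
}

#' Dominant inheritance model
#'
#' Retains variants heterozygous (strictly `het`; homalt does not qualify)
#' in both members of the affected pair, irrespective of any other sample's
#' genotype. A missing genotype in either member drops the variant.
#'
#' @inheritParams carrier_pattern_filter
#' @return Filtered variant table.
#' @export
dominant_model <- function(variants, pair = c("2-a", "2-b")) {
  stopifnot(length(pair) == 2L)
  a <- sample_codes(variants, pair[[1L]])
  b <- sample_codes(variants, pair[[2L]])
  out <- variants[a == "het" & b == "het", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recessive homozygous model
#'
#' Retains variants homozygous for the alternate allele in both members of
#' the affected pair.
#'
#' @inheritParams carrier_pattern_filter
#' @return Filtered variant table.
#' @export
recessive_hom <- function(variants, pair = c("2-a", "2-b")) {
  stopifnot(length(pair) == 2L)
  a <- sample_codes(variants, pair[[1L]])
  b <- sample_codes(variants, pair[[2L]])
  out <- variants[a == "homalt" & b == "homalt", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compound-heterozygote detection without phasing
#'
#' For each gene holding at least two distinct variants heterozygous in both
#' members of the affected pair, emits every unordered pair of such variants.
#' Without parental genotypes the trans configuration cannot be verified, so
#' every pair carries `phase_unknown = TRUE`.
#'
#' @param variants Variant table, normally already consequence- and
#'   frequency-filtered.
#' @inheritParams carrier_pattern_filter
#' @return Data.frame with one row per pair: `gene`, `key1`, `key2`,
#'   `phase_unknown`; genes with fewer than two qualifying variants are
#'   absent. Deterministically ordered by gene, then keys.
#' @export
compound_het <- function(variants, pair = c("2-a", "2-b")) {
  stopifnot(length(pair) == 2L)
  a <- sample_codes(variants, pair[[1L]])
  b <- sample_codes(variants, pair[[2L]])
  hh <- variants[a == "het" & b == "het", , drop = FALSE]
  out <- data.frame(gene = character(0), key1 = character(0),
                    key2 = character(0), phase_unknown = logical(0),
                    stringsAsFactors = FALSE)
  for (g in sort(unique(hh$gene))) {
    keys <- sort(unique(hh$key[hh$gene == g]))
    if (length(keys) < 2L) next
    cmb <- utils::combn(keys, 2L)
    out <- rbind(out, data.frame(gene = g, key1 = cmb[1L, ], key2 = cmb[2L, ],
                                 phase_unknown = TRUE, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Cross-family gene overlap
#'
#' Genes in which the affected pair's shared variants and the proband's
#' qualifying variants coincide at the gene level but through *different*
#' variants: a gene is reported iff the proband carries at least one variant
#' there whose key differs from every shared key of the pair in that gene.
#' Both inputs are expected to have passed the same consequence and
#' frequency rules (the proband side restricted to variants the proband
#' carries).
#'
#' @param shared_variants Variant table of the pair's shared variants (e.g.
#'   dominant-model output).
#' @param proband_variants Variant table of the proband's qualifying
#'   variants.
#' @return Sorted character vector of gene symbols.
#' @export
cross_family_gene_overlap <- function(shared_variants, proband_variants) {
  genes <- intersect(unique(shared_variants$gene),
                     unique(proband_variants$gene))
  hit <- vapply(genes, function(g) {
    shared_keys <- shared_variants$key[shared_variants$gene == g]
    pro_keys <- proband_variants$key[proband_variants$gene == g]
    any(!pro_keys %in% shared_keys)
  }, logical(1))
  sort(genes[hit])
}
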