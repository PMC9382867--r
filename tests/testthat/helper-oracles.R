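# Test fixtures built in code, plus independent brute-force oracles.
# The oracles deliberately re-derive every predicate from first principles
# and share no code with the package implementation.

FREQ_COLS <- c(
  "freq_gnomad_wes_ALL", "freq_gnomad_wes_SAS", "freq_gnomad_wes_EAS",
  "freq_gnomad_wgs_ALL", "freq_gnomad_wgs_EAS",
  "freq_kg1000_ALL", "freq_kg1000_EAS"
)

# Build one annotated-variant row the way the package represents it.
variant_row <- function(pos, chrom = "chr1", ref = "A", alt = "G",
                        gene = "PLOD2", region = "exonic",
                        exfun = "nonsynonymous_SNV",
                        gt = c("homref", "het", "het"), freq = numeric(0),
                        sift = 0.5, pp2 = 0.5, cadd = 20, gerp = 3,
                        qd = 30, filter = "PASS", from_multi = FALSE) {
  row <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    key = paste0(chrom, ":", pos, ref, ">", alt),
    gene = gene, region_class = region, exonic_function = exfun,
    hgvs = ".", dbsnp = ".",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (col in FREQ_COLS) {
    row[[col]] <- if (col %in% names(freq)) unname(freq[[col]]) else NA_real_
  }
  row$sift <- sift; row$polyphen2_hvar <- pp2
  row$cadd_phred <- cadd; row$gerp <- gerp
  row$qd <- qd; row$filter_field <- filter
  row$from_multiallelic <- from_multi
  row[["gt_1-b"]] <- gt[[1L]]; row[["gt_2-a"]] <- gt[[2L]]
  row[["gt_2-b"]] <- gt[[3L]]
  row
}

variant_table <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

shipped <- function(f) system.file("extdata", f, package = "varcascade")

# Hand-coded diploid GT parser (oracle for the VCF reader's genotype codes).
oracle_gt_code <- function(gt, k = 1L) {
  chars <- strsplit(gt, "")[[1L]]
  sep <- which(chars %in% c("/", "|"))
  if (length(sep) != 1L) return(NA_character_)
  a <- paste(chars[seq_len(sep - 1L)], collapse = "")
  b <- paste(chars[seq(sep + 1L, length(chars))], collapse = "")
  if (a == "." || b == ".") return("missing")
  a <- as.integer(a); b <- as.integer(b)
  n <- (a == k) + (b == k)
  c("homref", "het", "homalt")[n + 1L]
}

# Naive per-variant re-evaluation of every candidate-cascade predicate.
oracle_candidate_pass <- function(row, panel, threshold = 0.005) {
  if (!(toupper(row$gene) %in% toupper(panel))) return(FALSE)
  ok_class <- FALSE
  if (row$region_class %in% c("splicing", "UTR5", "UTR3")) ok_class <- TRUE
  if (row$region_class == "exonic" &&
      row$exonic_function %in% c("nonsynonymous_SNV", "stopgain", "stoploss",
                                 "frameshift_indel", "nonframeshift_indel")) {
    ok_class <- TRUE
  }
  if (!ok_class) return(FALSE)
  for (col in c("freq_gnomad_wes_ALL", "freq_gnomad_wgs_ALL",
                "freq_kg1000_ALL")) {
    f <- row[[col]]
    if (!is.na(f) && f >= threshold) return(FALSE)
  }
  carrier <- function(code) code == "het" || code == "homalt"
  carrier(row[["gt_1-b"]]) ||
    (carrier(row[["gt_2-a"]]) && carrier(row[["gt_2-b"]]))
}

# Exhaustive gene-by-gene pair enumeration for compound heterozygotes.
oracle_compound_het <- function(variants) {
  pairs <- list()
  for (g in unique(variants$gene)) {
    sub <- variants[variants$gene == g, , drop = FALSE]
    keys <- sort(unique(sub$key[sub[["gt_2-a"]] == "het" &
                                  sub[["gt_2-b"]] == "het"]))
    if (length(keys) < 2L) next
    for (i in seq_len(length(keys) - 1L)) {
      for (j in seq(i + 1L, length(keys))) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene = g, key1 = keys[[i]], key2 = keys[[j]],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(gene = character(0), key1 = character(0),
                      key2 = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  out[order(out$gene, out$key1, out$key2), , drop = FALSE]
}

# Emit a roster and read it back through the full ingestion path.
ingest_roster <- function(roster, name = "ds") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- emit_roster(roster, dir, prefix = name)
  suppressMessages(load_dataset(paths$vcf, paths$annotations, paths$cohort))
}
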