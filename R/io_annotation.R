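# Ingestion: multi-sample VCF, ANNOVAR-style annotation tables, cohort files.
#
# Coordinates are 1-based (VCF convention) throughout. Chromosome names are
# normalized to the "chr" prefix by default; the toggle accepts hg19 contigs
# with or without the prefix.

#' Read a cohort file
#'
#' Accepts either a headered TSV with columns `sample_id`, `family_id`,
#' `affected` (0/1 or TRUE/FALSE), or a header-less PED-like dialect
#' (family, individual, father, mother, sex, phenotype; phenotype 2 =
#' affected). Roles are derived per family: a family with a single affected
#' sequenced member contributes a `proband`; a family with exactly two
#' affected members contributes an `affected_pair`.
#'
#' @param path Path to the cohort file.
#' @return A data.frame of class `cohort` with columns `sample_id`,
#'   `family_id`, `affected`, `role`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("sample_id", first, fixed = TRUE)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("sample_id", "family_id", "affected")
    if (!all(need %in% names(tab))) {
      stop("cohort TSV must have columns: ", paste(need, collapse = ", "))
    }
    cohort <- data.frame(
      sample_id = as.character(tab$sample_id),
      family_id = as.character(tab$family_id),
      affected = as.logical(as.integer(tab$affected) != 0L |
        tolower(as.character(tab$affected)) == "true"),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.table(path, stringsAsFactors = FALSE)
    if (ncol(tab) < 6L) stop("PED-like cohort file needs >= 6 columns")
    cohort <- data.frame(
      sample_id = as.character(tab[[2L]]),
      family_id = as.character(tab[[1L]]),
      affected = tab[[6L]] == 2,
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(cohort$sample_id)) stop("duplicate sample_id in cohort file")
  cohort$role <- "other"
  for (fam in unique(cohort$family_id)) {
    idx <- which(cohort$family_id == fam & cohort$affected)
    if (length(idx) == 1L) cohort$role[idx] <- "proband"
    if (length(idx) == 2L) cohort$role[idx] <- "affected_pair"
  }
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Designated analysis groups of a cohort
#'
#' @param cohort A `cohort` data.frame from [read_cohort()].
#' @return List with `proband` (single affected member of a one-affected
#'   family, or NULL) and `pair` (the two-member affected pair, or NULL).
#' @export
cohort_groups <- function(cohort) {
  proband <- cohort$sample_id[cohort$role == "proband"]
  pair <- cohort$sample_id[cohort$role == "affected_pair"]
  list(
    proband = if (length(proband)) proband[[1L]] else NULL,
    pair = if (length(pair) == 2L) pair else NULL
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x), "samples in", length(unique(x$family_id)),
      "families\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Parse a diploid GT string into two allele indices (NA for "."). Phase
# separators "/" and "|" are equivalent; genotypes are treated unphased.
parse_gt <- function(gt) {
  m <- regmatches(gt, regexec("^([0-9]+|\\.)[/|]([0-9]+|\\.)$", gt))[[1L]]
  if (length(m) != 3L) return(NULL)
  suppressWarnings(as.integer(m[2:3]))
}

#' Read a multi-sample VCF into a raw record table
#'
#' Preserves FILTER, INFO/QD and per-sample GT strings; positions stay
#' 1-based. Genotype strings are validated as diploid; a malformed GT is a
#' record-level error reported with its record number.
#'
#' @param path Path to a VCF v4.x file.
#' @param cohort A `cohort`; every cohort sample must have a column in the
#'   VCF (a missing sample column is a fatal configuration error).
#' @param chr_style Chromosome-name normalization: `"chr"` (default),
#'   `"plain"`, or `"keep"`.
#' @return Data.frame with one row per VCF record: `chrom`, `pos`, `id`,
#'   `ref`, `alt` (comma-joined ALT list), `filter_field`, `qd`, `record`,
#'   and one raw `gt_<sample>` column per cohort sample.
#' @export
read_vcf <- function(path, cohort, chr_style = "chr") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- cohort$sample_id
  if (n == 0L) {
    out <- data.frame(
      chrom = character(0), pos = integer(0), id = character(0),
      ref = character(0), alt = character(0), filter_field = character(0),
      qd = numeric(0), record = integer(0),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (s in samples) out[[gt_column(s)]] <- character(0)
    return(out)
  }
  vcf_samples <- colnames(vcf@gt)[-1L]
  missing <- setdiff(samples, vcf_samples)
  if (length(missing)) {
    stop("cohort sample(s) missing from VCF: ", paste(missing, collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  qd <- suppressWarnings(vcfR::extract.info(vcf, element = "QD", as.numeric = TRUE))
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  out <- data.frame(
    chrom = normalize_chrom(fix[, "CHROM"], chr_style),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    filter_field = filt,
    qd = as.numeric(qd),
    record = seq_len(n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (s in samples) {
    raw <- unname(gt[, s])
    bad <- which(vapply(raw, function(g) is.na(g) || is.null(parse_gt(g)), logical(1)) & !is.na(raw))
    if (length(bad)) {
      stop("malformed GT '", raw[bad[1L]], "' for sample '", s,
           "' at VCF record ", bad[1L])
    }
    raw[is.na(raw)] <- "./."
    out[[gt_column(s)]] <- raw
  }
  out
}

# Recode one diploid genotype relative to ALT allele k of a split record.
recode_genotype <- function(alleles, k) {
  if (is.null(alleles) || anyNA(alleles)) return("missing")
  hits <- sum(alleles == k)
  if (hits == 2L) "homalt" else if (hits == 1L) "het" else "homref"
}

#' Decompose multiallelic records into biallelic variant skeletons
#'
#' Each ALT allele of a record becomes one biallelic skeleton. For ALT allele
#' `k`, a diploid genotype `a/b` recodes to `het` if exactly one of `a`,`b`
#' equals `k`, `homalt` if both do, `missing` if either allele is missing,
#' and `homref` otherwise. `from_multiallelic` marks skeletons whose source
#' record carried more than one ALT allele; genotypes with one missing allele
#' (e.g. `"0/."`) are classified `missing`, never guessed.
#'
#' @param records Raw record table from [read_vcf()].
#' @return Variant skeleton data.frame keyed by (`chrom`,`pos`,`ref`,`alt`)
#'   with per-sample genotype codes (`homref`/`het`/`homalt`/`missing`),
#'   `filter_field`, `qd`, `from_multiallelic` and `key`.
#' @export
split_multiallelic <- function(records) {
  gt_cols <- grep("^gt_", names(records), value = TRUE)
  samples <- sub("^gt_", "", gt_cols)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    alts <- strsplit(rec$alt, ",", fixed = TRUE)[[1L]]
    n_alt <- length(alts)
    if (n_alt < 1L) stop("record ", rec$record, " has no ALT allele")
    parsed <- lapply(gt_cols, function(col) parse_gt(rec[[col]]))
    names(parsed) <- samples
    for (al in parsed) {
      if (!is.null(al) && any(al > n_alt, na.rm = TRUE)) {
        stop("record ", rec$record, ": genotype allele index exceeds ALT count ",
             n_alt)
      }
    }
    sk <- lapply(seq_len(n_alt), function(k) {
      row <- data.frame(
        chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = alts[[k]],
        key = variant_key(rec$chrom, rec$pos, rec$ref, alts[[k]]),
        filter_field = rec$filter_field, qd = rec$qd,
        from_multiallelic = n_alt > 1L, record = rec$record,
        stringsAsFactors = FALSE, check.names = FALSE
      )
      for (s in samples) {
        row[[gt_column(s)]] <- recode_genotype(parsed[[s]], k)
      }
      row
    })
    rows[[i]] <- do.call(rbind, sk)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- records[0, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    out$key <- character(0)
    out$filter_field <- character(0)
    out$qd <- numeric(0)
    out$from_multiallelic <- logical(0)
    out$record <- integer(0)
    for (s in samples) out[[gt_column(s)]] <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Default annotation-table column mapping
#'
#' Names of the columns expected in the annotation TSV, mirroring the
#' ANNOVAR-style layout (gene symbol, region class, exonic function,
#' transcript/HGVS, dbSNP id, per-database per-population allele frequencies,
#' SIFT, PolyPhen2-HVAR, CADD phred, GERP++). Override entries to match a
#' differently-headed table.
#'
#' @return Named list mapping internal fields to TSV header names.
#' @export
annotation_columns <- function() {
  list(
    chrom = "Chr", pos = "Start", ref = "Ref", alt = "Alt",
    gene = "Gene", region = "Func", exonic_function = "ExonicFunc",
    hgvs = "AAChange", dbsnp = "dbSNP",
    freq = c(
      freq_gnomad_wes_ALL = "gnomAD_WES_ALL",
      freq_gnomad_wes_SAS = "gnomAD_WES_SAS",
      freq_gnomad_wes_EAS = "gnomAD_WES_EAS",
      freq_gnomad_wgs_ALL = "gnomAD_WGS_ALL",
      freq_gnomad_wgs_EAS = "gnomAD_WGS_EAS",
      freq_kg1000_ALL = "KG1000_ALL",
      freq_kg1000_EAS = "KG1000_EAS"
    ),
    scores = c(
      sift = "SIFT_score", polyphen2_hvar = "Polyphen2_HVAR_score",
      cadd_phred = "CADD_phred", gerp = "GERP_RS"
    )
  )
}

# Region-class vocabulary normalization (ANNOVAR Func values).
normalize_region <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("other", length(x))
  low <- tolower(x)
  out[low == "exonic"] <- "exonic"
  out[grepl("splicing", low)] <- "splicing"   # incl. "exonic;splicing"
  out[low %in% c("utr5", "5utr", "utr-5")] <- "UTR5"
  out[low %in% c("utr3", "3utr", "utr-3")] <- "UTR3"
  out[low == "intronic"] <- "intronic"
  out[low == "intergenic"] <- "intergenic"
  out
}

# Exonic-function vocabulary normalization (ANNOVAR ExonicFunc values).
normalize_exonic_function <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("none", length(x))
  out[x %in% c("nonsynonymous snv", "nonsynonymous_snv")] <- "nonsynonymous_SNV"
  out[x %in% c("synonymous snv", "synonymous_snv")] <- "synonymous_SNV"
  out[x == "stopgain"] <- "stopgain"
  out[x == "stoploss"] <- "stoploss"
  out[grepl("^frameshift", x)] <- "frameshift_indel"
  out[grepl("^nonframeshift", x)] <- "nonframeshift_indel"
  out[x == "unknown"] <- "unknown"
  out
}

# "." and "" cells are explicit missingness, never coerced to 0.
parse_numeric_cell <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", ".", "NA")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Join an annotation table onto variant skeletons
#'
#' Annotation rows are keyed by (`chrom`, `pos`, `ref`, `alt`). A duplicated
#' annotation key is fatal (both line numbers reported). Variants without an
#' annotation row are excluded from the returned table, flagged via a message
#' and the `unannotated` attribute. Frequency cells equal to `""` or `"."`
#' become missing (`NA`), and all present frequencies are checked to lie in
#' [0, 1].
#'
#' @param variants Variant skeletons from [split_multiallelic()].
#' @param annotations Path to a headered TSV, or an equivalent data.frame.
#' @param columns Column mapping, see [annotation_columns()].
#' @param chr_style Chromosome normalization applied to the annotation table.
#' @return Annotated variant table, deterministically ordered by
#'   (chrom, pos, ref, alt), with attribute `unannotated` holding the keys of
#'   dropped variants.
#' @export
join_annotations <- function(variants, annotations,
                             columns = annotation_columns(),
                             chr_style = "chr") {
  ann <- if (is.character(annotations)) {
    if (!file.exists(annotations)) stop("annotation file not found: ", annotations)
    utils::read.delim(annotations, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
  } else {
    annotations
  }
  need <- unlist(columns[c("chrom", "pos", "ref", "alt", "gene", "region",
                           "exonic_function")], use.names = FALSE)
  absent <- setdiff(need, names(ann))
  if (length(absent)) {
    stop("annotation table lacks required column(s): ",
         paste(absent, collapse = ", "))
  }
  akey <- variant_key(
    normalize_chrom(as.character(ann[[columns$chrom]]), chr_style),
    as.integer(ann[[columns$pos]]),
    as.character(ann[[columns$ref]]), as.character(ann[[columns$alt]])
  )
  if (anyDuplicated(akey)) {
    dup_key <- akey[duplicated(akey)][1L]
    d <- which(akey == dup_key)
    stop("duplicate annotation key '", dup_key, "' at annotation lines ",
         paste(d + 1L, collapse = " and "))
  }
  idx <- match(variants$key, akey)
  unann <- variants$key[is.na(idx)]
  if (length(unann)) {
    message(length(unann), " variant(s) had no annotation row and were excluded")
  }
  keep <- !is.na(idx)
  out <- variants[keep, , drop = FALSE]
  idx <- idx[keep]
  out$gene <- toupper(trimws(as.character(ann[[columns$gene]])[idx]))
  out$region_class <- normalize_region(ann[[columns$region]][idx])
  out$exonic_function <- normalize_exonic_function(ann[[columns$exonic_function]][idx])
  bad <- out$exonic_function != "none" & out$region_class != "exonic" &
    out$region_class != "splicing"
  if (any(bad)) {
    warning(sum(bad), " variant(s) carry an exonic function outside an exonic ",
            "region; exonic_function reset to 'none'")
    out$exonic_function[bad] <- "none"
  }
  hg <- columns$hgvs
  out$hgvs <- if (!is.null(hg) && hg %in% names(ann)) as.character(ann[[hg]])[idx] else NA_character_
  db <- columns$dbsnp
  out$dbsnp <- if (!is.null(db) && db %in% names(ann)) as.character(ann[[db]])[idx] else NA_character_
  for (field in names(columns$freq)) {
    col <- columns$freq[[field]]
    vals <- if (col %in% names(ann)) parse_numeric_cell(ann[[col]][idx]) else NA_real_
    if (any(!is.na(vals) & (vals < 0 | vals > 1))) {
      stop("frequency outside [0,1] in annotation column '", col, "'")
    }
    out[[field]] <- vals
  }
  for (field in names(columns$scores)) {
    col <- columns$scores[[field]]
    out[[field]] <- if (col %in% names(ann)) parse_numeric_cell(ann[[col]][idx]) else NA_real_
  }
  out <- order_variants(out)
  rownames(out) <- NULL
  attr(out, "unannotated") <- unann
  out
}

#' Upstream quality-control filter
#'
#' Removes variants whose quality-by-depth falls below `qd_min` (strict `<`,
#' so a variant at exactly the threshold is retained) and, when
#' `require_pass` is set, variants whose FILTER field is not the literal
#' `PASS` (reflecting upstream VQSR verdicts). A missing QD value is retained
#' and counted in the `n_missing_qd` attribute, since absence of the tag is
#' not evidence of low quality.
#'
#' @param variants Variant table carrying `qd` and `filter_field`.
#' @param qd_min Quality-by-depth threshold (default 5).
#' @param require_pass Drop non-PASS FILTER rows (default TRUE).
#' @return Filtered variant table with attribute `n_missing_qd`.
#' @export
qc_filter <- function(variants, qd_min = 5, require_pass = TRUE) {
  miss <- is.na(variants$qd)
  if (any(miss)) {
    message(sum(miss), " variant(s) lack an INFO/QD value; retained")
  }
  keep <- miss | variants$qd >= qd_min
  if (require_pass) keep <- keep & variants$filter_field == "PASS"
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_qd") <- sum(miss & keep)
  out
}

#' Load a complete annotated dataset
#'
#' Convenience wrapper: reads cohort + VCF, splits multiallelic records and
#' joins annotations in one call.
#'
#' @inheritParams read_vcf
#' @inheritParams join_annotations
#' @param cohort_path Path to a cohort file (see [read_cohort()]).
#' @param annotations Path to the annotation TSV.
#' @return List with `cohort` and the annotated `variants` table.
#' @export
load_dataset <- function(path, annotations, cohort_path,
                         columns = annotation_columns(), chr_style = "chr") {
  cohort <- read_cohort(cohort_path)
  records <- read_vcf(path, cohort, chr_style = chr_style)
  variants <- split_multiallelic(records)
  variants <- join_annotations(variants, annotations, columns = columns,
                               chr_style = chr_style)
  list(cohort = cohort, variants = variants)
}
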