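# Synthetic multi-sample exome datasets with planted, fully known truth:
# the validation stand-in for undeposited patient exomes. Generates variant
# rosters (each entry labelled with its intended fate in the filtering
# cascade), emits them as VCF + annotation TSV + cohort + truth files, and
# ships three fixed fixtures recapitulating the worked examples.

SYNTH_SAMPLES <- c("1-b", "2-a", "2-b")

ROSTER_FATES <- c("survives_all", "fails_consequence", "fails_frequency",
                  "fails_panel", "fails_carrier_pattern", "fails_qc",
                  "multiallelic_demo")

# Candidate panel (shipped as extdata/candidate_panel.txt): genes from
# monogenic bone disorders in which atypical femur fractures have been
# reported, plus genes named in prior AFF sequencing and candidate-gene
# studies (the published list's second part is not printed in full; these
# are its members named in the study text).
CANDIDATE_PANEL <- c(
  "ALPL", "COL1A1", "COL1A2", "CRTAP", "LEPRE1", "PPIB", "SERPINH1",
  "FKBP10", "PLOD2", "SP7", "CTSK", "PHEX", "TCIRG1", "CLCN7", "OSTM1",
  "PLEKHM1", "SNX10", "TNFSF11", "TNFRSF11A", "CA2", "LRP5", "PLS3",
  "GGPS1", "CYP1A1", "TMEM25", "ENPP1", "FGF23", "CYP27B1", "CYP3A4",
  "SLC34A3", "CYP2R1", "ATRAID"
)

#' The three-sample two-family synthetic cohort
#'
#' Family F1 contributes a single sequenced affected proband (1-b; the
#' second affected member was never sequenced), family F2 an affected sister
#' pair (2-a, 2-b).
#'
#' @return A `cohort` data.frame.
#' @export
synthetic_cohort <- function() {
  cohort <- data.frame(
    sample_id = SYNTH_SAMPLES,
    family_id = c("F1", "F2", "F2"),
    affected = TRUE,
    role = c("proband", "affected_pair", "affected_pair"),
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

# Build one roster row. gt is ordered (1-b, 2-a, 2-b); freq is a named
# numeric vector of overrides over all-missing frequency cells.
roster_row <- function(chrom, pos, ref, alt, gene, fate,
                       region = "exonic",
                       exonic_function = "nonsynonymous_SNV",
                       gt = c("homref", "homref", "homref"),
                       freq = numeric(0), hgvs = ".", dbsnp = ".",
                       sift = 0.5, polyphen2 = 0.5, cadd = 20, gerp = 3,
                       qd = 30, filter = "PASS",
                       n_alt = 1L, allele_index = 1L) {
  stopifnot(fate %in% ROSTER_FATES, length(gt) == 3L)
  row <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    key = variant_key(chrom, pos, ref, alt),
    gene = gene, region_class = region, exonic_function = exonic_function,
    hgvs = hgvs, dbsnp = dbsnp,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (col in FREQ_COLUMNS) {
    row[[col]] <- if (col %in% names(freq)) unname(freq[[col]]) else NA_real_
  }
  row$sift <- sift
  row$polyphen2_hvar <- polyphen2
  row$cadd_phred <- cadd
  row$gerp <- gerp
  row$qd <- qd
  row$filter_field <- filter
  for (i in seq_along(SYNTH_SAMPLES)) {
    stopifnot(gt[[i]] %in% GT_CODES)
    row[[gt_column(SYNTH_SAMPLES[[i]])]] <- gt[[i]]
  }
  row$fate <- fate
  row$n_alt <- as.integer(n_alt)
  row$allele_index <- as.integer(allele_index)
  row$site_id <- paste(chrom, pos, ref, sep = ":")
  row
}

as_roster <- function(rows) {
  roster <- do.call(rbind, rows)
  if (anyDuplicated(roster$key)) stop("roster keys must be unique")
  rownames(roster) <- NULL
  class(roster) <- c("roster", "data.frame")
  roster
}

#' Roster mixture configuration for the random generator
#'
#' @param fate_weights Named non-negative weights over the fate labels,
#'   summing to 1. The defaults plant a majority of cascade survivors with
#'   every failure mode represented.
#' @return Configuration list.
#' @export
roster_config <- function(fate_weights = c(
  survives_all = 0.35, fails_consequence = 0.15, fails_frequency = 0.15,
  fails_panel = 0.10, fails_carrier_pattern = 0.15, fails_qc = 0.06,
  multiallelic_demo = 0.04)) {
  if (!setequal(names(fate_weights), ROSTER_FATES)) {
    stop("fate_weights must name exactly: ", paste(ROSTER_FATES, collapse = ", "))
  }
  if (any(fate_weights < 0) || abs(sum(fate_weights) - 1) > 1e-8) {
    stop("fate_weights must be non-negative and sum to 1")
  }
  list(fate_weights = fate_weights[ROSTER_FATES])
}

# Genotype triples (1-b, 2-a, 2-b) satisfying / violating the carrier rule.
CARRIER_OK_GT <- list(
  c("het", "homref", "homref"), c("homref", "het", "het"),
  c("het", "het", "het"), c("homref", "homalt", "homalt"),
  c("homalt", "homref", "homref"), c("het", "het", "homref")
)
CARRIER_FAIL_GT <- list(
  c("homref", "het", "homref"), c("homref", "homref", "het"),
  c("homref", "homalt", "homref"), c("homref", "missing", "het")
)
CONSEQ_OK <- list(
  c("exonic", "nonsynonymous_SNV"), c("exonic", "stopgain"),
  c("exonic", "stoploss"), c("exonic", "frameshift_indel"),
  c("splicing", "none"), c("UTR3", "none"), c("UTR5", "none")
)
CONSEQ_FAIL <- list(
  c("exonic", "synonymous_SNV"), c("intronic", "none"),
  c("intergenic", "none"), c("exonic", "unknown")
)
# Per-sample (allele-1 code, allele-2 code) combinations representable as one
# diploid genotype at a triallelic site.
MULTI_GT_COMBOS <- list(
  c("homref", "homref"), c("het", "homref"), c("homref", "het"),
  c("het", "het"), c("homalt", "homref"), c("homref", "homalt")
)

#' Generate a random roster with planted truth
#'
#' Every entry is assigned a fate label and its fields are drawn so that the
#' entry passes every candidate-cascade step except the one its fate names
#' (`survives_all` passes all; `multiallelic_demo` entries are emitted as
#' shared multi-ALT records and analyzed in the separate multiallelic
#' section). Reproducible: the same `(n, seed, config)` yields an identical
#' roster; a single integer seed drives one PRNG stream and global RNG state
#' is restored afterwards.
#'
#' @param n Number of roster entries (>= 1).
#' @param seed Integer seed.
#' @param config Mixture weights from [roster_config()].
#' @return A `roster` data.frame.
#' @export
generate_random_roster <- function(n, seed, config = roster_config()) {
  stopifnot(n >= 1)
  w <- config$fate_weights
  with_seed(seed, {
    fates <- sample(names(w), n, replace = TRUE, prob = w)
    multi_idx <- which(fates == "multiallelic_demo")
    if (length(multi_idx) %% 2L == 1L) {
      fates[multi_idx[length(multi_idx)]] <- "survives_all"
      multi_idx <- multi_idx[-length(multi_idx)]
    }
    pos <- sample.int(2e8, n)
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    bases <- c("A", "C", "G", "T")
    rows <- vector("list", n)
    i <- 1L
    while (i <= n) {
      fate <- fates[[i]]
      gene <- if (fate == "fails_panel") sprintf("DECOY%03d", i)
              else sample(CANDIDATE_PANEL, 1L)
      cls <- if (fate == "fails_consequence") sample(CONSEQ_FAIL, 1L)[[1L]]
             else sample(CONSEQ_OK, 1L)[[1L]]
      gt <- if (fate == "fails_carrier_pattern") sample(CARRIER_FAIL_GT, 1L)[[1L]]
            else sample(CARRIER_OK_GT, 1L)[[1L]]
      freq <- stats::setNames(stats::runif(length(FREQ_COLUMNS), 0, 0.0049),
                              FREQ_COLUMNS)
      freq <- freq[stats::runif(length(freq)) > 0.4]
      if (fate == "fails_frequency") {
        cell <- sample(c("freq_gnomad_wes_ALL", "freq_gnomad_wgs_ALL",
                         "freq_kg1000_ALL"), 1L)
        freq[cell] <- stats::runif(1L, 0.005, 0.5)
      }
      qd <- round(stats::runif(1L, 5, 60), 2)
      filt <- "PASS"
      if (fate == "fails_qc") {
        if (stats::runif(1L) < 0.5) qd <- round(stats::runif(1L, 0, 4.99), 2)
        else filt <- "VQSRTrancheSNP99.80to100.00"
      }
      ref <- sample(bases, 1L)
      if (fate == "multiallelic_demo") {
        # consume two consecutive multiallelic slots as one triallelic site
        j <- multi_idx[match(i, multi_idx) + 1L]
        alts <- sample(setdiff(bases, ref), 2L)
        combos <- sample(MULTI_GT_COMBOS, 3L, replace = TRUE)
        gt1 <- vapply(combos, `[[`, character(1), 1L)
        gt2 <- vapply(combos, `[[`, character(1), 2L)
        common <- list(chrom = chrom[[i]], pos = pos[[i]], ref = ref,
                       gene = gene, freq = freq, qd = qd)
        rows[[i]] <- roster_row(common$chrom, common$pos, common$ref, alts[[1L]],
                                common$gene, "multiallelic_demo",
                                region = cls[[1L]], exonic_function = cls[[2L]],
                                gt = gt1, freq = common$freq, qd = common$qd,
                                sift = round(stats::runif(1L), 3),
                                cadd = round(stats::runif(1L, 0, 40), 2),
                                n_alt = 2L, allele_index = 1L)
        rows[[j]] <- roster_row(common$chrom, common$pos, common$ref, alts[[2L]],
                                common$gene, "multiallelic_demo",
                                region = cls[[1L]], exonic_function = cls[[2L]],
                                gt = gt2, freq = common$freq, qd = common$qd,
                                sift = round(stats::runif(1L), 3),
                                cadd = round(stats::runif(1L, 0, 40), 2),
                                n_alt = 2L, allele_index = 2L)
        fates[[j]] <- "placed"
        i <- i + 1L
        while (i <= n && fates[[i]] == "placed") i <- i + 1L
        next
      }
      alt <- sample(setdiff(bases, ref), 1L)
      rows[[i]] <- roster_row(chrom[[i]], pos[[i]], ref, alt, gene, fate,
                              region = cls[[1L]], exonic_function = cls[[2L]],
                              gt = gt, freq = freq, qd = qd, filter = filt,
                              sift = round(stats::runif(1L), 3),
                              polyphen2 = round(stats::runif(1L), 3),
                              cadd = round(stats::runif(1L, 0, 40), 2),
                              gerp = round(stats::runif(1L, -2, 6), 2))
      i <- i + 1L
      while (i <= n && fates[[i]] == "placed") i <- i + 1L
    }
    as_roster(rows)
  })
}

#' Expected candidate-cascade membership of each roster entry
#'
#' Closed-form truth for the candidate-gene cascade: per entry, whether it
#' passes quality control, panel membership, the CANDIDATE consequence
#' classes, the overall-population frequency rule in all three databases,
#' and the carrier-pattern rule — and hence whether it survives the full
#' biallelic cascade (`multiallelic_demo` entries are routed to the separate
#' multiallelic section instead).
#'
#' @param roster A `roster`.
#' @param panel Candidate panel genes.
#' @param threshold Frequency threshold.
#' @param qd_min QC threshold.
#' @return Data.frame keyed by `key` with logical step columns and
#'   `survives`.
#' @export
roster_truth_table <- function(roster, panel = CANDIDATE_PANEL,
                               threshold = 0.005, qd_min = 5) {
  pass_qc <- (is.na(roster$qd) | roster$qd >= qd_min) &
    roster$filter_field == "PASS"
  in_panel <- toupper(roster$gene) %in% toupper(panel)
  tok <- consequence_token(roster$region_class, roster$exonic_function)
  pass_consequence <- !is.na(tok) & tok %in% consequence_preset("CANDIDATE")
  freq_all <- c("freq_gnomad_wes_ALL", "freq_gnomad_wgs_ALL")
  pass_gnomad <- rep(TRUE, nrow(roster))
  for (col in freq_all) {
    f <- roster[[col]]
    pass_gnomad <- pass_gnomad & (is.na(f) | f < threshold)
  }
  fkg <- roster$freq_kg1000_ALL
  pass_kg <- is.na(fkg) | fkg < threshold
  p <- roster[[gt_column("1-b")]]
  a <- roster[[gt_column("2-a")]]
  b <- roster[[gt_column("2-b")]]
  pass_carrier <- is_carrier(p) | (is_carrier(a) & is_carrier(b))
  multi <- roster$n_alt > 1L
  truth <- data.frame(
    key = roster$key, fate = roster$fate,
    pass_qc = pass_qc, in_panel = in_panel,
    pass_consequence = pass_consequence, pass_gnomad = pass_gnomad,
    pass_kg1000 = pass_kg, pass_carrier = pass_carrier,
    is_multiallelic = multi,
    survives = pass_qc & in_panel & pass_consequence & pass_gnomad &
      pass_kg & pass_carrier & !multi,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  truth
}

#' Fixture R1: the candidate-gene worked example
#'
#' Embeds the two published candidate-cascade survivors — the PLOD2
#' chr3:145799628T>A missense carried heterozygously by the proband 1-b, and
#' the TMEM25 chr11:118402939G>A missense shared heterozygously by both
#' sisters — verbatim (keys, genotypes, database frequencies, scores), among
#' twelve decoys that each violate exactly one candidate-cascade step: genes
#' off the panel, a synonymous and an intronic panel variant, panel variants
#' too frequent in gnomAD (WES or WGS) or only in 1000 Genomes, and panel
#' variants carried by a single sister.
#'
#' @return A `roster`.
#' @export
build_fixture_R1 <- function() {
  as_roster(list(
    roster_row("chr3", 145799628, "T", "A", "PLOD2", "survives_all",
               gt = c("het", "homref", "homref"),
               hgvs = "NM_182943:c.A1255T:p.Thr419Ser", dbsnp = "rs776654051",
               freq = c(freq_gnomad_wes_ALL = 3.99e-06,
                        freq_gnomad_wes_SAS = 0, freq_gnomad_wes_EAS = 5.44e-05),
               sift = 0.88, polyphen2 = 0.515, cadd = 10.78, gerp = 5.53),
    roster_row("chr11", 118402939, "G", "A", "TMEM25", "survives_all",
               gt = c("homref", "het", "het"),
               hgvs = "NM_032780:c.G145A:p.Ala49Thr", dbsnp = "rs782188288",
               freq = c(freq_gnomad_wes_ALL = 1.00e-04,
                        freq_gnomad_wes_SAS = 1.00e-04,
                        freq_gnomad_wes_EAS = 0.0013),
               sift = 0.55, polyphen2 = 0.209, cadd = 15.48, gerp = 3.26),
    # off-panel genes (fail step 1 only)
    roster_row("chr17", 27903000, "G", "A", "TRAF4", "fails_panel",
               gt = c("homref", "het", "het")),
    roster_row("chr3", 51422000, "C", "T", "MANF", "fails_panel",
               gt = c("het", "homref", "homref")),
    roster_row("chr2", 179431000, "T", "C", "TTN", "fails_panel",
               gt = c("homref", "het", "het")),
    # wrong consequence class (fail step 2 only)
    roster_row("chr17", 48262000, "C", "T", "COL1A1", "fails_consequence",
               region = "exonic", exonic_function = "synonymous_SNV",
               gt = c("het", "homref", "homref")),
    roster_row("chr11", 68171000, "G", "A", "LRP5", "fails_consequence",
               region = "intronic", exonic_function = "none",
               gt = c("homref", "het", "het")),
    # too frequent in gnomAD WES / WGS (fail step 3 only)
    roster_row("chr1", 21887000, "A", "G", "ALPL", "fails_frequency",
               gt = c("het", "homref", "homref"),
               freq = c(freq_gnomad_wes_ALL = 0.01)),
    roster_row("chr1", 150768000, "C", "G", "CTSK", "fails_frequency",
               gt = c("homref", "het", "het"),
               freq = c(freq_gnomad_wgs_ALL = 0.02)),
    # passing gnomAD but too frequent in 1000 Genomes (fail step 4 only)
    roster_row("chrX", 22050000, "G", "T", "PHEX", "fails_frequency",
               gt = c("het", "homref", "homref"),
               freq = c(freq_gnomad_wes_ALL = 1e-04, freq_kg1000_ALL = 0.01)),
    roster_row("chrX", 114795000, "A", "C", "PLS3", "fails_frequency",
               gt = c("homref", "het", "het"),
               freq = c(freq_gnomad_wgs_ALL = 2e-04, freq_kg1000_ALL = 0.008)),
    # carried by only one of the sisters (fail step 5 only)
    roster_row("chr7", 94027000, "G", "A", "COL1A2", "fails_carrier_pattern",
               gt = c("homref", "het", "homref")),
    roster_row("chr11", 75562000, "C", "T", "SERPINH1", "fails_carrier_pattern",
               gt = c("homref", "homref", "het")),
    roster_row("chr17", 39969000, "T", "G", "FKBP10", "fails_carrier_pattern",
               gt = c("homref", "homalt", "homref"))
  ))
}

#' Fixture R2: recessive and compound-heterozygous worked example
#'
#' Plants one rare missense shared homozygously by both sisters (MANF) and
#' het-het variant pairs in three genes (SYNPO2L, TTN, GSX2; both sisters
#' heterozygous at both sites of each pair), plus decoys: a gene whose two
#' heterozygous variants sit in one sister only, a gene with only one of two
#' variants shared, a too-frequent pair, a homozygote in a single sister,
#' and a synonymous shared homozygote.
#'
#' @return A `roster`.
#' @export
build_fixture_R2 <- function() {
  sis_het <- c("homref", "het", "het")
  as_roster(list(
    roster_row("chr3", 51422800, "G", "A", "MANF", "survives_all",
               gt = c("homref", "homalt", "homalt")),
    roster_row("chr10", 75604000, "G", "A", "SYNPO2L", "survives_all", gt = sis_het),
    roster_row("chr10", 75608000, "C", "T", "SYNPO2L", "survives_all", gt = sis_het),
    roster_row("chr2", 179440000, "A", "G", "TTN", "survives_all", gt = sis_het),
    roster_row("chr2", 179452000, "C", "A", "TTN", "survives_all", gt = sis_het),
    roster_row("chr4", 54966500, "G", "C", "GSX2", "survives_all", gt = sis_het),
    roster_row("chr4", 54967500, "T", "C", "GSX2", "survives_all", gt = sis_het),
    # both hets in one sister only: never a shared pair
    roster_row("chr15", 63569000, "C", "T", "APH1B", "fails_carrier_pattern",
               gt = c("homref", "het", "homref")),
    roster_row("chr15", 63571000, "G", "A", "APH1B", "fails_carrier_pattern",
               gt = c("homref", "het", "homref")),
    # only one of the two variants shared by both sisters
    roster_row("chr10", 108332000, "A", "G", "SORCS1", "survives_all", gt = sis_het),
    roster_row("chr10", 108336000, "C", "T", "SORCS1", "fails_carrier_pattern",
               gt = c("homref", "homref", "het")),
    # pair removed by the frequency rule (East Asian stratum)
    roster_row("chr1", 38180000, "G", "A", "EPHA10", "fails_frequency",
               gt = sis_het, freq = c(freq_gnomad_wes_EAS = 0.01)),
    roster_row("chr1", 38184000, "C", "T", "EPHA10", "fails_frequency",
               gt = sis_het, freq = c(freq_gnomad_wes_EAS = 0.02)),
    # homozygous in one sister only
    roster_row("chr9", 131740000, "C", "G", "PHYHD1", "survives_all",
               gt = c("homref", "homalt", "het")),
    # synonymous shared homozygote: removed by the consequence filter
    roster_row("chr8", 86376000, "T", "C", "CA2", "fails_consequence",
               region = "exonic", exonic_function = "synonymous_SNV",
               gt = c("homref", "homalt", "homalt"))
  ))
}

#' Fixture R3: cross-family gene-overlap worked example
#'
#' Plants rare shared-heterozygous variants of the sister pair across seven
#' genes. The proband 1-b carries a *different* qualifying variant in
#' exactly four of them (TTN, FAN1, ANKS3, IL2RG), the identical variant key
#' in one further gene (EPHA10, which must be excluded: same variant, not a
#' different one), and no variant in the remaining genes. One additional
#' shared variant fails the frequency rule.
#'
#' @return A `roster`.
#' @export
build_fixture_R3 <- function() {
  sis_het <- c("homref", "het", "het")
  pro_het <- c("het", "homref", "homref")
  as_roster(list(
    roster_row("chr2", 179460000, "G", "A", "TTN", "survives_all", gt = sis_het),
    roster_row("chr15", 31200000, "C", "T", "FAN1", "survives_all", gt = sis_het),
    roster_row("chr16", 4751000, "G", "C", "ANKS3", "survives_all", gt = sis_het),
    roster_row("chrX", 70330000, "A", "G", "IL2RG", "survives_all", gt = sis_het),
    roster_row("chr10", 108340000, "T", "C", "SORCS1", "survives_all", gt = sis_het),
    roster_row("chr19", 18702000, "C", "A", "C19ORF60", "survives_all", gt = sis_het),
    # identical key carried by all three: excluded from the overlap
    roster_row("chr1", 38188000, "G", "T", "EPHA10", "survives_all",
               gt = c("het", "het", "het")),
    # proband's different variants in four of the shared genes
    roster_row("chr2", 179475000, "C", "T", "TTN", "survives_all", gt = pro_het),
    roster_row("chr15", 31214000, "G", "A", "FAN1", "survives_all", gt = pro_het),
    roster_row("chr16", 4756000, "A", "G", "ANKS3", "survives_all", gt = pro_het),
    roster_row("chrX", 70336000, "G", "C", "IL2RG", "survives_all", gt = pro_het),
    # shared variant dropped by the frequency rule
    roster_row("chr9", 131744000, "A", "G", "PHYHD1", "fails_frequency",
               gt = sis_het, freq = c(freq_gnomad_wes_ALL = 0.01))
  ))
}

# Diploid GT string for a genotype code relative to ALT allele k.
code_to_gt <- function(code, k) {
  switch(code,
    homref = "0/0",
    het = paste0("0/", k),
    homalt = paste0(k, "/", k),
    missing = "./.",
    stop("unknown genotype code: ", code)
  )
}

# Joint GT string for one sample at a 2-ALT site from its per-allele codes.
combine_multi_gt <- function(code1, code2) {
  pair <- paste(code1, code2)
  switch(pair,
    "homref homref" = "0/0",
    "het homref" = "0/1",
    "homref het" = "0/2",
    "het het" = "1/2",
    "homalt homref" = "1/1",
    "homref homalt" = "2/2",
    "missing missing" = "./.",
    stop("per-allele genotype codes '", pair,
         "' are not representable as one diploid genotype")
  )
}

fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))

#' Emit a roster as an on-disk dataset
#'
#' Writes four files under `dir`: `<prefix>.vcf` (VCF v4.2, multi-ALT
#' records for multiallelic entries), `<prefix>.annotations.tsv` (one row
#' per biallelic key, default column headers), `<prefix>.cohort.tsv` and
#' `<prefix>.truth.tsv` ([roster_truth_table()] output). Reading the files
#' back with [load_dataset()] reconstructs the roster exactly.
#'
#' @param roster A `roster`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"dataset"`).
#' @return Named list of file paths, invisibly.
#' @export
emit_roster <- function(roster, dir, prefix = "dataset") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  roster <- roster[order(chrom_rank(roster$chrom), roster$pos, roster$ref,
                         roster$allele_index), , drop = FALSE]
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    annotations = file.path(dir, paste0(prefix, ".annotations.tsv")),
    cohort = file.path(dir, paste0(prefix, ".cohort.tsv")),
    truth = file.path(dir, paste0(prefix, ".truth.tsv"))
  )

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varcascade synthetic generator",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by Depth">',
    '##FILTER=<ID=PASS,Description="All filters passed">',
    '##FILTER=<ID=VQSRTrancheSNP99.80to100.00,Description="Upstream VQSR tranche">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", SYNTH_SAMPLES), collapse = "\t")
  )
  body <- character(0)
  for (site in unique(roster$site_id)) {
    ent <- roster[roster$site_id == site, , drop = FALSE]
    ent <- ent[order(ent$allele_index), , drop = FALSE]
    first <- ent[1L, ]
    if (nrow(ent) == 1L) {
      gts <- vapply(SYNTH_SAMPLES, function(s)
        code_to_gt(first[[gt_column(s)]], 1L), character(1))
      alt <- first$alt
    } else {
      gts <- vapply(SYNTH_SAMPLES, function(s)
        combine_multi_gt(ent[[gt_column(s)]][1L], ent[[gt_column(s)]][2L]),
        character(1))
      alt <- paste(ent$alt, collapse = ",")
    }
    info <- if (is.na(first$qd)) "." else paste0("QD=", fmt_num(first$qd))
    body <- c(body, paste(c(first$chrom, first$pos, first$dbsnp, first$ref,
                            alt, ".", first$filter_field, info, "GT", gts),
                          collapse = "\t"))
  }
  writeLines(c(header, body), paths$vcf)

  cols <- annotation_columns()
  ann <- data.frame(
    Chr = roster$chrom, Start = roster$pos, Ref = roster$ref,
    Alt = roster$alt, Gene = roster$gene, Func = roster$region_class,
    ExonicFunc = ifelse(roster$exonic_function == "none", ".",
                        roster$exonic_function),
    AAChange = roster$hgvs, dbSNP = roster$dbsnp,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (field in names(cols$freq)) ann[[cols$freq[[field]]]] <- fmt_num(roster[[field]])
  for (field in names(cols$scores)) ann[[cols$scores[[field]]]] <- fmt_num(roster[[field]])
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cohort <- synthetic_cohort()
  utils::write.table(
    data.frame(sample_id = cohort$sample_id, family_id = cohort$family_id,
               affected = as.integer(cohort$affected)),
    paths$cohort, sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(roster_truth_table(roster), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
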