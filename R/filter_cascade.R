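# Consequence-class, population-frequency and candidate-panel filters, and
# their composition into auditable cascades with per-step survivor counts.

CONSEQUENCE_TOKENS <- c("UTR5", "UTR3", "exonic_nonsynonymous", "splicing",
                        "stopgain", "stoploss", "exonic_indel")

#' Consequence-class presets
#'
#' `CANDIDATE` retains UTR, exonic nonsynonymous, splicing, stopgain,
#' stoploss and exonic indel variants (the candidate-gene cascade).
#' `UNBIASED` is identical but excludes the untranslated regions (the
#' dominant/recessive cascades). Synonymous and intronic variants are never
#' retained by either preset.
#'
#' @param name `"CANDIDATE"` or `"UNBIASED"`.
#' @return Character vector of allowed consequence tokens.
#' @export
consequence_preset <- function(name = c("CANDIDATE", "UNBIASED")) {
  name <- match.arg(name)
  if (name == "CANDIDATE") CONSEQUENCE_TOKENS
  else setdiff(CONSEQUENCE_TOKENS, c("UTR5", "UTR3"))
}

# Map (region_class, exonic_function) to a consequence token, or NA when the
# combination belongs to no retainable class (synonymous, intronic, ...).
consequence_token <- function(region_class, exonic_function) {
  tok <- rep(NA_character_, length(region_class))
  tok[region_class == "splicing"] <- "splicing"
  tok[region_class == "UTR5"] <- "UTR5"
  tok[region_class == "UTR3"] <- "UTR3"
  ex <- region_class == "exonic"
  tok[ex & exonic_function == "nonsynonymous_SNV"] <- "exonic_nonsynonymous"
  tok[ex & exonic_function == "stopgain"] <- "stopgain"
  tok[ex & exonic_function == "stoploss"] <- "stoploss"
  tok[ex & exonic_function %in% c("frameshift_indel", "nonframeshift_indel")] <-
    "exonic_indel"
  tok
}

#' Filter variants by consequence class
#'
#' @param variants Annotated variant table.
#' @param classes Allowed consequence tokens, usually from
#'   [consequence_preset()].
#' @return Variants whose (region class, exonic function) maps into an
#'   allowed class. An unrecognized region class raises a warning and the
#'   variant is excluded.
#' @export
consequence_filter <- function(variants,
                               classes = consequence_preset("CANDIDATE")) {
  known <- c("exonic", "splicing", "UTR5", "UTR3", "intronic", "intergenic",
             "other")
  unknown <- !variants$region_class %in% known
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) with unrecognized region class excluded")
  }
  tok <- consequence_token(variants$region_class, variants$exonic_function)
  out <- variants[!unknown & !is.na(tok) & tok %in% classes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population-frequency rule
#'
#' A variant passes the rule iff for *every* (database, population) cell in
#' scope its frequency is `< threshold`, or the cell is missing and
#' `missing_passes` is set ("not present in the database"). Missingness is
#' explicit: a missing cell never compares as below the threshold.
#'
#' @param threshold Frequency cut-off in (0, 1]; default 0.005.
#' @param databases Subset of `gnomad_wes`, `gnomad_wgs`, `kg1000`.
#' @param populations Population strata to check (e.g. `"ALL"`, `"EAS"`).
#' @param missing_passes Whether an absent frequency passes (default TRUE).
#' @return An object of class `frequency_rule`.
#' @export
frequency_rule <- function(threshold = 0.005, databases = FREQ_DATABASES,
                           populations = "ALL", missing_passes = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  databases <- match.arg(databases, FREQ_DATABASES, several.ok = TRUE)
  structure(list(threshold = threshold, databases = databases,
                 populations = populations, missing_passes = missing_passes),
            class = "frequency_rule")
}

#' Filter variants by population allele frequency
#'
#' @param variants Annotated variant table with `freq_<database>_<population>`
#'   columns.
#' @param rule A [frequency_rule()]. A frequency column absent from the table
#'   counts as missing for every variant.
#' @return Variants passing the rule in every cell in scope. A frequency
#'   outside [0, 1] is a fatal data error.
#' @export
frequency_filter <- function(variants, rule = frequency_rule()) {
  stopifnot(inherits(rule, "frequency_rule"))
  cells <- as.vector(outer(rule$databases, rule$populations,
                           function(d, p) paste("freq", d, p, sep = "_")))
  pass <- rep(TRUE, nrow(variants))
  for (col in cells) {
    f <- if (col %in% names(variants)) variants[[col]] else rep(NA_real_, nrow(variants))
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop("frequency outside [0,1] in column '", col, "'")
    }
    cell_ok <- ifelse(is.na(f), rule$missing_passes, f < rule$threshold)
    pass <- pass & cell_ok
  }
  out <- variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a candidate-gene panel file
#'
#' One gene symbol per line; blank lines and `#` comments ignored. The
#' package ships a default panel of genes from monogenic bone disorders in
#' which atypical femur fractures have been reported
#' (`system.file("extdata", "candidate_panel.txt", package = "varcascade")`).
#'
#' @param path Panel file path.
#' @return Upper-cased character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("candidate panel file is empty: ", path)
  unique(toupper(lines))
}

#' Restrict variants to a candidate-gene panel
#'
#' Exact symbol match after upper-casing; no alias resolution.
#'
#' @param variants Annotated variant table.
#' @param panel Non-empty character vector of gene symbols.
#' @return Variants whose gene is in the panel.
#' @export
candidate_gene_filter <- function(variants, panel) {
  if (length(panel) == 0L) stop("candidate gene panel must be non-empty")
  out <- variants[toupper(variants$gene) %in% toupper(panel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run an ordered filter cascade
#'
#' Applies filters in order, recording the step label and surviving count at
#' each stage; the report's first row is the input size, and counts are
#' non-increasing along the cascade.
#'
#' @param variants Input variant table.
#' @param steps Named list of functions, each mapping a variant table to a
#'   filtered variant table; names are the step labels.
#' @return List of class `cascade_result` with `variants` (final survivors)
#'   and `report` (a `cascade_report` data.frame of step/count rows).
#' @export
run_cascade <- function(variants, steps) {
  if (!length(steps)) stop("cascade needs at least one step")
  if (is.null(names(steps)) || any(!nzchar(names(steps)))) {
    stop("every cascade step must be labelled")
  }
  labels <- "Total number of variants"
  counts <- nrow(variants)
  current <- variants
  for (nm in names(steps)) {
    current <- steps[[nm]](current)
    labels <- c(labels, nm)
    counts <- c(counts, nrow(current))
  }
  report <- data.frame(step = labels, count = as.integer(counts),
                       stringsAsFactors = FALSE)
  class(report) <- c("cascade_report", "data.frame")
  structure(list(variants = current, report = report),
            class = "cascade_result")
}

#' @export
print.cascade_report <- function(x, ...) {
  w <- max(nchar(x$step))
  cat(sprintf(paste0("%-", w, "s  %s\n"), "Filtering step", "n"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(paste0("%-", w, "s  %s\n"), x$step[i],
                format(x$count[i], big.mark = ",")))
  }
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write a cascade report as TSV
#'
#' @param report A `cascade_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cascade_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Candidate-gene cascade
#'
#' The candidate-gene discovery cascade over annotated biallelic variants:
#' (1) panel membership, (2) consequence classes including UTR (preset
#' `CANDIDATE`), (3) gnomAD WES+WGS overall frequency < threshold, (4) 1000
#' Genomes overall frequency < threshold, (5) carrier-pattern rule — keep
#' variants carried by the family-1 proband and/or by both affected sisters,
#' dropping variants carried by only one sister.
#'
#' @param variants Annotated variant table.
#' @param panel Candidate gene symbols.
#' @param threshold Frequency threshold (default 0.005).
#' @param proband Family-1 proband sample id.
#' @param pair Family-2 affected pair sample ids (length 2).
#' @return A `cascade_result`.
#' @export
candidate_cascade <- function(variants, panel, threshold = 0.005,
                              proband = "1-b", pair = c("2-a", "2-b")) {
  steps <- list(
    "All variants in candidate genes" = function(v)
      candidate_gene_filter(v, panel),
    "Selecting UTR, exonic nonsynonymous + splice variants (excluding intronic + exonic synonymous)" = function(v)
      consequence_filter(v, consequence_preset("CANDIDATE")),
    "Variants with gnomAD WES and WGS frequency below threshold" = function(v)
      frequency_filter(v, frequency_rule(threshold,
                                         c("gnomad_wes", "gnomad_wgs"), "ALL")),
    "Additional filtering with 1000 Genomes frequency below threshold" = function(v)
      frequency_filter(v, frequency_rule(threshold, "kg1000", "ALL")),
    "Filtering out variants only carried by one of the affected sisters" = function(v)
      carrier_pattern_filter(v, proband = proband, pair = pair)
  )
  run_cascade(variants, steps)
}

# Shared consequence + frequency prefilter of the unbiased (inheritance-model)
# cascades: no panel, no UTR, and frequency checked in the overall and East
# Asian strata of all three databases.
unbiased_prefilter_steps <- function(threshold = 0.005) {
  list(
    "Selecting exonic nonsynonymous + splice variants (excluding intronic + exonic synonymous)" = function(v)
      consequence_filter(v, consequence_preset("UNBIASED")),
    "Variants with gnomAD WES and WGS overall population frequency below threshold" = function(v)
      frequency_filter(v, frequency_rule(threshold,
                                         c("gnomad_wes", "gnomad_wgs"), "ALL")),
    "Additional filtering with 1000 Genomes frequency below threshold" = function(v)
      frequency_filter(v, frequency_rule(threshold, "kg1000", "ALL")),
    "Variants with gnomAD WES and WGS and 1000 Genomes East Asian subpopulation frequency below threshold" = function(v)
      frequency_filter(v, frequency_rule(threshold, FREQ_DATABASES, "EAS"))
  )
}

#' Dominant-inheritance cascade
#'
#' Unbiased consequence + frequency prefilter followed by the dominant model:
#' both members of the affected pair heterozygous, irrespective of the
#' proband's genotype.
#'
#' @inheritParams candidate_cascade
#' @return A `cascade_result`.
#' @export
dominant_cascade <- function(variants, threshold = 0.005,
                             pair = c("2-a", "2-b")) {
  steps <- c(
    unbiased_prefilter_steps(threshold),
    list("Variants heterozygous in both affected sisters" = function(v)
      dominant_model(v, pair = pair))
  )
  run_cascade(variants, steps)
}

#' Recessive-inheritance cascade
#'
#' Unbiased prefilter followed by the recessive-homozygous model (both pair
#' members homozygous for the alternate allele). Compound-heterozygous pairs
#' are detected on the prefiltered set and returned alongside.
#'
#' @inheritParams candidate_cascade
#' @return A `cascade_result` whose `variants` are the shared-homozygous
#'   survivors, with an extra `compound_het` element (see [compound_het()]).
#' @export
recessive_cascade <- function(variants, threshold = 0.005,
                              pair = c("2-a", "2-b")) {
  pre <- run_cascade(variants, unbiased_prefilter_steps(threshold))
  hom <- recessive_hom(pre$variants, pair = pair)
  report <- rbind(
    pre$report,
    data.frame(step = "Variants homozygous in both affected sisters",
               count = nrow(hom), stringsAsFactors = FALSE)
  )
  class(report) <- c("cascade_report", "data.frame")
  structure(list(variants = hom, report = report,
                 compound_het = compound_het(pre$variants, pair = pair)),
            class = "cascade_result")
}
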