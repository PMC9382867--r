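# Internal helpers shared across modules.

GT_CODES <- c("homref", "het", "homalt", "missing")
FREQ_DATABASES <- c("gnomad_wes", "gnomad_wgs", "kg1000")
FREQ_COLUMNS <- c(
  "freq_gnomad_wes_ALL", "freq_gnomad_wes_SAS", "freq_gnomad_wes_EAS",
  "freq_gnomad_wgs_ALL", "freq_gnomad_wgs_EAS",
  "freq_kg1000_ALL", "freq_kg1000_EAS"
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical variant key
#'
#' Builds the `chrom:posref>alt` identifier used to key variants after
#' multiallelic decomposition, e.g. `"chr3:145799628T>A"`.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref Reference allele(s).
#' @param alt Alternate allele(s).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ref, ">", alt)
}

#' Allele frequency from allele counts
#'
#' @param ac Alternate allele count (observations of the allele).
#' @param an Total number of alleles genotyped.
#' @return `ac / an`.
#' @examples
#' round(allele_frequency(1, 250756), 6)  # 4e-06
#' @export
allele_frequency <- function(ac, an) {
  if (any(an <= 0)) stop("allele number 'an' must be positive")
  if (any(ac < 0) || any(ac > an)) stop("allele count 'ac' must lie in [0, an]")
  ac / an
}

# Normalize chromosome names to a consistent style.
normalize_chrom <- function(x, style = c("chr", "plain", "keep")) {
  style <- match.arg(style)
  if (style == "keep") return(x)
  bare <- sub("^chr", "", x)
  if (style == "chr") paste0("chr", bare) else bare
}

# Numeric chromosome rank for deterministic sorting (chr1..22, X, Y, MT, rest).
chrom_rank <- function(chrom) {
  bare <- sub("^chr", "", chrom)
  r <- suppressWarnings(as.numeric(bare))
  r[bare == "X"] <- 23
  r[bare == "Y"] <- 24
  r[bare %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26
  r
}

# Deterministic variant-table ordering: chrom, pos, ref, alt.
order_variants <- function(df) {
  df[order(chrom_rank(df$chrom), df$pos, df$ref, df$alt), , drop = FALSE]
}

gt_column <- function(sample_id) paste0("gt_", sample_id)

# Fetch one sample's genotype-code column, failing loudly if absent.
sample_codes <- function(variants, sample_id) {
  col <- gt_column(sample_id)
  if (!col %in% names(variants)) {
    stop("no genotype column for sample '", sample_id, "' in variant table")
  }
  variants[[col]]
}

is_carrier <- function(code) code %in% c("het", "homalt")

# Evaluate code while temporarily seeding R's RNG, restoring prior state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
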