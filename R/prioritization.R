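# Damage-class prioritization, gene-set (pathway) intersection with
# gene-family expansion, and CADD phred-to-percentile conversion.

#' Partition variants by predicted damage
#'
#' Splits a variant table into a `TRUNCATING` subset (stopgain, stoploss or
#' frameshift indel; splicing variants count only when
#' `splicing_as_truncating` is set, since truncation through splice
#' disruption is not certain) and a `HIGH_CADD` subset (phred-scaled CADD
#' strictly greater than `cadd_min`). The subsets may overlap; their union
#' is returned as well.
#'
#' @param variants Annotated, scored variant table.
#' @param cadd_min CADD phred cut-off (default 30; strict `>`).
#' @param splicing_as_truncating Count splicing variants as truncating.
#' @return List of class `damage_partition` with elements `truncating`,
#'   `high_cadd`, `union`.
#' @export
prioritize_damaging <- function(variants, cadd_min = 30,
                                splicing_as_truncating = FALSE) {
  trunc <- variants$exonic_function %in% c("stopgain", "stoploss",
                                           "frameshift_indel")
  if (splicing_as_truncating) trunc <- trunc | variants$region_class == "splicing"
  high <- !is.na(variants$cadd_phred) & variants$cadd_phred > cadd_min
  res <- list(
    truncating = variants[trunc, , drop = FALSE],
    high_cadd = variants[high, , drop = FALSE],
    union = variants[trunc | high, , drop = FALSE]
  )
  res <- lapply(res, function(d) { rownames(d) <- NULL; d })
  structure(res, class = "damage_partition")
}

#' @export
print.damage_partition <- function(x, ...) {
  cat("Damage partition:", nrow(x$truncating), "truncating,",
      nrow(x$high_cadd), "high-CADD,", nrow(x$union), "in union\n")
  invisible(x)
}

#' Read gene sets from a GMT-like file
#'
#' Format: `set_id <TAB> name <TAB> gene1 <TAB> gene2 ...`, one set per
#' line. Symbols are upper-cased.
#'
#' @param path GMT file path.
#' @return List of gene sets, each a list with `set_id`, `name`, `genes`.
#'   An empty file or a set without genes is a fatal error.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gene-set file is empty: ", path)
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("gene set '", parts[1L], "' has no genes")
    list(set_id = parts[1L], name = parts[2L],
         genes = unique(toupper(parts[-(1:2)])))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  sets
}

#' Read a gene-family map
#'
#' Two-column TSV (`gene`, `family`), headered. Each gene may belong to at
#' most one family.
#'
#' @param path Family-map file path.
#' @return Named character vector: family keyed by upper-cased gene symbol.
#' @export
read_family_map <- function(path) {
  if (!file.exists(path)) stop("family-map file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("family map needs two columns (gene, family)")
  genes <- toupper(trimws(tab[[1L]]))
  if (anyDuplicated(genes)) {
    stop("gene '", genes[duplicated(genes)][1L], "' mapped to more than one family")
  }
  stats::setNames(as.character(tab[[2L]]), genes)
}

#' Intersect a gene list with pathway gene sets
#'
#' For each gene set, reports the direct intersection with the input genes.
#' When a family map is supplied, additionally reports input genes whose
#' gene family contains any pathway member — the route by which a variant in
#' one family member (e.g. TRAF4) is flagged through pathway membership of
#' its relatives (TRAF2/TRAF6). An optional prefix heuristic (off by
#' default) derives families by stripping trailing digits from symbols.
#'
#' @param genes Character vector of gene symbols.
#' @param genesets List of gene sets from [read_gmt()].
#' @param family_map Optional named vector from [read_family_map()].
#' @param prefix_heuristic Derive a family map from symbol prefixes
#'   (opt-in).
#' @return Data.frame of class `pathway_hits`: one row per gene set with
#'   `set_id`, `name`, `n_set`, and list-columns `direct_hits`,
#'   `family_hits` (family hits exclude genes already hit directly).
#' @export
pathway_intersect <- function(genes, genesets, family_map = NULL,
                              prefix_heuristic = FALSE) {
  if (!length(genesets)) stop("no gene sets supplied")
  genes <- unique(toupper(genes))
  if (prefix_heuristic && is.null(family_map)) {
    all_sym <- unique(c(genes, unlist(lapply(genesets, `[[`, "genes"))))
    family_map <- stats::setNames(sub("[0-9]+$", "", all_sym), all_sym)
  }
  rows <- lapply(genesets, function(gs) {
    direct <- sort(intersect(genes, gs$genes))
    fam <- character(0)
    if (!is.null(family_map)) {
      set_fams <- unique(stats::na.omit(unname(family_map[gs$genes])))
      in_fam <- !is.na(family_map[genes]) & family_map[genes] %in% set_fams
      fam <- sort(setdiff(genes[in_fam], direct))
    }
    data.frame(set_id = gs$set_id, name = gs$name,
               n_set = length(gs$genes),
               direct_hits = I(list(direct)), family_hits = I(list(fam)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pathway_hits", "data.frame")
  out
}

#' @export
print.pathway_hits <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(x$set_id[i], " (", x$name[i], ", ", x$n_set[i], " genes): ", sep = "")
    d <- x$direct_hits[[i]]; f <- x$family_hits[[i]]
    cat(if (length(d)) paste("direct:", paste(d, collapse = ", ")) else "no direct hits")
    if (length(f)) cat("; family-level:", paste(f, collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' CADD phred score to deleteriousness percentile
#'
#' A phred-scaled CADD score `s` places a substitution within the
#' `100 * 10^(-s/10)` percent most deleterious substitutions: a score of 10
#' means the top 10%, 15 about the top 3%, and 0 the whole range (100%).
#' Strictly decreasing in the score.
#'
#' @param score Non-negative phred-scaled CADD score(s).
#' @return Percent of substitutions at least as deleterious, in (0, 100].
#' @examples
#' cadd_percentile(10)  # 10
#' round(cadd_percentile(15))  # 3
#' @export
cadd_percentile <- function(score) {
  if (any(is.na(score)) || any(score < 0)) {
    stop("CADD phred score must be non-negative")
  }
  100 * 10^(-score / 10)
}
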