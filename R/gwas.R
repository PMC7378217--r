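#' Split a MAPPED_GENE string into gene symbols
#'
#' GWAS-catalog `MAPPED_GENE` entries may list several symbols joined by
#' commas and/or hyphens (intergenic variants are reported as
#' `"GENE1 - GENE2"`). The extraction rule splits on both separators, trims
#' whitespace, drops empty tokens and deduplicates preserving first
#' occurrence. Note that the hyphen rule also breaks genuinely hyphenated
#' symbols; token counts are retained in the catalog for auditing.
#'
#' @param raw a single `MAPPED_GENE` string (possibly empty or `NA`).
#' @return character vector of unique gene symbols (possibly empty).
#' @export
extract_mapped_genes <- function(raw) {
  if (length(raw) != 1L) stop("extract_mapped_genes takes a single string",
                              call. = FALSE)
  if (is.na(raw) || !nzchar(raw)) return(character(0L))
  tokens <- trimws(strsplit(raw, "[,-]")[[1L]])
  unique(tokens[nzchar(tokens)])
}

#' Parse a GWAS-catalog export
#'
#' Reads a tab-separated GWAS-catalog download, extracts the mapped gene
#' symbols of every row with [extract_mapped_genes()], and builds the
#' deduplicated index of all genes mapped anywhere in the catalog.
#'
#' @param path TSV file path.
#' @param trait_filter optional exact trait label(s); only matching rows are
#'   kept.
#' @param mapped_col name of the mapped-gene column (GWAS-catalog dialect:
#'   `MAPPED_GENE`).
#' @param trait_col name of the trait column (`DISEASE/TRAIT`).
#' @return object of class `gwas_catalog`: list with `records` (data.frame
#'   incl. `trait`, `mapped_gene_raw`, `n_tokens`), `genes_by_row` (list of
#'   parsed symbol vectors) and `unique_genes` (deduplicated index).
#' @export
parse_catalog <- function(path, trait_filter = NULL,
                          mapped_col = "MAPPED_GENE",
                          trait_col = "DISEASE/TRAIT") {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  if (!mapped_col %in% names(tab)) {
    stop("no '", mapped_col, "' column; available columns: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  trait <- if (trait_col %in% names(tab)) tab[[trait_col]] else
    rep(NA_character_, nrow(tab))
  if (!is.null(trait_filter)) {
    keep <- trait %in% trait_filter
    tab <- tab[keep, , drop = FALSE]
    trait <- trait[keep]
  }
  genes_by_row <- lapply(tab[[mapped_col]], extract_mapped_genes)
  records <- data.frame(
    trait = trait,
    mapped_gene_raw = if (nrow(tab)) tab[[mapped_col]] else character(0L),
    n_tokens = vapply(genes_by_row, length, integer(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(
    records = records,
    genes_by_row = genes_by_row,
    unique_genes = unique(unlist(genes_by_row, use.names = FALSE))
  ), class = "gwas_catalog")
}

#' @export
print.gwas_catalog <- function(x, ...) {
  cat("GWAS catalog: ", nrow(x$records), " records, ",
      length(x$unique_genes), " unique mapped genes\n", sep = "")
  invisible(x)
}

#' Permutation enrichment of one GWAS's targets in a gene set
#'
#' Counts how many members of the gene set appear among the mapped targets
#' of a single GWAS, and compares against matched-size random gene draws
#' (statistic `overlap_count`, see [permutation_test()]). `p_high` small
#' means the set contains more GWAS targets than random genes.
#'
#' @param gene_set character vector of gene ids, subset of `universe`.
#' @param targets character vector of mapped genes for one GWAS.
#' @param universe character vector of all tested gene ids.
#' @param n_perm,seed,smoothing passed to [permutation_test()].
#' @return list with `result` (a `permutation_result`) and
#'   `overlapping_genes` (the set members that are GWAS targets).
#' @export
gwas_overlap_enrichment <- function(gene_set, targets, universe,
                                    n_perm = 10000L, seed = 1L,
                                    smoothing = FALSE) {
  res <- permutation_test(gene_set, universe, membership = targets,
                          statistic_kind = "overlap_count",
                          n_perm = n_perm, seed = seed, smoothing = smoothing)
  list(result = res,
       overlapping_genes = intersect(gene_set, unique(targets)))
}

#' Permutation enrichment of whole-catalog membership in a gene set
#'
#' Statistic: number of set members mapped by any variant in the catalog
#' (the catalog's unique-gene index). Both one-sided p-values are reported:
#' `p_high` small means the set is mapped more often than random genes,
#' `p_low` small means less often.
#'
#' @param gene_set character vector of gene ids, subset of `universe`.
#' @param catalog a `gwas_catalog` from [parse_catalog()].
#' @param universe character vector of all tested gene ids.
#' @param n_perm,seed,smoothing passed to [permutation_test()].
#' @return a `permutation_result`.
#' @export
catalog_membership_enrichment <- function(gene_set, catalog, universe,
                                          n_perm = 10000L, seed = 1L,
                                          smoothing = FALSE) {
  if (!inherits(catalog, "gwas_catalog")) {
    stop("catalog must come from parse_catalog()", call. = FALSE)
  }
  permutation_test(gene_set, universe, membership = catalog$unique_genes,
                   statistic_kind = "overlap_count",
                   n_perm = n_perm, seed = seed, smoothing = smoothing)
}
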