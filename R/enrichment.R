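#' Read a gene-set collection (GMT)
#'
#' Thin wrapper around [fgsea::gmtPathways()] returning a named list of
#' character vectors with duplicate members removed within each set.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write a gene-set collection (GMT)
#'
#' @param sets named list of gene-id character vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Upper-tail hypergeometric probability P(X >= k) with X ~ Hyper(N, m, q):
# k white draws in q draws from an urn with m white of N total.
hyper_upper_tail <- function(k, m, q, N) {
  stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set in the collection, the upper-tail hypergeometric probability
#' of observing at least the seen overlap between the query gene list and the
#' set, in a population of `N` genes (the analysis convention is
#' `N = 20000`). Adjusted p-values are Benjamini-Hochberg across the
#' collection; the gene ratio `k/q` is the fraction of the query found in the
#' set.
#'
#' @param query character vector of gene ids (the DE gene list).
#' @param collection named list of gene-id vectors (see [read_gmt()]).
#' @param N population (universe) size.
#' @return `data.frame` with `set`, `k`, `q`, `m`, `N`, `p`, `padj`,
#'   `gene_ratio`, ordered as the collection.
#' @export
hypergeom_enrich <- function(query, collection, N = 20000L) {
  query <- unique(query)
  q <- length(query)
  m <- vapply(collection, function(s) length(unique(s)), integer(1L))
  if (N < q || any(N < m)) {
    stop("universe size N (", N, ") smaller than a query or set size",
         call. = FALSE)
  }
  k <- vapply(collection, function(s) length(intersect(query, s)), integer(1L))
  p <- hyper_upper_tail(k, m, q, N)
  data.frame(
    set = names(collection) %||% as.character(seq_along(collection)),
    k = k, q = q, m = m, N = N,
    p = p,
    padj = bh_adjust(p),
    gene_ratio = ifelse(q > 0, k / q, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of drawing at least `|A` \eqn{\cap} `B|` members of
#' `A` when drawing `|B|` genes from the universe. Symmetric in `A` and `B`.
#' The universe is a required explicit argument: it should be the shared
#' tested-gene universe of the analysis, never an implicit default.
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all tested gene ids.
#' @return list with `k` (overlap size) and `p`.
#' @export
overlap_test <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(setA, setB))
  list(k = k,
       p = hyper_upper_tail(k, length(setA), length(setB), length(universe)))
}

# Two-sided Fisher exact p for a 2x2 table by the point-probability rule: the
# sum of the probabilities of all tables (same margins) no more probable than
# the observed one. The 1e-7 relative tolerance guards against ties lost to
# floating point, matching the convention of R's conditional exact test.
fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N)
  hi <- min(r1, c1)
  x <- lo:hi
  dens <- stats::dhyper(x, c1, N - c1, r1)
  min(1, sum(dens[dens <= dens[x == a] * (1 + 1e-7)]))
}

#' Sex-hormonal target content test
#'
#' Two-sided Fisher exact test of whether the acquired gene set is richer in
#' sex-hormonal targets (estrogen / androgen / progestin response genes) than
#' the intrinsic gene set. Rows of the 2x2 table are
#' `{acquired, intrinsic}`, columns `{hormonal, not}`.
#'
#' @param intrinsic,acquired disjoint character vectors of gene ids.
#' @param hormonal_genes character vector of gene ids flagged as sex-hormonal
#'   targets.
#' @return list with the 2x2 `table` and the two-sided `p`.
#' @export
hormonal_target_test <- function(intrinsic, acquired, hormonal_genes) {
  intrinsic <- unique(intrinsic); acquired <- unique(acquired)
  if (length(intersect(intrinsic, acquired))) {
    stop("intrinsic and acquired sets must be disjoint", call. = FALSE)
  }
  if (!length(acquired) || !length(intrinsic)) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  a <- sum(acquired %in% hormonal_genes)
  b <- length(acquired) - a
  c <- sum(intrinsic %in% hormonal_genes)
  d <- length(intrinsic) - c
  tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE,
                dimnames = list(set = c("acquired", "intrinsic"),
                                hormonal = c("hormonal", "not")))
  list(table = tab, p = fisher_two_sided(a, b, c, d))
}

#' Regulator content of a gene set
#'
#' Percentages of set members annotated as transcription factors and as
#' epigenetic modifiers, half-up rounded to one decimal (e.g. 15 TFs in a
#' 207-gene set = 7.2%).
#'
#' @param gene_set character vector of gene ids.
#' @param annotation gene annotation with `gene_id` and `regulator_class`
#'   (values `TF`, `epigenetic`, `none`).
#' @return list with `pct_tf` and `pct_epigenetic` (both 0 for an empty set).
#' @export
regulator_content <- function(gene_set, annotation) {
  idx <- match(unique(gene_set), annotation$gene_id)
  if (anyNA(idx)) stop("gene(s) missing from annotation", call. = FALSE)
  n <- length(idx)
  if (n == 0) return(list(pct_tf = 0, pct_epigenetic = 0))
  cls <- annotation$regulator_class[idx]
  list(pct_tf = round_half_up(100 * sum(cls == "TF") / n, 1L),
       pct_epigenetic = round_half_up(100 * sum(cls == "epigenetic") / n, 1L))
}
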