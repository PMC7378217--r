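#' Classify genes into intrinsic and acquired sex differences
#'
#' Combines the birth-stage (paired) and adult-stage (unpaired) DE tables on
#' their shared gene universe and applies the lifespan classification:
#'
#' * **intrinsic** — sex-biased at birth (`birth_fdr < birth_fdr` cutoff) and
#'   concordantly sex-biased in adults (`adult_p < adult_p` cutoff, same
#'   non-zero sign of the log2 fold change at both stages);
#' * **acquired** — no birth signal (`birth_p > acquired_birth_p_min`), adult
#'   sex bias (`adult_p < adult_p` cutoff) and an absolute adult log2 fold
#'   change strictly greater than the median absolute log2 fold change of all
#'   adult-significant genes (a stringency filter against marginal calls);
#' * **neither** — everything else.
#'
#' Direction (`female_higher` / `male_higher`) is taken from the sign of the
#' adult log2 fold change; unclassified genes have direction `none`. The two
#' classes are disjoint by construction, since `fdr >= p` implies a gene with
#' `birth_fdr` below the cutoff cannot also have `birth_p > 0.5`.
#'
#' @param birth,adult DE tables from [de_paired()] and [de_unpaired()].
#' @param thr a [threshold_config()].
#' @return `data.frame` with `gene_id`, `class`, `direction`, the carried
#'   `birth_lfc`, `birth_p`, `birth_fdr`, `adult_lfc`, `adult_p`, and an
#'   attribute `stringency_median` (the median |adult lfc| used by the filter).
#' @export
classify_genes <- function(birth, adult, thr = threshold_config()) {
  if (anyDuplicated(birth$gene_id) || anyDuplicated(adult$gene_id)) {
    stop("duplicate gene ids in a DE table", call. = FALSE)
  }
  shared <- intersect(birth$gene_id, adult$gene_id)
  if (!length(shared)) stop("empty shared gene universe", call. = FALSE)
  b <- birth[match(shared, birth$gene_id), ]
  a <- adult[match(shared, adult$gene_id), ]

  adult_sig <- a$p < thr$adult_p
  # stringency filter is undefined (and both classes empty) without any
  # adult-significant gene
  stringency <- if (any(adult_sig)) stats::median(abs(a$lfc[adult_sig])) else Inf

  intrinsic <- b$fdr < thr$birth_fdr & adult_sig &
    sign(b$lfc) == sign(a$lfc) & sign(a$lfc) != 0
  acquired <- b$p > thr$acquired_birth_p_min & adult_sig &
    abs(a$lfc) > stringency
  acquired <- acquired & !intrinsic  # analytically disjoint; belt and braces

  cls <- rep("neither", length(shared))
  cls[intrinsic] <- "intrinsic"
  cls[acquired] <- "acquired"
  dir <- rep("none", length(shared))
  dir[cls != "neither" & a$lfc > 0] <- "female_higher"
  dir[cls != "neither" & a$lfc < 0] <- "male_higher"

  out <- data.frame(
    gene_id = shared,
    class = cls,
    direction = dir,
    birth_lfc = b$lfc, birth_p = b$p, birth_fdr = b$fdr,
    adult_lfc = a$lfc, adult_p = a$p,
    stringsAsFactors = FALSE
  )
  attr(out, "stringency_median") <- stringency
  out
}

#' Direction-stratified class counts
#'
#' Counts genes per class split by direction of the sex difference, with
#' per-class totals (e.g. 124 female-higher + 144 male-higher = 268 intrinsic).
#'
#' @param classified output of [classify_genes()], or any data.frame with
#'   `class` and `direction` columns.
#' @return `data.frame` with columns `class`, `female_higher`, `male_higher`,
#'   `total`, one row per class (`intrinsic`, `acquired`).
#' @export
direction_counts <- function(classified) {
  classes <- c("intrinsic", "acquired")
  fh <- vapply(classes, function(cl) {
    sum(classified$class == cl & classified$direction == "female_higher")
  }, integer(1L))
  mh <- vapply(classes, function(cl) {
    sum(classified$class == cl & classified$direction == "male_higher")
  }, integer(1L))
  data.frame(class = classes, female_higher = fh, male_higher = mh,
             total = fh + mh, row.names = NULL, stringsAsFactors = FALSE)
}

#' Sex-chromosomal content of a gene set
#'
#' Number and percentage of genes on chrX or chrY, half-up rounded to one
#' decimal (e.g. 34 of 268 intrinsic genes = 12.7%).
#'
#' @param gene_set character vector of gene ids.
#' @param annotation gene annotation with `gene_id` and `chrom`.
#' @return list with `count` and `percent`.
#' @export
sex_chromosomal_fraction <- function(gene_set, annotation) {
  idx <- match(gene_set, annotation$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) missing from annotation: ",
         paste(utils::head(gene_set[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  count <- sum(annotation$chrom[idx] %in% c("chrX", "chrY"))
  pct <- if (length(gene_set)) round_half_up(100 * count / length(gene_set), 1L) else 0
  list(count = count, percent = pct)
}

#' Per-chromosome fractions of differentially expressed genes
#'
#' For each chromosome, the percentage of interrogated genes called
#' significant, split by direction (female-higher / male-higher), optionally
#' restricted to genes with `|lfc| > lfc_min` (the display filter used for
#' adult-stage per-chromosome summaries). Significance uses the stage-specific
#' rule carried in the DE table: `fdr < birth_fdr` for birth, `p < adult_p`
#' for adults.
#'
#' @param de a DE table from [de_paired()] or [de_unpaired()].
#' @param annotation gene annotation covering all tested genes.
#' @param thr a [threshold_config()].
#' @param lfc_min optional absolute log2 fold-change display filter.
#' @return `data.frame` with `chrom`, `n_interrogated`, `n_female_higher`,
#'   `n_male_higher`, `pct_female_higher`, `pct_male_higher`.
#' @export
chromosome_fractions <- function(de, annotation, thr = threshold_config(),
                                 lfc_min = NULL) {
  idx <- match(de$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("annotation does not cover all tested genes",
                       call. = FALSE)
  chrom <- annotation$chrom[idx]
  stage <- de$stage[1L]
  sig <- if (identical(stage, "birth")) de$fdr < thr$birth_fdr else de$p < thr$adult_p
  if (!is.null(lfc_min)) sig <- sig & abs(de$lfc) > lfc_min
  fh <- sig & de$lfc > 0
  mh <- sig & de$lfc < 0
  chroms <- unique(chrom)
  n_all <- vapply(chroms, function(c) sum(chrom == c), integer(1L))
  n_fh <- vapply(chroms, function(c) sum(fh & chrom == c), integer(1L))
  n_mh <- vapply(chroms, function(c) sum(mh & chrom == c), integer(1L))
  data.frame(
    chrom = chroms,
    n_interrogated = n_all,
    n_female_higher = n_fh,
    n_male_higher = n_mh,
    pct_female_higher = round_half_up(100 * n_fh / n_all, 1L),
    pct_male_higher = round_half_up(100 * n_mh / n_all, 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
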