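# Conservation summarization. All public coordinates are 0-based half-open
# (BED/bedGraph convention); conversion to the 1-based closed GRanges
# representation happens only at the package boundary.

#' Strand-aware promoter window around the TSS
#'
#' Returns the promoter interval `up` bases upstream to `down` bases
#' downstream of the transcription start site, in 0-based half-open
#' coordinates. For a `+` strand gene (TSS = `start`) this is
#' `[tss - up, tss + down)`; for a `-` strand gene (TSS = `end - 1`) the
#' mirror image `[tss - down + 1, tss + up + 1)`. The window length is always
#' `up + down`. Windows running below coordinate 0 are clipped with a warning.
#'
#' @param annotation gene annotation rows with `gene_id`, `chrom`, `strand`,
#'   `tss` columns.
#' @param up,down bases upstream/downstream of the TSS (non-negative).
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
promoter_window <- function(annotation, up = 200L, down = 100L) {
  stopifnot_scalar_number(up, "up", min = 0)
  stopifnot_scalar_number(down, "down", min = 0)
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - up, annotation$tss - down + 1)
  end <- ifelse(plus, annotation$tss + down, annotation$tss + up + 1)
  if (any(start < 0)) {
    warning(sum(start < 0), " promoter window(s) clipped at coordinate 0")
    start <- pmax(start, 0)
  }
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = start, end = pmax(end, start),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Read / write a bedGraph score track
#'
#' IO via rtracklayer; the returned data.frame is 0-based half-open with a
#' `score` column, one row per scored interval.
#'
#' @param path bedGraph file.
#' @return `data.frame` with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track score track data.frame (`chrom`, `start`, `end`, `score`,
#'   0-based half-open).
#' @export
write_bedgraph <- function(track, path) {
  gr <- intervals_to_granges(track)
  gr$score <- track$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Mean conservation score over genomic intervals
#'
#' Arithmetic mean of the per-base scores over all bases of each interval
#' that the track covers. Bases absent from the track are excluded from the
#' mean (bedGraph tracks are sparse); an interval with no covered base gets
#' `NA`.
#'
#' @param track score track data.frame (`chrom`, `start`, `end`, `score`,
#'   0-based half-open); overlapping track rows must not double-cover bases.
#' @param intervals data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [promoter_window()] or gene bodies.
#' @return named numeric vector of means, one per interval row (names =
#'   `gene_id`).
#' @export
summarize_scores <- function(track, intervals) {
  gr_track <- intervals_to_granges(track)
  gr_iv <- intervals_to_granges(intervals)
  hits <- GenomicRanges::findOverlaps(gr_iv, gr_track)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_width <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_iv)[qi], IRanges::ranges(gr_track)[si]))
  wsum <- rep(0, nrow(intervals))
  base_n <- rep(0, nrow(intervals))
  add <- tapply(ov_width * track$score[si], qi, sum)
  cnt <- tapply(ov_width, qi, sum)
  idx <- as.integer(names(add))
  wsum[idx] <- add
  base_n[idx] <- cnt
  means <- ifelse(base_n > 0, wsum / base_n, NA_real_)
  names(means) <- intervals$gene_id
  means
}

#' High / low conservation classes
#'
#' Dichotomizes per-gene mean scores at the median of a reference
#' distribution (typically the genome-wide per-gene means): `high` if
#' strictly above the reference median, `low` otherwise (ties are `low`).
#'
#' @param means named numeric vector of per-gene means.
#' @param reference numeric vector of means defining the split point.
#' @return character vector (`"high"`/`"low"`, `NA` for missing means),
#'   same names as `means`.
#' @export
classify_high_low <- function(means, reference) {
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("reference distribution is empty", call. = FALSE)
  cut_at <- stats::median(reference)
  out <- ifelse(is.na(means), NA_character_,
                ifelse(means > cut_at, "high", "low"))
  names(out) <- names(means)
  out
}

#' Full conservation summary for an annotation
#'
#' Convenience wrapper: promoter and gene-body means for every annotated gene
#' plus their high/low classes (median split against all genes).
#'
#' @param track score track data.frame.
#' @param annotation gene annotation (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`).
#' @param thr a [threshold_config()] supplying the promoter window extent.
#' @return `data.frame` with `gene_id`, `promoter_mean`, `genebody_mean`,
#'   `promoter_class`, `genebody_class`.
#' @export
conservation_summary <- function(track, annotation, thr = threshold_config()) {
  prom <- promoter_window(annotation, thr$promoter_up, thr$promoter_down)
  body <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                     start = annotation$start, end = annotation$end,
                     stringsAsFactors = FALSE)
  pm <- summarize_scores(track, prom)
  gm <- summarize_scores(track, body)
  data.frame(
    gene_id = annotation$gene_id,
    promoter_mean = unname(pm),
    genebody_mean = unname(gm),
    promoter_class = unname(classify_high_low(pm, pm)),
    genebody_class = unname(classify_high_low(gm, gm)),
    stringsAsFactors = FALSE
  )
}
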