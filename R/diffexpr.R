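#' Analysis thresholds
#'
#' Bundles the significance and reporting thresholds used throughout the
#' two-stage analysis: birth-stage FDR cutoff, adult-stage p cutoff, the
#' birth-stage "no signal" gate for the acquired class, the display log-fold
#' change filter for per-chromosome summaries, the gene universe size for
#' hypergeometric enrichment, the number of permutations, and the promoter
#' window extent around the TSS.
#'
#' @param birth_fdr FDR cutoff for birth-stage (paired) calls.
#' @param adult_p raw p cutoff for adult-stage (unpaired) calls.
#' @param acquired_birth_p_min minimum birth p for the acquired class gate.
#' @param display_lfc_min absolute log2 fold-change filter for display tables.
#' @param enrich_universe population size for hypergeometric enrichment.
#' @param n_perm number of random-gene permutations.
#' @param promoter_up,promoter_down promoter window, bases upstream/downstream
#'   of the TSS.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(birth_fdr = 0.1, adult_p = 0.05,
                             acquired_birth_p_min = 0.5,
                             display_lfc_min = 0.2,
                             enrich_universe = 20000L,
                             n_perm = 10000L,
                             promoter_up = 200L, promoter_down = 100L) {
  thr <- list(birth_fdr = birth_fdr, adult_p = adult_p,
              acquired_birth_p_min = acquired_birth_p_min,
              display_lfc_min = display_lfc_min,
              enrich_universe = enrich_universe,
              n_perm = n_perm,
              promoter_up = promoter_up, promoter_down = promoter_down)
  for (nm in names(thr)) stopifnot_scalar_number(thr[[nm]], nm, min = 0)
  if (!all(vapply(thr, function(x) x > 0, logical(1L))[
        c("birth_fdr", "adult_p", "acquired_birth_p_min")])) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (thr$acquired_birth_p_min <= thr$adult_p) {
    stop("acquired_birth_p_min must exceed adult_p", call. = FALSE)
  }
  structure(thr, class = "threshold_config")
}

#' Library-size normalization to log2 counts per million
#'
#' `log2(1e6 * (count + 0.5) / (library_size + 1))`, the usual pseudo-counted
#' CPM transform. The pseudo-count keeps zero counts finite; the +1 on the
#' library size keeps a hypothetical all-mass-in-one-gene sample finite too.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return numeric matrix of log2-CPM values, same dimnames.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  log2(sweep(counts + 0.5, 2L, (lib + 1) / 1e6, "/"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, preserving input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Shared per-gene linear-model engine. All genes share one design matrix, so a
# single QR factorization serves the whole matrix. Genes with (numerically)
# zero residual variance get the degenerate convention lfc = 0, p = 1, so no
# gene is ever dropped and gene universes stay aligned across stages.
fit_lm_de <- function(expr, design, coef, stage, mean_expr = NULL) {
  expr <- as.matrix(expr)
  fit <- stats::lm.fit(design, t(expr))
  if (fit$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  df_resid <- nrow(design) - fit$rank
  if (df_resid <= 0) {
    stop("no residual degrees of freedom in the design", call. = FALSE)
  }
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = ncol(design),
                                     dimnames = list(colnames(design), NULL))
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, nrow = nrow(design))
  rss <- colSums(res^2)
  sigma2 <- rss / df_resid
  j <- which(colnames(design) == coef)
  xtx_inv_jj <- solve(crossprod(design))[j, j]
  se <- sqrt(sigma2 * xtx_inv_jj)
  lfc <- cf[coef, ]
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_resid)
  # degenerate genes: no residual variability left to test against
  degen <- (rss <= 1e-10 * max(1, mean(expr^2)) * nrow(design)) | !is.finite(p)
  lfc[degen] <- 0
  p[degen] <- 1
  if (is.null(mean_expr)) mean_expr <- rowMeans(expr)
  data.frame(
    gene_id = rownames(expr) %||% paste0("gene", seq_len(nrow(expr))),
    lfc = unname(lfc),
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    mean_expr = unname(mean_expr),
    stage = stage,
    degenerate = unname(degen),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_sample_sheet <- function(expr, samples) {
  need <- c("sample_id", "sex")
  if (!all(need %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(samples$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (is.null(colnames(expr)) || !all(samples$sample_id %in% colnames(expr))) {
    stop("expression matrix lacks columns for some samples", call. = FALSE)
  }
  expr[, samples$sample_id, drop = FALSE]
}

#' Paired (twin) differential expression
#'
#' Per-gene linear model for the mother-blocked birth design:
#' `expression ~ sex + pair (+ activation)`. The pair indicators absorb any
#' effect shared by co-twins (the maternal/intra-uterine environment), and the
#' optional activation covariate adjusts for endothelial activation level
#' (e.g. FOS counts per million). The log2 fold change is the sex coefficient
#' (female over male, positive = higher in females); the p-value is the
#' two-sided t-test on that coefficient; FDR is Benjamini-Hochberg over all
#' genes. Without the covariate the model is algebraically a paired t-test.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param samples sample sheet with `sample_id`, `sex`, `pair_id`.
#' @param use_activation include the `activation` column as a covariate.
#' @return a `data.frame` DE table: `gene_id`, `lfc`, `p`, `fdr`,
#'   `mean_expr`, `stage`, `degenerate`.
#' @export
de_paired <- function(expr, samples, use_activation = TRUE) {
  expr <- check_sample_sheet(expr, samples)
  if (!"pair_id" %in% names(samples) || anyNA(samples$pair_id)) {
    stop("paired analysis requires a complete pair_id column", call. = FALSE)
  }
  tab <- table(samples$pair_id, samples$sex)
  if (any(rowSums(tab) < 2)) {
    stop("every pair_id must have at least two samples", call. = FALSE)
  }
  complete <- sum(tab[, "F"] > 0 & tab[, "M"] > 0)
  if (complete < 2) {
    stop("need at least 2 complete opposite-sex pairs (found ", complete, ")",
         call. = FALSE)
  }
  sexF <- as.numeric(samples$sex == "F")
  pair <- factor(samples$pair_id)
  design <- stats::model.matrix(~sexF + pair)
  if (use_activation) {
    if (!"activation" %in% names(samples)) {
      stop("use_activation = TRUE but sample sheet has no 'activation' column",
           call. = FALSE)
    }
    design <- cbind(design, activation = samples$activation)
  }
  fit_lm_de(expr, design, coef = "sexF", stage = "birth")
}

#' Unpaired differential expression
#'
#' Per-gene two-sided equal-variance t-test of female versus male log2
#' expression (equivalently, the sex coefficient of `expression ~ sex`), for
#' the adult design where no pairing exists. `lfc = mean(F) - mean(M)`.
#'
#' @inheritParams de_paired
#' @return a DE table as in [de_paired()], stage `"adult"`.
#' @export
de_unpaired <- function(expr, samples) {
  expr <- check_sample_sheet(expr, samples)
  n_by_sex <- table(factor(samples$sex, levels = c("F", "M")))
  if (any(n_by_sex < 2)) {
    stop("need at least 2 samples of each sex (F=", n_by_sex[["F"]],
         ", M=", n_by_sex[["M"]], ")", call. = FALSE)
  }
  sexF <- as.numeric(samples$sex == "F")
  design <- stats::model.matrix(~sexF)
  fit_lm_de(expr, design, coef = "sexF", stage = "adult")
}

#' P-value distribution diagnostics
#'
#' Histogram of adjusted p-values at a fixed bin width, the fraction below the
#' birth-stage FDR cutoff, and the Kolmogorov-Smirnov distance from the
#' uniform distribution. A left-skewed histogram is the signature of a
#' well-powered contrast; a flat one indicates no detectable signal.
#'
#' @param results a DE table from [de_paired()] or [de_unpaired()].
#' @param bin_width histogram bin width on `[0, 1]`.
#' @param thr a [threshold_config()].
#' @return list with `histogram` (data.frame bin_lo/bin_hi/count),
#'   `fraction_below` and `ks_distance`.
#' @export
pvalue_skew <- function(results, bin_width = 0.05, thr = threshold_config()) {
  if (!nrow(results)) stop("empty DE table", call. = FALSE)
  x <- results$fdr
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  xs <- sort(x)
  n <- length(xs)
  ks <- max(seq_len(n) / n - xs, xs - (seq_len(n) - 1) / n)
  list(
    histogram = data.frame(bin_lo = h$breaks[-length(h$breaks)],
                           bin_hi = h$breaks[-1], count = h$counts),
    fraction_below = mean(x < thr$birth_fdr),
    ks_distance = ks
  )
}
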