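#' Random-gene permutation test
#'
#' Generic permutation framework used for conservation scores, regulator
#' content, class membership and GWAS-target statistics. The observed
#' statistic is computed on the target gene set; each of `n_perm` null draws
#' samples `|target_set|` genes from the universe without replacement and
#' recomputes the statistic. One-sided p-values follow the counting rule
#'
#' \deqn{p_{high} = \#\{null > observed\} / n_{perm}, \quad
#'       p_{low} = \#\{null < observed\} / n_{perm}}
#'
#' with strict inequalities, so ties count toward neither tail and p = 0 is
#' possible. `smoothing = TRUE` switches to the add-one estimator
#' `(k + 1) / (n_perm + 1)` for users needing strictly positive p-values.
#'
#' Supported statistics:
#' * `median_of_values` / `mean_of_values` — median/mean of a per-gene value
#'   (e.g. promoter conservation) over the set;
#' * `class_fraction` — fraction of the set in the `"high"` class (values
#'   may be logical or `"high"`/`"low"` labels);
#' * `overlap_count` — number of set members present in a reference
#'   membership set (e.g. GWAS targets).
#'
#' Draws on which the statistic is undefined (all values missing) are
#' resampled and counted in `n_resampled`.
#'
#' @param target_set character vector of gene ids, subset of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @param values named per-gene vector over the universe (for the value and
#'   class statistics).
#' @param membership character vector of reference gene ids (for
#'   `overlap_count`).
#' @param statistic_kind one of `"median_of_values"`, `"mean_of_values"`,
#'   `"class_fraction"`, `"overlap_count"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; fixed seed implies identical null draws.
#' @param smoothing use the add-one p-value estimator.
#' @return object of class `permutation_result`: list with `observed`,
#'   `null_values`, `p_high`, `p_low`, `statistic_kind`, `n_perm`, `seed`,
#'   `n_resampled`.
#' @export
permutation_test <- function(target_set, universe, values = NULL,
                             membership = NULL,
                             statistic_kind = c("median_of_values",
                                                "mean_of_values",
                                                "class_fraction",
                                                "overlap_count"),
                             n_perm = 10000L, seed = 1L, smoothing = FALSE) {
  statistic_kind <- match.arg(statistic_kind)
  universe <- unique(universe)
  target_set <- unique(target_set)
  stopifnot_scalar_number(n_perm, "n_perm", min = 1, integer = TRUE)
  if (!all(target_set %in% universe)) {
    stop("target_set must be a subset of the universe", call. = FALSE)
  }
  s <- length(target_set)
  if (s == 0) stop("target_set is empty", call. = FALSE)
  if (s > length(universe)) {
    stop("target_set larger than universe", call. = FALSE)
  }

  stat_fun <- switch(statistic_kind,
    median_of_values = ,
    mean_of_values = {
      if (is.null(values)) stop("'values' required for value statistics",
                                call. = FALSE)
      if (!all(universe %in% names(values))) {
        stop("'values' must be defined (named) on the whole universe",
             call. = FALSE)
      }
      v <- values[universe]
      names(v) <- universe
      agg <- if (statistic_kind == "median_of_values") stats::median else mean
      function(genes) {
        x <- v[genes]
        if (all(is.na(x))) NA_real_ else agg(x, na.rm = TRUE)
      }
    },
    class_fraction = {
      if (is.null(values)) stop("'values' required for class_fraction",
                                call. = FALSE)
      if (!all(universe %in% names(values))) {
        stop("'values' must be defined (named) on the whole universe",
             call. = FALSE)
      }
      hi <- if (is.logical(values)) values[universe] else values[universe] == "high"
      names(hi) <- universe
      function(genes) {
        x <- hi[genes]
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      }
    },
    overlap_count = {
      if (is.null(membership)) stop("'membership' required for overlap_count",
                                    call. = FALSE)
      member <- universe %in% unique(membership)
      names(member) <- universe
      function(genes) sum(member[genes])
    }
  )

  observed <- stat_fun(target_set)
  if (is.na(observed)) {
    stop("statistic undefined on the target set (all values missing)",
         call. = FALSE)
  }

  null_values <- numeric(n_perm)
  n_resampled <- 0L
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      repeat {
        stat <- stat_fun(sample(universe, s))
        if (!is.na(stat)) break
        n_resampled <- n_resampled + 1L
        if (n_resampled > 100L * n_perm) {
          stop("statistic undefined on virtually every draw", call. = FALSE)
        }
      }
      null_values[i] <- stat
    }
  })

  k_high <- sum(null_values > observed)
  k_low <- sum(null_values < observed)
  denom <- if (smoothing) n_perm + 1L else n_perm
  structure(list(
    observed = observed,
    null_values = null_values,
    p_high = (k_high + smoothing) / denom,
    p_low = (k_low + smoothing) / denom,
    statistic_kind = statistic_kind,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    n_resampled = n_resampled
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", x$statistic_kind, ", ", x$n_perm, " draws)\n",
      "  observed = ", format(x$observed), "\n",
      "  p_high = ", format(x$p_high), ", p_low = ", format(x$p_low), "\n",
      sep = "")
  invisible(x)
}

#' Fraction of a gene set in the high-conservation class
#'
#' @param gene_set character vector of gene ids.
#' @param classes named character (`"high"`/`"low"`) or logical vector
#'   covering the set.
#' @return fraction of set members classified `high`.
#' @export
class_fraction_statistic <- function(gene_set, classes) {
  if (!all(gene_set %in% names(classes))) {
    stop("classes must cover the gene set", call. = FALSE)
  }
  x <- classes[gene_set]
  if (!is.logical(x)) x <- x == "high"
  mean(x, na.rm = TRUE)
}
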