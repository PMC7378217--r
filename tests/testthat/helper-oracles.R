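# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration and closed-form formulas only.

# BH step-up by the direct formula: p_(i) * m / i, cumulative minimum from the
# right, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration over all
# C(N, q) draws of q from a universe of N with m marked elements.
oracle_hyper_tail <- function(k, m, q, N) {
  if (q == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, q)
  hits <- colSums(draws <= m)  # elements 1..m are the marked ones
  mean(hits >= k)
}

# Two-sided Fisher p by full enumeration over tables with the observed
# margins, using choose() ratios only (no dhyper, no fisher.test).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  min(1, sum(pr[pr <= pr[xs == a] * (1 + 1e-7)]))
}

# Exact tail of the overlap-count null: P(overlap with a marked set of size m
# is > obs) when drawing s genes from N, by enumeration.
oracle_overlap_tail_above <- function(obs, s, m, N) {
  draws <- utils::combn(N, s)
  mean(colSums(draws <= m) > obs)
}

make_annotation <- function(gene_id, chrom, strand = NULL, start = NULL,
                            end = NULL, regulator_class = NULL,
                            hormonal = NULL) {
  n <- length(gene_id)
  strand <- strand %||% rep("+", n)
  start <- start %||% seq(1000L, by = 5000L, length.out = n)
  end <- end %||% (start + 1000L)
  data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end - 1L),
    regulator_class = regulator_class %||% rep("none", n),
    hormonal_target = hormonal %||% rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hand-built DE table.
make_de <- function(gene_id, lfc, p, stage, fdr = NULL) {
  data.frame(gene_id = gene_id, lfc = lfc, p = p,
             fdr = fdr %||% stats::p.adjust(p, "BH"),
             mean_expr = 0, stage = stage, degenerate = FALSE,
             stringsAsFactors = FALSE)
}
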