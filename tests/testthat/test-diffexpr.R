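test_that("log2-CPM normalization follows the pseudo-counted formula", {
  counts <- matrix(c(999999L, 0L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  lc <- normalize_counts(counts)
  expect_equal(lc["g1", 1], log2(1e6 * 999999.5 / 1e6))
  expect_equal(lc["g1", 1], 19.93157, tolerance = 1e-6)
  expect_true(all(is.finite(lc)))  # zero count stays finite
  expect_equal(lc["g2", 1], log2(1e6 * 0.5 / 1e6))
})

test_that("doubling a sample's counts leaves log2-CPM nearly unchanged", {
  set.seed(11)
  counts <- matrix(rpois(40, 500), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  doubled <- counts * 2L
  d <- normalize_counts(doubled) - normalize_counts(counts)
  # exact invariance up to the pseudo-count term, which shrinks with depth
  expect_lt(max(abs(d)), 0.01)
})

test_that("zero-total samples are rejected by name", {
  counts <- matrix(c(1L, 2L, 0L, 0L), nrow = 2,
                   dimnames = list(NULL, c("ok", "empty")))
  expect_error(normalize_counts(counts), "empty")
  expect_error(normalize_counts(counts * -1L), "non-negative")
})

make_paired_sheet <- function(n_pairs) {
  data.frame(
    sample_id = paste0("P", rep(seq_len(n_pairs), each = 2), c("F", "M")),
    sex = rep(c("F", "M"), n_pairs),
    stage = "birth",
    pair_id = paste0("P", rep(seq_len(n_pairs), each = 2)),
    activation = 0,
    stringsAsFactors = FALSE
  )
}

test_that("paired model reduces to the paired t-test without the covariate", {
  # three pairs with within-pair female-minus-male differences 1.0, 1.2, 0.8
  sheet <- make_paired_sheet(3)
  base <- c(5, 7, 6)
  expr <- matrix(NA_real_, 1, 6, dimnames = list("g1", sheet$sample_id))
  diffs <- c(1.0, 1.2, 0.8)
  expr[1, sheet$sex == "M"] <- base
  expr[1, sheet$sex == "F"] <- base + diffs
  res <- de_paired(expr, sheet, use_activation = FALSE)
  expect_equal(res$lfc, 1.0)
  expect_equal(res$lfc / (sd(diffs) / sqrt(3)), 8.660254, tolerance = 1e-6)
  expect_equal(res$p, 2 * pt(-8.660254, df = 2), tolerance = 1e-6)
  expect_equal(res$p, 0.01306, tolerance = 1e-3)
})

test_that("paired model equals the closed-form paired t on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n_pairs <- sample(3:8, 1)
    sheet <- make_paired_sheet(n_pairs)
    expr <- matrix(rnorm(5 * 2 * n_pairs, mean = 8),
                   nrow = 5, dimnames = list(paste0("g", 1:5),
                                             sheet$sample_id))
    res <- de_paired(expr, sheet, use_activation = FALSE)
    for (g in 1:5) {
      f <- expr[g, sheet$sex == "F"]
      m <- expr[g, sheet$sex == "M"]
      tt <- t.test(f, m, paired = TRUE)
      expect_equal(res$p[g], tt$p.value, tolerance = 1e-10)
      expect_equal(res$lfc[g], unname(tt$estimate), tolerance = 1e-10)
    }
  }
})

test_that("pair indicators absorb arbitrary mother effects exactly", {
  set.seed(7)
  sheet <- make_paired_sheet(4)
  expr <- matrix(rnorm(3 * 8, mean = 8), nrow = 3,
                 dimnames = list(paste0("g", 1:3), sheet$sample_id))
  res0 <- de_paired(expr, sheet, use_activation = FALSE)
  shift <- rep(c(100, -3, 0.5, 12), each = 2)  # per-pair, shared by co-twins
  res1 <- de_paired(sweep(expr, 2, shift, "+"), sheet,
                    use_activation = FALSE)
  expect_equal(res0$lfc, res1$lfc, tolerance = 1e-8)
  expect_equal(res0$p, res1$p, tolerance = 1e-8)
})

test_that("constant genes get the degenerate convention lfc 0, p 1", {
  sheet <- make_paired_sheet(3)
  expr <- matrix(5, 2, 6, dimnames = list(c("flat", "g2"), sheet$sample_id))
  expr[2, ] <- rnorm(6)
  res <- de_paired(expr, sheet, use_activation = FALSE)
  expect_equal(res$lfc[res$gene_id == "flat"], 0)
  expect_equal(res$p[res$gene_id == "flat"], 1)
  expect_true(res$degenerate[res$gene_id == "flat"])
  expect_false(res$degenerate[res$gene_id == "g2"])
})

test_that("paired model validates its inputs", {
  sheet <- make_paired_sheet(1)
  expr <- matrix(rnorm(2), 1, 2, dimnames = list("g", sheet$sample_id))
  expect_error(de_paired(expr, sheet, use_activation = FALSE),
               "2 complete opposite-sex pairs")
  sheet2 <- make_paired_sheet(3)
  sheet2$pair_id[1] <- NA
  expr2 <- matrix(rnorm(6), 1, 6, dimnames = list("g", sheet2$sample_id))
  expect_error(de_paired(expr2, sheet2), "pair_id")
})

test_that("unpaired test equals the closed-form equal-variance t", {
  sheet <- data.frame(sample_id = paste0("s", 1:6),
                      sex = c("F", "F", "F", "M", "M", "M"),
                      stringsAsFactors = FALSE)
  expr <- matrix(c(3.0, 3.2, 2.8, 2.0, 2.2, 1.8), 1,
                 dimnames = list("g1", sheet$sample_id))
  res <- de_unpaired(expr, sheet)
  expect_equal(res$lfc, 1.0)
  # pooled sd 0.2, t = 1 / (0.2 * sqrt(2/3)) = 6.123724, df = 4
  expect_equal(res$p, 2 * pt(-6.123724, df = 4), tolerance = 1e-6)
  expect_equal(res$p, 0.003602, tolerance = 1e-3)
  tt <- t.test(expr[1, 1:3], expr[1, 4:6], var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("unpaired degenerate genes are flagged with p 1", {
  sheet <- data.frame(sample_id = paste0("s", 1:4),
                      sex = c("F", "F", "M", "M"), stringsAsFactors = FALSE)
  expr <- matrix(c(2, 2, 1, 1), 1, dimnames = list("g", sheet$sample_id))
  res <- de_unpaired(expr, sheet)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  expect_error(de_unpaired(expr, transform(sheet, sex = "F")), "each sex")
})

test_that("identical group distributions give p near 1", {
  sheet <- data.frame(sample_id = paste0("s", 1:8),
                      sex = rep(c("F", "M"), each = 4),
                      stringsAsFactors = FALSE)
  expr <- matrix(rep(c(1, 2, 3, 4), 2), 1, dimnames = list("g", sheet$sample_id))
  res <- de_unpaired(expr, sheet)
  expect_gt(res$p, 0.999)
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjusted values track their genes under permutation", {
  set.seed(13)
  p <- runif(30)
  adj <- bh_adjust(p)
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_true(all(adj >= p))
})

test_that("p-value skew diagnostics report the right scalars", {
  fdr <- c(rep(0.01, 4), rep(0.6, 6))
  res <- make_de(paste0("g", 1:10), lfc = 0, p = fdr, stage = "birth",
                 fdr = fdr)
  skew <- pvalue_skew(res, bin_width = 0.1)
  expect_equal(skew$fraction_below, 0.4)
  expect_equal(sum(skew$histogram$count), 10)
  all_small <- make_de(paste0("g", 1:5), 0, rep(0.01, 5), "birth",
                       fdr = rep(0.01, 5))
  expect_equal(pvalue_skew(all_small)$fraction_below, 1)
  # KS distance shrinks for a uniform sample as n grows
  set.seed(2)
  u_small <- make_de(paste0("a", 1:50), 0, (1:50) / 51, "birth",
                     fdr = runif(50))
  u_big <- make_de(paste0("b", 1:5000), 0, (1:5000) / 5001, "birth",
                   fdr = runif(5000))
  expect_gt(pvalue_skew(u_small)$ks_distance,
            pvalue_skew(u_big)$ks_distance)
})
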