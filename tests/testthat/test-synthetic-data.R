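test_that("config validation catches bad sizes and fractions", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(n_genes = 10.5), "integer")
  expect_error(sim_config(frac_sex_chromosomal = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 10, n_intrinsic = 8, n_acquired = 8),
               "exceed n_genes")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("annotation has the requested shape and sex-chromosome content", {
  cfg0 <- sim_config(n_genes = 0, n_intrinsic = 0, n_acquired = 0)
  expect_equal(nrow(gen_annotation(cfg0)), 0)
  cfg <- sim_config(n_genes = 100, frac_sex_chromosomal = 0.05,
                    n_intrinsic = 5, n_acquired = 5, seed = 1)
  ann <- gen_annotation(cfg)
  expect_equal(nrow(ann), 100)
  expect_equal(sum(ann$chrom %in% c("chrX", "chrY")), 5)
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_true(all(ann$end > ann$start))
  expect_equal(ann$tss, ifelse(ann$strand == "+", ann$start, ann$end - 1L))
  expect_true(all(ann$regulator_class %in% c("TF", "epigenetic", "none")))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 80, n_intrinsic = 6, n_acquired = 6,
                    n_gwas_traits = 2, genes_per_trait = 8, seed = 77)
  a1 <- gen_annotation(cfg); a2 <- gen_annotation(cfg)
  expect_identical(a1, a2)
  s1 <- gen_two_stage_study(a1, cfg); s2 <- gen_two_stage_study(a2, cfg)
  expect_identical(s1, s2)
  expect_identical(gen_gene_sets(a1, cfg), gen_gene_sets(a1, cfg))
  expect_identical(gen_gwas_catalog(a1, cfg), gen_gwas_catalog(a1, cfg))
  expect_identical(gen_conservation_track(a1, cfg),
                   gen_conservation_track(a1, cfg))
  # a different seed changes the data
  cfg2 <- sim_config(n_genes = 80, n_intrinsic = 6, n_acquired = 6,
                     n_gwas_traits = 2, genes_per_trait = 8, seed = 78)
  expect_false(identical(gen_annotation(cfg2), a1))
})

test_that("planted labels match the requested counts exactly", {
  cfg <- sim_config(n_genes = 200, n_intrinsic = 30, n_acquired = 30,
                    seed = 7)
  ann <- gen_annotation(cfg)
  study <- gen_two_stage_study(ann, cfg)
  expect_equal(sum(study$truth$planted_class == "intrinsic"), 30)
  expect_equal(sum(study$truth$planted_class == "acquired"), 30)
  # direction is none exactly for unplanted genes
  expect_true(all((study$truth$planted_direction == "none") ==
                    (study$truth$planted_class == "none")))
  # zero-effect config plants nothing
  cfg0 <- sim_config(n_genes = 50, n_intrinsic = 0, n_acquired = 0,
                     lfc_intrinsic = 0, lfc_acquired = 0)
  st0 <- gen_two_stage_study(gen_annotation(cfg0), cfg0)
  expect_true(all(st0$truth$planted_class == "none"))
  expect_error(gen_two_stage_study(ann[1:10, ], cfg), "does not match")
})

test_that("study tables have the configured dimensions and metadata", {
  cfg <- sim_config(n_genes = 60, n_pairs_opposite = 7, n_pairs_same = 7,
                    n_adult_female = 9, n_adult_male = 21,
                    n_intrinsic = 4, n_acquired = 4, seed = 5)
  st <- gen_two_stage_study(gen_annotation(cfg), cfg)
  expect_equal(dim(st$birth$counts), c(60, 28))
  expect_equal(dim(st$adult$expr), c(60, 30))
  # co-twins share pair ids; 7 opposite + 3 boy-boy + 4 girl-girl
  tab <- table(st$birth$samples$pair_id)
  expect_true(all(tab == 2))
  mixed <- tapply(st$birth$samples$sex, st$birth$samples$pair_id,
                  function(s) length(unique(s)))
  expect_equal(sum(mixed == 2), 7)
  same <- names(mixed)[mixed == 1]
  sexes <- tapply(st$birth$samples$sex, st$birth$samples$pair_id, unique)
  expect_equal(sum(unlist(sexes[same]) == "M"), 3)
  expect_equal(sum(unlist(sexes[same]) == "F"), 4)
  expect_true(all(st$birth$samples$activation > 0))
  expect_true(all(st$birth$counts >= 0))
  expect_true(all(st$birth$counts == round(st$birth$counts)))
})

test_that("planted effects are recovered empirically at both stages", {
  # many replicate planted genes; empirical F-minus-M log2 difference should
  # sit within Monte-Carlo error of the configured effect
  cfg <- sim_config(n_genes = 600, n_intrinsic = 200, n_acquired = 200,
                    lfc_intrinsic = 1.5, lfc_acquired = 1.2,
                    noise_sd = 0.5, seed = 31)
  ann <- gen_annotation(cfg)
  st <- gen_two_stage_study(ann, cfg)
  sgn <- ifelse(st$truth$planted_direction == "female_higher", 1, -1)

  adultF <- st$adult$samples$sex == "F"
  d_adult <- rowMeans(st$adult$expr[, adultF]) -
    rowMeans(st$adult$expr[, !adultF])
  for (cl in c("intrinsic", "acquired")) {
    i <- st$truth$planted_class == cl
    want <- if (cl == "intrinsic") cfg$lfc_intrinsic else cfg$lfc_acquired
    est <- mean(d_adult[i] * sgn[i])
    se <- sd(d_adult[i] * sgn[i]) / sqrt(sum(i))
    expect_lt(abs(est - want), 3 * se + 0.02)
  }

  lc <- normalize_counts(st$birth$counts)
  bg <- st$birth$samples[grepl("^BG", st$birth$samples$pair_id), ]
  d_birth <- rowMeans(lc[, bg$sample_id[bg$sex == "F"]]) -
    rowMeans(lc[, bg$sample_id[bg$sex == "M"]])
  i <- st$truth$planted_class == "intrinsic"
  est_b <- mean(d_birth[i] * sgn[i])
  se_b <- sd(d_birth[i] * sgn[i]) / sqrt(sum(i))
  expect_lt(abs(est_b - cfg$lfc_intrinsic), 3 * se_b + 0.02)
  # acquired genes carry no birth effect
  j <- st$truth$planted_class == "acquired"
  est_null <- mean(d_birth[j] * sgn[j])
  expect_lt(abs(est_null), 3 * sd(d_birth[j]) / sqrt(sum(j)) + 0.02)
})

test_that("zero-effect studies yield uniform downstream p-values", {
  cfg <- sim_config(n_genes = 1000, n_intrinsic = 0, n_acquired = 0,
                    lfc_intrinsic = 0, lfc_acquired = 0,
                    n_adult_female = 20, n_adult_male = 40, seed = 101)
  ann <- gen_annotation(cfg)
  st <- gen_two_stage_study(ann, cfg)
  bg <- st$birth$samples[grepl("^BG", st$birth$samples$pair_id), ]
  db <- de_paired(normalize_counts(st$birth$counts)[, bg$sample_id], bg)
  da <- de_unpaired(st$adult$expr, st$adult$samples)
  expect_gt(suppressWarnings(ks.test(db$p, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(da$p, "punif"))$p.value, 0.01)
})

test_that("gene sets respect config sizes and hormonal union semantics", {
  cfg <- sim_config(n_genes = 100, n_gene_sets = 0, n_intrinsic = 5,
                    n_acquired = 5, seed = 3)
  sets0 <- gen_gene_sets(gen_annotation(cfg), cfg)
  expect_false(any(grepl("^SET", names(sets0))))
  cfg2 <- sim_config(n_genes = 100, n_gene_sets = 4, genes_per_set = 12,
                     n_intrinsic = 5, n_acquired = 5, seed = 3)
  ann2 <- gen_annotation(cfg2)
  sets2 <- gen_gene_sets(ann2, cfg2)
  generic <- sets2[grepl("^SET", names(sets2))]
  expect_equal(length(generic), 4)
  expect_true(all(lengths(generic) == 12))
  expect_true(all(unlist(sets2) %in% ann2$gene_id))
  horm <- sets2[["SEX_HORMONAL_TARGETS"]]
  expect_equal(anyDuplicated(horm), 0)
  expect_equal(sort(horm),
               sort(unique(unlist(sets2[c("ESTROGEN_RESPONSE",
                                          "ANDROGEN_RESPONSE",
                                          "PROGESTIN_RESPONSE")]))))
  expect_error(gen_gene_sets(ann2, sim_config(n_genes = 100,
                                              genes_per_set = 101)),
               "genes_per_set")
})

test_that("conservation tracks cover genes and carry the planted boost", {
  cfg <- sim_config(n_genes = 150, n_intrinsic = 40, n_acquired = 0,
                    promoter_conservation_boost = 0.3, seed = 13)
  ann <- gen_annotation(cfg)
  st <- gen_two_stage_study(ann, cfg)
  track <- gen_conservation_track(ann, cfg)
  expect_true(all(track$score >= 0 & track$score <= 1))
  prom <- promoter_window(ann, 200, 100)
  body <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                     start = ann$start, end = ann$end)
  pm <- summarize_scores(track, prom)
  bm <- summarize_scores(track, body)
  expect_true(all(!is.na(pm)) && all(!is.na(bm)))
  boosted <- st$truth$planted_conserved_promoter
  # direct recomputation from the emitted track: boost appears on promoters
  diff_prom <- mean(pm[boosted]) - mean(pm[!boosted])
  se <- sqrt(var(pm[boosted]) / sum(boosted) +
               var(pm[!boosted]) / sum(!boosted))
  expect_lt(abs(diff_prom - 0.3), 3 * se)
  # gene bodies only see the boost through the 100 promoter bases that lie
  # inside the body (downstream-of-TSS part of the window)
  diff_body <- mean(bm[boosted]) - mean(bm[!boosted])
  se_b <- sqrt(var(bm[boosted]) / sum(boosted) +
                 var(bm[!boosted]) / sum(!boosted))
  leak <- mean(0.3 * 100 / (ann$end - ann$start)[boosted])
  expect_lt(abs(diff_body - leak), 4 * se_b)
  expect_lt(diff_body, 0.5 * diff_prom)
  # zero boost: planted and background promoters indistinguishable
  cfg0 <- sim_config(n_genes = 150, n_intrinsic = 40, n_acquired = 0,
                     promoter_conservation_boost = 0, seed = 13)
  pm0 <- summarize_scores(gen_conservation_track(ann, cfg0), prom)
  d0 <- mean(pm0[boosted]) - mean(pm0[!boosted])
  se0 <- sqrt(var(pm0[boosted]) / sum(boosted) +
                var(pm0[!boosted]) / sum(!boosted))
  expect_lt(abs(d0), 3 * se0)
})
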