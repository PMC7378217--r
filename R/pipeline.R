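#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or a set of input paths must
#' be given, not neither. Paths mode expects tab-separated inputs: a birth
#' count matrix (`gene_id` first column), an adult log2 intensity matrix, a
#' sample sheet covering both stages (`sample_id`, `sex`, `stage`, `pair_id`,
#' `activation`), a gene annotation, and optionally a GMT gene-set file, a
#' bedGraph conservation track and a GWAS-catalog TSV.
#'
#' @param simulate optional [sim_config()]; when present all inputs are
#'   generated.
#' @param paths optional named list: `birth_counts`, `adult_expr`, `samples`,
#'   `annotation`, and optionally `gene_sets`, `conservation`, `gwas`.
#' @param thresholds a [threshold_config()].
#' @param outdir output directory for report tables.
#' @param seed integer seed for permutation draws (and the simulation when
#'   `simulate` lacks one).
#' @param use_activation adjust the birth model for the activation covariate.
#' @param smoothing use add-one smoothing for permutation p-values.
#' @param n_perm permutations for the enrichment tests (defaults to the
#'   threshold config's).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            thresholds = threshold_config(),
                            outdir = tempfile("sexbiasDE_run_"),
                            seed = 1L, use_activation = TRUE,
                            smoothing = FALSE, n_perm = NULL) {
  if (is.null(simulate) && is.null(paths)) {
    stop("pipeline_config needs either a simulate block or input paths",
         call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    stop("simulate must be a sim_config", call. = FALSE)
  }
  structure(list(simulate = simulate, paths = paths, thresholds = thresholds,
                 outdir = outdir, seed = as.integer(seed),
                 use_activation = use_activation, smoothing = smoothing,
                 n_perm = n_perm %||% thresholds$n_perm),
            class = "pipeline_config")
}

run_stage <- function(stage_name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage_name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    annotation <- gen_annotation(sim)
    study <- gen_two_stage_study(annotation, sim)
    list(annotation = annotation,
         birth_counts = study$birth$counts,
         birth_samples = study$birth$samples,
         adult_expr = study$adult$expr,
         adult_samples = study$adult$samples,
         truth = study$truth,
         gene_sets = gen_gene_sets(annotation, sim),
         conservation = gen_conservation_track(annotation, sim),
         gwas = gen_gwas_catalog(annotation, sim))
  } else {
    p <- config$paths
    need <- c("birth_counts", "adult_expr", "samples", "annotation")
    if (!all(need %in% names(p))) {
      stop("paths must include: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    read_matrix <- function(path) {
      tab <- read_tsv_plain(path)
      m <- as.matrix(tab[, -1, drop = FALSE])
      rownames(m) <- tab[[1L]]
      m
    }
    samples <- read_tsv_plain(p$samples)
    gwas_df <- NULL
    list(annotation = read_tsv_plain(p$annotation),
         birth_counts = read_matrix(p$birth_counts),
         birth_samples = samples[samples$stage == "birth", , drop = FALSE],
         adult_expr = read_matrix(p$adult_expr),
         adult_samples = samples[samples$stage == "adult", , drop = FALSE],
         truth = NULL,
         gene_sets = if (!is.null(p$gene_sets)) read_gmt(p$gene_sets),
         conservation = if (!is.null(p$conservation))
           read_bedgraph(p$conservation),
         gwas = if (!is.null(p$gwas)) utils::read.delim(
           p$gwas, sep = "\t", check.names = FALSE,
           stringsAsFactors = FALSE, quote = ""))
  }
}

#' Run the full two-stage sex-bias pipeline
#'
#' Orchestrates every analysis stage from one configuration: normalization
#' and paired DE at birth (plus the optional boy-boy versus girl-girl
#' contrast on the same-sex pairs), unpaired DE in adults, intrinsic /
#' acquired classification, direction and per-chromosome summaries,
#' hypergeometric gene-set enrichment per direction, the hormonal-target
#' Fisher test, regulator content, conservation summaries with their
#' permutation tests, GWAS overlap and catalog-membership enrichment, the
#' adult volcano table and the two-stage log fold-change table for
#' classified genes. All tables are written to `config$outdir` as TSV with a
#' comment header recording seed and thresholds, alongside a JSON run
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the report bundle: a named list of all tables and
#'   test results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must come from pipeline_config()", call. = FALSE)
  }
  thr <- config$thresholds
  inputs <- run_stage("load", load_pipeline_inputs(config))
  ann <- inputs$annotation

  de_birth <- run_stage("de_birth", {
    logcpm <- normalize_counts(inputs$birth_counts)
    bg <- inputs$birth_samples[
      inputs$birth_samples$pair_id %in%
        names(which(tapply(inputs$birth_samples$sex,
                           inputs$birth_samples$pair_id,
                           function(s) length(unique(s)) == 2L))),
      , drop = FALSE]
    de_paired(logcpm[, bg$sample_id, drop = FALSE], bg,
              use_activation = config$use_activation)
  })
  de_samesex <- run_stage("de_samesex", {
    ss <- inputs$birth_samples[
      inputs$birth_samples$pair_id %in%
        names(which(tapply(inputs$birth_samples$sex,
                           inputs$birth_samples$pair_id,
                           function(s) length(unique(s)) == 1L))),
      , drop = FALSE]
    if (nrow(ss) >= 4 && length(unique(ss$sex)) == 2L) {
      logcpm <- normalize_counts(inputs$birth_counts)
      de_unpaired(logcpm[, ss$sample_id, drop = FALSE], ss)
    } else NULL
  })
  de_adult <- run_stage("de_adult",
                        de_unpaired(inputs$adult_expr, inputs$adult_samples))

  classified <- run_stage("classify", classify_genes(de_birth, de_adult, thr))
  universe <- classified$gene_id
  intrinsic <- classified$gene_id[classified$class == "intrinsic"]
  acquired <- classified$gene_id[classified$class == "acquired"]

  summaries <- run_stage("summaries", list(
    direction_counts = direction_counts(classified),
    sexchrom_birth = sex_chromosomal_fraction(
      de_birth$gene_id[de_birth$fdr < thr$birth_fdr], ann),
    sexchrom_adult = sex_chromosomal_fraction(
      de_adult$gene_id[de_adult$p < thr$adult_p], ann),
    sexchrom_intrinsic = sex_chromosomal_fraction(intrinsic, ann),
    sexchrom_acquired = sex_chromosomal_fraction(acquired, ann),
    chrom_birth = chromosome_fractions(de_birth, ann, thr),
    chrom_adult = chromosome_fractions(de_adult, ann, thr,
                                       lfc_min = thr$display_lfc_min),
    pskew_birth = pvalue_skew(de_birth, thr = thr),
    pskew_samesex = if (!is.null(de_samesex))
      pvalue_skew(de_samesex, thr = thr)
  ))

  # adult volcano table, with the autosomal-only restriction available
  volcano <- run_stage("volcano", {
    idx <- match(de_adult$gene_id, ann$gene_id)
    data.frame(de_adult[, c("gene_id", "lfc", "p")],
               autosomal = !(ann$chrom[idx] %in% c("chrX", "chrY")),
               neg_log2_p = -log2(pmax(de_adult$p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })

  lfc_table <- run_stage("lfc_table", {
    cl <- classified[classified$class != "neither", ]
    cl[order(cl$class, -cl$adult_lfc),
       c("gene_id", "class", "direction", "birth_lfc", "adult_lfc")]
  })

  enrich <- run_stage("enrich", {
    if (is.null(inputs$gene_sets) || !length(inputs$gene_sets)) NULL else {
      by_dir <- list(
        adult_female = de_adult$gene_id[de_adult$p < thr$adult_p &
                                          de_adult$lfc > 0],
        adult_male = de_adult$gene_id[de_adult$p < thr$adult_p &
                                        de_adult$lfc < 0],
        birth_female = de_birth$gene_id[de_birth$fdr < thr$birth_fdr &
                                          de_birth$lfc > 0],
        birth_male = de_birth$gene_id[de_birth$fdr < thr$birth_fdr &
                                        de_birth$lfc < 0],
        intrinsic = intrinsic,
        acquired = acquired
      )
      res <- lapply(names(by_dir), function(nm) {
        q <- by_dir[[nm]]
        if (!length(q)) return(NULL)
        tab <- hypergeom_enrich(q, inputs$gene_sets, N = thr$enrich_universe)
        tab$query <- nm
        tab$neg_log10_padj <- -log10(pmax(tab$padj, .Machine$double.xmin))
        tab
      })
      do.call(rbind, res)
    }
  })

  hormonal <- run_stage("hormonal", {
    hs <- attr(inputs$gene_sets, "hormonal_set")
    if (!is.null(inputs$gene_sets) && !is.null(hs) &&
        hs %in% names(inputs$gene_sets) &&
        length(intrinsic) && length(acquired)) {
      hormonal_target_test(intrinsic, acquired, inputs$gene_sets[[hs]])
    } else NULL
  })

  regulators <- run_stage("regulators", {
    if ("regulator_class" %in% names(ann)) {
      list(intrinsic = regulator_content(intrinsic, ann),
           acquired = regulator_content(acquired, ann))
    } else NULL
  })

  conservation <- run_stage("conservation", {
    if (is.null(inputs$conservation)) NULL else {
      summ <- conservation_summary(inputs$conservation, ann, thr)
      perms <- list()
      prom_means <- stats::setNames(summ$promoter_mean, summ$gene_id)
      body_means <- stats::setNames(summ$genebody_mean, summ$gene_id)
      for (set_nm in c("intrinsic", "acquired")) {
        gs <- intersect(get(set_nm), universe)
        if (length(gs)) {
          perms[[paste0(set_nm, "_promoter")]] <- permutation_test(
            gs, universe, values = prom_means[universe],
            statistic_kind = "median_of_values", n_perm = config$n_perm,
            seed = config$seed + 11L, smoothing = config$smoothing)
          perms[[paste0(set_nm, "_genebody")]] <- permutation_test(
            gs, universe, values = body_means[universe],
            statistic_kind = "median_of_values", n_perm = config$n_perm,
            seed = config$seed + 12L, smoothing = config$smoothing)
        }
      }
      list(summary = summ, permutations = perms)
    }
  })

  gwas <- run_stage("gwas", {
    if (is.null(inputs$gwas)) NULL else {
      tmp <- tempfile(fileext = ".tsv")
      utils::write.table(inputs$gwas, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      catalog <- parse_catalog(tmp)
      unlink(tmp)
      traits <- unique(catalog$records$trait)
      per_trait <- list()
      for (set_nm in c("intrinsic", "acquired")) {
        gs <- get(set_nm)
        if (!length(gs)) next
        for (tr in traits) {
          keep <- catalog$records$trait == tr
          targets <- unique(unlist(catalog$genes_by_row[keep],
                                   use.names = FALSE))
          ov <- gwas_overlap_enrichment(gs, targets, universe,
                                        n_perm = config$n_perm,
                                        seed = config$seed + 21L,
                                        smoothing = config$smoothing)
          per_trait[[paste(set_nm, tr, sep = " | ")]] <- ov
        }
        per_trait[[paste(set_nm, "whole catalog", sep = " | ")]] <-
          list(result = catalog_membership_enrichment(
                 gs, catalog, universe, n_perm = config$n_perm,
                 seed = config$seed + 22L, smoothing = config$smoothing),
               overlapping_genes = intersect(gs, catalog$unique_genes))
      }
      list(catalog = catalog, enrichment = per_trait)
    }
  })

  bundle <- list(
    de_birth = de_birth, de_samesex = de_samesex, de_adult = de_adult,
    classified = classified, summaries = summaries, volcano = volcano,
    lfc_table = lfc_table, enrichment = enrich, hormonal = hormonal,
    regulators = regulators, conservation = conservation, gwas = gwas,
    truth = inputs$truth, annotation = ann,
    manifest = list(
      package = "sexbiasDE",
      version = as.character(utils::packageVersion("sexbiasDE")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      thresholds = unclass(thr),
      n_perm = config$n_perm,
      use_activation = config$use_activation,
      smoothing = config$smoothing,
      simulated = !is.null(config$simulate),
      sim_config = if (!is.null(config$simulate)) unclass(config$simulate)
    )
  )
  run_stage("write", write_bundle(bundle, config))
  invisible(bundle)
}

write_bundle <- function(bundle, config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed,
               birth_fdr = config$thresholds$birth_fdr,
               adult_p = config$thresholds$adult_p,
               n_perm = config$n_perm)
  wr <- function(df, nm) {
    if (!is.null(df) && is.data.frame(df)) {
      write_tsv_commented(df, file.path(outdir, paste0(nm, ".tsv")), meta)
    }
  }
  wr(bundle$de_birth, "de_birth")
  wr(bundle$de_samesex, "de_samesex")
  wr(bundle$de_adult, "de_adult")
  wr(bundle$classified, "classification")
  wr(bundle$summaries$direction_counts, "direction_counts")
  wr(bundle$summaries$chrom_birth, "chromosome_fractions_birth")
  wr(bundle$summaries$chrom_adult, "chromosome_fractions_adult")
  wr(bundle$summaries$pskew_birth$histogram, "pvalue_histogram_birth")
  if (!is.null(bundle$summaries$pskew_samesex)) {
    wr(bundle$summaries$pskew_samesex$histogram, "pvalue_histogram_samesex")
  }
  wr(bundle$volcano, "volcano_adult")
  wr(bundle$lfc_table, "lfc_two_stage")
  wr(bundle$enrichment, "enrichment")
  if (!is.null(bundle$conservation)) wr(bundle$conservation$summary,
                                        "conservation_summary")
  perm_rows <- list()
  if (!is.null(bundle$conservation)) {
    for (nm in names(bundle$conservation$permutations)) {
      pr <- bundle$conservation$permutations[[nm]]
      perm_rows[[nm]] <- data.frame(test = nm, observed = pr$observed,
                                    p_high = pr$p_high, p_low = pr$p_low,
                                    n_perm = pr$n_perm)
    }
  }
  if (!is.null(bundle$gwas)) {
    for (nm in names(bundle$gwas$enrichment)) {
      pr <- bundle$gwas$enrichment[[nm]]$result
      perm_rows[[nm]] <- data.frame(
        test = nm, observed = pr$observed, p_high = pr$p_high,
        p_low = pr$p_low, n_perm = pr$n_perm,
        genes = paste(bundle$gwas$enrichment[[nm]]$overlapping_genes,
                      collapse = ","))
    }
  }
  if (length(perm_rows)) {
    perm_df <- do.call(rbind, lapply(perm_rows, function(d) {
      if (!"genes" %in% names(d)) d$genes <- ""
      d
    }))
    wr(perm_df, "permutation_tests")
  }
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(outdir)
}

#' Plain-text report from a pipeline bundle
#'
#' Renders counts, percentages and test p-values already present in the
#' bundle without recomputing anything.
#'
#' @param bundle output of [run_pipeline()].
#' @param path optional file to write the report to.
#' @return character vector of report lines (invisibly when written).
#' @export
make_report <- function(bundle, path = NULL) {
  dc <- bundle$summaries$direction_counts
  lines <- c(
    "Two-stage sex-bias analysis report",
    "==================================",
    sprintf("Genes in shared universe: %d", nrow(bundle$classified)),
    sprintf("Birth DEGs (FDR < %g): %d", bundle$manifest$thresholds$birth_fdr,
            sum(bundle$de_birth$fdr < bundle$manifest$thresholds$birth_fdr)),
    sprintf("Adult DEGs (p < %g): %d", bundle$manifest$thresholds$adult_p,
            sum(bundle$de_adult$p < bundle$manifest$thresholds$adult_p)),
    "",
    "Lifespan classes (female-higher + male-higher = total):"
  )
  for (i in seq_len(nrow(dc))) {
    lines <- c(lines, sprintf("  %-10s %d + %d = %d", dc$class[i],
                              dc$female_higher[i], dc$male_higher[i],
                              dc$total[i]))
  }
  if (all(dc$total == 0)) {
    lines <- c(lines, "  no significant genes in either class")
  }
  sx <- bundle$summaries
  lines <- c(lines, "",
             sprintf("Sex-chromosomal content: birth DEGs %d (%.1f%%), adult DEGs %d (%.1f%%)",
                     sx$sexchrom_birth$count, sx$sexchrom_birth$percent,
                     sx$sexchrom_adult$count, sx$sexchrom_adult$percent),
             sprintf("                         intrinsic %d (%.1f%%), acquired %d (%.1f%%)",
                     sx$sexchrom_intrinsic$count, sx$sexchrom_intrinsic$percent,
                     sx$sexchrom_acquired$count, sx$sexchrom_acquired$percent))
  if (!is.null(bundle$hormonal)) {
    lines <- c(lines, "",
               sprintf("Hormonal-target Fisher test (acquired vs intrinsic): p = %.4g",
                       bundle$hormonal$p))
  }
  if (!is.null(bundle$regulators)) {
    lines <- c(lines,
               sprintf("Regulator content: acquired %.1f%% TF / %.1f%% epigenetic; intrinsic %.1f%% TF / %.1f%% epigenetic",
                       bundle$regulators$acquired$pct_tf,
                       bundle$regulators$acquired$pct_epigenetic,
                       bundle$regulators$intrinsic$pct_tf,
                       bundle$regulators$intrinsic$pct_epigenetic))
  }
  if (!is.null(bundle$conservation)) {
    for (nm in names(bundle$conservation$permutations)) {
      pr <- bundle$conservation$permutations[[nm]]
      lines <- c(lines, sprintf("Conservation permutation [%s]: observed %.4f, p_high %.4g, p_low %.4g",
                                nm, pr$observed, pr$p_high, pr$p_low))
    }
  }
  if (!is.null(bundle$gwas)) {
    lines <- c(lines, "", "GWAS enrichment (overlap counts, permutation p):")
    for (nm in names(bundle$gwas$enrichment)) {
      pr <- bundle$gwas$enrichment[[nm]]$result
      lines <- c(lines, sprintf("  %-45s observed %g, p_high %.4g",
                                nm, pr$observed, pr$p_high))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
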