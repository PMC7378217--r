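# Seeded synthetic two-stage study generator with planted ground truth.
# Emulates the statistical structure the analysis assumes: a paired birth
# cohort of twins sharing a maternal random effect with an endothelial
# activation covariate and negative-binomial counts, and an unbalanced
# unpaired adult cohort with Gaussian log2 intensities. Planted intrinsic
# genes carry the same-sign sex effect at both stages; acquired genes only in
# adults.

#' Synthetic study configuration
#'
#' Defaults mirror the two-stage study shape: 7 opposite-sex twin pairs plus
#' 7 same-sex pairs (3 boy-boy, 4 girl-girl) at birth, 43 female / 129 male
#' unpaired adults, 2,000 genes with 5% on the sex chromosomes, and 30
#' intrinsic + 30 acquired genes planted at |log2 FC| = 1.5.
#'
#' @param n_genes number of genes.
#' @param frac_sex_chromosomal fraction of genes on chrX/chrY.
#' @param n_pairs_opposite opposite-sex (boy-girl) twin pairs.
#' @param n_pairs_same same-sex twin pairs (split boy-boy / girl-girl).
#' @param n_adult_female,n_adult_male adult cohort sizes.
#' @param n_intrinsic,n_acquired planted gene-set sizes.
#' @param lfc_intrinsic,lfc_acquired planted |log2 fold change| magnitudes.
#' @param mother_sd sd of the shared-pair (maternal) random intercept, log2
#'   scale.
#' @param noise_sd residual sd of adult log2 intensities.
#' @param nb_dispersion negative-binomial dispersion of birth counts.
#' @param frac_tf,frac_epi fractions of genes labelled transcription factor /
#'   epigenetic modifier.
#' @param n_gwas_traits,genes_per_trait synthetic GWAS-catalog shape.
#' @param gwas_planted_overlap planted intrinsic genes inside the first
#'   (CAD-like) trait's target list.
#' @param n_gene_sets,genes_per_set synthetic gene-set collection shape.
#' @param promoter_conservation_boost additive conservation score on planted
#'   promoters (clipped at 1).
#' @param seed integer master seed; all generator randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       frac_sex_chromosomal = 0.05,
                       n_pairs_opposite = 7L,
                       n_pairs_same = 7L,
                       n_adult_female = 43L,
                       n_adult_male = 129L,
                       n_intrinsic = 30L,
                       n_acquired = 30L,
                       lfc_intrinsic = 1.5,
                       lfc_acquired = 1.5,
                       mother_sd = 1.0,
                       noise_sd = 0.5,
                       nb_dispersion = 0.02,
                       frac_tf = 0.07,
                       frac_epi = 0.05,
                       n_gwas_traits = 12L,
                       genes_per_trait = 20L,
                       gwas_planted_overlap = 6L,
                       n_gene_sets = 10L,
                       genes_per_set = 50L,
                       promoter_conservation_boost = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  ints <- c("n_genes", "n_pairs_opposite", "n_pairs_same", "n_adult_female",
            "n_adult_male", "n_intrinsic", "n_acquired", "n_gwas_traits",
            "genes_per_trait", "gwas_planted_overlap", "n_gene_sets",
            "genes_per_set", "seed")
  for (nm in ints) stopifnot_scalar_number(cfg[[nm]], nm, min = if (nm == "seed") -Inf else 0,
                                           integer = TRUE)
  for (nm in c("frac_sex_chromosomal", "frac_tf", "frac_epi")) {
    stopifnot_scalar_number(cfg[[nm]], nm, min = 0)
    if (cfg[[nm]] > 1) stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("lfc_intrinsic", "lfc_acquired", "mother_sd", "noise_sd",
               "nb_dispersion", "promoter_conservation_boost")) {
    stopifnot_scalar_number(cfg[[nm]], nm, min = 0)
  }
  if (cfg$frac_tf + cfg$frac_epi > 1) {
    stop("frac_tf + frac_epi must not exceed 1", call. = FALSE)
  }
  if (cfg$n_intrinsic + cfg$n_acquired > cfg$n_genes) {
    stop("n_intrinsic + n_acquired must not exceed n_genes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Planted labels are a pure function of the config so every generator
# component (annotation flags, expression effects, conservation boost, GWAS
# planting) sees the same truth without passing state around.
planted_labels <- function(config) {
  n <- config$n_genes
  cls <- rep("none", n)
  dir <- rep("none", n)
  n_planted <- config$n_intrinsic + config$n_acquired
  if (n_planted > 0) {
    with_seed(config$seed + 101L, {
      idx <- sample.int(n, n_planted)
      cls[idx[seq_len(config$n_intrinsic)]] <- "intrinsic"
      if (config$n_acquired > 0) {
        cls[idx[config$n_intrinsic + seq_len(config$n_acquired)]] <- "acquired"
      }
      dir[idx] <- sample(c("female_higher", "male_higher"), n_planted,
                         replace = TRUE)
    })
  }
  data.frame(index = seq_len(n), planted_class = cls, planted_direction = dir,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic gene annotation
#'
#' Deterministic per seed. `round(frac_sex_chromosomal * n_genes)` genes are
#' placed on chrX/chrY (roughly 4:1), the rest cycle over chr1..chr22. Genes
#' are laid out non-overlapping, 0-based half-open, with lengths that are
#' multiples of 10; the TSS is `start` for `+` strand genes and `end - 1` for
#' `-` strand genes. Regulator class labels and the sex-hormonal target flag
#' are sampled per gene; the hormonal flag is enriched on planted acquired
#' genes so the downstream hormonal-content contrast has signal to find.
#'
#' @param config a [sim_config()].
#' @return `data.frame` with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `regulator_class`, `hormonal_target`.
#' @export
gen_annotation <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config",
                                            call. = FALSE)
  n <- config$n_genes
  empty <- data.frame(gene_id = character(0L), chrom = character(0L),
                      strand = character(0L), start = integer(0L),
                      end = integer(0L), tss = integer(0L),
                      regulator_class = character(0L),
                      hormonal_target = logical(0L),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  planted <- planted_labels(config)
  with_seed(config$seed + 102L, {
    gene_id <- sprintf("G%05d", seq_len(n))
    n_sex <- round(config$frac_sex_chromosomal * n)
    n_y <- floor(n_sex / 5)
    chrom <- rep(paste0("chr", 1:22), length.out = n)
    if (n_sex > 0) {
      sex_idx <- seq_len(n_sex)  # deterministic block; which genes are sexual
      chrom[sex_idx] <- c(rep("chrY", n_y), rep("chrX", n_sex - n_y))
      chrom <- sample(chrom)     # shuffle so planting is independent of chrom
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- 10L * sample(50:200, n, replace = TRUE)
    # per-chromosome sequential layout, 5 kb pitch: regions never overlap
    start <- integer(n)
    for (chr in unique(chrom)) {
      i <- which(chrom == chr)
      start[i] <- 10000L + (seq_along(i) - 1L) * 5000L
    }
    end <- start + len
    tss <- ifelse(strand == "+", start, end - 1L)
    u <- stats::runif(n)
    regulator_class <- ifelse(u < config$frac_tf, "TF",
                              ifelse(u < config$frac_tf + config$frac_epi,
                                     "epigenetic", "none"))
    p_horm <- ifelse(planted$planted_class == "acquired", 0.35, 0.05)
    hormonal_target <- stats::runif(n) < p_horm
    data.frame(gene_id, chrom, strand, start, end, tss, regulator_class,
               hormonal_target, stringsAsFactors = FALSE)
  })
}

#' Generate the paired birth and unpaired adult datasets
#'
#' Birth: for each twin pair, two samples sharing a gene-wise maternal random
#' intercept (`N(0, mother_sd)` per gene and pair, identical for co-twins —
#' the nuisance a pair-blocked model removes and a library-size normalization
#' cannot); a per-sample activation covariate (FOS-like CPM)
#' additively shifts a random 10% of genes; counts are negative-binomial
#' around `2^(log2 baseline + sex effect + mother + activation effect +
#' log2 library factor)`. Adults: Gaussian log2 intensities with sex effect
#' and residual sd `noise_sd`. Intrinsic genes carry the same-signed sex
#' effect at both stages; acquired genes only in adults.
#'
#' @param annotation output of [gen_annotation()] for the same config.
#' @param config a [sim_config()].
#' @return list with `birth` (`counts` integer matrix + `samples` sheet),
#'   `adult` (`expr` log2 matrix + `samples` sheet) and `truth` (per-gene
#'   `planted_class`, `planted_direction`, `planted_conserved_promoter`).
#' @export
gen_two_stage_study <- function(annotation, config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config",
                                            call. = FALSE)
  if (nrow(annotation) != config$n_genes) {
    stop("annotation does not match config (", nrow(annotation), " vs ",
         config$n_genes, " genes)", call. = FALSE)
  }
  n <- config$n_genes
  planted <- planted_labels(config)
  dir_sign <- ifelse(planted$planted_direction == "female_higher", 1,
                     ifelse(planted$planted_direction == "male_higher", -1, 0))
  birth_effect <- dir_sign * config$lfc_intrinsic *
    (planted$planted_class == "intrinsic")
  adult_effect <- dir_sign *
    ifelse(planted$planted_class == "intrinsic", config$lfc_intrinsic,
           ifelse(planted$planted_class == "acquired", config$lfc_acquired, 0))

  # birth sample sheet: opposite-sex pairs then same-sex pairs (bb then gg)
  n_bb <- floor(config$n_pairs_same / 2)
  n_gg <- config$n_pairs_same - n_bb
  pair_ids <- c(sprintf("BG%02d", seq_len(config$n_pairs_opposite)),
                sprintf("BB%02d", seq_len(n_bb)),
                sprintf("GG%02d", seq_len(n_gg)))
  pair_sex <- c(rep(list(c("F", "M")), config$n_pairs_opposite),
                rep(list(c("M", "M")), n_bb),
                rep(list(c("F", "F")), n_gg))
  birth_samples <- data.frame(
    sample_id = unlist(lapply(seq_along(pair_ids), function(i) {
      paste0(pair_ids[i], "_", c("a", "b"))
    })),
    sex = unlist(pair_sex),
    stage = "birth",
    pair_id = rep(pair_ids, each = 2L),
    stringsAsFactors = FALSE
  )
  n_birth <- nrow(birth_samples)

  with_seed(config$seed + 103L, {
    baseline_birth <- stats::rnorm(n, mean = 9, sd = 1.5)
    # gene x pair maternal effect, shared by co-twins; a per-sample scalar
    # would be indistinguishable from library size and vanish under CPM
    mother <- matrix(stats::rnorm(n * length(pair_ids), 0, config$mother_sd),
                     nrow = n, dimnames = list(NULL, pair_ids))
    activation <- stats::rlnorm(n_birth, meanlog = log(100), sdlog = 0.5)
    act_z <- (activation - mean(activation)) / stats::sd(activation)
    act_genes <- sample.int(n, max(0L, round(0.1 * n)))
    act_beta <- numeric(n)
    act_beta[act_genes] <- stats::rnorm(length(act_genes), 0, 0.5)
    lib_factor <- stats::rlnorm(n_birth, meanlog = 0, sdlog = 0.3)

    sexF <- as.numeric(birth_samples$sex == "F")
    log2mu <- outer(baseline_birth, rep(1, n_birth)) +
      outer(birth_effect, sexF) +
      mother[, birth_samples$pair_id, drop = FALSE] +
      outer(act_beta, act_z) +
      matrix(log2(lib_factor), n, n_birth, byrow = TRUE)
    mu <- 2^log2mu
    counts <- matrix(
      if (config$nb_dispersion > 0) {
        stats::rnbinom(n * n_birth, mu = mu, size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(n * n_birth, lambda = mu)
      },
      nrow = n, ncol = n_birth,
      dimnames = list(annotation$gene_id, birth_samples$sample_id)
    )
    birth_samples$activation <- activation

    # adult cohort
    adult_samples <- data.frame(
      sample_id = c(sprintf("AF%03d", seq_len(config$n_adult_female)),
                    sprintf("AM%03d", seq_len(config$n_adult_male))),
      sex = c(rep("F", config$n_adult_female),
              rep("M", config$n_adult_male)),
      stage = "adult", pair_id = NA_character_, activation = NA_real_,
      stringsAsFactors = FALSE
    )
    n_adult <- nrow(adult_samples)
    baseline_adult <- stats::rnorm(n, mean = 7, sd = 1.5)
    sexF_a <- as.numeric(adult_samples$sex == "F")
    expr <- outer(baseline_adult, rep(1, n_adult)) +
      outer(adult_effect, sexF_a) +
      matrix(stats::rnorm(n * n_adult, 0, config$noise_sd), n, n_adult)
    dimnames(expr) <- list(annotation$gene_id, adult_samples$sample_id)

    truth <- data.frame(
      gene_id = annotation$gene_id,
      planted_class = planted$planted_class,
      planted_direction = planted$planted_direction,
      planted_conserved_promoter = planted$planted_class != "none",
      stringsAsFactors = FALSE
    )

    list(
      birth = list(counts = counts, samples = birth_samples),
      adult = list(expr = expr, samples = adult_samples),
      truth = truth
    )
  })
}

#' Generate a synthetic gene-set collection
#'
#' `n_gene_sets` generic sets of `genes_per_set` genes each, plus three
#' sex-hormonal response subsets (estrogen, androgen, progestin) drawn from
#' the hormonal-target genes of the annotation, and their union as the
#' designated hormonal meta-set (`SEX_HORMONAL_TARGETS`).
#'
#' @param annotation output of [gen_annotation()].
#' @param config a [sim_config()].
#' @return named list of gene-id vectors, with attribute `hormonal_set`
#'   naming the meta-set.
#' @export
gen_gene_sets <- function(annotation, config) {
  if (config$genes_per_set > config$n_genes) {
    stop("genes_per_set exceeds n_genes", call. = FALSE)
  }
  sets <- list()
  with_seed(config$seed + 104L, {
    if (config$n_gene_sets > 0) {
      for (i in seq_len(config$n_gene_sets)) {
        sets[[sprintf("SET%02d", i)]] <-
          sample(annotation$gene_id, config$genes_per_set)
      }
    }
    horm <- annotation$gene_id[annotation$hormonal_target]
    if (length(horm)) {
      for (nm in c("ESTROGEN_RESPONSE", "ANDROGEN_RESPONSE",
                   "PROGESTIN_RESPONSE")) {
        sets[[nm]] <- sort(sample(horm, ceiling(2 * length(horm) / 3)))
      }
      sets[["SEX_HORMONAL_TARGETS"]] <-
        sort(unique(unlist(sets[c("ESTROGEN_RESPONSE", "ANDROGEN_RESPONSE",
                                  "PROGESTIN_RESPONSE")], use.names = FALSE)))
    }
  })
  attr(sets, "hormonal_set") <- "SEX_HORMONAL_TARGETS"
  sets
}

#' Generate a synthetic GWAS-catalog export
#'
#' Writes/returns records in the GWAS-catalog download dialect
#' (tab-separated, `DISEASE/TRAIT`, `STUDY ACCESSION` and `MAPPED_GENE`
#' columns). Some rows carry multi-gene strings joined by `", "` or `" - "`
#' to exercise the splitting rule. The first trait (`"coronary artery
#' disease"`) has `gwas_planted_overlap` of its targets drawn from the
#' planted intrinsic genes, giving the overlap enrichment a ground truth.
#'
#' @param annotation output of [gen_annotation()].
#' @param config a [sim_config()].
#' @param path optional file to write the TSV to.
#' @return `data.frame` of catalog rows (invisibly the path when written).
#' @export
gen_gwas_catalog <- function(annotation, config, path = NULL) {
  planted <- planted_labels(config)
  trait_names <- c("coronary artery disease", "inflammatory bowel disease",
                   "Crohn's disease", "ulcerative colitis",
                   "Alzheimer's disease", "body mass index",
                   "heel bone mineral density", "height", "hypertension",
                   "multiple sclerosis", "rheumatoid arthritis",
                   "type 2 diabetes mellitus")
  rows <- list()
  with_seed(config$seed + 105L, {
    if (config$n_gwas_traits > 0) {
      for (t in seq_len(config$n_gwas_traits)) {
        trait <- if (t <= length(trait_names)) trait_names[t] else
          sprintf("synthetic trait %02d", t)
        n_t <- min(config$genes_per_trait, config$n_genes)
        if (t == 1L && config$gwas_planted_overlap > 0) {
          intr <- annotation$gene_id[planted$planted_class == "intrinsic"]
          n_plant <- min(config$gwas_planted_overlap, length(intr), n_t)
          genes <- c(sample(intr, n_plant),
                     sample(setdiff(annotation$gene_id, intr),
                            n_t - n_plant))
        } else {
          genes <- sample(annotation$gene_id, n_t)
        }
        # fold every 5th pair of genes into one multi-gene row, alternating
        # the comma and hyphen dialects
        i <- 1L
        while (i <= length(genes)) {
          if (i %% 5L == 0L && i < length(genes)) {
            sep <- if (i %% 10L == 0L) " - " else ", "
            mapped <- paste(genes[i], genes[i + 1L], sep = sep)
            i <- i + 2L
          } else {
            mapped <- genes[i]
            i <- i + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            `DISEASE/TRAIT` = trait,
            `STUDY ACCESSION` = sprintf("GCST%06d", t * 1000L + length(rows)),
            MAPPED_GENE = mapped,
            check.names = FALSE, stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  catalog <- if (length(rows)) do.call(rbind, rows) else
    data.frame(`DISEASE/TRAIT` = character(0L),
               `STUDY ACCESSION` = character(0L),
               MAPPED_GENE = character(0L), check.names = FALSE,
               stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  catalog
}

#' Generate a synthetic conservation score track
#'
#' Per-interval (10 bp resolution) scores in `[0, 1]` covering every
#' annotated gene body and promoter window, with background scores uniform
#' on `[0, 0.6]`. Genes with a planted conserved promoter get
#' `promoter_conservation_boost` added over their promoter window, clipped
#' at 1. Gene coordinates from [gen_annotation()] are 10-base aligned, so
#' promoter boundaries coincide with chunk boundaries and the planted boost
#' covers the window exactly.
#'
#' @param annotation output of [gen_annotation()].
#' @param config a [sim_config()].
#' @param path optional bedGraph file to write.
#' @return score track `data.frame` (`chrom`, `start`, `end`, `score`,
#'   0-based half-open), or invisibly the path when written.
#' @export
gen_conservation_track <- function(annotation, config, path = NULL) {
  planted <- planted_labels(config)
  boosted <- planted$planted_class != "none"
  prom <- promoter_window(annotation, 200L, 100L)
  chunk <- 10L
  pieces <- vector("list", nrow(annotation))
  with_seed(config$seed + 106L, {
    for (g in seq_len(nrow(annotation))) {
      lo <- max(0L, min(annotation$start[g], prom$start[g]) - 100L)
      hi <- max(annotation$end[g], prom$end[g]) + 100L
      lo <- chunk * (lo %/% chunk)
      starts <- seq.int(lo, hi - 1L, by = chunk)
      score <- stats::runif(length(starts), 0, 0.6)
      if (boosted[g] && config$promoter_conservation_boost > 0) {
        in_prom <- starts >= prom$start[g] & starts < prom$end[g]
        score[in_prom] <- pmin(1, score[in_prom] +
                                 config$promoter_conservation_boost)
      }
      pieces[[g]] <- data.frame(chrom = annotation$chrom[g], start = starts,
                                end = starts + chunk, score = score,
                                stringsAsFactors = FALSE)
    }
  })
  track <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(0L), start = integer(0L), end = integer(0L),
               score = numeric(0L), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_bedgraph(track, path)
    return(invisible(path))
  }
  track
}
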