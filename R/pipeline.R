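## End-to-end orchestration: simulate -> fixed-diff -> ase -> bias -> de ->
## dosage -> enrich -> report. Every stage writes its outputs under the run
## directory and is skipped on resume when they already exist; the report
## carries per-stage record counts, the package version and a config hash.

#' Pipeline configuration
#'
#' @param out_dir run directory for intermediates and the report.
#' @param sim a [sim_config()] describing the synthetic dataset.
#' @param thresholds a [filter_thresholds()].
#' @param alpha significance level for classifications.
#' @param pseudocount pseudocount for log2 ratios.
#' @param n_bins bins for [grouped_total_expression_test()].
#' @param ancestry,geography named population-to-group vectors for
#'   [fit_ancestry_geography_model()].
#' @param seed integer seed (overrides `sim$seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            thresholds = filter_thresholds(),
                            alpha = 0.05, pseudocount = 0.5, n_bins = 4,
                            ancestry = c(south_america = "native",
                                         north_america = "invasive", taiwan = "invasive"),
                            geography = c(south_america = "americas",
                                          north_america = "americas", taiwan = "taiwan"),
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, sim = sim, thresholds = thresholds,
                 alpha = alpha, pseudocount = pseudocount, n_bins = n_bins,
                 ancestry = ancestry, geography = geography),
            class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # hash analysis parameters, not the run location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                              auto_unbox = TRUE, force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes all stages in order, writing fixtures and per-stage TSVs under
#' `config$out_dir`, and returns (and writes as `report.json`) a run report
#' keyed to the study's hypothesis list: fixed allelic differences,
#' consistency of allelic bias, ancestry vs geography, body-part effects,
#' social-bias enrichment and direction, the dosage-compensation curve
#' comparison, the degeneration regression and the quadrant classification.
#' Identical seeds give identical reports.
#'
#' @param config a [pipeline_config()].
#' @param resume skip stages whose outputs already exist.
#' @return the run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  fx <- file.path(out, "fixtures")
  stage_done <- function(f) resume && all(file.exists(f))
  counts <- list()

  ## -- simulate ----------------------------------------------------------
  if (!stage_done(file.path(fx, "genotypes.vcf"))) {
    sim <- simulate_dataset(config$sim)
    write_fixtures(sim, fx)
  }
  panel <- read_vcf(file.path(fx, "genotypes.vcf"))
  cohort_df <- read_tsv(file.path(fx, "cohort.tsv"))
  cohort <- haploid_cohort(cohort_df$id, cohort_df$variant, cohort_df$population)
  region <- read_bed(file.path(fx, "supergene.bed"))
  models <- read_gene_models(file.path(fx, "genes.gff3"), file.path(fx, "cds.fasta"))
  snp_counts <- read_tsv(file.path(fx, "snp_counts.tsv"))
  meta <- read_tsv(file.path(fx, "meta.tsv"))
  expr_df <- read_tsv(file.path(fx, "expression.tsv"))
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene
  truth_genes <- read_tsv(file.path(fx, "truth_genes.tsv"))
  counts$samples <- nrow(meta)
  counts$genes <- nrow(expr)

  ## -- fixed differences (per population, then intersected) -------------
  fd_file <- file.path(out, "fixed_differences.tsv")
  pops_with_males <- unique(cohort$population)
  per_pop <- lapply(pops_with_males, function(pop) {
    sub <- cohort[cohort$population == pop, , drop = FALSE]
    class(sub) <- class(cohort)
    filt <- filter_sites(panel, sub, config$thresholds)
    fd <- call_fixed_differences(filt, sub)
    restrict_to_region(fd, region)
  })
  names(per_pop) <- pops_with_males
  shared <- Reduce(function(a, b) intersect_fixed_sets(a, b)$shared, per_pop)
  shared <- classify_coding_effect(shared, models)
  write_tsv(shared, fd_file)
  counts$fixed_differences <- nrow(shared)
  counts$fixed_differences_per_population <- vapply(per_pop, nrow, integer(1))

  ## -- ase ----------------------------------------------------------------
  gene_counts <- summarize_allele_counts(snp_counts)
  gene_counts <- gene_counts[gene_counts$gene %in% unique(shared$gene), , drop = FALSE]
  het_meta <- meta[meta$genotype == "SB/Sb", , drop = FALSE]
  expressed <- filter_expressed(gene_counts, het_meta, "all_samples")
  gene_counts <- gene_counts[gene_counts$gene %in% expressed, , drop = FALSE]
  write_tsv(gene_counts, file.path(out, "gene_allele_counts.tsv"))
  counts$expressed_genes <- length(expressed)

  ## -- allelic bias -------------------------------------------------------
  obs <- build_bias_observations(gene_counts, meta, config$pseudocount)
  joint <- fit_joint_model(obs, config$alpha)
  write_tsv(joint$genes, file.path(out, "allelic_bias_joint.tsv"))
  per_pop_bias <- test_allelic_bias_per_population(gene_counts, meta)
  write_tsv(per_pop_bias, file.path(out, "allelic_bias_per_population.tsv"))
  ratio_tab <- tapply(obs$ratio, list(obs$gene, obs$population), mean)
  r2 <- correlate_populations(ratio_tab)
  med <- median_bias_test(rowMeans(ratio_tab, na.rm = TRUE))
  sa_meta <- meta[meta$population == "south_america" & meta$genotype == "SB/Sb", ]
  bp_res <- NULL
  if (nrow(sa_meta) && length(unique(sa_meta$body_part)) >= 2) {
    sa_counts <- gene_counts[gene_counts$sample %in% sa_meta$sample, , drop = FALSE]
    bp_res <- test_body_part_interaction(sa_counts, sa_meta)
  }
  anc_geo <- if (length(unique(obs$population)) >= 3)
    fit_ancestry_geography_model(obs, config$ancestry, config$geography) else NULL

  ## -- social de ----------------------------------------------------------
  de_meta <- meta[meta$caste == "queen" &
                  meta$social_form %in% c("single_queen", "multiple_queen") &
                  meta$population == "north_america", , drop = FALSE]
  de <- wald_test_social(expr[, de_meta$sample, drop = FALSE], de_meta)
  write_tsv(de, file.path(out, "social_de.tsv"))
  counts$socially_biased <- sum(de$padj < config$alpha, na.rm = TRUE)

  ## -- dosage compensation ------------------------------------------------
  sf_all <- estimate_size_factors(expr, pseudo_reference = TRUE)
  het_na <- meta$sample[meta$genotype == "SB/Sb" & meta$population == "north_america"]
  gc_na <- gene_counts[gene_counts$sample %in% het_na, , drop = FALSE]
  gc_na$x_B <- gc_na$x_B / sf_all[gc_na$sample]
  gc_na$x_b <- gc_na$x_b / sf_all[gc_na$sample]
  allele_means <- do.call(rbind, lapply(split(gc_na, gc_na$gene), function(d)
    data.frame(gene = d$gene[1], x_B = mean(d$x_B), x_b = mean(d$x_b))))
  social_means <- data.frame(gene = de$gene, x_SQ = de$mean_SQ, x_MQ = de$mean_MQ)
  points <- compute_proportions(allele_means, social_means)
  write_tsv(points, file.path(out, "proportions.tsv"))
  reg <- if (nrow(points) >= 3) fit_regression(points) else NULL
  cmp <- if (nrow(points) >= 3) compare_curves(points) else NULL
  nonsyn <- tapply(shared$effect %in% c("nonsynonymous", "stop_gained"),
                   shared$gene, sum)
  am <- allele_means[allele_means$gene %in% names(nonsyn), , drop = FALSE]
  deg <- if (nrow(am) >= 3)
    regress_nonsyn_bias(as.integer(nonsyn[am$gene]),
                        log2_ratio(am$x_B, am$x_b, config$pseudocount)) else NULL
  na_bias <- per_pop_bias[per_pop_bias$population == "north_america", , drop = FALSE]
  grouped <- if (nrow(points) >= 8 && nrow(na_bias))
    grouped_total_expression_test(points, na_bias, config$alpha, config$n_bins) else NULL

  ## -- enrichment & quadrants --------------------------------------------
  gene_region <- data.frame(
    gene = de$gene,
    region = ifelse(de$gene %in% truth_genes$gene_id[truth_genes$region == "supergene"],
                    "supergene", "background"),
    biased = !is.na(de$padj) & de$padj < config$alpha)
  names(gene_region)[2] <- "region"
  enr <- tryCatch(region_enrichment(gene_region), error = function(e) NULL)
  k_mq <- sum(gene_region$biased & de$lfc > 0, na.rm = TRUE)
  n_biased <- sum(gene_region$biased)
  dir_test <- if (n_biased > 0)
    list(k_MQ = k_mq, n = n_biased, percent_MQ = round(100 * k_mq / n_biased),
         p = binom_two_sided(k_mq, n_biased)) else NULL
  quad <- classify_quadrants(
    setNames(na_bias[, c("gene", "lfc", "padj")], c("gene", "lfc", "padj")),
    de[de$gene %in% na_bias$gene, c("gene", "lfc", "padj")], config$alpha)
  write_tsv(quad$labels, file.path(out, "quadrants.tsv"))

  report <- list(
    package_version = as.character(utils::packageVersion("supergeneASE")),
    seed = config$sim$seed,
    config_hash = config_hash(config),
    stage_counts = counts,
    hypotheses = list(
      fixed_allelic_differences = list(
        n_snps = counts$fixed_differences,
        n_genes = length(unique(shared$gene)),
        effects = as.list(table(shared$effect))),
      allelic_bias_consistent_across_populations = list(
        n_tested = nrow(joint$genes),
        n_significant = sum(joint$genes$padj < config$alpha, na.rm = TRUE),
        method = joint$method,
        median_ratio = med$median, median_p = med$p),
      correlation_by_relatedness = as.list(
        setNames(r2[upper.tri(r2)],
                 outer(rownames(r2), colnames(r2), paste, sep = "_vs_")[upper.tri(r2)])),
      ancestry_vs_geography = if (!is.null(anc_geo))
        setNames(lapply(seq_len(nrow(anc_geo)), function(i)
          list(F = anc_geo$F[i], p = anc_geo$p[i])), anc_geo$term) else NULL,
      no_body_part_effect = if (!is.null(bp_res)) list(
        n_tests = nrow(bp_res),
        n_significant = sum(bp_res$padj < config$alpha, na.rm = TRUE)) else NULL,
      social_bias_enriched_in_supergene = if (!is.null(enr)) list(
        chi2 = enr$test$statistic, p = enr$test$p.value,
        observed = unname(enr$table[1, 1]),
        expected = enr$expected_biased_supergene) else NULL,
      social_bias_direction_genome_wide = dir_test,
      balanced_expression_regression = if (!is.null(reg)) list(
        fit_at_half = reg$fit_at_half, deviation = reg$deviation, p = reg$p) else NULL,
      dosage_compensation_model = if (!is.null(cmp)) list(
        preferred = cmp$preferred, rss_null = cmp$rss_null,
        rss_compensation = cmp$rss_compensation, p = cmp$p) else NULL,
      degeneration_increases_sb_bias = if (!is.null(deg)) list(
        coefficient = deg$coefficient, p = deg$p) else NULL,
      grouped_total_expression = if (!is.null(grouped))
        list(n_bins = nrow(grouped), min_p = min(grouped$p, na.rm = TRUE)) else NULL,
      quadrant_classification = as.list(table(quad$labels$class))))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
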