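## Synthetic fire-ant supergene cohorts with known per-gene regimes.
##
## The generator states a small world: two haplotype groups (SB, Sb) of
## haploid males with fixed differences; an invasion bottleneck thinning
## segregating variation; heterozygous SB/Sb RNA samples whose gene totals
## are negative-binomial and whose allele splits are (beta-)binomial; and
## four gene regimes (neutral, degenerate, compensated, antagonistic) plus a
## genome background with a strong multiple-queen bias among socially biased
## genes.

REGIMES <- c("neutral", "degenerate", "compensated", "antagonistic")

default_populations <- function() list(
  list(name = "south_america", ancestry = "native",   geography = "americas",
       bottleneck = 1.0, n_SB_males = 13, n_Sb_males = 13),
  list(name = "north_america", ancestry = "invasive", geography = "americas",
       bottleneck = 0.2, n_SB_males = 7, n_Sb_males = 7),
  list(name = "taiwan",        ancestry = "invasive", geography = "taiwan",
       bottleneck = 0.2, n_SB_males = 0, n_Sb_males = 0))

default_samples <- function() rbind(
  data.frame(population = "south_america", caste = "worker",
             body_part = "whole", social_form = "multiple_queen",
             genotype = "SB/Sb", n = 6),
  data.frame(population = "south_america", caste = "queen",
             body_part = c("head", "thorax", "abdomen"),
             social_form = "multiple_queen", genotype = "SB/Sb", n = 6),
  data.frame(population = "north_america", caste = "queen", body_part = "whole",
             social_form = c("multiple_queen", "single_queen"),
             genotype = c("SB/Sb", "SB/SB"), n = 6),
  data.frame(population = "taiwan", caste = "queen", body_part = "whole",
             social_form = "multiple_queen", genotype = "SB/Sb", n = 6))

#' Simulation configuration
#'
#' Defaults encode the study design being emulated: a native South American
#' panel of 13 SB + 13 Sb males with full diversity, invasive panels with a
#' strong bottleneck (0.2), queen/worker RNA replicates across body parts, and
#' a background gene set in which ~10% of genes are socially biased, 94% of
#' them toward multiple-queen colonies.
#'
#' @param n_genes_supergene,n_genes_background gene counts (> 0 supergene).
#' @param regime_mix named proportions over
#'   `neutral`, `degenerate`, `compensated`, `antagonistic`; must sum to 1.
#' @param populations list of population descriptors: `name`, `ancestry`,
#'   `geography`, `bottleneck` in (0,1], `n_SB_males`, `n_Sb_males`.
#' @param samples data.frame of RNA sample groups: `population`, `caste`,
#'   `body_part`, `social_form`, `genotype`, `n` replicates.
#' @param mean_expression_log_mu,mean_expression_log_sd lognormal parameters
#'   for per-gene mean expression (reads per gene per sample).
#' @param nb_dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha mu^2); 0 gives Poisson totals.
#' @param allele_split_overdispersion beta-binomial rho in [0,1) for the
#'   SB/Sb split; 0 gives binomial splits.
#' @param degeneration_slope shift in log2 allelic ratio per non-synonymous
#'   mutation for degenerate genes.
#' @param snps_per_gene_lambda Poisson mean for extra fixed SNPs per supergene
#'   gene (every gene gets at least one).
#' @param segregating_per_gene expected segregating (non-fixed) sites per gene
#'   in a population without bottleneck; thinned by `bottleneck`.
#' @param filter_violation_rate fraction of sites given exactly one
#'   quality-filter violation (for filter testing).
#' @param background_bias_prop fraction of background genes socially biased.
#' @param background_mq_direction probability a biased background gene is
#'   biased toward multiple-queen colonies.
#' @param ancestry_effect_sd sd (log2-odds scale) of per-gene allelic-bias
#'   offsets shared within an ancestry group; 0 (default) makes all
#'   populations identical.
#' @param size_factor_log_sd lognormal sd of per-sample library size factors.
#' @param mean_depth_genomic mean per-individual depth at genotyped sites.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes_supergene = 40,
                       n_genes_background = 160,
                       regime_mix = c(neutral = 0.4, degenerate = 0.25,
                                      compensated = 0.2, antagonistic = 0.15),
                       populations = default_populations(),
                       samples = default_samples(),
                       mean_expression_log_mu = log(500),
                       mean_expression_log_sd = 1,
                       nb_dispersion = 0.05,
                       allele_split_overdispersion = 0.02,
                       degeneration_slope = 0.05,
                       snps_per_gene_lambda = 2,
                       segregating_per_gene = 2,
                       filter_violation_rate = 0.1,
                       background_bias_prop = 0.10,
                       background_mq_direction = 0.94,
                       ancestry_effect_sd = 0,
                       size_factor_log_sd = 0.15,
                       mean_depth_genomic = 8,
                       seed = 1L) {
  if (n_genes_supergene < 1) stop_input("n_genes_supergene must be positive")
  if (n_genes_background < 0) stop_input("n_genes_background must be non-negative")
  if (!setequal(names(regime_mix), REGIMES)) stop_input("regime_mix must name all four regimes")
  if (abs(sum(regime_mix) - 1) > 1e-9) stop_input("regime proportions must sum to 1")
  if (any(regime_mix < 0)) stop_input("regime proportions must be non-negative")
  for (p in populations) {
    if (p$bottleneck <= 0 || p$bottleneck > 1) stop_input("bottleneck must lie in (0, 1]")
    if (p$n_SB_males < 0 || p$n_Sb_males < 0) stop_input("male counts must be non-negative")
  }
  stopifnot(is.data.frame(samples),
            all(c("population", "caste", "body_part", "social_form", "genotype", "n") %in% names(samples)))
  if (any(samples$genotype == "SB/Sb" & samples$social_form != "multiple_queen"))
    stop_input("SB/Sb heterozygotes occur only in multiple-queen colonies")
  if (nb_dispersion < 0) stop_input("nb_dispersion must be >= 0")
  if (allele_split_overdispersion < 0 || allele_split_overdispersion >= 1)
    stop_input("allele_split_overdispersion must lie in [0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

logit2 <- function(p) log2(p / (1 - p))
plogis2 <- function(x) 2^x / (1 + 2^x)

rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(rbinom(n, size, prob))
  shape <- (1 - rho) / rho
  rbinom(n, size, rbeta(n, prob * shape, (1 - prob) * shape))
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- apply(matrix(sample(BASES, 3 * (n_codons - 1), replace = TRUE), ncol = 3),
                  1L, paste, collapse = "")
  while (any(codons %in% STOPS))
    codons[codons %in% STOPS] <- replicate(sum(codons %in% STOPS),
      paste(sample(BASES, 3, replace = TRUE), collapse = ""))
  paste(c("ATG", codons[-1], "TAA"), collapse = "")
}

## Plus-strand reference base at a genomic position of a gene, given its model.
## Returns NA for non-CDS positions (their reference base is free).
plus_strand_cds_base <- function(pos, gene_row, cds, cds_seq) {
  cpos <- cds_coordinate(pos, cds, gene_row$strand)
  if (is.na(cpos)) return(NA_character_)
  b <- substr(cds_seq, cpos, cpos)
  if (gene_row$strand == "-") COMPLEMENT[[b]] else b
}

build_gene_models <- function(config) {
  n_sg <- config$n_genes_supergene
  n_bg <- config$n_genes_background
  make <- function(ids, chrom) {
    cursor <- 1000L
    genes <- vector("list", length(ids)); cds <- vector("list", length(ids))
    utr <- vector("list", length(ids)); seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      n_codons <- sample(100:200, 1)
      len_cds <- 3L * n_codons
      len1 <- 3L * sample(30:(n_codons - 30), 1)     # exon split, codon-aligned
      strand <- sample(c("+", "-"), 1)
      utr5 <- 30L; intron <- 90L; utr3 <- 30L
      start <- cursor
      cds1 <- c(start + utr5, start + utr5 + len1 - 1L)
      cds2 <- c(cds1[2] + intron + 1L, cds1[2] + intron + (len_cds - len1))
      end <- cds2[2] + utr3
      genes[[i]] <- data.frame(gene_id = ids[i], chrom = chrom, strand = strand,
                               start = start, end = end)
      cds[[i]] <- data.frame(gene_id = ids[i], chrom = chrom,
                             start = c(cds1[1], cds2[1]), end = c(cds1[2], cds2[2]))
      utr[[i]] <- data.frame(gene_id = ids[i], chrom = chrom,
                             start = c(start, cds2[2] + 1L),
                             end = c(cds1[1] - 1L, end))
      seqs[i] <- random_cds(n_codons)
      cursor <- end + 400L
    }
    list(genes = do.call(rbind, genes), cds = do.call(rbind, cds),
         utr = do.call(rbind, utr), seqs = setNames(seqs, ids), span = cursor)
  }
  sg <- make(sprintf("sg_gene_%03d", seq_len(n_sg)), "social_chr")
  bg <- if (n_bg > 0) make(sprintf("bg_gene_%03d", seq_len(n_bg)), "chr_bg") else
    list(genes = sg$genes[0, ], cds = sg$cds[0, ], utr = sg$utr[0, ],
         seqs = character(0), span = 0L)
  models <- gene_models(rbind(sg$genes, bg$genes), rbind(sg$cds, bg$cds),
                        rbind(sg$utr, bg$utr), c(sg$seqs, bg$seqs))
  region <- data.frame(chrom = "social_chr", start = 1L,
                       end = as.integer(sg$span + 200L), name = "supergene")
  list(models = models, region = region)
}

## Whole-protein translation of reference vs mutant CDS: the generator-side
## effect oracle, independent of classify_coding_effect's codon lookup.
effect_by_translation <- function(pos, sb, lb, gene_row, cds, utr, cds_seq) {
  cpos <- cds_coordinate(pos, cds, gene_row$strand)
  if (is.na(cpos)) {
    in_utr <- nrow(utr) > 0 && any(utr$start <= pos & utr$end >= pos)
    return(if (in_utr) "UTR" else "intronic")
  }
  alt <- if (gene_row$strand == "-") COMPLEMENT[[lb]] else lb
  mut <- cds_seq
  substr(mut, cpos, cpos) <- alt
  ## no.init.codon: treat codon 1 literally, not as an alternative initiator
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                              no.init.codon = TRUE))
  p_mut <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                              no.init.codon = TRUE))
  if (p_ref == p_mut) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
  if (substr(p_mut, i, i) == "*") "stop_gained" else "nonsynonymous"
}

#' Simulate haploid male cohorts with fixed and segregating variation
#'
#' Builds gene models for the supergene and the genome background, assigns
#' every supergene gene at least one fixed SB/Sb difference (1 plus a Poisson
#' extra count), annotates each fixed SNP's coding effect by whole-protein
#' translation, adds population-specific segregating sites thinned by the
#' bottleneck factor, and draws per-individual depths and allele-support
#' fractions such that `filter_violation_rate` of sites each violate exactly
#' one site filter.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` ([haploid_cohort()]), `panel`
#'   ([variant_panel()]), `models` ([gene_models()]), `region` (supergene
#'   interval, 1-based), and `truth` (a `ground_truth` list: `genes`, `sites`,
#'   `P_B` matrix, `populations`).
#' @export
simulate_haploid_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gm <- build_gene_models(config)
  models <- gm$models
  sg_ids <- models$genes$gene_id[models$genes$chrom == "social_chr"]
  bg_ids <- setdiff(models$genes$gene_id, sg_ids)

  ## --- fixed differences -------------------------------------------------
  site_rows <- list()
  nonsyn <- setNames(integer(length(sg_ids)), sg_ids)
  for (gid in sg_ids) {
    g <- models$genes[models$genes$gene_id == gid, ]
    cds <- models$cds[models$cds$gene_id == gid, ]
    utr <- models$utr[models$utr$gene_id == gid, ]
    n_snp <- 1L + rpois(1, config$snps_per_gene_lambda)
    pos <- sort(sample(seq(g$start - 100L, g$end + 100L), n_snp))
    for (p in pos) {
      ref <- plus_strand_cds_base(p, g, cds, models$cds_seq[[gid]])
      if (is.na(ref)) ref <- sample(BASES, 1)
      alt <- sample(setdiff(BASES, ref), 1)
      eff <- effect_by_translation(p, ref, alt, g, cds, utr, models$cds_seq[[gid]])
      if (eff %in% c("nonsynonymous", "stop_gained")) nonsyn[gid] <- nonsyn[gid] + 1L
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(chrom = g$chrom, pos = p, SB_allele = ref, Sb_allele = alt,
                   gene = gid, type = "fixed", population = NA_character_,
                   effect = eff, stringsAsFactors = FALSE)
    }
  }

  ## --- cohort ------------------------------------------------------------
  pops <- do.call(rbind, lapply(config$populations, function(p)
    data.frame(name = p$name, ancestry = p$ancestry, geography = p$geography,
               bottleneck = p$bottleneck, n_SB = p$n_SB_males, n_Sb = p$n_Sb_males,
               stringsAsFactors = FALSE)))
  ind <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    p <- pops[i, ]
    if (p$n_SB + p$n_Sb == 0) return(NULL)
    data.frame(id = c(sprintf("%s_SB_%02d", p$name, seq_len(p$n_SB)),
                      sprintf("%s_Sb_%02d", p$name, seq_len(p$n_Sb))),
               variant = rep(c("SB", "Sb"), c(p$n_SB, p$n_Sb)),
               population = p$name, stringsAsFactors = FALSE)
  }))
  if (is.null(ind) || !nrow(ind)) stop_input("no genotyped males in any population")
  cohort <- haploid_cohort(ind$id, ind$variant, ind$population)

  ## --- segregating sites (thinned by bottleneck) -------------------------
  region_len <- gm$region$end - gm$region$start + 1L
  used <- unique(vapply(site_rows, function(r) r$pos, numeric(1)))
  for (i in seq_len(nrow(pops))) {
    p <- pops[i, ]
    if (p$n_SB + p$n_Sb < 2) next
    n_seg <- rpois(1, config$n_genes_supergene * config$segregating_per_gene * p$bottleneck)
    if (!n_seg) next
    avail <- setdiff(seq_len(region_len), used)
    pos <- sample(avail, min(n_seg, length(avail)))
    used <- c(used, pos)
    for (pp in pos) {
      ref <- sample(BASES, 1)
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(chrom = "social_chr", pos = pp, SB_allele = ref,
                   Sb_allele = sample(setdiff(BASES, ref), 1),
                   gene = NA_character_, type = "segregating", population = p$name,
                   effect = NA_character_, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL

  ## --- genotypes ---------------------------------------------------------
  n_site <- nrow(sites); n_ind <- nrow(cohort)
  gt <- matrix(NA_character_, n_site, n_ind, dimnames = list(NULL, cohort$id))
  for (i in seq_len(n_site)) {
    if (sites$type[i] == "fixed") {
      gt[i, ] <- ifelse(cohort$variant == "SB", sites$SB_allele[i], sites$Sb_allele[i])
    } else {
      gt[i, ] <- sites$SB_allele[i]
      grp <- which(cohort$population == sites$population[i] &
                   cohort$variant == sample(c("SB", "Sb"), 1))
      if (length(grp) >= 2) {
        carriers <- sample(grp, max(1L, rbinom(1, length(grp) - 1L, 0.5)))
        gt[i, carriers] <- sites$Sb_allele[i]
      }
    }
  }

  ## --- depths, support fractions, quality, injected violations -----------
  dp <- matrix(1L + rpois(n_site * n_ind, config$mean_depth_genomic - 1), n_site, n_ind,
               dimnames = list(NULL, cohort$id))
  af <- matrix(runif(n_site * n_ind, 0.85, 1), n_site, n_ind,
               dimnames = list(NULL, cohort$id))
  qual <- runif(n_site, 30, 1000)
  sites$filter_pass <- TRUE
  n_viol <- round(config$filter_violation_rate * n_site)
  if (n_viol > 0) {
    viol <- sample(n_site, n_viol)
    kind <- rep_len(c("qual", "depth0", "high_depth", "low_af"), n_viol)
    for (k in seq_len(n_viol)) {
      i <- viol[k]
      switch(kind[k],
             qual = { qual[i] <- runif(1, 1, 24) },
             depth0 = { dp[i, sample(n_ind, 1)] <- 0L },
             high_depth = { dp[i, ] <- 40L + rpois(n_ind, 5) },
             low_af = { af[i, sample(n_ind, 1)] <- runif(1, 0.1, 0.59) })
      sites$filter_pass[i] <- FALSE
    }
  }
  site_df <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$SB_allele,
                        alt = sites$Sb_allele, qual = qual, stringsAsFactors = FALSE)
  panel <- variant_panel(site_df, gt, dp, af)

  ## --- per-gene ground truth ---------------------------------------------
  regime <- sample(REGIMES, length(sg_ids), replace = TRUE,
                   prob = config$regime_mix[REGIMES])
  s <- config$degeneration_slope
  p_b <- vapply(seq_along(sg_ids), function(i) switch(regime[i],
    neutral = 0.5,
    degenerate = plogis2(s * nonsyn[[sg_ids[i]]]),
    compensated = runif(1, 0.65, 0.9),
    antagonistic = runif(1, 0.15, 0.4)), numeric(1))
  ## antagonistic social effects are 2-4 fold: the regime must be recoverable
  ## by the downstream classifier at stated depths (module invariant), and
  ## candidate genes in this system show clear multi-fold social bias
  lfc_mq <- vapply(seq_along(sg_ids), function(i) switch(regime[i],
    neutral = 0,
    degenerate = log2(1 / (2 * p_b[i])),
    compensated = 0,
    antagonistic = runif(1, 1, 2)), numeric(1))

  bg_biased <- if (length(bg_ids)) runif(length(bg_ids)) < config$background_bias_prop else logical(0)
  bg_dir <- ifelse(runif(length(bg_ids)) < config$background_mq_direction, 1, -1)
  bg_lfc <- ifelse(bg_biased, bg_dir * runif(length(bg_ids), 0.5, 2), 0)

  genes <- data.frame(
    gene_id = c(sg_ids, bg_ids),
    region = rep(c("supergene", "background"), c(length(sg_ids), length(bg_ids))),
    regime = c(regime, rep("background", length(bg_ids))),
    true_P_B = c(p_b, rep(NA_real_, length(bg_ids))),
    true_lfc_mq = c(lfc_mq, bg_lfc),
    nonsyn_count = c(unname(nonsyn[sg_ids]), rep(NA_integer_, length(bg_ids))),
    socially_biased = c(lfc_mq != 0, bg_biased),
    stringsAsFactors = FALSE)

  ## per-population allelic proportions: log2-odds offsets shared within an
  ## ancestry group, so populations of shared ancestry have correlated biases
  P_B <- matrix(rep(p_b, nrow(pops)), ncol = nrow(pops),
                dimnames = list(sg_ids, pops$name))
  if (config$ancestry_effect_sd > 0) {
    for (anc in unique(pops$ancestry)) {
      delta <- rnorm(length(sg_ids), 0, config$ancestry_effect_sd)
      for (pn in pops$name[pops$ancestry == anc])
        P_B[, pn] <- plogis2(logit2(pmin(pmax(p_b, 1e-6), 1 - 1e-6)) + delta)
    }
  }

  truth <- structure(list(genes = genes, sites = sites, P_B = P_B, populations = pops),
                     class = "ground_truth")
  list(cohort = cohort, panel = panel, models = models, region = gm$region,
       truth = truth)
}

#' Simulate RNA-seq count tables from a ground truth
#'
#' Per gene g and sample s, totals are
#' \eqn{T_{gs} \sim NB(\mu_g s_s 2^{l_g[s\,is\,MQ]}, \alpha)}; in SB/Sb
#' heterozygotes the SB share is beta-binomial,
#' \eqn{x_B \sim BetaBin(T_{gs}, P_B, \rho)}, with \eqn{x_b = T - x_B}.
#' SNP-level counts re-sample the gene split per SNP by multinomial
#' distribution of `n_snps * x` reads over the gene's SNPs, so each SNP's
#' count varies around the gene value and the per-gene median recovers it.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_haploid_cohort()].
#' @return list with `snp_counts` (sample, chrom, pos, gene, reads_SB,
#'   reads_Sb), `gene_counts` (gene, sample, x_B, x_b), `expr` (gene x sample
#'   integer matrix of totals), `meta` (sample metadata).
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(derive_seed(config$seed, 2L))
  genes <- truth$genes
  ## sample sheet expansion
  sm <- config$samples
  meta <- do.call(rbind, lapply(seq_len(nrow(sm)), function(i) {
    r <- sm[i, ]
    if (r$n < 1) return(NULL)
    data.frame(sample = sprintf("%s_%s_%s_%s_%d", r$population,
                                sub("_queen", "q", r$social_form), r$caste,
                                r$body_part, seq_len(r$n)),
               population = r$population, caste = r$caste, body_part = r$body_part,
               colony = sprintf("%s_col%d", r$population, seq_len(r$n)),
               social_form = r$social_form, genotype = r$genotype,
               stringsAsFactors = FALSE)
  }))
  if (is.null(meta)) meta <- data.frame(sample = character(), population = character(),
                                        caste = character(), body_part = character(),
                                        colony = character(), social_form = character(),
                                        genotype = character(), stringsAsFactors = FALSE)
  n_s <- nrow(meta); n_g <- nrow(genes)
  mu <- rlnorm(n_g, config$mean_expression_log_mu, config$mean_expression_log_sd)
  sf <- rlnorm(n_s, 0, config$size_factor_log_sd)
  is_mq <- meta$social_form == "multiple_queen"
  expr <- matrix(0L, n_g, n_s, dimnames = list(genes$gene_id, meta$sample))
  for (j in seq_len(n_s)) {
    m <- mu * sf[j] * (if (is_mq[j]) 2^genes$true_lfc_mq else rep(1, n_g))
    expr[, j] <- if (config$nb_dispersion > 0)
      rnbinom(n_g, mu = m, size = 1 / config$nb_dispersion) else rpois(n_g, m)
  }

  ## allele-resolved counts in heterozygotes, supergene genes only
  het <- which(meta$genotype == "SB/Sb")
  sg <- which(genes$region == "supergene")
  fixed_sites <- truth$sites[truth$sites$type == "fixed", ]
  gc_rows <- list(); snp_rows <- list()
  for (j in het) {
    pop <- meta$population[j]
    pb <- if (pop %in% colnames(truth$P_B)) truth$P_B[genes$gene_id[sg], pop]
          else truth$genes$true_P_B[sg]
    tot <- expr[sg, j]
    xb <- rbetabinom(length(sg), tot, pb, config$allele_split_overdispersion)
    gc_rows[[length(gc_rows) + 1L]] <-
      data.frame(gene = genes$gene_id[sg], sample = meta$sample[j],
                 x_B = xb, x_b = tot - xb, stringsAsFactors = FALSE)
    for (k in seq_along(sg)) {
      gid <- genes$gene_id[sg[k]]
      snps <- fixed_sites[fixed_sites$gene == gid, ]
      ns <- nrow(snps)
      if (!ns) next
      per_B <- as.vector(rmultinom(1, ns * xb[k], rep(1 / ns, ns)))
      per_b <- as.vector(rmultinom(1, ns * (tot[k] - xb[k]), rep(1 / ns, ns)))
      snp_rows[[length(snp_rows) + 1L]] <-
        data.frame(sample = meta$sample[j], chrom = snps$chrom, pos = snps$pos,
                   gene = gid, reads_SB = per_B, reads_Sb = per_b,
                   stringsAsFactors = FALSE)
    }
  }
  empty_gc <- data.frame(gene = character(), sample = character(),
                         x_B = integer(), x_b = integer(), stringsAsFactors = FALSE)
  empty_snp <- data.frame(sample = character(), chrom = character(), pos = integer(),
                          gene = character(), reads_SB = integer(), reads_Sb = integer(),
                          stringsAsFactors = FALSE)
  snp_counts <- if (length(snp_rows)) do.call(rbind, snp_rows) else empty_snp
  gene_counts <- if (length(gc_rows)) do.call(rbind, gc_rows) else empty_gc
  rownames(snp_counts) <- rownames(gene_counts) <- rownames(meta) <- NULL
  list(snp_counts = snp_counts, gene_counts = gene_counts, expr = expr, meta = meta)
}

#' Simulate a complete dataset (cohort plus counts)
#' @param config a [sim_config()].
#' @return list combining [simulate_haploid_cohort()] and [simulate_counts()].
#' @export
simulate_dataset <- function(config) {
  hap <- simulate_haploid_cohort(config)
  cnt <- simulate_counts(config, hap$truth)
  c(hap, cnt)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the minimal VCF (haploid GT:DP:AF), the supergene BED interval,
#' GFF3 gene models with CDS FASTA, and TSVs for the cohort, SNP and gene
#' allele counts, total counts, sample metadata and ground truth. Round-trip
#' reading reproduces the in-memory objects.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_input("cannot create directory %s", dir)
  f <- function(x) file.path(dir, x)
  write_vcf(sim$panel, f("genotypes.vcf"))
  write_bed(sim$region, f("supergene.bed"))
  write_gene_models(sim$models, f("genes.gff3"), f("cds.fasta"))
  write_tsv(as.data.frame(sim$cohort), f("cohort.tsv"))
  write_tsv(sim$snp_counts, f("snp_counts.tsv"))
  write_tsv(sim$gene_counts, f("gene_counts.tsv"))
  expr_df <- data.frame(gene = rownames(sim$expr), sim$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, f("expression.tsv"))
  write_tsv(sim$meta, f("meta.tsv"))
  write_tsv(sim$truth$genes, f("truth_genes.tsv"))
  write_tsv(sim$truth$sites, f("truth_sites.tsv"))
  write_tsv(data.frame(gene = rownames(sim$truth$P_B), sim$truth$P_B,
                       check.names = FALSE), f("truth_P_B.tsv"))
  c(vcf = f("genotypes.vcf"), bed = f("supergene.bed"), gff3 = f("genes.gff3"),
    cds = f("cds.fasta"), cohort = f("cohort.tsv"), snp_counts = f("snp_counts.tsv"),
    gene_counts = f("gene_counts.tsv"), expression = f("expression.tsv"),
    meta = f("meta.tsv"), truth_genes = f("truth_genes.tsv"),
    truth_sites = f("truth_sites.tsv"), truth_P_B = f("truth_P_B.tsv"))
}
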