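## Shared fixtures, all built in code.

## Hand-built panel: 4 individuals (2 SB, 2 Sb), clean baseline values that
## pass every default filter unless a test perturbs them.
tiny_panel <- function(n_sites = 6, qual = 100, dp = 8, af = 0.95) {
  ids <- c("SB_1", "SB_2", "Sb_1", "Sb_2")
  sites <- data.frame(chrom = "social_chr", pos = seq(10, by = 50, length.out = n_sites),
                      ref = rep(c("A", "C", "G"), length.out = n_sites),
                      alt = rep(c("G", "T", "A"), length.out = n_sites),
                      qual = qual, stringsAsFactors = FALSE)
  gt <- matrix(NA_character_, n_sites, 4, dimnames = list(NULL, ids))
  for (i in seq_len(n_sites)) gt[i, ] <- c(sites$ref[i], sites$ref[i], sites$alt[i], sites$alt[i])
  variant_panel(sites,
                gt = gt,
                dp = matrix(dp, n_sites, 4, dimnames = list(NULL, ids)),
                af = matrix(af, n_sites, 4, dimnames = list(NULL, ids)))
}

tiny_cohort <- function() haploid_cohort(c("SB_1", "SB_2", "Sb_1", "Sb_2"),
                                         c("SB", "SB", "Sb", "Sb"),
                                         rep("south_america", 4))

## Random panel with injected rule violations, for brute-force filter oracles.
random_panel <- function(n_sites, ids, seed) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    sites <- data.frame(chrom = "social_chr", pos = sample.int(1e6, n_sites),
                        ref = ref, alt = alt,
                        qual = runif(n_sites, 0, 100), stringsAsFactors = FALSE)
    ## a few indel-like records to exercise snps_only
    mnp <- sample(n_sites, max(1, n_sites %/% 20))
    sites$alt[mnp] <- paste0(sites$alt[mnp], "T")
    n <- length(ids)
    gt <- matrix(sample(bases, n_sites * n, replace = TRUE), n_sites, n,
                 dimnames = list(NULL, ids))
    dp <- matrix(rpois(n_sites * n, 8), n_sites, n, dimnames = list(NULL, ids))
    af <- matrix(runif(n_sites * n, 0.4, 1), n_sites, n, dimnames = list(NULL, ids))
    variant_panel(sites, gt, dp, af)
  })
}

## Small single-population simulation used by several statistical tests.
one_pop_config <- function(n_genes, seed, regime_mix = c(neutral = 1, degenerate = 0,
                                                         compensated = 0, antagonistic = 0),
                           depth = 500, n_rep = 6, ...) {
  sim_config(n_genes_supergene = n_genes, n_genes_background = 0,
             regime_mix = regime_mix,
             populations = list(list(name = "north_america", ancestry = "invasive",
                                     geography = "americas", bottleneck = 0.2,
                                     n_SB_males = 7, n_Sb_males = 7)),
             samples = data.frame(population = "north_america", caste = "queen",
                                  body_part = "whole", social_form = "multiple_queen",
                                  genotype = "SB/Sb", n = n_rep),
             mean_expression_log_mu = log(depth), mean_expression_log_sd = 0.3,
             snps_per_gene_lambda = 1, seed = seed, ...)
}

## Hand-built gene model on the plus and minus strand for effect tests.
## CDS sequence: ATG GCT TGG AAA TAC TAA (Met Ala Trp Lys Tyr Stop).
toy_models <- function(strand = "+") {
  seq <- "ATGGCTTGGAAATACTAA"
  genes <- data.frame(gene_id = "toy", chrom = "chr1", strand = strand,
                      start = 101L, end = 180L, stringsAsFactors = FALSE)
  ## gene span 101..180: UTR 101-110, CDS exon1 111-119, intron 120-129,
  ## CDS exon2 130-138, UTR 139-180
  cds <- data.frame(gene_id = "toy", chrom = "chr1",
                    start = c(111L, 130L), end = c(119L, 138L))
  utr <- data.frame(gene_id = "toy", chrom = "chr1",
                    start = c(101L, 139L), end = c(110L, 180L))
  gene_models(genes, cds, utr, cds_seq = c(toy = seq))
}

## Genomic plus-strand base of the toy gene at CDS coordinate i (1..18).
toy_genomic_pos <- function(cds_pos, strand = "+") {
  plus_positions <- c(111:119, 130:138)
  if (strand == "+") plus_positions[cds_pos]
  else rev(plus_positions)[cds_pos]
}
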