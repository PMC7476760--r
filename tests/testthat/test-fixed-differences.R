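test_that("single-rule violations at the threshold boundary are removed", {
  cohort <- tiny_cohort()
  p <- tiny_panel(); p$sites$qual[2] <- 24.9
  expect_identical(filter_sites(p, cohort)$sites$pos, p$sites$pos[-2])
  p <- tiny_panel(); p$af[3, "Sb_1"] <- 0.59
  expect_identical(filter_sites(p, cohort)$sites$pos, p$sites$pos[-3])
  p <- tiny_panel(); p$dp[4, "SB_2"] <- 0L
  expect_identical(filter_sites(p, cohort)$sites$pos, p$sites$pos[-4])
  p <- tiny_panel(dp = 20)  # mean depth above the 12 cap for south_america
  expect_identical(nrow(filter_sites(p, cohort)$sites), 0L)
  expect_error(filter_sites(tiny_panel(), haploid_cohort(c("SB_1", "ghost"),
                                                         c("SB", "Sb"), "south_america")),
               "ghost")
})

test_that("filter survival matches a brute-force rule-by-rule scan", {
  ids <- sprintf("i%02d", 1:10)
  cohort <- haploid_cohort(ids, rep(c("SB", "Sb"), each = 5),
                           rep(c("south_america", "north_america"), 5))
  panel <- random_panel(400, ids, seed = 77)
  th <- filter_thresholds()
  got <- filter_sites(panel, cohort, th)$sites$pos
  keep <- logical(nrow(panel$sites))
  for (i in seq_len(nrow(panel$sites))) {
    s <- panel$sites[i, ]
    ok <- nchar(s$ref) == 1 && all(nchar(strsplit(s$alt, ",")[[1]]) == 1)
    ok <- ok && s$qual >= 25
    for (j in seq_along(ids)) {
      ok <- ok && panel$dp[i, ids[j]] >= 1
      ok <- ok && panel$af[i, ids[j]] >= 0.60
    }
    for (pop in unique(cohort$population)) {
      cap <- th$max_mean_depth[[pop]]
      ok <- ok && mean(panel$dp[i, cohort$id[cohort$population == pop]]) <= cap
    }
    keep[i] <- ok
  }
  expect_identical(got, panel$sites$pos[keep])
  expect_gt(sum(keep), 0)
  expect_lt(sum(keep), nrow(panel$sites))
})

test_that("tightening any threshold never increases survivors", {
  ids <- sprintf("i%02d", 1:6)
  cohort <- haploid_cohort(ids, rep(c("SB", "Sb"), each = 3), "south_america")
  panel <- random_panel(200, ids, seed = 5)
  base <- nrow(filter_sites(panel, cohort, filter_thresholds())$sites)
  tighter <- list(filter_thresholds(min_quality = 40),
                  filter_thresholds(min_depth_per_individual = 4),
                  filter_thresholds(max_mean_depth = c(south_america = 8)),
                  filter_thresholds(min_allele_support_fraction = 0.8))
  for (th in tighter)
    expect_lte(nrow(filter_sites(panel, cohort, th)$sites), base)
})

test_that("fixed differences follow the definition and are SB-oriented", {
  cohort <- tiny_cohort()
  p <- tiny_panel(n_sites = 3)
  ## site 2: one SB individual carries the Sb allele -> not fixed
  p$gt[2, "SB_2"] <- p$sites$alt[2]
  ## site 3: both groups identical -> not fixed
  p$gt[3, ] <- p$sites$ref[3]
  fd <- call_fixed_differences(p, cohort)
  expect_identical(fd$pos, p$sites$pos[1])
  expect_identical(fd$SB_allele, p$sites$ref[1])
  expect_identical(fd$Sb_allele, p$sites$alt[1])
  expect_error(call_fixed_differences(p, haploid_cohort(c("SB_1", "SB_2"),
                                                        c("SB", "Sb"), "x")[1, ]),
               "Sb")
})

test_that("caller is exact against simulator ground truth without injected noise", {
  cfg <- sim_config(n_genes_supergene = 20, n_genes_background = 0,
                    filter_violation_rate = 0, seed = 13)
  hap <- simulate_haploid_cohort(cfg)
  sa <- hap$cohort[hap$cohort$population == "south_america", ]
  class(sa) <- class(hap$cohort)
  fd <- call_fixed_differences(filter_sites(hap$panel, sa), sa)
  fd <- restrict_to_region(fd, hap$region)
  truth <- hap$truth$sites[hap$truth$sites$type == "fixed", ]
  expect_setequal(paste(fd$pos, fd$SB_allele, fd$Sb_allele),
                  paste(truth$pos, truth$SB_allele, truth$Sb_allele))
  expect_identical(nrow(fd), nrow(truth))  # precision = recall = 1
})

test_that("region restriction respects the BED coordinate convention", {
  fd <- data.frame(chrom = "c", pos = 100L, SB_allele = "A", Sb_allele = "G")
  bed_exc <- cbind(chrom = "c", bed_to_1based(99, 100))   # covers pos 100 only
  expect_identical(nrow(restrict_to_region(fd, bed_exc)), 1L)
  bed_miss <- cbind(chrom = "c", bed_to_1based(100, 101)) # covers 101 only
  expect_identical(nrow(restrict_to_region(fd, bed_miss)), 0L)
  expect_identical(nrow(restrict_to_region(fd, bed_exc[0, ])), 0L)
})

test_that("region restriction matches a naive double loop", {
  withr::with_seed(8, {
    fd <- data.frame(chrom = sample(c("c1", "c2"), 200, TRUE),
                     pos = sample.int(1000, 200, TRUE),
                     SB_allele = "A", Sb_allele = "G")
    region <- data.frame(chrom = sample(c("c1", "c2"), 5, TRUE),
                         start = sample.int(800, 5), stringsAsFactors = FALSE)
    region$end <- region$start + sample.int(150, 5)
  })
  got <- restrict_to_region(fd, region)
  naive <- fd[vapply(seq_len(nrow(fd)), function(i) {
    any(vapply(seq_len(nrow(region)), function(j)
      region$chrom[j] == fd$chrom[i] &&
      fd$pos[i] >= region$start[j] && fd$pos[i] <= region$end[j], logical(1)))
  }, logical(1)), ]
  expect_identical(got, naive)
})

test_that("coding effects match the codon table on known substitutions", {
  m <- toy_models("+")
  ## CDS codon 2 is GCT (Ala): position 3 of codon 2 is CDS coordinate 6
  d <- data.frame(chrom = "chr1", pos = toy_genomic_pos(6), SB_allele = "T", Sb_allele = "C")
  expect_identical(classify_coding_effect(d, m)$effect, "synonymous")   # GCT -> GCC
  ## codon 3 TGG (Trp): G->A at codon position 3 gives TGA stop
  d <- data.frame(chrom = "chr1", pos = toy_genomic_pos(9), SB_allele = "G", Sb_allele = "A")
  expect_identical(classify_coding_effect(d, m)$effect, "stop_gained")
  ## codon 4 AAA (Lys) position 1 -> GAA (Glu)
  d <- data.frame(chrom = "chr1", pos = toy_genomic_pos(10), SB_allele = "A", Sb_allele = "G")
  expect_identical(classify_coding_effect(d, m)$effect, "nonsynonymous")
  ## non-CDS categories
  d <- data.frame(chrom = "chr1", pos = c(105L, 125L, 150L, 50L),
                  SB_allele = "A", Sb_allele = "G")
  expect_identical(classify_coding_effect(d, m)$effect,
                   c("UTR", "intronic", "UTR", "intergenic"))
  expect_error(gene_models(m$genes, data.frame(gene_id = "toy", chrom = "chr1",
                                               start = 111L, end = 120L),
                           cds_seq = c(toy = "ATGGCTTGGA")), "divisible by 3")
})

test_that("random substitutions agree with a whole-protein translation oracle", {
  for (strand in c("+", "-")) {
    m <- toy_models(strand)
    seq <- m$cds_seq[["toy"]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    withr::with_seed(31, {
      for (rep in 1:30) {
        cpos <- sample(18, 1)
        ref_cds <- substr(seq, cpos, cpos)
        alt_cds <- sample(setdiff(c("A", "C", "G", "T"), ref_cds), 1)
        mut <- seq; substr(mut, cpos, cpos) <- alt_cds
        p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                                    no.init.codon = TRUE))
        p_mut <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                                    no.init.codon = TRUE))
        expected <- if (p_ref == p_mut) "synonymous" else {
          i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
          if (substr(p_mut, i, i) == "*") "stop_gained" else "nonsynonymous"
        }
        gpos <- toy_genomic_pos(cpos, strand)
        ref_g <- if (strand == "+") ref_cds else comp[[ref_cds]]
        alt_g <- if (strand == "+") alt_cds else comp[[alt_cds]]
        d <- data.frame(chrom = "chr1", pos = gpos, SB_allele = ref_g, Sb_allele = alt_g)
        expect_identical(classify_coding_effect(d, m)$effect, expected,
                         label = sprintf("strand %s cds %d %s>%s", strand, cpos, ref_cds, alt_cds))
      }
    })
  }
})

test_that("set intersection partitions correctly", {
  a <- data.frame(chrom = "c", pos = 1:5, SB_allele = "A", Sb_allele = "G")
  shared <- intersect_fixed_sets(a, a)
  expect_identical(nrow(shared$shared), 5L)
  expect_identical(nrow(shared$only_a), 0L)
  b <- a; b$pos <- 6:10
  dis <- intersect_fixed_sets(a, b)
  expect_identical(nrow(dis$shared), 0L)
  expect_identical(nrow(dis$only_a), 5L)
  expect_identical(nrow(dis$only_b), 5L)
  withr::with_seed(4, {
    a <- data.frame(chrom = "c", pos = sample.int(50, 30), SB_allele = sample(c("A", "C"), 30, TRUE),
                    Sb_allele = "G")
    b <- data.frame(chrom = "c", pos = sample.int(50, 30), SB_allele = sample(c("A", "C"), 30, TRUE),
                    Sb_allele = "G")
  })
  part <- intersect_fixed_sets(a, b)
  key <- function(d) paste(d$chrom, d$pos, d$SB_allele, d$Sb_allele)
  expect_setequal(key(part$shared), intersect(key(a), key(b)))
  expect_setequal(key(part$only_a), setdiff(key(a), key(b)))
  expect_setequal(key(part$only_b), setdiff(key(b), key(a)))
})

test_that("cohort subsampling is seeded, bounded and fixation-monotone", {
  cfg <- sim_config(n_genes_supergene = 15, n_genes_background = 0,
                    filter_violation_rate = 0, seed = 17)
  hap <- simulate_haploid_cohort(cfg)
  sa <- hap$cohort[hap$cohort$population == "south_america", ]
  class(sa) <- class(hap$cohort)
  expect_identical(subsample_cohort(sa, 13, seed = 1)$id, sa$id)
  s1 <- subsample_cohort(sa, 7, seed = 99)
  expect_identical(s1, subsample_cohort(sa, 7, seed = 99))
  expect_identical(as.integer(table(s1$variant)), c(7L, 7L))
  expect_error(subsample_cohort(sa, 20, seed = 1), "exceeds")
  ## removing individuals never loses a fixed difference
  filt <- filter_sites(hap$panel, sa)
  full <- call_fixed_differences(filt, sa)
  for (s in 1:5) {
    sub <- subsample_cohort(sa, 7, seed = s)
    fd_sub <- call_fixed_differences(filter_sites(hap$panel, sub), sub)
    expect_true(all(paste(full$pos, full$SB_allele) %in%
                    paste(fd_sub$pos, fd_sub$SB_allele)))
  }
})
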