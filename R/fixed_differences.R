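## Fixed allelic differences between SB and Sb haploid males: site filters,
## the fixation call itself, region restriction and coding-effect annotation.

#' Variant panel of haploid genotype calls
#'
#' Container for a set of variant sites genotyped across haploid individuals.
#' `gt` stores the called allele as a nucleotide string (not an index), which
#' makes multi-allelic sites and reorientation trivial.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multi-allelic sites), `qual` (phred-scaled site
#'   quality).
#' @param gt character matrix (sites x individuals) of called alleles.
#' @param dp integer matrix of per-individual read depths.
#' @param af numeric matrix of per-individual fractions of reads supporting
#'   the called allele, in `[0, 1]`.
#' @return object of class `variant_panel`.
#' @export
variant_panel <- function(sites, gt, dp, af) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)),
            nrow(gt) == nrow(sites), all(dim(gt) == dim(dp)), all(dim(gt) == dim(af)))
  if (any(sites$pos < 1)) stop_input("positions must be >= 1")
  if (any(af < 0 | af > 1, na.rm = TRUE)) stop_input("allele-support fractions must lie in [0, 1]")
  if (is.null(colnames(gt))) stop_input("gt must have individual ids as column names")
  structure(list(sites = sites, gt = gt, dp = dp, af = af,
                 individuals = colnames(gt)),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d sites x %d individuals\n",
              nrow(x$sites), length(x$individuals)))
  invisible(x)
}

subset_panel <- function(panel, keep) {
  variant_panel(panel$sites[keep, , drop = FALSE],
                panel$gt[keep, , drop = FALSE],
                panel$dp[keep, , drop = FALSE],
                panel$af[keep, , drop = FALSE])
}

#' Haploid cohort description
#'
#' @param id individual identifiers (must match VCF sample columns).
#' @param variant supergene haplotype carried, `"SB"` or `"Sb"`.
#' @param population population label.
#' @return data.frame of class `haploid_cohort`.
#' @export
haploid_cohort <- function(id, variant, population) {
  variant <- as.character(variant)
  if (!all(variant %in% c("SB", "Sb"))) stop_input("variant labels must be 'SB' or 'Sb'")
  if (length(unique(variant)) < 2L) stop_input("both variant labels must be present")
  out <- data.frame(id = as.character(id), variant = variant,
                    population = as.character(population), stringsAsFactors = FALSE)
  class(out) <- c("haploid_cohort", "data.frame")
  out
}

#' Site filter thresholds
#'
#' Defaults follow the variant-site quality control used for the fire-ant
#' haploid male panels: SNPs only, site quality Q >= 25, every individual
#' covered by at least one read, a per-population cap on mean depth (16 for
#' the invasive North American panel, 12 for the South American panel; the cap
#' removes collapsed repeats) and at least 60% of each individual's reads
#' supporting its called allele.
#'
#' @param min_quality minimum phred site quality.
#' @param min_depth_per_individual minimum per-individual depth.
#' @param max_mean_depth named vector of per-population caps on mean depth
#'   (a single unnamed value applies to all populations).
#' @param min_allele_support_fraction minimum per-individual fraction of reads
#'   supporting the called allele.
#' @param snps_only drop sites whose alleles are not single nucleotides.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_quality = 25,
                              min_depth_per_individual = 1,
                              max_mean_depth = c(north_america = 16, south_america = 12),
                              min_allele_support_fraction = 0.60,
                              snps_only = TRUE) {
  stopifnot(min_quality >= 0, min_depth_per_individual >= 0,
            all(max_mean_depth >= 0),
            min_allele_support_fraction > 0, min_allele_support_fraction <= 1)
  structure(list(min_quality = min_quality,
                 min_depth_per_individual = min_depth_per_individual,
                 max_mean_depth = max_mean_depth,
                 min_allele_support_fraction = min_allele_support_fraction,
                 snps_only = snps_only),
            class = "filter_thresholds")
}

mean_depth_cap <- function(thresholds, population) {
  cap <- thresholds$max_mean_depth
  if (is.null(names(cap)) || length(cap) == 1L && names(cap)[1] == "") return(cap[[1]])
  if (population %in% names(cap)) return(cap[[population]])
  Inf
}

#' Apply site filters to a variant panel
#'
#' Retains sites that (i) are SNPs, (ii) have site quality >= `min_quality`,
#' (iii) cover every cohort individual with at least
#' `min_depth_per_individual` reads, (iv) have mean depth across each
#' population's individuals no greater than that population's cap, and (v)
#' have every individual supported by at least
#' `min_allele_support_fraction` of its reads. Site order is preserved.
#'
#' @param panel a [variant_panel()].
#' @param cohort a [haploid_cohort()]; all its individuals must be genotyped.
#' @param thresholds a [filter_thresholds()].
#' @return the filtered `variant_panel`.
#' @export
filter_sites <- function(panel, cohort, thresholds = filter_thresholds()) {
  stopifnot(inherits(panel, "variant_panel"), inherits(thresholds, "filter_thresholds"))
  missing <- setdiff(cohort$id, panel$individuals)
  if (length(missing))
    stop_input("no genotype record for individual(s) %s", paste(missing, collapse = ", "))
  idx <- match(cohort$id, panel$individuals)
  gt <- panel$gt[, idx, drop = FALSE]
  dp <- panel$dp[, idx, drop = FALSE]
  af <- panel$af[, idx, drop = FALSE]
  s <- panel$sites

  keep <- rep(TRUE, nrow(s))
  if (isTRUE(thresholds$snps_only)) {
    alt_ok <- vapply(strsplit(s$alt, ",", fixed = TRUE),
                     function(a) all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
                     logical(1))
    keep <- keep & nchar(s$ref) == 1L & s$ref %in% c("A", "C", "G", "T") & alt_ok
  }
  keep <- keep & s$qual >= thresholds$min_quality
  keep <- keep & apply(dp >= thresholds$min_depth_per_individual, 1L, all)
  for (pop in unique(cohort$population)) {
    cols <- cohort$population == pop
    keep <- keep & rowMeans(dp[, cols, drop = FALSE]) <= mean_depth_cap(thresholds, pop)
  }
  keep <- keep & apply(af >= thresholds$min_allele_support_fraction, 1L, all)
  subset_panel(panel, keep)
}

#' Call SNPs with fixed differences between the SB and Sb groups
#'
#' A site is a fixed difference when all SB individuals carry one allele, all
#' Sb individuals carry another, and the two alleles differ. Output is
#' reoriented so the SB allele is reported as reference-orientation
#' (`SB_allele`) and the Sb allele as alternate.
#'
#' @param panel a filtered [variant_panel()].
#' @param cohort a [haploid_cohort()].
#' @return data.frame with `chrom`, `pos`, `SB_allele`, `Sb_allele`.
#' @export
call_fixed_differences <- function(panel, cohort) {
  for (v in c("SB", "Sb"))
    if (!any(cohort$variant == v)) stop_input("cohort has no %s individuals", v)
  idx_sb <- match(cohort$id[cohort$variant == "SB"], panel$individuals)
  idx_lb <- match(cohort$id[cohort$variant == "Sb"], panel$individuals)
  if (anyNA(c(idx_sb, idx_lb))) stop_input("cohort individuals missing from panel")
  one_allele <- function(m) {
    apply(m, 1L, function(x) if (!anyNA(x) && length(unique(x)) == 1L) x[1] else NA_character_)
  }
  a_sb <- one_allele(panel$gt[, idx_sb, drop = FALSE])
  a_lb <- one_allele(panel$gt[, idx_lb, drop = FALSE])
  fixed <- !is.na(a_sb) & !is.na(a_lb) & a_sb != a_lb
  data.frame(chrom = panel$sites$chrom[fixed], pos = panel$sites$pos[fixed],
             SB_allele = unname(a_sb[fixed]), Sb_allele = unname(a_lb[fixed]),
             stringsAsFactors = FALSE)
}

#' Restrict fixed differences to a genomic region
#'
#' @param diffs data.frame from [call_fixed_differences()].
#' @param region data.frame of 1-based inclusive intervals (`chrom`, `start`,
#'   `end`), e.g. from [read_bed()].
#' @return the subset of `diffs` inside the region, order preserved.
#' @export
restrict_to_region <- function(diffs, region) {
  if (nrow(diffs) == 0L || nrow(region) == 0L) return(diffs[integer(0), , drop = FALSE])
  diffs[pos_in_intervals(diffs$chrom, diffs$pos, region), , drop = FALSE]
}

#' Gene models for coding-effect classification
#'
#' @param genes data.frame: `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (gene span, 1-based inclusive).
#' @param cds data.frame of CDS intervals: `gene_id`, `chrom`, `start`, `end`;
#'   non-overlapping, total length divisible by 3.
#' @param utr data.frame of UTR intervals (same columns), may be empty.
#' @param cds_seq named character vector: spliced CDS sequence (coding strand)
#'   per gene id.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, cds, utr = NULL, cds_seq = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (is.null(utr)) utr <- data.frame(gene_id = character(), chrom = character(),
                                      start = integer(), end = integer())
  if (!is.null(cds_seq)) {
    len <- vapply(split(cds$end - cds$start + 1L, cds$gene_id), sum, numeric(1))
    bad <- names(len)[len %% 3 != 0]
    if (length(bad)) stop_input("CDS length not divisible by 3 for gene(s): %s",
                                paste(bad, collapse = ", "))
  }
  structure(list(genes = genes, cds = cds, utr = utr, cds_seq = cds_seq),
            class = "gene_models")
}

## 1-based CDS coordinate of a genomic position (strand-aware); NA outside CDS
cds_coordinate <- function(pos, cds_intervals, strand) {
  cds_intervals <- cds_intervals[order(cds_intervals$start), , drop = FALSE]
  lens <- cds_intervals$end - cds_intervals$start + 1L
  hit <- which(cds_intervals$start <= pos & cds_intervals$end >= pos)
  if (!length(hit)) return(NA_integer_)
  plus_coord <- sum(lens[seq_len(hit - 1L)]) + (pos - cds_intervals$start[hit]) + 1L
  if (strand == "+") plus_coord else sum(lens) - plus_coord + 1L
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify the coding effect of fixed differences
#'
#' For substitutions inside a CDS the affected codon is translated with and
#' without the Sb allele (standard nuclear genetic code, strand-aware):
#' identical amino acid gives `synonymous`, a new stop gives `stop_gained`,
#' any other change `nonsynonymous`. Positions inside an annotated UTR are
#' `UTR`, inside a gene but neither CDS nor UTR `intronic`, and otherwise
#' `intergenic`. Co-occurring substitutions in one codon are classified
#' independently (with a warning).
#'
#' @param diffs data.frame with `chrom`, `pos`, `SB_allele`, `Sb_allele`.
#' @param models a [gene_models()] with CDS sequences.
#' @return `diffs` with added `gene` (`NA` outside genes) and `effect`.
#' @export
classify_coding_effect <- function(diffs, models) {
  stopifnot(inherits(models, "gene_models"))
  code <- Biostrings::GENETIC_CODE
  n <- nrow(diffs)
  gene <- rep(NA_character_, n)
  effect <- rep("intergenic", n)
  g <- models$genes
  for (i in seq_len(n)) {
    hit <- which(g$chrom == diffs$chrom[i] & g$start <= diffs$pos[i] & g$end >= diffs$pos[i])
    if (!length(hit)) next
    gid <- g$gene_id[hit[1]]
    gene[i] <- gid
    strand <- g$strand[hit[1]]
    cds <- models$cds[models$cds$gene_id == gid & models$cds$chrom == diffs$chrom[i], , drop = FALSE]
    cpos <- if (nrow(cds)) cds_coordinate(diffs$pos[i], cds, strand) else NA_integer_
    if (!is.na(cpos)) {
      seq <- models$cds_seq[[gid]]
      if (is.null(seq)) stop_input("no CDS sequence for gene %s", gid)
      if (nchar(seq) %% 3 != 0) stop_input("CDS of gene %s not divisible by 3", gid)
      ref_base <- diffs$SB_allele[i]
      alt_base <- diffs$Sb_allele[i]
      if (strand == "-") {
        ref_base <- COMPLEMENT[[ref_base]]
        alt_base <- COMPLEMENT[[alt_base]]
      }
      if (substr(seq, cpos, cpos) != ref_base)
        warning(sprintf("SB allele at %s:%d does not match CDS of %s; classifying against annotated base",
                        diffs$chrom[i], diffs$pos[i], gid))
      codon_i <- (cpos - 1L) %/% 3L
      codon <- substr(seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      off <- cpos - codon_i * 3L
      mut <- codon
      substr(mut, off, off) <- alt_base
      aa_ref <- code[[codon]]
      aa_mut <- code[[mut]]
      effect[i] <- if (aa_mut == aa_ref) "synonymous"
                   else if (aa_mut == "*") "stop_gained"
                   else "nonsynonymous"
    } else {
      utr <- models$utr[models$utr$gene_id == gid, , drop = FALSE]
      in_utr <- nrow(utr) > 0 && any(utr$start <= diffs$pos[i] & utr$end >= diffs$pos[i])
      effect[i] <- if (in_utr) "UTR" else "intronic"
    }
  }
  diffs$gene <- gene
  diffs$effect <- effect
  diffs
}

#' Partition two fixed-difference sets by identity
#'
#' Sites are matched on `(chrom, pos, SB_allele, Sb_allele)`, reproducing the
#' intersection of independently called population panels.
#'
#' @param a,b fixed-difference data.frames.
#' @return list with `shared`, `only_a`, `only_b`.
#' @export
intersect_fixed_sets <- function(a, b) {
  key <- function(d) paste(d$chrom, d$pos, d$SB_allele, d$Sb_allele, sep = "\r")
  ka <- key(a); kb <- key(b)
  list(shared = a[ka %in% kb, , drop = FALSE],
       only_a = a[!ka %in% kb, , drop = FALSE],
       only_b = b[!kb %in% ka, , drop = FALSE])
}

#' Downsample a haploid cohort to equal group sizes
#'
#' Seeded uniform sampling without replacement within each variant group,
#' mirroring the check that population differences in fixed-difference counts
#' are not driven by sample size alone.
#'
#' @param cohort a [haploid_cohort()].
#' @param n_per_group individuals to keep per variant label.
#' @param seed integer seed.
#' @return the subsampled `haploid_cohort`.
#' @export
subsample_cohort <- function(cohort, n_per_group, seed) {
  keep <- integer(0)
  for (v in c("SB", "Sb")) {
    rows <- which(cohort$variant == v)
    if (n_per_group > length(rows))
      stop_input("n_per_group = %d exceeds the %d %s individuals", n_per_group, length(rows), v)
    keep <- c(keep, withr::with_seed(derive_seed(seed, match(v, c("SB", "Sb"))),
                                     sample(rows, n_per_group)))
  }
  out <- cohort[sort(keep), , drop = FALSE]
  class(out) <- class(cohort)
  out
}
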