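## Gene-level SB/Sb expression from SNP-level allele-resolved read counts.

#' Summarize one gene's SNP counts to allele expression values
#'
#' The gene-level expression of each allele is the median of its per-SNP read
#' counts, taken independently for SB and Sb (a gene with SB support 12, 15,
#' 18 and Sb support 5, 8, 6 reads is reported as SB = 15, Sb = 6). For an
#' even number of SNPs the median is the midpoint of the central pair.
#'
#' @param reads_SB,reads_Sb numeric vectors of per-SNP read counts
#'   (equal length, >= 1 SNP).
#' @return named numeric vector `c(x_B=, x_b=)`.
#' @examples
#' summarize_gene(c(12, 15, 18), c(5, 8, 6))
#' @export
summarize_gene <- function(reads_SB, reads_Sb) {
  stopifnot(length(reads_SB) == length(reads_Sb), length(reads_SB) >= 1L)
  c(x_B = median(reads_SB), x_b = median(reads_Sb))
}

#' Summarize a SNP count table to gene x sample allele counts
#'
#' @param snp_counts data.frame with `sample`, `chrom`, `pos`, `gene`,
#'   `reads_SB`, `reads_Sb`.
#' @param random_snp if `TRUE`, use a single randomly chosen SNP per
#'   gene x sample instead of the median (sensitivity check); seed the RNG
#'   beforehand for reproducibility.
#' @return data.frame with `gene`, `sample`, `x_B`, `x_b`; genes without SNP
#'   counts in a sample are absent.
#' @export
summarize_allele_counts <- function(snp_counts, random_snp = FALSE) {
  stopifnot(all(c("sample", "gene", "reads_SB", "reads_Sb") %in% names(snp_counts)))
  if (!nrow(snp_counts))
    return(data.frame(gene = character(), sample = character(),
                      x_B = numeric(), x_b = numeric(), stringsAsFactors = FALSE))
  key <- interaction(snp_counts$gene, snp_counts$sample, drop = TRUE)
  parts <- split(snp_counts, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    xs <- if (random_snp) {
      i <- sample(nrow(d), 1L)
      c(x_B = d$reads_SB[i], x_b = d$reads_Sb[i])
    } else summarize_gene(d$reads_SB, d$reads_Sb)
    data.frame(gene = d$gene[1], sample = d$sample[1],
               x_B = unname(xs[1]), x_b = unname(xs[2]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$sample), ]
}

#' Expression filter for allele-count tables
#'
#' `mode = "all_samples"` keeps genes with `x_B + x_b > 0` in every sample
#' (used for the joint multi-population analyses); `mode = "any_body_part"`
#' keeps genes expressed in every replicate of at least one body-part group
#' (used for body-part resolved datasets).
#'
#' @param counts data.frame with `gene`, `sample`, `x_B`, `x_b`.
#' @param meta data.frame with `sample`, `body_part`.
#' @param mode `"all_samples"` or `"any_body_part"`.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, meta, mode = c("all_samples", "any_body_part")) {
  mode <- match.arg(mode)
  samples <- unique(meta$sample)
  genes <- unique(counts$gene)
  if (!length(genes)) return(character(0))
  expressed <- matrix(FALSE, length(genes), length(samples),
                      dimnames = list(genes, samples))
  have <- counts$sample %in% samples
  idx <- cbind(match(counts$gene[have], genes), match(counts$sample[have], samples))
  expressed[idx] <- counts$x_B[have] + counts$x_b[have] > 0
  if (mode == "all_samples") return(genes[rowSums(expressed) == length(samples)])
  bp <- meta$body_part[match(samples, meta$sample)]
  keep <- rep(FALSE, length(genes))
  for (b in unique(bp)) {
    cols <- which(bp == b)
    keep <- keep | rowSums(expressed[, cols, drop = FALSE]) == length(cols)
  }
  genes[keep]
}

#' Log2 allelic expression ratio
#'
#' `log2((x_B + c)/(x_b + c))` where the pseudocount `c` is applied only to
#' pairs in which either count is zero, so exact counts are untouched.
#' Positive values indicate higher SB expression.
#'
#' @param x_B,x_b allele read counts (vectors recycle).
#' @param pseudocount pseudocount for zero-containing pairs (default 0.5).
#' @return numeric vector of log2 ratios; `NA` where both counts are 0.
#' @examples
#' log2_ratio(15, 6)      # 1.3219
#' log2_ratio(8, 0)       # log2(8.5/0.5)
#' @export
log2_ratio <- function(x_B, x_b, pseudocount = 0.5) {
  n <- max(length(x_B), length(x_b))
  x_B <- rep_len(x_B, n); x_b <- rep_len(x_b, n)
  if (any(x_B < 0 | x_b < 0)) stop_input("counts must be non-negative")
  zero <- x_B == 0 | x_b == 0
  c_add <- ifelse(zero, pseudocount, 0)
  out <- log2((x_B + c_add) / (x_b + c_add))
  out[x_B == 0 & x_b == 0] <- NA_real_
  out
}
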