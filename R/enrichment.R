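## Contingency-table enrichment, exact binomial direction tests and the
## four-quadrant (allelic x social) classification of genes.

#' Pearson chi-square test for a 2x2 table with Yates continuity correction
#'
#' The corrected statistic is \eqn{\sum (\max(|O-E| - 1/2, 0))^2 / E} on one
#' degree of freedom. The correction is on by default because small 2x2 gene
#' tallies are the typical input; set `correct = FALSE` for the uncorrected
#' Pearson statistic.
#'
#' @param tab 2x2 matrix (or table) of non-negative integer counts.
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return list with `statistic`, `p.value`, `expected`, `df`.
#' @examples
#' chi2_yates(rbind(c(5, 3), c(1, 14)))
#' @export
chi2_yates <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_input("chi2_yates needs a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop_input("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop_input("zero margin: statistic undefined")
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat,
       p.value = pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = expected, df = 1L)
}

#' Exact two-sided binomial test
#'
#' Two-sided p-value by the standard exact convention: the sum of the
#' probabilities of all outcomes no more likely than the observed one. For
#' `p0 = 0.5` this equals twice the smaller tail (capped at 1).
#'
#' @param k observed successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability.
#' @return the exact two-sided p-value.
#' @examples
#' binom_two_sided(13, 15) # 0.00739
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, k <= n, n >= 1)
  d <- dbinom(0:n, n, p0)
  ## relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}

#' Test a gene class for overrepresentation in a genomic region
#'
#' Builds the 2x2 table of region membership (supergene vs background) against
#' a binary per-gene flag (e.g. socially biased expression), reports the count
#' expected in the region-flagged cell under independence, and the
#' continuity-corrected chi-square test.
#'
#' @param genes data.frame with columns `region` (values `"supergene"` /
#'   `"background"`) and `biased` (logical).
#' @param correct passed to [chi2_yates()].
#' @return list with `table`, `expected_biased_supergene`, `test`.
#' @export
region_enrichment <- function(genes, correct = TRUE) {
  stopifnot(all(c("region", "biased") %in% names(genes)))
  region <- factor(genes$region, levels = c("supergene", "background"))
  if (anyNA(region)) stop_input("region labels must be 'supergene' or 'background'")
  biased <- factor(genes$biased, levels = c(TRUE, FALSE))
  tab <- table(region, biased)
  res <- chi2_yates(unclass(tab), correct = correct)
  list(table = tab,
       expected_biased_supergene = res$expected[1, 1],
       test = res)
}

#' Classify genes by significance of allelic and social expression bias
#'
#' Reproduces the four-panel layout used to separate dosage compensation from
#' antagonistic selection: each gene is classed by which of the two tests is
#' significant at `alpha` on BH-adjusted p-values, with directions taken from
#' the fold-change signs (allelic: positive = SB-biased; social: positive =
#' higher in multiple-queen colonies).
#'
#' @param allelic data.frame with columns `gene`, `lfc`, `padj`.
#' @param social data.frame with columns `gene`, `lfc`, `padj`.
#' @param alpha significance threshold on adjusted p-values.
#' @return list with `labels` (per-gene data.frame: `gene`, `class`,
#'   `allelic_direction`, `social_direction`) and `counts` (class by direction
#'   tally).
#' @export
classify_quadrants <- function(allelic, social, alpha = 0.05) {
  for (d in list(allelic, social))
    stopifnot(all(c("gene", "lfc", "padj") %in% names(d)))
  genes <- union(allelic$gene, social$gene)
  a <- allelic[match(genes, allelic$gene), ]
  s <- social[match(genes, social$gene), ]
  a_sig <- !is.na(a$padj) & a$padj < alpha
  s_sig <- !is.na(s$padj) & s$padj < alpha
  cls <- ifelse(a_sig & s_sig, "both",
         ifelse(a_sig, "allelic_only",
         ifelse(s_sig, "social_only", "none")))
  adir <- ifelse(a_sig, ifelse(a$lfc > 0, "SB", "Sb"), "none")
  sdir <- ifelse(s_sig, ifelse(s$lfc > 0, "MQ", "SQ"), "none")
  labels <- data.frame(gene = genes, class = cls,
                       allelic_direction = adir, social_direction = sdir,
                       stringsAsFactors = FALSE)
  counts <- table(class = factor(cls, levels = c("none", "social_only", "allelic_only", "both")),
                  allelic = factor(adir, levels = c("none", "SB", "Sb")),
                  social = factor(sdir, levels = c("none", "MQ", "SQ")))
  list(labels = labels, counts = counts)
}
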