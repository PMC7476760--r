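## The analytic core: per-gene (P_B, P_MQ) coordinates, the degeneration-only
## null curve, the dosage-compensation curve, regression diagnostics, curve
## comparison, the degeneration-bias regression and the grouped
## total-expression test.
##
## Derivation of the null curve: write the Sb allele's expression as a
## fraction r of the SB allele's, x_b = r x_B. Single-queen (SB/SB) queens
## then express 2 x_B in total while multiple-queen (SB/Sb) queens express
## x_B + x_b, giving P_B = 1/(1+r) and P_MQ = (1+r)/(3+r) = 1/(2 P_B + 1).
## Its minimum P_MQ = 1/3 occurs at x_b = 0 (P_B = 1). The compensation
## model instead ties P_B to the social-form difference, P_B = (1 - P_MQ/2)/P_MQ,
## equivalently P_MQ = 1/(P_B + 1/2): the SB allele is up-regulated in
## heterozygotes so that totals match the homozygote.

#' Per-gene allelic and social expression proportions
#'
#' `P_B = x_B / (x_B + x_b)` (share of allelic expression from SB in
#' heterozygotes) and `P_MQ = x_MQ / (x_SQ + x_MQ)` (share of total
#' expression from multiple-queen queens). The two measurements come from
#' independently normalized datasets and are joined on gene id; genes with a
#' zero denominator in either are dropped with a message.
#'
#' @param allele_means data.frame with `gene`, `x_B`, `x_b` (mean normalized
#'   allele expression).
#' @param social_means data.frame with `gene`, `x_SQ`, `x_MQ` (mean
#'   normalized totals per social form).
#' @return data.frame with `gene`, `x_B`, `x_b`, `x_SQ`, `x_MQ`, `P_B`,
#'   `P_MQ`, `weight` (mean multiple-queen expression).
#' @examples
#' compute_proportions(data.frame(gene = "g", x_B = 30, x_b = 10),
#'                     data.frame(gene = "g", x_SQ = 40, x_MQ = 40))
#' @export
compute_proportions <- function(allele_means, social_means) {
  stopifnot(all(c("gene", "x_B", "x_b") %in% names(allele_means)),
            all(c("gene", "x_SQ", "x_MQ") %in% names(social_means)))
  d <- merge(allele_means, social_means, by = "gene")
  bad <- d$x_B + d$x_b <= 0 | d$x_SQ + d$x_MQ <= 0
  if (any(bad)) {
    message(sum(bad), " gene(s) dropped: zero denominator")
    d <- d[!bad, , drop = FALSE]
  }
  d$P_B <- d$x_B / (d$x_B + d$x_b)
  d$P_MQ <- d$x_MQ / (d$x_SQ + d$x_MQ)
  d$weight <- d$x_MQ
  rownames(d) <- NULL
  d
}

#' Degeneration-only null curve
#'
#' Expected `P_MQ` when the social-form difference is driven entirely by the
#' baseline allelic ratio: `P_MQ = 1 / (2 P_B + 1)`, with range `[1/3, 1]`.
#'
#' @param P_B allelic proportion(s) in `[0, 1]`.
#' @return predicted `P_MQ`.
#' @examples
#' null_curve(1) # 1/3, no Sb expression
#' @export
null_curve <- function(P_B) {
  stopifnot(all(P_B >= 0 & P_B <= 1))
  1 / (2 * P_B + 1)
}

#' Dosage-compensation curve
#'
#' Under gene-specific compensation the allelic proportion implied by a
#' social-form proportion is `P_B = (1 - P_MQ/2) / P_MQ`; the inverse form
#' `P_MQ = 1 / (P_B + 1/2)` is convenient for plotting over `P_B`.
#'
#' @param P_MQ social-form proportion(s) in `(0, 1]`.
#' @return predicted `P_B`.
#' @export
compensation_curve <- function(P_MQ) {
  stopifnot(all(P_MQ > 0 & P_MQ <= 1))
  (1 - P_MQ / 2) / P_MQ
}

#' @rdname compensation_curve
#' @param P_B allelic proportion(s) for the inverse parameterization; values
#'   below 0.5 give predictions above 1 (the curve only reaches `[2/3, 1]`
#'   within the observable band).
#' @export
compensation_curve_pmq <- function(P_B) {
  stopifnot(all(P_B >= 0))
  1 / (P_B + 0.5)
}

#' Linear regression of P_MQ on P_B and its value at balance
#'
#' Ordinary least squares of `P_MQ` on `P_B`; reports the fitted value at
#' `P_B = 0.5` and a t-test of its deviation from 0.5. Passing through
#' (0.5, 0.5) means genes with balanced alleles show no social-form
#' difference.
#'
#' @param points data.frame from [compute_proportions()].
#' @param weights optional regression weights (e.g. `points$weight`).
#' @return list with `slope`, `intercept`, `fit_at_half`, `deviation`, `se`,
#'   `p`, `model`.
#' @export
fit_regression <- function(points, weights = NULL) {
  stopifnot(nrow(points) >= 3)
  fit <- lm(P_MQ ~ P_B, data = points, weights = weights)
  cvec <- c(1, 0.5)
  fit_half <- sum(cvec * coef(fit))
  se <- sqrt(drop(t(cvec) %*% vcov(fit) %*% cvec))
  tstat <- (fit_half - 0.5) / se
  df <- fit$df.residual
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit_at_half = fit_half, deviation = fit_half - 0.5, se = se,
       p = 2 * stats::pt(-abs(tstat), df), model = fit)
}

#' Compare the null and compensation curves on observed points
#'
#' Both curves are parameter-free, so the comparison is on residual sums of
#' squares of observed `P_MQ` against each prediction: an F-like ratio of the
#' two RSS (equal model dimension, two-sided p from the F reference on
#' (n, n) df) plus a distribution-free paired Wilcoxon signed-rank test on
#' the per-gene absolute residual differences. The preferred model is the
#' one with lower RSS; `p` reports the signed-rank test.
#'
#' @param points data.frame from [compute_proportions()].
#' @return list of class `curve_comparison`: `rss_null`, `rss_compensation`,
#'   `f_stat`, `p_f`, `p` (signed-rank), `preferred`
#'   (`"null"`, `"compensation"` or `"tie"`), `n`.
#' @export
compare_curves <- function(points) {
  stopifnot(nrow(points) >= 3)
  if (sd(points$P_B) == 0 && sd(points$P_MQ) == 0)
    stop_input("degenerate input: all points identical")
  r_null <- points$P_MQ - null_curve(points$P_B)
  r_comp <- points$P_MQ - compensation_curve_pmq(points$P_B)
  rss_n <- sum(r_null^2); rss_c <- sum(r_comp^2)
  n <- nrow(points)
  f <- rss_n / rss_c
  p_f <- 2 * min(pf(f, n, n), pf(f, n, n, lower.tail = FALSE))
  dif <- abs(r_null) - abs(r_comp)
  p_w <- if (all(dif == 0)) 1 else
    suppressWarnings(wilcox.test(dif, mu = 0)$p.value)
  preferred <- if (abs(rss_n - rss_c) <= 1e-12 * max(rss_n, rss_c)) "tie"
               else if (rss_n < rss_c) "null" else "compensation"
  structure(list(rss_null = rss_n, rss_compensation = rss_c,
                 f_stat = f, p_f = p_f, p = p_w, preferred = preferred, n = n),
            class = "curve_comparison")
}

#' Regression of allelic bias on non-synonymous mutation load
#'
#' OLS of per-gene log2(SB/Sb) expression ratios on the number of
#' non-synonymous mutations carried by the Sb allele. A positive coefficient
#' means allelic bias toward SB grows with sequence degeneration.
#'
#' @param nonsyn integer vector of per-gene non-synonymous counts.
#' @param log2_ratios numeric vector of per-gene log2 SB/Sb ratios.
#' @return list with `coefficient`, `se`, `p`, `model`.
#' @export
regress_nonsyn_bias <- function(nonsyn, log2_ratios) {
  stopifnot(length(nonsyn) == length(log2_ratios))
  ok <- is.finite(nonsyn) & is.finite(log2_ratios)
  if (sum(ok) < 3) stop_input("need >= 3 genes with both values")
  fit <- lm(log2_ratios[ok] ~ nonsyn[ok])
  sm <- summary(fit)$coefficients
  list(coefficient = unname(sm[2, 1]), se = unname(sm[2, 2]),
       p = unname(sm[2, 4]), model = fit)
}

#' Grouped total-expression test across allelic-bias bins
#'
#' Tests whether total expression differs between social forms once genes are
#' grouped by their relative SB/Sb expression. Excludes (i) antagonistic-
#' selection candidates — genes with significant Sb allelic bias whose SB
#' genotype totals are higher in heterozygotes (x_MQ > x_SQ) — and (ii) genes
#' with fewer than `min_reads` reads for either allele. Remaining genes are
#' binned by quantiles of the log2 SB/Sb ratio (quartiles by default) and a
#' rank-sum test compares `x_MQ` with `x_SQ` within each bin. Under complete
#' compensation no bin differs.
#'
#' @param points data.frame from [compute_proportions()].
#' @param allelic per-gene allelic test results (`gene`, `lfc`, `padj`).
#' @param alpha significance level for the exclusion rule.
#' @param n_bins number of quantile bins.
#' @param min_reads minimum reads per allele.
#' @return data.frame with one row per bin: `bin`, `n`, `median_log2_ratio`,
#'   `median_SQ`, `median_MQ`, `p`; excluded gene ids in
#'   `attr(, "excluded")`.
#' @export
grouped_total_expression_test <- function(points, allelic, alpha = 0.05,
                                          n_bins = 4, min_reads = 3) {
  stopifnot(all(c("gene", "lfc", "padj") %in% names(allelic)))
  d <- points
  a <- allelic[match(d$gene, allelic$gene), ]
  sb_antagonistic <- !is.na(a$padj) & a$padj < alpha & a$lfc < 0 & d$x_MQ > d$x_SQ
  low <- d$x_B < min_reads | d$x_b < min_reads
  excluded <- d$gene[sb_antagonistic | low]
  d <- d[!(sb_antagonistic | low), , drop = FALSE]
  if (!nrow(d)) stop_input("no genes left after exclusions")
  lr <- log2(d$x_B / d$x_b)
  br <- unique(quantile(lr, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(lr, breaks = br, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    rows <- bins == b
    if (!any(rows)) {
      warning("empty bin ", b, " skipped")
      return(NULL)
    }
    p <- if (sum(rows) >= 2)
      suppressWarnings(wilcox.test(d$x_MQ[rows], d$x_SQ[rows])$p.value)
    else NA_real_
    data.frame(bin = b, n = sum(rows),
               median_log2_ratio = median(lr[rows]),
               median_SQ = median(d$x_SQ[rows]), median_MQ = median(d$x_MQ[rows]),
               p = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
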