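## Tests of SB-vs-Sb expression bias: inverse-variance weights, the joint
## weighted linear mixed model across populations and body parts, the
## ancestry-vs-geography variance decomposition, per-population paired
## negative-binomial tests (library normalization disabled: both alleles of a
## sample come from the same library), body-part interaction tests,
## between-population correlations and the median-ratio location test.

#' Inverse-variance weights for log2 allelic ratios
#'
#' Delta-method variance of `log2(x_B/x_b)` for independent counts:
#' `Var = (1/x_B + 1/x_b) / ln(2)^2`; the weight is its reciprocal, so genes
#' with low expression are down-weighted. The pseudocount is applied only to
#' zero counts, matching [log2_ratio()].
#'
#' @param x_B,x_b allele read counts.
#' @param pseudocount pseudocount for zero counts.
#' @return numeric vector of weights.
#' @examples
#' compute_weights(100, 100) # (ln 2)^2 / 0.02
#' @export
compute_weights <- function(x_B, x_b, pseudocount = 0.5) {
  n <- max(length(x_B), length(x_b))
  x_B <- rep_len(x_B, n); x_b <- rep_len(x_b, n)
  if (any(x_B + x_b <= 0)) stop_input("x_B + x_b must be positive")
  xb2 <- ifelse(x_B == 0, pseudocount, x_B)
  xl2 <- ifelse(x_b == 0, pseudocount, x_b)
  log(2)^2 / (1 / xb2 + 1 / xl2)
}

#' Build per-observation log2-ratio records for the mixed models
#'
#' @param counts data.frame with `gene`, `sample`, `x_B`, `x_b`.
#' @param meta data.frame with `sample`, `population`, `body_part`, `caste`,
#'   `genotype`.
#' @param pseudocount passed to [log2_ratio()] and [compute_weights()].
#' @return data.frame with `gene`, `sample`, `population`, `body_part`,
#'   `caste`, `ratio`, `weight`, `total`; rows with `x_B + x_b = 0` dropped.
#' @export
build_bias_observations <- function(counts, meta, pseudocount = 0.5) {
  m <- match(counts$sample, meta$sample)
  if (anyNA(m)) stop_input("samples missing from metadata: %s",
                           paste(unique(counts$sample[is.na(m)]), collapse = ", "))
  keep <- counts$x_B + counts$x_b > 0
  d <- counts[keep, , drop = FALSE]; m <- m[keep]
  data.frame(gene = d$gene, sample = d$sample,
             population = meta$population[m], body_part = meta$body_part[m],
             caste = meta$caste[m],
             ratio = log2_ratio(d$x_B, d$x_b, pseudocount),
             weight = compute_weights(d$x_B, d$x_b, pseudocount),
             total = d$x_B + d$x_b, stringsAsFactors = FALSE)
}

joint_cell_contrasts <- function(X, data, genes, pops) {
  ## first design row realising each gene x population cell (the fixed-effect
  ## predictor depends on the cell only)
  key <- paste(data$gene, data$population, sep = "\r")
  setNames(lapply(genes, function(g) {
    rows <- vapply(pops, function(p) match(paste(g, p, sep = "\r"), key), integer(1))
    list(cells = lapply(setNames(rows, pops), function(r) X[r, ]),
         avg = colMeans(X[rows, , drop = FALSE]))
  }), genes)
}

#' Joint weighted mixed model of allelic bias across populations
#'
#' Fits `ratio ~ 0 + gene * population + (1 | body_part:gene)` with
#' inverse-variance weights, restricted to genes observed in every included
#' population. The per-gene significance is a Wald test (normal reference) of
#' the gene's fixed effect averaged over populations; per-population cell
#' estimates are reported alongside. When the random effect cannot be
#' estimated (single body part or singular fit) the model falls back to
#' weighted least squares with body part as a fixed blocking factor, flagged
#' in `method`.
#'
#' @param obs data.frame from [build_bias_observations()].
#' @param alpha significance level used downstream (stored, not applied).
#' @return list of class `joint_fit`: `genes` (gene, estimate, se, p, padj),
#'   `cells` (gene, population, estimate, se, p, padj), `method`
#'   (`"lmm"` or `"wls"`), `singular`, `model`.
#' @export
fit_joint_model <- function(obs, alpha = 0.05) {
  obs <- obs[is.finite(obs$ratio), , drop = FALSE]
  pops <- sort(unique(obs$population))
  bps <- unique(obs$body_part)
  if (length(pops) < 2 && length(bps) < 2)
    stop_input("need >= 2 populations or >= 2 body parts")
  keep_genes <- names(which(tapply(obs$population, obs$gene,
                                   function(p) all(pops %in% p))))
  obs <- obs[obs$gene %in% keep_genes, , drop = FALSE]
  if (!nrow(obs)) stop_input("no gene is observed in all populations")
  obs$gene <- factor(obs$gene)
  obs$population <- factor(obs$population)
  obs$bp_gene <- interaction(obs$body_part, obs$gene, drop = TRUE)

  multi_pop <- nlevels(obs$population) > 1
  fixed_rhs <- if (multi_pop) "0 + gene * population" else "0 + gene"
  method <- "lmm"; singular <- FALSE
  fitted_parts <- NULL
  if (length(bps) >= 2) {
    fitted_parts <- tryCatch({
      model <- suppressWarnings(suppressMessages(lme4::lmer(
        as.formula(paste("ratio ~", fixed_rhs, "+ (1 | bp_gene)")),
        data = obs, weights = obs$weight, REML = TRUE)))
      if (lme4::isSingular(model, tol = 1e-5)) singular <- TRUE
      if (singular) NULL else
        list(model = model, X = lme4::getME(model, "X"),
             beta = lme4::fixef(model),
             V = as.matrix(suppressWarnings(vcov(model))))
    }, error = function(e) NULL)
  }
  if (is.null(fitted_parts)) {
    method <- "wls"
    blocking <- if (length(bps) >= 2) "+ body_part" else ""
    model <- lm(as.formula(paste("ratio ~", fixed_rhs, blocking)),
                data = obs, weights = obs$weight)
    X <- model.matrix(model)
    beta <- coef(model); V <- vcov(model)
    ok <- !is.na(beta)
    X <- X[, ok, drop = FALSE]; beta <- beta[ok]; V <- V[ok, ok, drop = FALSE]
  } else {
    model <- fitted_parts$model
    X <- fitted_parts$X; beta <- fitted_parts$beta; V <- fitted_parts$V
  }

  genes <- levels(obs$gene)
  ctr <- joint_cell_contrasts(X, obs, genes, levels(obs$population))
  wald <- function(cvec) {
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    p <- if (se == 0) as.numeric(abs(est) <= 1e-12) else 2 * pnorm(-abs(est / se))
    c(est, se, p)
  }
  gene_tab <- do.call(rbind, lapply(genes, function(g) {
    w <- wald(ctr[[g]]$avg)
    data.frame(gene = g, estimate = w[1], se = w[2], p = w[3], stringsAsFactors = FALSE)
  }))
  gene_tab$padj <- bh_adjust(gene_tab$p)
  cell_tab <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(names(ctr[[g]]$cells), function(p) {
      w <- wald(ctr[[g]]$cells[[p]])
      data.frame(gene = g, population = p, estimate = w[1], se = w[2], p = w[3],
                 stringsAsFactors = FALSE)
    }))
  }))
  cell_tab$padj <- NA_real_
  for (p in unique(cell_tab$population)) {
    rows <- cell_tab$population == p
    cell_tab$padj[rows] <- bh_adjust(cell_tab$p[rows])
  }
  rownames(gene_tab) <- rownames(cell_tab) <- NULL
  structure(list(genes = gene_tab, cells = cell_tab, method = method,
                 singular = singular, alpha = alpha, model = model),
            class = "joint_fit")
}

#' Ancestry vs geography decomposition of allelic bias
#'
#' Fits `ratio ~ 0 + gene * ancestry + gene * geography + (1|body_part:gene)`
#' with inverse-variance weights and reports the sequential
#' analysis-of-variance F statistics for the `gene:ancestry` and
#' `gene:geography` interaction terms (ancestry entered first; on balanced
#' factorial population designs the two sums of squares are orthogonal and
#' order does not matter). A strong ancestry term with a null geography term
#' indicates that allelic bias tracks shared haplotype history rather than
#' location.
#'
#' @param obs data.frame from [build_bias_observations()]; all three
#'   populations must be present.
#' @param ancestry,geography named character vectors mapping population name
#'   to group label.
#' @return data.frame with `term`, `df1`, `df2`, `F`, `p` for the two
#'   interaction terms; attribute `"model"` carries the fit.
#' @export
fit_ancestry_geography_model <- function(obs,
    ancestry = c(south_america = "native", north_america = "invasive", taiwan = "invasive"),
    geography = c(south_america = "americas", north_america = "americas", taiwan = "taiwan")) {
  obs <- obs[is.finite(obs$ratio), , drop = FALSE]
  pops <- unique(obs$population)
  if (length(pops) < 3) stop_input("all three populations are required")
  if (!all(pops %in% names(ancestry)) || !all(pops %in% names(geography)))
    stop_input("ancestry/geography groupings must cover all populations")
  keep_genes <- names(which(tapply(obs$population, obs$gene,
                                   function(p) all(pops %in% p))))
  obs <- obs[obs$gene %in% keep_genes, , drop = FALSE]
  obs$gene <- factor(obs$gene)
  obs$ancestry <- factor(ancestry[obs$population])
  obs$geography <- factor(geography[obs$population])
  obs$bp_gene <- interaction(obs$body_part, obs$gene, drop = TRUE)

  use_lmm <- length(unique(obs$body_part)) >= 2
  model <- NULL
  if (use_lmm)
    model <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(
        ratio ~ 0 + gene * ancestry + gene * geography + (1 | bp_gene),
        data = obs, weights = obs$weight, REML = TRUE))),
      error = function(e) NULL)
  ## sequential (type-I) analysis of variance on the fitted model, ancestry
  ## terms entered first; on balanced factorial population designs the two
  ## interaction sums of squares are orthogonal and the order is irrelevant
  if (is.null(model)) {
    model <- lm(ratio ~ 0 + gene * ancestry + gene * geography,
                data = obs, weights = obs$weight)
    an <- anova(model)
    rows <- an[c("gene:ancestry", "gene:geography"), ]
    out <- data.frame(term = rownames(rows), df1 = rows$Df,
                      df2 = an["Residuals", "Df"], F = rows$`F value`,
                      p = rows$`Pr(>F)`, stringsAsFactors = FALSE)
  } else {
    an <- suppressWarnings(anova(model))
    rows <- an[c("gene:ancestry", "gene:geography"), ]
    df2 <- nrow(obs) - length(lme4::fixef(model))  # residual-df approximation
    out <- data.frame(term = rownames(rows), df1 = rows$npar, df2 = df2,
                      F = rows$`F value`,
                      p = pf(rows$`F value`, rows$npar, df2, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "model") <- model
  out
}

#' Per-population paired negative-binomial test of allelic bias
#'
#' For each gene within each population, fits a negative-binomial GLM on the
#' allele read counts with `sample` as blocking factor and allele as the
#' tested effect. Both alleles of a sample come from the same sequencing
#' library, so library scaling factors are fixed to 1. Dispersion is a
#' method-of-moments estimate shrunk toward the mean-dispersion trend; the
#' Wald test on the allele coefficient gives the p-value (BH-adjusted within
#' population). Non-converging fits are flagged with `p = 1`.
#'
#' @param counts data.frame with `gene`, `sample`, `x_B`, `x_b`
#'   (heterozygous samples only).
#' @param meta sample metadata with `sample`, `population`, `genotype`.
#' @param prior_df prior degrees of freedom for dispersion shrinkage.
#' @return data.frame with `gene`, `population`, `lfc` (log2 SB/Sb), `se`,
#'   `stat`, `p`, `padj`, `alpha_disp`, `converged`.
#' @export
test_allelic_bias_per_population <- function(counts, meta, prior_df = 20) {
  m <- match(counts$sample, meta$sample)
  if (anyNA(m)) stop_input("samples missing from metadata")
  if (any(meta$genotype[m] != "SB/Sb"))
    stop_input("allelic-bias tests require SB/Sb heterozygous samples")
  counts$population <- meta$population[m]
  out <- list()
  for (pop in unique(counts$population)) {
    d <- counts[counts$population == pop, , drop = FALSE]
    gene_data <- lapply(split(d, d$gene), function(g)
      data.frame(y = c(g$x_B, g$x_b),
                 sample = factor(rep(g$sample, 2)),
                 allele = factor(rep(c("SB", "Sb"), each = nrow(g)),
                                 levels = c("Sb", "SB"))))
    disp <- estimate_dispersions(gene_data, y ~ sample + allele, prior_df,
                                 paired_contrast_params = 1L)
    res <- do.call(rbind, lapply(seq_along(gene_data), function(i) {
      fit <- nb_glm_fixed(y ~ sample + allele, gene_data[[i]], disp$alpha[i])
      w <- wald_from_fit(fit, "alleleSB", df = disp$test_df[i])
      data.frame(gene = names(gene_data)[i], population = pop,
                 lfc = w$lfc, se = w$se, stat = w$stat, p = w$p,
                 alpha_disp = disp$alpha[i], converged = w$converged,
                 stringsAsFactors = FALSE)
    }))
    res$padj <- bh_adjust(res$p)
    out[[pop]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test allele-by-body-part (or caste) interaction
#'
#' Likelihood-ratio test of the allele x body-part interaction in the
#' negative-binomial model (`y ~ sample + allele` vs
#' `y ~ sample + allele + allele:body_part`; the sample blocking factor
#' absorbs body-part main effects), plus all pairwise Wald contrasts between
#' the per-body-part allele effects. BH adjustment is over genes and
#' contrasts jointly.
#'
#' @param counts data.frame with `gene`, `sample`, `x_B`, `x_b`.
#' @param meta metadata with `sample` and the grouping column.
#' @param group metadata column defining the interaction levels
#'   (default `"body_part"`).
#' @param prior_df dispersion shrinkage prior df.
#' @return data.frame with `gene`, `test` (`"LRT"` or `"pair:<a>-<b>"`),
#'   `stat`, `df`, `p`, `padj`.
#' @export
test_body_part_interaction <- function(counts, meta, group = "body_part", prior_df = 20) {
  m <- match(counts$sample, meta$sample)
  if (anyNA(m)) stop_input("samples missing from metadata")
  counts$grp <- meta[[group]][m]
  lv <- sort(unique(counts$grp))
  if (length(lv) < 2) stop_input("need >= 2 %s levels", group)
  ## numeric SB indicator: `z:grp` gives one allele-effect coefficient per
  ## group level with no aliasing against the sample blocking factor
  gene_data <- lapply(split(counts, counts$gene), function(g)
    data.frame(y = c(g$x_B, g$x_b),
               sample = factor(rep(g$sample, 2)),
               grp = factor(rep(g$grp, 2), levels = lv),
               allele = factor(rep(c("SB", "Sb"), each = nrow(g)),
                               levels = c("Sb", "SB")),
               z = rep(c(1, 0), each = nrow(g))))
  disp <- estimate_dispersions(gene_data, y ~ sample + z:grp, prior_df,
                               paired_contrast_params = length(lv))
  rows <- list()
  for (i in seq_along(gene_data)) {
    d <- gene_data[[i]]; gid <- names(gene_data)[i]
    full <- nb_glm_fixed(y ~ sample + z:grp, d, disp$alpha[i])
    red <- nb_glm_fixed(y ~ sample + z, d, disp$alpha[i])
    if (is.null(full) || is.null(red)) next
    lrt <- max(red$deviance - full$deviance, 0)
    dfree <- length(lv) - 1L
    rows[[length(rows) + 1L]] <-
      data.frame(gene = gid, test = "LRT", stat = lrt, df = dfree,
                 p = pchisq(lrt, dfree, lower.tail = FALSE), stringsAsFactors = FALSE)
    cn <- names(full$coef)
    for (a in seq_along(lv)) for (b in seq_along(lv)) {
      if (a >= b) next
      na_ <- paste0("z:grp", lv[a]); nb_ <- paste0("z:grp", lv[b])
      if (!all(c(na_, nb_) %in% cn)) next
      cvec <- setNames(numeric(length(cn)), cn)
      cvec[na_] <- 1; cvec[nb_] <- -1
      est <- sum(cvec * full$coef)
      se <- sqrt(drop(t(cvec) %*% full$vcov %*% cvec))
      z <- est / se
      rows[[length(rows) + 1L]] <-
        data.frame(gene = gid, test = sprintf("pair:%s-%s", lv[a], lv[b]),
                   stat = z, df = 1L, p = 2 * stats::pt(-abs(z), df = disp$test_df[i]),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Pairwise Spearman rank correlations (squared) between populations
#'
#' @param ratio_table numeric matrix or data.frame of per-gene mean log2
#'   ratios, genes in rows, populations in columns.
#' @return symmetric matrix of squared Spearman correlations.
#' @export
correlate_populations <- function(ratio_table) {
  tab <- as.matrix(ratio_table)
  if (ncol(tab) < 2) stop_input("need >= 2 populations")
  for (i in seq_len(ncol(tab) - 1)) for (j in (i + 1):ncol(tab))
    if (sum(complete.cases(tab[, c(i, j)])) < 2)
      stop_input("fewer than 2 shared genes between %s and %s",
                 colnames(tab)[i], colnames(tab)[j])
  cor(tab, method = "spearman", use = "pairwise.complete.obs")^2
}

#' Median log2 allelic ratio and its deviation from zero
#'
#' One-sample Wilcoxon signed-rank test of the per-gene log2 SB/Sb ratios
#' against 0 (an overall transcriptional bias toward either haplotype).
#'
#' @param ratios numeric vector of per-gene log2 ratios.
#' @return list with `median`, `p`, `statistic`.
#' @export
median_bias_test <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) stop_input("no finite ratios")
  wt <- tryCatch(suppressWarnings(wilcox.test(ratios, mu = 0)),
                 error = function(e) list(p.value = 1, statistic = NA_real_))
  list(median = median(ratios), p = wt$p.value, statistic = unname(wt$statistic))
}
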