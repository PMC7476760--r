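## Shared negative-binomial GLM machinery: method-of-moments dispersion with
## shrinkage toward a parametric mean-dispersion trend, and fixed-dispersion
## Wald fits. Deliberately simpler than a full empirical-Bayes engine; the
## calibration is validated by type-I-error properties in the test suite.

DISP_FLOOR <- 1e-8

## MoM dispersion from a fitted mean: solves var = mu + alpha mu^2 using the
## df-corrected residual sum of squares.
mom_dispersion <- function(y, mu, n_params) {
  n <- length(y)
  df <- max(n - n_params, 1L)
  num <- sum((y - mu)^2) * n / df - sum(mu)
  max(num / sum(mu^2), DISP_FLOOR)
}

## Parametric trend alpha(mu) = a0 + a1/mu fitted to per-gene MoM estimates;
## falls back to the median dispersion when the fit fails or goes negative.
dispersion_trend <- function(means, alphas) {
  const <- max(median(alphas), DISP_FLOOR)
  ok <- is.finite(means) & means > 0 & is.finite(alphas)
  if (sum(ok) < 10) return(function(mu) rep(const, length(mu)))
  fit <- tryCatch(
    nls(a ~ a0 + a1 / m, data = data.frame(a = alphas[ok], m = means[ok]),
        start = list(a0 = const, a1 = 1),
        lower = c(a0 = DISP_FLOOR, a1 = 0), algorithm = "port",
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(function(mu) rep(const, length(mu)))
  cf <- coef(fit)
  function(mu) pmax(cf[["a0"]] + cf[["a1"]] / pmax(mu, 1), DISP_FLOOR)
}

## Log-scale shrinkage of per-gene dispersions toward the trend value,
## weighting data by residual df against `prior_df` prior degrees of freedom.
## The log of a moment estimator is biased low (Jensen); the chi-square
## correction digamma(df/2) - log(df/2) removes it before averaging.
shrink_dispersion <- function(alpha_mom, alpha_trend, data_df, prior_df = 20) {
  w <- data_df / (data_df + prior_df)
  log_corr <- digamma(data_df / 2) - log(data_df / 2)
  pmax(exp(w * (log(pmax(alpha_mom, DISP_FLOOR)) - log_corr) +
           (1 - w) * log(pmax(alpha_trend, DISP_FLOOR))), DISP_FLOOR)
}

nb_family <- function(alpha) {
  if (alpha <= DISP_FLOOR * 2) poisson(link = "log")
  else MASS::negative.binomial(theta = 1 / alpha, link = "log")
}

## Fixed-dispersion NB GLM; returns coefficients, covariance (dispersion
## parameter of the GLM fixed at 1), deviance and a convergence flag.
nb_glm_fixed <- function(formula, data, alpha, offset = NULL) {
  ## do.call so `offset` is passed by value (glm evaluates it non-standardly)
  args <- list(formula, data = data, family = nb_family(alpha),
               control = list(maxit = 50))
  if (!is.null(offset)) args$offset <- offset
  fit <- tryCatch(suppressWarnings(do.call(glm, args)), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  sm <- summary(fit, dispersion = 1)
  cf <- coef(fit)
  cf <- cf[!is.na(cf)]  # drop aliased coefficients; se/vcov already exclude them
  list(coef = cf, se = sm$coefficients[, "Std. Error"],
       vcov = sm$cov.scaled, deviance = fit$deviance,
       converged = isTRUE(fit$converged), fit = fit)
}

## Wald test of one coefficient; estimates reported on the log2 scale. The
## reference distribution is t with the effective df of the dispersion
## estimate (residual df + prior df), the usual small-sample correction for
## plug-in dispersions; df = Inf gives the normal reference.
wald_from_fit <- function(fit, coef_name, df = Inf) {
  if (is.null(fit) || !coef_name %in% names(fit$coef))
    return(list(lfc = NA_real_, se = NA_real_, stat = NA_real_, p = 1, converged = FALSE))
  est <- fit$coef[[coef_name]]; se <- fit$se[[coef_name]]
  z <- est / se
  list(lfc = est / log(2), se = se / log(2), stat = z,
       p = if (fit$converged) 2 * stats::pt(-abs(z), df = df) else 1,
       converged = fit$converged)
}

## Contrast-scale MoM dispersion for paired allele designs. The two allele
## counts of a sample are an anti-correlated split of the sample total, so
## marginal residual variance understates the variance of the within-sample
## allele contrast (the scale the Wald test operates on). Solving
## var(y_SB - y_Sb) = mu_SB + mu_Sb + alpha (mu_SB^2 + mu_Sb^2) on the
## per-sample contrast residuals calibrates the allele test; for truly
## independent NB counts it estimates the ordinary dispersion.
mom_dispersion_contrast <- function(d, mu, n_contrast_params) {
  split_idx <- split(seq_len(nrow(d)), d$sample)
  r2 <- 0; lin <- 0; quad <- 0; n <- 0
  for (idx in split_idx) {
    if (length(idx) != 2L) next
    i <- idx[order(d$allele[idx], decreasing = TRUE)]  # SB first
    r <- (d$y[i[1]] - mu[i[1]]) - (d$y[i[2]] - mu[i[2]])
    r2 <- r2 + r^2; lin <- lin + sum(mu[i]); quad <- quad + sum(mu[i]^2)
    n <- n + 1L
  }
  df <- max(n - n_contrast_params, 1L)
  max((r2 * n / df - lin) / quad, DISP_FLOOR)
}

## Two-stage dispersion estimation across genes: Poisson working fits give
## MoM dispersions and fitted means, then shrinkage toward the trend.
## `paired_contrast_params`, when non-NULL, switches to the contrast-scale
## estimator with that many parameters acting on the contrast.
estimate_dispersions <- function(gene_data, formula, prior_df = 20, offset_col = NULL,
                                 paired_contrast_params = NULL) {
  n_genes <- length(gene_data)
  alpha_mom <- numeric(n_genes); mean_count <- numeric(n_genes); data_df <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    d <- gene_data[[i]]
    args <- list(formula, data = d, family = poisson())
    if (!is.null(offset_col)) args$offset <- d[[offset_col]]
    fit <- tryCatch(suppressWarnings(do.call(glm, args)), error = function(e) NULL)
    if (is.null(fit)) {
      alpha_mom[i] <- NA; mean_count[i] <- mean(d$y); data_df[i] <- 1
      next
    }
    p <- fit$rank
    if (is.null(paired_contrast_params)) {
      alpha_mom[i] <- mom_dispersion(d$y, fitted(fit), p)
      data_df[i] <- max(nrow(d) - p, 1L)
    } else {
      alpha_mom[i] <- mom_dispersion_contrast(d, fitted(fit), paired_contrast_params)
      data_df[i] <- max(length(unique(d$sample)) - paired_contrast_params, 1L)
    }
    mean_count[i] <- mean(fitted(fit))
  }
  ok <- !is.na(alpha_mom)
  trend <- dispersion_trend(mean_count[ok], alpha_mom[ok])
  alpha <- shrink_dispersion(ifelse(ok, alpha_mom, median(alpha_mom[ok])),
                             trend(mean_count), data_df, prior_df)
  list(alpha = alpha, alpha_mom = alpha_mom, mean_count = mean_count,
       test_df = data_df + prior_df)
}
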