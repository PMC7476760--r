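## Gene-level differential expression between single-queen (SB/SB) and
## multiple-queen (SB/Sb) colonies: median-of-ratios normalization and a
## fixed-dispersion negative-binomial Wald test.

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of the ratio of its count to the
#' geometric mean of that gene's counts across samples; only genes with
#' non-zero counts in every sample contribute. The resulting factors have
#' geometric mean 1. With no all-nonzero gene the default is an error;
#' `pseudo_reference = TRUE` instead computes each gene's geometric mean over
#' its positive counts only.
#'
#' @param mat gene x sample matrix of non-negative integer counts.
#' @param pseudo_reference fall back to positive-count geometric means.
#' @return named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(mat, pseudo_reference = FALSE) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop_input("counts must be non-negative")
  logs <- log(mat)
  if (pseudo_reference) {
    log_geo <- apply(logs, 1L, function(x) {
      x <- x[is.finite(x)]
      if (length(x)) mean(x) else -Inf
    })
  } else {
    log_geo <- rowMeans(logs)
    if (!any(is.finite(log_geo)))
      stop_input(paste("no gene has non-zero counts in all samples;",
                       "consider pseudo_reference = TRUE"))
  }
  sf <- apply(logs, 2L, function(lc) {
    r <- (lc - log_geo)[is.finite(lc) & is.finite(log_geo)]
    if (!length(r)) stop_input("a sample shares no usable gene with the reference")
    exp(median(r))
  })
  setNames(sf, colnames(mat))
}

#' Negative-binomial Wald test of social-form expression differences
#'
#' Per gene, fits `count ~ social_form` with `log(size factor)` offsets and a
#' method-of-moments dispersion shrunk toward the mean-dispersion trend, then
#' Wald-tests the social-form coefficient. Positive log2 fold changes mean
#' higher expression in multiple-queen colonies. Non-converging fits are
#' flagged with `p = 1`. BH adjustment is over genes.
#'
#' @param mat gene x sample count matrix.
#' @param meta metadata with `sample` and `social_form`
#'   (`"single_queen"` / `"multiple_queen"`); >= 2 replicates per form.
#' @param size_factors optional precomputed factors
#'   (default [estimate_size_factors()]).
#' @param prior_df dispersion shrinkage prior df.
#' @return data.frame with `gene`, `lfc` (log2 MQ/SQ), `se`, `stat`, `p`,
#'   `padj`, `mean_SQ`, `mean_MQ` (normalized per-form means), `alpha_disp`,
#'   `converged`.
#' @export
wald_test_social <- function(mat, meta, size_factors = NULL, prior_df = 20) {
  mat <- as.matrix(mat)
  m <- match(colnames(mat), meta$sample)
  if (anyNA(m)) stop_input("samples missing from metadata")
  form <- factor(meta$social_form[m], levels = c("single_queen", "multiple_queen"))
  if (any(table(form) < 2)) stop_input("need >= 2 replicates per social form")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(mat)
  sf <- size_factors[colnames(mat)]
  if (any(!is.finite(sf) | sf <= 0)) stop_input("size factors must be positive")
  norm <- sweep(mat, 2L, sf, "/")
  off <- log(sf)
  gene_data <- lapply(seq_len(nrow(mat)), function(i)
    data.frame(y = mat[i, ], form = form, off = off))
  names(gene_data) <- rownames(mat)
  disp <- estimate_dispersions(gene_data, y ~ form, prior_df, offset_col = "off")
  res <- do.call(rbind, lapply(seq_along(gene_data), function(i) {
    d <- gene_data[[i]]
    fit <- nb_glm_fixed(y ~ form, d, disp$alpha[i], offset = d$off)
    w <- wald_from_fit(fit, "formmultiple_queen", df = disp$test_df[i])
    data.frame(gene = names(gene_data)[i], lfc = w$lfc, se = w$se, stat = w$stat,
               p = w$p,
               mean_SQ = mean(norm[i, form == "single_queen"]),
               mean_MQ = mean(norm[i, form == "multiple_queen"]),
               alpha_disp = disp$alpha[i], converged = w$converged,
               stringsAsFactors = FALSE)
  }))
  res$padj <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}
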