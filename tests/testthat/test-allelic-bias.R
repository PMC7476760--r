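make_obs <- function(truth, pops, bps, n_rep, noise_sd, seed, weight = 24, bp_sd = 0) {
  ## truth: named vector of per-gene log2 ratios, or function(gene, pop) -> mean
  withr::with_seed(seed, {
    grid <- expand.grid(gene = names(truth), population = pops, body_part = bps,
                        rep = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    mu <- if (is.function(attr(truth, "fn") %||% NULL))
      attr(truth, "fn")(grid$gene, grid$population) else truth[grid$gene]
    bpg <- interaction(grid$body_part, grid$gene)
    bp_off <- rnorm(nlevels(bpg), 0, bp_sd)[as.integer(bpg)]
    data.frame(gene = grid$gene, sample = paste0(grid$population, "_", grid$body_part,
                                                 "_", grid$rep),
               population = grid$population, body_part = grid$body_part,
               caste = "queen",
               ratio = mu + bp_off + rnorm(nrow(grid), 0, noise_sd),
               weight = weight, total = 200, stringsAsFactors = FALSE)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("inverse-variance weights match the delta-method closed form", {
  expect_equal(compute_weights(100, 100), log(2)^2 / 0.02, tolerance = 1e-12)
  expect_equal(round(compute_weights(100, 100), 2), 24.02)
  expect_equal(compute_weights(40, 60), 2 * compute_weights(20, 30), tolerance = 1e-12)
  w <- compute_weights(c(1, 10, 100), c(1, 10, 100))
  expect_true(all(diff(w) > 0))
  expect_error(compute_weights(0, 0), "positive")
})

test_that("joint model recovers per-gene effects and flags the null gene", {
  truth <- c(geneA = 1, geneB = 0)
  obs <- make_obs(truth, c("p1", "p2"), c("head", "thorax"), 6, 0.2, seed = 1,
                  bp_sd = 0.3)
  fit <- fit_joint_model(obs)
  g <- fit$genes
  a <- g[g$gene == "geneA", ]; b <- g[g$gene == "geneB", ]
  expect_lt(a$padj, 0.05)
  expect_gt(b$padj, 0.05)
  expect_lt(abs(a$estimate - 1), 2 * a$se)
  expect_identical(nrow(fit$cells), 4L)
  ## shuffling row order leaves estimates unchanged
  obs2 <- obs[sample(nrow(obs)), ]
  fit2 <- fit_joint_model(obs2)
  expect_identical(fit2$method, fit$method)
  expect_equal(fit2$genes[order(fit2$genes$gene), ]$estimate,
               g[order(g$gene), ]$estimate, tolerance = 1e-6)
})

test_that("all-zero ratios give no significant gene", {
  obs <- make_obs(c(g1 = 0, g2 = 0), c("p1", "p2"), c("head", "thorax"), 4, 0, seed = 2)
  fit <- fit_joint_model(obs)
  expect_true(all(fit$genes$p > 0.99))
})

test_that("ancestry vs geography attributes the signal to the right grouping", {
  anc <- c(south_america = "native", north_america = "invasive", taiwan = "invasive")
  geo <- c(south_america = "americas", north_america = "americas", taiwan = "taiwan")
  pops <- names(anc)
  genes <- sprintf("g%02d", 1:20)
  ## ancestry-driven world: south_america deviates per gene
  withr::with_seed(3, delta <- rnorm(length(genes), 0, 0.8))
  fn <- function(g, p) ifelse(p == "south_america", delta[match(g, genes)], 0)
  truth <- setNames(rep(0, length(genes)), genes); attr(truth, "fn") <- fn
  obs <- make_obs(truth, pops, c("head", "thorax"), 4, 0.2, seed = 4)
  res <- fit_ancestry_geography_model(obs, anc, geo)
  expect_lt(res$p[res$term == "gene:ancestry"], 0.01)
  expect_gt(res$p[res$term == "gene:geography"], 0.1)
  ## identical populations: both terms null
  obs3 <- make_obs(setNames(rep(0.3, 20), genes), pops, c("head", "thorax"), 4, 0.2, seed = 13)
  res3 <- fit_ancestry_geography_model(obs3, anc, geo)
  expect_true(all(res3$p > 0.05))
  expect_error(fit_ancestry_geography_model(obs[obs$population != "taiwan", ], anc, geo),
               "three populations")
})

test_that("swapping the groupings swaps the F statistics on a factorial design", {
  ## balanced 2x2 population design: the two interaction sums of squares are
  ## orthogonal, so the sequential decomposition is order-invariant
  anc4 <- c(p_na = "native", p_ia = "invasive", p_nb = "native", p_ib = "invasive")
  geo4 <- c(p_na = "west", p_ia = "west", p_nb = "east", p_ib = "east")
  genes <- sprintf("g%02d", 1:10)
  withr::with_seed(7, delta <- rnorm(length(genes), 0, 0.6))
  fn <- function(g, p) ifelse(p %in% c("p_na", "p_nb"), delta[match(g, genes)], 0)
  truth <- setNames(rep(0, length(genes)), genes); attr(truth, "fn") <- fn
  obs <- make_obs(truth, names(anc4), "whole", 4, 0.2, seed = 8)
  res <- fit_ancestry_geography_model(obs, anc4, geo4)
  swapped <- fit_ancestry_geography_model(obs, ancestry = geo4, geography = anc4)
  expect_equal(res$F[res$term == "gene:ancestry"],
               swapped$F[swapped$term == "gene:geography"], tolerance = 1e-8)
  expect_equal(res$F[res$term == "gene:geography"],
               swapped$F[swapped$term == "gene:ancestry"], tolerance = 1e-8)
})

nb_meta <- function(samples) data.frame(sample = samples, population = "north_america",
                                        caste = "queen", body_part = "whole",
                                        colony = samples, social_form = "multiple_queen",
                                        genotype = "SB/Sb", stringsAsFactors = FALSE)

test_that("per-population NB test recovers a known allelic bias", {
  samples <- sprintf("s%d", 1:6)
  withr::with_seed(7, {
    counts <- do.call(rbind, lapply(sprintf("g%02d", 1:40), function(g) {
      tot <- rnbinom(6, mu = 500, size = 20)
      xb <- rbinom(6, tot, 0.75)
      data.frame(gene = g, sample = samples, x_B = xb, x_b = tot - xb)
    }))
  })
  res <- test_allelic_bias_per_population(counts, nb_meta(samples))
  expect_true(all(res$converged))
  expect_gt(mean(res$padj < 0.05), 0.95)
  expect_gt(mean(abs(res$lfc - log2(3)) < 2 * res$se), 0.85)
})

test_that("identical allele counts give exactly zero fold change", {
  samples <- sprintf("s%d", 1:4)
  counts <- data.frame(gene = "g1", sample = samples,
                       x_B = c(10, 20, 30, 40), x_b = c(10, 20, 30, 40))
  res <- test_allelic_bias_per_population(counts, nb_meta(samples))
  expect_equal(res$lfc, 0, tolerance = 1e-9)
})

test_that("allele relabeling negates fold changes and keeps p-values", {
  cfg <- one_pop_config(30, seed = 23,
                        regime_mix = c(neutral = 0.5, degenerate = 0,
                                       compensated = 0.5, antagonistic = 0))
  sim <- simulate_dataset(cfg)
  gc <- sim$gene_counts
  res <- test_allelic_bias_per_population(gc, sim$meta)
  swapped <- gc; swapped$x_B <- gc$x_b; swapped$x_b <- gc$x_B
  res2 <- test_allelic_bias_per_population(swapped, sim$meta)
  expect_equal(res2$lfc, -res$lfc, tolerance = 1e-6)
  expect_equal(res2$p, res$p, tolerance = 1e-6)
})

test_that("null simulation yields roughly uniform allele-test p-values", {
  cfg <- one_pop_config(200, seed = 29)
  sim <- simulate_dataset(cfg)
  res <- test_allelic_bias_per_population(sim$gene_counts, sim$meta)
  expect_lt(mean(res$p < 0.05), 0.12)
  expect_gt(mean(res$p), 0.4)
  expect_lt(mean(res$p), 0.6)
})

test_that("body-part interaction: null under constant bias, detected when real", {
  samples <- sprintf("s%02d", 1:12)
  meta <- data.frame(sample = samples, body_part = rep(c("head", "abdomen"), each = 6))
  ## duplicated identical groups -> LRT ~ 0
  counts0 <- data.frame(gene = "g1", sample = samples,
                        x_B = rep(c(30, 40, 50, 60, 70, 80), 2),
                        x_b = rep(c(28, 41, 52, 61, 69, 77), 2))
  r0 <- test_body_part_interaction(counts0, meta)
  expect_lt(r0$stat[r0$test == "LRT"], 1e-6)
  ## head P_B = 0.8, abdomen P_B = 0.5 at depth 1000 -> detected
  withr::with_seed(9, {
    tot <- rnbinom(12, mu = 1000, size = 20)
    pb <- ifelse(meta$body_part == "head", 0.8, 0.5)
    xb <- rbinom(12, tot, pb)
  })
  counts1 <- data.frame(gene = "g1", sample = samples, x_B = xb, x_b = tot - xb)
  r1 <- test_body_part_interaction(counts1, meta)
  expect_lt(r1$p[r1$test == "LRT"], 0.01)
  ## tissue-constant simulation: >= 95% of genes non-significant after BH
  cfg <- sim_config(n_genes_supergene = 40, n_genes_background = 0,
                    regime_mix = c(neutral = 0.5, degenerate = 0,
                                   compensated = 0.5, antagonistic = 0),
                    populations = list(list(name = "south_america", ancestry = "native",
                                            geography = "americas", bottleneck = 1,
                                            n_SB_males = 7, n_Sb_males = 7)),
                    samples = data.frame(population = "south_america", caste = "queen",
                                         body_part = c("head", "thorax", "abdomen"),
                                         social_form = "multiple_queen",
                                         genotype = "SB/Sb", n = 6),
                    seed = 31)
  sim <- simulate_dataset(cfg)
  rr <- test_body_part_interaction(sim$gene_counts, sim$meta)
  lrt <- rr[rr$test == "LRT", ]
  expect_gt(mean(lrt$padj >= 0.05), 0.95)
  expect_error(test_body_part_interaction(counts1, transform(meta, body_part = "head")),
               ">= 2")
})

test_that("population correlations are squared Spearman coefficients", {
  x <- c(1, 2, 3, 4, 5)
  tab <- cbind(a = x, b = x, c = -x)
  r2 <- correlate_populations(tab)
  expect_equal(unname(r2["a", "b"]), 1)
  expect_equal(unname(r2["a", "c"]), 1)  # rank correlation -1, squared
  withr::with_seed(10, tab2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z"))))
  r2b <- correlate_populations(tab2)
  manual <- cor(apply(tab2, 2, rank))^2
  expect_equal(r2b, manual, tolerance = 1e-12)
  expect_error(correlate_populations(tab2[, 1, drop = FALSE]), ">= 2")
})

test_that("median bias test behaves at the symmetric and shifted extremes", {
  sym <- rep(c(-0.4, 0.4), 10)
  r <- median_bias_test(sym)
  expect_equal(r$median, 0)
  expect_gt(r$p, 0.9)
  r1 <- median_bias_test(rep(1, 12))
  expect_equal(r1$median, 1)
  expect_lt(r1$p, 0.01)
  withr::with_seed(11, shifted <- rnorm(20, 0.5, 0.1))
  expect_lt(median_bias_test(shifted)$p, 1e-4)
  expect_error(median_bias_test(numeric(0)), "no finite")
})

test_that("BH adjustment matches the step-up definition and the reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_adjust(0.2), 0.2)
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      adj <- bh_adjust(p)
      expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-14)
      ## explicit step-up: min over j >= i of m p_(j) / j
      o <- order(p); m <- length(p)
      brute <- numeric(m)
      for (i2 in seq_len(m))
        brute[o[i2]] <- min(1, min(p[o][i2:m] * m / (i2:m)))
      expect_equal(adj, brute, tolerance = 1e-14)
      expect_true(all(adj >= p & adj <= 1))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
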