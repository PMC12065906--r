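test_that("low-count filter keeps exactly the supported genes", {
  counts <- tiny_counts()
  ## gA always expressed; gB has 5 reads in exactly 3 samples; gC all zero
  kept <- filter_low_counts(counts)
  expect_identical(kept$gene_id, c("gA", "gB"))

  ## counts of 4 everywhere never reach the 5-read bar
  four <- tibble::tibble(gene_id = "g", s1 = 4L, s2 = 4L, s3 = 4L, s4 = 4L)
  expect_warning(out4 <- filter_low_counts(four), "every gene")
  expect_equal(nrow(out4), 0L)

  all_zero <- tibble::tibble(gene_id = c("a", "b"),
                             s1 = 0L, s2 = 0L, s3 = 0L)
  expect_warning(out <- filter_low_counts(all_zero), "every gene")
  expect_equal(nrow(out), 0L)

  ## order preserved
  sh <- counts[c(2, 1, 3), ]
  expect_identical(filter_low_counts(sh)$gene_id, c("gB", "gA"))
})

test_that("median-of-ratios size factors match hand computation", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           s1 = c(10L, 20L, 40L), s2 = c(10L, 20L, 40L))
  expect_equal(unname(estimate_size_factors(counts)), c(1, 1))

  doubled <- counts
  doubled$s2 <- counts$s1 * 2L
  sf <- estimate_size_factors(doubled)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  ## invariant to gene order
  expect_equal(estimate_size_factors(doubled[c(3, 1, 2), ]), sf)

  no_common <- tibble::tibble(gene_id = c("a", "b"),
                              s1 = c(5L, 0L), s2 = c(0L, 5L))
  expect_error(estimate_size_factors(no_common), "nonzero")
})

test_that("BH adjustment matches the step-up hand example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  out <- bh_adjust(c(0.01, NaN, 0.04))
  expect_true(is.nan(out[2]))
  expect_equal(out[c(1, 3)], c(0.02, 0.04))  # NaN excluded from m
  p <- withr::with_seed(1, runif(100))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Wald contrast is antisymmetric and handles degenerate genes", {
  mu <- matrix(rep(c(100, 400), each = 3), nrow = 1)
  mu <- mu[rep(1, 30), ]
  colnames(mu) <- paste0("s", 1:6)
  counts <- nb_counts_from_means(mu, dispersion = 0.05, seed = 42)
  counts[1, ] <- 0L                      # all-zero gene
  counts[2, 4:6] <- 0L                   # zero in group B
  tb <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%02d", 1:30)),
                         tibble::as_tibble(counts))
  samples <- tiny_samples()
  sf <- stats::setNames(rep(1, 6), samples$sample_id)

  ab <- nb_wald(tb, samples, contrast = c("B", "A"), size_factors = sf)
  ba <- nb_wald(tb, samples, contrast = c("A", "B"), size_factors = sf)
  expect_equal(ab$log2fc[-c(1, 2)], -ba$log2fc[-c(1, 2)], tolerance = 1e-6)
  expect_equal(ab$pvalue[-c(1, 2)], ba$pvalue[-c(1, 2)], tolerance = 1e-6)

  expect_equal(ab$pvalue[1], 1)
  expect_equal(ab$log2fc[1], 0)
  expect_equal(ab$note[1], "all_zero")
  expect_equal(ab$note[2], "zero_group")
  ## pseudo-count fold change for the zero group
  expect_lt(ab$log2fc[2], 0)
})

test_that("Wald log2fc approaches the group mean ratio at tiny dispersion", {
  ## closed-form limit: deterministic 4x ratio, dispersion -> 0
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"),
    s1 = c(1000L, 500L), s2 = c(1000L, 500L), s3 = c(1000L, 500L),
    s4 = c(4000L, 500L), s5 = c(4000L, 500L), s6 = c(4000L, 500L)
  )
  samples <- tiny_samples()
  res <- nb_wald(counts, samples, contrast = c("B", "A"),
                 size_factors = stats::setNames(rep(1, 6), samples$sample_id))
  expect_equal(res$log2fc[1], 2, tolerance = 1e-3)
  expect_equal(res$log2fc[2], 0, tolerance = 1e-6)
})

test_that("NB fit agrees with a brute-force grid-search oracle", {
  y <- withr::with_seed(77, stats::rnbinom(6, mu = rep(c(80, 320), each = 3),
                                           size = 1 / 0.05))
  group <- rep(c("A", "B"), each = 3)
  oracle <- smadsig:::nb_grid_mle(y, group)
  X <- cbind(1, as.numeric(group == "B"))
  fit <- smadsig:::nb_wald_fit(y, X, offset = rep(0, 6), alpha = oracle$alpha)
  mu_fit <- exp(c(fit$beta[1], fit$beta[1] + fit$beta[2]))
  expect_equal(unname(mu_fit), unname(oracle$mu), tolerance = 0.02)
  ## the glm-based likelihood can only beat or match the grid
  expect_gte(fit$ll + 1e-6, oracle$ll)
})

test_that("DE results are invariant to rescaling one sample's library", {
  sim <- simulate_bulk_counts(bulk_sim_config(
    n_genes = 120, seed = 15, class_fractions = c(early_up = 0.2)
  ))
  counts <- filter_low_counts(sim$counts)
  samples <- dplyr::mutate(sim$samples, group = paste0(genotype, "_", time))
  res1 <- nb_wald(counts, samples, contrast = c("WT_1", "WT_0"))
  scaled <- counts
  scaled[[2]] <- scaled[[2]] * 2L
  res2 <- nb_wald(scaled, samples, contrast = c("WT_1", "WT_0"))
  expect_equal(res1$log2fc, res2$log2fc, tolerance = 0.05)
  expect_equal(res1$pvalue < 0.05, res2$pvalue < 0.05)
})

test_that("LRT degenerates to zero for identical designs and is non-negative", {
  sim <- simulate_bulk_counts(bulk_sim_config(n_genes = 60, seed = 2))
  counts <- filter_low_counts(sim$counts)
  samples <- sim$samples
  same <- nb_lrt(counts, samples, ~ genotype, ~ genotype)
  expect_true(all(same$stat == 0))
  expect_true(all(same$pvalue == 1))

  lrt <- nb_lrt(counts, samples, ~ genotype * factor(time),
                ~ genotype + factor(time))
  expect_true(all(lrt$stat >= 0, na.rm = TRUE))
  expect_true(all(lrt$df == 2))

  expect_error(nb_lrt(counts, samples, ~ genotype, ~ factor(time)),
               "not nested")
})

test_that("LRT ranks planted genotype x time interactions ahead of null genes", {
  sim <- simulate_bulk_counts(bulk_sim_config(
    n_genes = 150, seed = 31, effect_lfc = 3,
    class_fractions = c(smad4_dependent = 0.3)
  ))
  counts <- filter_low_counts(sim$counts)
  lrt <- nb_lrt(counts, sim$samples, ~ genotype * factor(time),
                ~ genotype + factor(time))
  truth <- sim$truth[match(lrt$gene_id, sim$truth$gene_id), ]
  p_planted <- median(lrt$pvalue[truth$class == "smad4_dependent"], na.rm = TRUE)
  p_null <- median(lrt$pvalue[truth$class == "null"], na.rm = TRUE)
  expect_lt(p_planted, p_null)
  expect_lt(p_planted, 1e-4)
})

test_that("DEG calls respect the inclusive fold-change boundary", {
  res <- de_tbl(c("a", "b", "c"))
  res$log2fc <- c(1.5, 2, -1.6)
  res$padj <- c(0.01, 0.06, 0.001)
  out <- call_deg(res)
  expect_identical(out$gene_id, c("a", "c"))
  expect_identical(out$direction, c("up", "down"))
})

test_that("Wald estimates agree with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_bulk_counts(bulk_sim_config(
    n_genes = 200, seed = 55, effect_lfc = 3,
    class_fractions = c(early_up = 0.2)
  ))
  counts <- filter_low_counts(sim$counts)
  samples <- dplyr::mutate(sim$samples, group = paste0(genotype, "_", time))
  mine <- nb_wald(counts, samples, contrast = c("WT_1", "WT_0"))

  suppressMessages({
    m <- as.matrix(counts[, -1])
    rownames(m) <- counts$gene_id
    coldata <- as.data.frame(samples)
    coldata$group <- factor(coldata$group)
    dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, ~ group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("group", "WT_1", "WT_0"))
  })
  ref <- as.data.frame(ref)[mine$gene_id, ]

  ## point estimates track the reference implementation closely
  expect_gt(stats::cor(mine$log2fc, ref$log2FoldChange, use = "complete.obs"),
            0.98)
  expect_lt(median(abs(mine$log2fc - ref$log2FoldChange), na.rm = TRUE), 0.1)
  ## and the called DEG sets mostly coincide
  mine_up <- mine$gene_id[!is.na(mine$padj) & mine$padj < 0.05 & mine$log2fc >= 1.5]
  ref_up <- rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05 &
                            ref$log2FoldChange >= 1.5]
  jac <- length(intersect(mine_up, ref_up)) / length(union(mine_up, ref_up))
  expect_gt(jac, 0.85)
})
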