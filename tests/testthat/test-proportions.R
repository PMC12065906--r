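make_cells <- function(n_a_by_cluster, n_b_by_cluster,
                       conditions = c("WT", "KO")) {
  stopifnot(identical(names(n_a_by_cluster), names(n_b_by_cluster)))
  mk <- function(counts, cond) {
    tibble::tibble(
      condition = factor(cond, levels = conditions),
      cluster = rep(names(counts), counts)
    )
  }
  cells <- dplyr::bind_rows(mk(n_a_by_cluster, conditions[1]),
                            mk(n_b_by_cluster, conditions[2]))
  cells$cell_id <- sprintf("c%05d", seq_len(nrow(cells)))
  cells$sample_id <- cells$condition
  cells
}

test_that("QC filter applies all four criteria and reports removals", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:5),
    n_genes = c(100, 300, 300, 300, 300),
    n_umi = c(600, 400, 600, 600, 600),
    mito_fraction = c(0.01, 0.01, 0.2, 0.14, 0.01),
    log10_genes_per_umi = c(0.9, 0.9, 0.9, 0.81, 0.5)
  )
  expect_message(kept <- qc_filter_cells(cells), "cell QC removed")
  ## c1 fails genes, c2 UMI, c3 mito, c5 genes/UMI; c4 is borderline-in
  expect_identical(kept$cell_id, "c4")

  empty <- cells[0, ]
  expect_identical(qc_filter_cells(empty), empty)

  ## doublet column respected when present
  cells$doublet <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_message(kept2 <- qc_filter_cells(cells))
  expect_equal(nrow(kept2), 0L)
})

test_that("observed proportion log2FC matches arithmetic", {
  cells <- make_cells(c(X = 10, rest = 90), c(X = 20, rest = 80))
  res <- suppressWarnings(proportion_test(cells, n_perm = 99, n_boot = 99,
                                          seed = 1))
  x <- res[res$cluster == "X", ]
  ## 10/100 vs 20/100 -> log2(0.2/0.1) = 1 exactly
  expect_equal(x$obs_log2fc, 1)
  expect_equal(x$prop_a, 0.1)
  expect_equal(x$prop_b, 0.2)
})

test_that("identical compositions give null p-values and CIs covering zero", {
  cells <- make_cells(c(A = 60, B = 60, C = 80), c(A = 60, B = 60, C = 80))
  res <- proportion_test(cells, n_perm = 199, n_boot = 199, seed = 5)
  expect_equal(res$obs_log2fc, rep(0, 3))
  expect_true(all(res$pvalue > 0.5))
  expect_true(all(res$ci_low <= 0 & res$ci_high >= 0))
  ## proportions sum to one per condition
  expect_equal(sum(res$prop_a), 1)
  expect_equal(sum(res$prop_b), 1)
})

test_that("swapping condition labels negates log2FC and keeps p-values", {
  cells <- make_cells(c(A = 30, B = 90, C = 80), c(A = 55, B = 65, C = 80))
  res1 <- proportion_test(cells, n_perm = 299, n_boot = 49, seed = 11)
  swapped <- cells
  swapped$condition <- factor(ifelse(cells$condition == "WT", "KO", "WT"),
                              levels = c("WT", "KO"))
  res2 <- proportion_test(swapped, n_perm = 299, n_boot = 49, seed = 11)
  expect_equal(res1$obs_log2fc, -res2$obs_log2fc)
  expect_equal(res1$pvalue, res2$pvalue)
})

test_that("clusters absent from one condition get a flagged pseudo-count", {
  cells <- make_cells(c(A = 100, B = 0, C = 100), c(A = 80, B = 40, C = 80))
  expect_warning(res <- proportion_test(cells, n_perm = 49, n_boot = 49,
                                        seed = 2), "pseudo-count")
  b <- res[res$cluster == "B", ]
  expect_true(b$pseudo)
  expect_true(is.finite(b$obs_log2fc))
})

test_that("marker test keeps separating genes and drops low-detection genes", {
  n <- 120
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:n),
    condition = factor(rep(c("WT", "KO"), each = n / 2),
                       levels = c("WT", "KO")),
    cluster = rep(c("k1", "k2"), n / 2)
  )
  expr <- withr::with_seed(21, {
    e <- matrix(stats::rpois(3 * n, 1), nrow = 3,
                dimnames = list(c("marker", "lowdet", "flat"), cells$cell_id))
    e["marker", ] <- ifelse(cells$cluster == "k1",
                            stats::rpois(n, 8), stats::rpois(n, 0.2))
    ## detected in ~10% of cells on both sides
    e["lowdet", ] <- stats::rbinom(n, 1, 0.1) * 5
    e
  })
  out <- wilcoxon_markers(cells, expr)
  top_k1 <- out[out$cluster == "k1", ]
  expect_equal(top_k1$gene[1], "marker")
  expect_lt(top_k1$padj[1], 1e-6)
  expect_false("lowdet" %in% out$gene)

  tiny <- cells[1:5, ]
  tiny$cluster <- c("solo", "k2", "k2", "k2", "k2")
  expect_warning(wilcoxon_markers(tiny, expr[, tiny$cell_id]), "fewer than")
})

test_that("pseudo-bulk comparison recovers planted suppression", {
  n <- 500
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:(2 * n)),
    condition = factor(rep(c("WT", "KO"), each = n), levels = c("WT", "KO")),
    cluster = "all"
  )
  expr <- withr::with_seed(33, {
    e <- matrix(0, nrow = 2, ncol = 2 * n,
                dimnames = list(c("Id1_like", "same"), cells$cell_id))
    e["Id1_like", ] <- c(stats::rpois(n, 6), stats::rpois(n, 1.5))
    e["same", ] <- stats::rpois(2 * n, 3)
    e
  })
  res <- pseudobulk_compare(cells, expr, "Id1_like")
  expect_lt(res$log2fc, 0)          # suppressed in the KO condition
  expect_lt(res$pvalue, 0.05)

  flat <- pseudobulk_compare(cells, expr, "same")
  expect_gt(flat$pvalue, 0.01)

  ident <- expr
  ident["same", cells$condition == "KO"] <- ident["same", cells$condition == "WT"]
  expect_equal(pseudobulk_compare(cells, ident, "same")$pvalue, 1)
  expect_equal(pseudobulk_compare(cells, ident, "same")$log2fc, 0)

  expect_error(pseudobulk_compare(cells, expr, "nope"), "not found")
})

test_that("4x mean shift yields ~2 log2FC in pseudo-bulk", {
  n <- 300
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:(2 * n)),
    condition = factor(rep(c("WT", "KO"), each = n), levels = c("WT", "KO")),
    cluster = "all"
  )
  expr <- withr::with_seed(9, matrix(
    c(stats::rpois(n, 50), stats::rpois(n, 200)), nrow = 1,
    dimnames = list("g", cells$cell_id)
  ))
  res <- pseudobulk_compare(cells, expr, "g")
  expect_equal(res$log2fc, 2, tolerance = 0.1)
})
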