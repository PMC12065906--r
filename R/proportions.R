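#' QC-filter cells
#'
#' Retains cells that satisfy all of: detected gene number within
#' `genes_range` (inclusive), UMI count strictly above `umi_min`,
#' mitochondrial fraction strictly below `mito_max`, and log10 genes per
#' UMI strictly above `lgpu_min`. If a logical `doublet` column is present,
#' doublets are removed as well. The number of cells failing each
#' criterion is reported via `message()`.
#'
#' @param cells cell table (one row per cell with QC columns `n_genes`,
#'   `n_umi`, `mito_fraction`, `log10_genes_per_umi`).
#' @param genes_range inclusive bounds on detected genes (default 250-7000).
#' @param umi_min minimum UMI count, exclusive (default 500).
#' @param mito_max maximum mitochondrial fraction, exclusive (default 0.15).
#' @param lgpu_min minimum log10 genes per UMI, exclusive (default 0.80).
#' @return the filtered cell table.
#' @export
qc_filter_cells <- function(cells, genes_range = c(250, 7000), umi_min = 500,
                            mito_max = 0.15, lgpu_min = 0.80) {
  if (nrow(cells) == 0L) return(cells)
  ok_genes <- cells$n_genes >= genes_range[1L] & cells$n_genes <= genes_range[2L]
  ok_umi <- cells$n_umi > umi_min
  ok_mito <- cells$mito_fraction < mito_max
  ok_lgpu <- cells$log10_genes_per_umi > lgpu_min
  ok_dbl <- if ("doublet" %in% names(cells)) !cells$doublet else TRUE
  inform(sprintf(
    "cell QC removed: %d (genes), %d (UMI), %d (mito), %d (genes/UMI)%s",
    sum(!ok_genes), sum(!ok_umi), sum(!ok_mito), sum(!ok_lgpu),
    if ("doublet" %in% names(cells)) sprintf(", %d (doublet)", sum(cells$doublet)) else ""
  ))
  cells[ok_genes & ok_umi & ok_mito & ok_lgpu & ok_dbl, , drop = FALSE]
}

## per-cluster counts for an index subset, with optional +1 pseudo-cell
## when a cluster is empty on one side (keeps log ratios finite)
prop_counts <- function(cl_int, K, idx) tabulate(cl_int[idx], nbins = K)

prop_log2fc <- function(count_a, count_b) {
  count_a <- ifelse(count_a == 0L, 1L, count_a)
  count_b <- ifelse(count_b == 0L, 1L, count_b)
  log2((count_b / sum(count_b)) / (count_a / sum(count_a)))
}

#' Permutation test for condition-wise cluster proportions
#'
#' For each cluster, the observed statistic is
#' `obs_log2FC = log2(prop_b / prop_a)` where `a` is the first and `b` the
#' second condition level. Condition labels are permuted over cells
#' (`n_perm` times) and the two-sided p-value is the fraction of permuted
#' |log2FC| at least as large as the observed one, with add-one smoothing.
#' A percentile bootstrap (resampling cells with replacement within each
#' condition) gives a confidence interval for the log2FC, and p-values are
#' BH-adjusted across clusters. A cluster absent from one condition is
#' given a pseudo-count of one cell and flagged.
#'
#' @param cells cell table with `condition` and `cluster` columns. When
#'   `condition` is a factor its level order defines the reference (`a` =
#'   first level); a character column is ordered alphabetically.
#' @param n_perm number of label permutations (default 1000).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param conf confidence level of the bootstrap interval (default 0.95).
#' @param seed optional integer seed.
#' @return a tibble per cluster: `cluster`, `n_a`, `n_b`, `prop_a`,
#'   `prop_b`, `obs_log2fc`, `ci_low`, `ci_high`, `pvalue`, `fdr`,
#'   `pseudo` (pseudo-count applied).
#' @export
proportion_test <- function(cells, n_perm = 1000, n_boot = 1000, conf = 0.95,
                            seed = NULL) {
  cond <- droplevels(as.factor(cells$condition))
  if (nlevels(cond) != 2L) abort("exactly two conditions are required.")
  cl <- factor(cells$cluster)
  K <- nlevels(cl)
  if (K < 2L) abort("at least two clusters are required.")
  cl_int <- as.integer(cl)
  idx_a <- which(cond == levels(cond)[1L])
  idx_b <- which(cond == levels(cond)[2L])
  n <- length(cl_int)
  n_b <- length(idx_b)

  count_a <- prop_counts(cl_int, K, idx_a)
  count_b <- prop_counts(cl_int, K, idx_b)
  pseudo <- count_a == 0L | count_b == 0L
  if (any(pseudo)) {
    warn(paste0("cluster(s) absent in one condition, pseudo-count applied: ",
                paste(levels(cl)[pseudo], collapse = ", ")))
  }
  obs <- prop_log2fc(count_a, count_b)

  res <- with_seed_(seed, {
    perm_ge <- integer(K)
    ## tiny slack so exact ties (e.g. the unpermuted arrangement) count as
    ## >= regardless of floating-point rounding direction
    obs_bar <- abs(obs) - 1e-9
    for (b in seq_len(n_perm)) {
      pb <- sample.int(n, n_b)
      cb <- prop_counts(cl_int, K, pb)
      ca <- count_a + count_b - cb
      perm_ge <- perm_ge + (abs(prop_log2fc(ca, cb)) >= obs_bar)
    }
    boot <- matrix(0, n_boot, K)
    for (b in seq_len(n_boot)) {
      ca <- as.integer(rmultinom(1L, length(idx_a), count_a / sum(count_a)))
      cb <- as.integer(rmultinom(1L, n_b, count_b / sum(count_b)))
      boot[b, ] <- prop_log2fc(ca, cb)
    }
    list(perm_ge = perm_ge, boot = boot)
  })

  pvalue <- (res$perm_ge + 1) / (n_perm + 1)
  a2 <- (1 - conf) / 2
  ci <- if (n_boot > 0) {
    apply(res$boot, 2L, quantile, probs = c(a2, 1 - a2))
  } else {
    matrix(NA_real_, 2L, K)
  }

  tibble(
    cluster = levels(cl),
    n_a = count_a, n_b = count_b,
    prop_a = count_a / sum(count_a),
    prop_b = count_b / sum(count_b),
    obs_log2fc = obs,
    ci_low = ci[1L, ], ci_high = ci[2L, ],
    pvalue = pvalue,
    fdr = bh_adjust(pvalue),
    pseudo = pseudo
  )
}

#' Wilcoxon cluster marker test
#'
#' For each cluster versus all other cells: genes are pre-filtered to those
#' with `|log2 fold-change| >= lfc_thresh` (log2 of means with pseudo-count
#' 1) and detected in at least `min_frac` of the cells on at least one
#' side; surviving genes are tested with a two-sided Wilcoxon rank-sum test
#' and Bonferroni-adjusted over the full gene panel.
#'
#' @param cells cell table (`cell_id`, `cluster`).
#' @param expr numeric matrix, genes in rows, cells in columns (column
#'   names must match `cells$cell_id`).
#' @param lfc_thresh absolute log2 fold-change pre-filter (default 0.25).
#' @param min_frac minimum expressed fraction on one side (default 0.25).
#' @param min_cells clusters with fewer cells are skipped with a warning.
#' @return a tibble: `cluster`, `gene`, `log2fc`, `frac_in`, `frac_out`,
#'   `pvalue`, `padj`.
#' @export
wilcoxon_markers <- function(cells, expr, lfc_thresh = 0.25, min_frac = 0.25,
                             min_cells = 3L) {
  if (is.null(colnames(expr)) || !all(cells$cell_id %in% colnames(expr))) {
    abort("`expr` must have column names covering every cell id.")
  }
  expr <- expr[, cells$cell_id, drop = FALSE]
  n_genes_total <- nrow(expr)
  clusters <- sort(unique(cells$cluster))
  out <- purrr::map(clusters, function(k) {
    in_k <- cells$cluster == k
    if (sum(in_k) < min_cells) {
      warn(paste0("cluster ", k, " has fewer than ", min_cells,
                  " cells; skipped."))
      return(NULL)
    }
    m_in <- rowMeans(expr[, in_k, drop = FALSE])
    m_out <- rowMeans(expr[, !in_k, drop = FALSE])
    f_in <- rowMeans(expr[, in_k, drop = FALSE] > 0)
    f_out <- rowMeans(expr[, !in_k, drop = FALSE] > 0)
    lfc <- log2(m_in + 1) - log2(m_out + 1)
    test <- abs(lfc) >= lfc_thresh & pmax(f_in, f_out) >= min_frac
    if (!any(test)) return(NULL)
    p <- vapply(which(test), function(g) {
      suppressWarnings(wilcox.test(expr[g, in_k], expr[g, !in_k])$p.value)
    }, numeric(1))
    tibble(cluster = k, gene = rownames(expr)[test], log2fc = lfc[test],
           frac_in = f_in[test], frac_out = f_out[test], pvalue = p)
  }) |> purrr::compact() |> list_rbind()
  if (nrow(out)) {
    out$padj <- pmin(out$pvalue * n_genes_total, 1)
    out <- arrange(out, .data$cluster, .data$padj, desc(abs(.data$log2fc)))
  }
  out
}

#' Pseudo-bulk two-condition comparison of one gene
#'
#' Pools all cells of each condition and compares the gene's expression
#' with a two-sided Wilcoxon rank-sum test; the reported log2 fold-change
#' is of condition means with pseudo-count 1 (second condition level over
#' the first).
#'
#' @param cells cell table with `cell_id` and `condition`.
#' @param expr expression matrix as in [wilcoxon_markers()].
#' @param gene gene (row) name to test.
#' @return a one-row tibble: `gene`, `log2fc`, `pvalue`.
#' @export
pseudobulk_compare <- function(cells, expr, gene) {
  if (!gene %in% rownames(expr)) abort(paste0("gene not found: ", gene))
  cond <- droplevels(as.factor(cells$condition))
  if (nlevels(cond) != 2L) abort("exactly two conditions are required.")
  v <- expr[gene, cells$cell_id]
  a <- v[cond == levels(cond)[1L]]
  b <- v[cond == levels(cond)[2L]]
  p <- if (identical(sort(a), sort(b))) 1 else {
    suppressWarnings(wilcox.test(b, a)$p.value)
  }
  tibble(gene = gene,
         log2fc = log2(mean(b) + 1) - log2(mean(a) + 1),
         pvalue = p)
}
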