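#' Configuration for the single-cell cluster-composition simulator
#'
#' Emulates the downstream inputs of a droplet scRNA-seq experiment after
#' clustering: one row per cell carrying its sample, condition, cluster
#' label and QC metrics. Only the cluster composition and QC marginals are
#' modelled; no count matrix is generated (clusters are consumed as labels
#' by the proportion machinery).
#'
#' The default cluster proportions echo the kind of shifts seen between
#' Smad4-proficient and Smad4-deficient caecal adenoma: a `Pak3_hi`
#' progenitor cluster expanded from 2.5% to 10.5%, `Slc14a1_hi` doubled,
#' the `Lgr5_ISC` and enterocyte clusters depleted, and a large remainder
#' cluster absorbing the rest.
#'
#' @param n_cells_per_sample cells drawn per sample.
#' @param n_samples_per_condition samples per condition.
#' @param conditions two condition labels (reference first).
#' @param cluster_proportions matrix (clusters x conditions) of multinomial
#'   probabilities; each column must sum to 1.
#' @param qc_umi_meanlog,qc_umi_sdlog log-normal parameters of UMI counts.
#' @param qc_mito_shape1,qc_mito_shape2 beta parameters of the
#'   mitochondrial fraction.
#' @param seed integer seed.
#' @return a list of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_cells_per_sample = 500,
                            n_samples_per_condition = 3,
                            conditions = c("WT", "KO"),
                            cluster_proportions = default_cluster_proportions(),
                            qc_umi_meanlog = log(4000),
                            qc_umi_sdlog = 0.5,
                            qc_mito_shape1 = 2,
                            qc_mito_shape2 = 38,
                            seed = 1L) {
  if (is.null(dim(cluster_proportions)) || ncol(cluster_proportions) != 2L ||
      is.null(rownames(cluster_proportions))) {
    abort("cluster_proportions must be a named matrix with one column per condition.")
  }
  if (nrow(cluster_proportions) < 1L) abort("empty cluster set.")
  if (any(abs(colSums(cluster_proportions) - 1) > 1e-8)) {
    abort("each condition's cluster probabilities must sum to 1.")
  }
  structure(list(
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    conditions = conditions,
    cluster_proportions = cluster_proportions,
    qc_umi_meanlog = qc_umi_meanlog, qc_umi_sdlog = qc_umi_sdlog,
    qc_mito_shape1 = qc_mito_shape1, qc_mito_shape2 = qc_mito_shape2,
    seed = as.integer(seed)
  ), class = "cell_sim_config")
}

#' Default per-condition cluster proportions
#'
#' @param conditions two condition labels (columns of the result).
#' @return a clusters x conditions probability matrix.
#' @export
default_cluster_proportions <- function(conditions = c("WT", "KO")) {
  m <- rbind(
    Pak3_hi    = c(0.025, 0.105),
    Slc14a1_hi = c(0.035, 0.070),
    Lgr5_ISC   = c(0.058, 0.027),
    EC         = c(0.234, 0.078),
    TA         = c(0.150, 0.150),
    Secretory  = c(0.080, 0.080)
  )
  m <- rbind(m, Other = 1 - colSums(m))
  colnames(m) <- conditions
  m
}

#' Simulate per-cell cluster labels and QC metrics
#'
#' @param config a [cell_sim_config()].
#' @return a list of class `cell_sim` with elements
#'   `cells` (tibble: `cell_id`, `sample_id`, `condition`, `cluster`,
#'   `n_genes`, `n_umi`, `mito_fraction`, `log10_genes_per_umi`) and
#'   `truth` (tibble: `cluster`, `condition`, `proportion`).
#' @examples
#' sim <- simulate_cells(cell_sim_config(n_cells_per_sample = 100, seed = 2))
#' table(sim$cells$condition, sim$cells$cluster)[, 1:3]
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "cell_sim_config"))
  with_seed_(config$seed, {
    props <- config$cluster_proportions
    clusters <- rownames(props)
    cells <- purrr::map(seq_along(config$conditions), function(ci) {
      cond <- config$conditions[ci]
      purrr::map(seq_len(config$n_samples_per_condition), function(si) {
        nc <- config$n_cells_per_sample
        cl <- sample(clusters, nc, replace = TRUE, prob = props[, ci])
        n_umi <- pmax(round(rlnorm(nc, config$qc_umi_meanlog, config$qc_umi_sdlog)), 50)
        ## genes per cell follow UMIs sub-linearly, as in droplet data
        n_genes <- pmax(round(n_umi^0.85 * rlnorm(nc, 0, 0.08)), 30)
        tibble(
          sample_id = paste0(cond, "_s", si),
          condition = cond,
          cluster = cl,
          n_genes = n_genes,
          n_umi = n_umi,
          mito_fraction = rbeta(nc, config$qc_mito_shape1, config$qc_mito_shape2),
          log10_genes_per_umi = log10(n_genes) / log10(n_umi)
        )
      }) |> list_rbind()
    }) |> list_rbind()
    cells <- cells |>
      mutate(condition = factor(.data$condition, levels = config$conditions),
             cell_id = sprintf("cell%06d", dplyr::row_number()),
             .before = 1L)

    truth <- as_tibble(props, rownames = "cluster") |>
      pivot_longer(-"cluster", names_to = "condition", values_to = "proportion")

    structure(list(cells = cells, truth = truth), class = "cell_sim")
  })
}

#' @export
print.cell_sim <- function(x, ...) {
  cat("Cell simulation:", nrow(x$cells), "cells,",
      length(unique(x$cells$cluster)), "clusters,",
      length(unique(x$cells$sample_id)), "samples\n")
  invisible(x)
}
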