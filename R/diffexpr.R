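#' Remove genes with insufficient read support
#'
#' Keeps exactly the genes with at least `min_reads` reads in at least
#' `min_samples` samples (the complement — fewer than `min_reads` reads in
#' all but fewer than `min_samples` samples — is removed). Gene order is
#' preserved.
#'
#' @param counts counts tibble (`gene_id` + one integer column per sample).
#' @param min_reads minimum read count per sample (default 5).
#' @param min_samples minimum number of samples reaching `min_reads`
#'   (default 3).
#' @return the filtered counts tibble.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"),
#'                          s1 = c(5L, 4L), s2 = c(5L, 4L), s3 = c(5L, 4L))
#' filter_low_counts(counts)
#' @export
filter_low_counts <- function(counts, min_reads = 5, min_samples = 3) {
  check_counts(counts)
  m <- counts_matrix(counts)
  keep <- rowSums(m >= min_reads) >= min_samples
  if (!any(keep)) warn("low-count filter removed every gene; returning an empty matrix.")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median across genes of
#' the ratio of each sample's count to the gene's geometric mean, using only
#' genes with nonzero counts in every sample.
#'
#' @param counts counts tibble.
#' @return a named numeric vector of positive factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  check_counts(counts)
  m <- counts_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) abort("no gene has nonzero counts in all samples; cannot normalise.")
  lg <- log(m[all_pos, , drop = FALSE])
  log_geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - log_geo)))
  setNames(sf, colnames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1. Non-finite
#' entries (NA/NaN) are propagated unchanged and excluded from the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

## shared pre-flight for the NB tests
nb_prepare <- function(counts, samples, size_factors) {
  check_counts(counts)
  samples <- check_samples_align(counts, samples)
  m <- counts_matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  size_factors <- size_factors[colnames(m)]
  if (anyNA(size_factors) || any(size_factors <= 0)) {
    abort("size factors must be positive and cover every sample.")
  }
  list(m = m, samples = samples, sf = size_factors, offset = log(size_factors))
}

#' Moderated per-gene dispersion estimates
#'
#' Estimates each gene's negative-binomial dispersion from all samples
#' under the one-factor group design by maximising the Cox-Reid adjusted
#' profile likelihood on a log-spaced grid, moderated toward the mean
#' profile across genes with `prior_df` pseudo-degrees of freedom. The
#' result can be passed to [nb_wald()] / [nb_lrt()] via their
#' `dispersions` argument to avoid re-estimating when several contrasts
#' share one matrix.
#'
#' @inheritParams nb_wald
#' @return a named numeric vector of dispersions (NA for all-zero genes).
#' @export
estimate_dispersions <- function(counts, samples, group = "group",
                                 size_factors = NULL, prior_df = 10) {
  prep <- nb_prepare(counts, samples, size_factors)
  if (!group %in% names(prep$samples)) {
    abort(paste0("grouping column `", group, "` not found in `samples`."))
  }
  X <- model.matrix(~ factor(prep$samples[[group]]))
  apl <- nb_apl_matrix(prep$m, X, prep$offset)
  alpha <- nb_moderate_dispersion(apl, resid_df = ncol(prep$m) - ncol(X),
                                  prior_df = prior_df)
  setNames(alpha, rownames(prep$m))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits a per-gene negative-binomial log-linear model and tests the log2
#' fold-change between two levels of a grouping variable with a Wald z
#' statistic (`z = log2fc / se`, two-sided normal p-value). Dispersions are
#' estimated once from *all* samples of the matrix under the full
#' one-factor group design (Cox-Reid adjusted profile likelihood, moderated
#' across genes; see Details), then the contrast is fitted on the two
#' groups involved.
#'
#' @details
#' Per-gene dispersion at typical replicate numbers is too noisy to give a
#' calibrated Wald test, so the per-gene Cox-Reid adjusted profile
#' likelihood is combined with the mean profile across genes using a fixed
#' prior weight of `prior_df` pseudo-degrees of freedom before maximising
#' (weighted-likelihood moderation). There is no trend fitting and no
#' outlier machinery. Genes with zero counts in one contrast group get
#' their fold-change recomputed from normalised group means with a
#' pseudo-count of 0.5 and are flagged in `note`.
#'
#' @param counts counts tibble.
#' @param samples sample metadata tibble with `sample_id` and the `group`
#'   column.
#' @param contrast character vector `c(level_b, level_a)`: the reported
#'   `log2fc` is level_b over level_a.
#' @param group name of the grouping column in `samples`.
#' @param size_factors optional named size-factor vector; computed by
#'   [estimate_size_factors()] when `NULL`.
#' @param prior_df prior weight (pseudo-residual-df) of the shared
#'   dispersion curve.
#' @param dispersions optional named per-gene dispersion vector from
#'   [estimate_dispersions()]; estimated internally when `NULL`.
#' @param shrink if `TRUE`, additionally report `log2fc_shrunk`, an
#'   approximate normal-prior posterior mean `log2fc * tau2/(tau2 + se^2)`
#'   with `tau2 = 4`; p-values always refer to the unshrunk estimate.
#' @return a tibble with columns `gene_id`, `base_mean`, `log2fc`,
#'   `se_log2fc`, `stat`, `pvalue`, `padj`, `contrast`, `note`.
#' @export
nb_wald <- function(counts, samples, contrast, group = "group",
                    size_factors = NULL, prior_df = 10, dispersions = NULL,
                    shrink = FALSE) {
  prep <- nb_prepare(counts, samples, size_factors)
  if (!group %in% names(prep$samples)) {
    abort(paste0("grouping column `", group, "` not found in `samples`."))
  }
  gvec <- as.character(prep$samples[[group]])
  if (length(contrast) == 3L) contrast <- contrast[-1L]  # tolerate DESeq2-style triplet
  if (length(contrast) != 2L || !all(contrast %in% gvec)) {
    abort("`contrast` must name two levels present in the grouping column.")
  }
  lev_b <- contrast[1L]; lev_a <- contrast[2L]
  if (sum(gvec == lev_a) < 2L || sum(gvec == lev_b) < 2L) {
    abort("each contrast group needs at least 2 samples.")
  }

  ## dispersion from the full one-factor design over all samples
  if (is.null(dispersions)) {
    X_full <- model.matrix(~ factor(gvec))
    apl <- nb_apl_matrix(prep$m, X_full, prep$offset)
    alpha <- nb_moderate_dispersion(apl, resid_df = ncol(prep$m) - ncol(X_full),
                                    prior_df = prior_df)
  } else {
    alpha <- unname(dispersions[rownames(prep$m)])
  }

  idx <- which(gvec %in% c(lev_a, lev_b))
  Xc <- cbind(1, as.numeric(gvec[idx] == lev_b))
  off <- prep$offset[idx]
  norm <- sweep(prep$m, 2L, prep$sf, "/")
  base_mean <- rowMeans(norm)
  mean_a <- rowMeans(norm[, gvec == lev_a, drop = FALSE])
  mean_b <- rowMeans(norm[, gvec == lev_b, drop = FALSE])

  ng <- nrow(prep$m)
  log2fc <- se <- stat <- pvalue <- rep(NA_real_, ng)
  note <- rep("", ng)
  for (g in seq_len(ng)) {
    y <- prep$m[g, idx]
    if (all(y == 0)) {
      log2fc[g] <- 0; se[g] <- NA; stat[g] <- 0; pvalue[g] <- 1
      note[g] <- "all_zero"
      next
    }
    a <- alpha[g]
    if (!is.finite(a)) a <- 0.1
    f <- nb_wald_fit(y, Xc, off, a)
    if (is.null(f)) { pvalue[g] <- NA; note[g] <- "fit_failed"; next }
    log2fc[g] <- f$beta[2L] / log(2)
    se[g] <- sqrt(f$cov[2L, 2L]) / log(2)
    stat[g] <- f$beta[2L] / sqrt(f$cov[2L, 2L])
    pvalue[g] <- 2 * pnorm(-abs(stat[g]))
    if (mean_a[g] == 0 || mean_b[g] == 0) {
      log2fc[g] <- log2((mean_b[g] + 0.5) / (mean_a[g] + 0.5))
      note[g] <- "zero_group"
    }
  }

  res <- tibble(
    gene_id = rownames(prep$m),
    base_mean = base_mean,
    log2fc = log2fc,
    se_log2fc = se,
    stat = stat,
    pvalue = pvalue,
    padj = bh_adjust(pvalue),
    contrast = paste0(lev_b, "_vs_", lev_a),
    note = note
  )
  if (shrink) {
    tau2 <- 4
    res$log2fc_shrunk <- res$log2fc * tau2 / (tau2 + ifelse(is.na(res$se_log2fc), 0, res$se_log2fc)^2)
  }
  res
}

#' Negative-binomial likelihood-ratio test between nested designs
#'
#' Fits each gene under a full and a reduced model formula (evaluated in
#' the sample metadata) at a common moderated dispersion estimated under
#' the full design, and compares twice the log-likelihood difference to a
#' chi-square with degrees of freedom equal to the difference in model
#' rank. This is the time-course test: with
#' `full = ~ genotype * time, reduced = ~ genotype + time` it ranks genes
#' whose TGF-beta response differs between genotypes.
#'
#' @param counts counts tibble.
#' @param samples sample metadata tibble.
#' @param full,reduced model formulas over columns of `samples`; `reduced`
#'   must be nested in `full`.
#' @param size_factors optional named size-factor vector.
#' @param prior_df dispersion moderation weight, as in [nb_wald()].
#' @param dispersions optional named per-gene dispersion vector (estimated
#'   under the full design when `NULL`).
#' @return a tibble with columns `gene_id`, `base_mean`, `log2fc` (the last
#'   full-model coefficient, typically an interaction), `stat`, `df`,
#'   `pvalue`, `padj`, `contrast`.
#' @export
nb_lrt <- function(counts, samples, full, reduced, size_factors = NULL,
                   prior_df = 10, dispersions = NULL) {
  prep <- nb_prepare(counts, samples, size_factors)
  Xf <- model.matrix(full, data = prep$samples)
  Xr <- model.matrix(reduced, data = prep$samples)
  rank_f <- qr(Xf)$rank
  rank_r <- qr(Xr)$rank
  if (qr(cbind(Xf, Xr))$rank > rank_f) {
    abort("`reduced` is not nested in `full`.")
  }
  df <- rank_f - rank_r
  ng <- nrow(prep$m)
  contrast_lab <- paste(deparse(full), "vs", deparse(reduced))

  norm <- sweep(prep$m, 2L, prep$sf, "/")
  base_mean <- rowMeans(norm)

  if (df == 0L) {
    return(tibble(gene_id = rownames(prep$m), base_mean = base_mean,
                  log2fc = 0, stat = 0, df = 0L, pvalue = 1,
                  padj = 1, contrast = contrast_lab))
  }

  if (is.null(dispersions)) {
    apl <- nb_apl_matrix(prep$m, Xf, prep$offset)
    alpha <- nb_moderate_dispersion(apl, resid_df = ncol(prep$m) - rank_f,
                                    prior_df = prior_df)
  } else {
    alpha <- unname(dispersions[rownames(prep$m)])
  }

  stat <- pvalue <- log2fc <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    y <- prep$m[g, ]
    if (all(y == 0)) { stat[g] <- 0; pvalue[g] <- 1; log2fc[g] <- 0; next }
    a <- alpha[g]
    if (!is.finite(a)) a <- 0.1
    ff <- nb_wald_fit(y, Xf, prep$offset, a)
    fr <- nb_wald_fit(y, Xr, prep$offset, a)
    if (is.null(ff) || is.null(fr)) next
    stat[g] <- max(0, 2 * (ff$ll - fr$ll))
    pvalue[g] <- pchisq(stat[g], df = df, lower.tail = FALSE)
    log2fc[g] <- ff$beta[length(ff$beta)] / log(2)
  }

  tibble(gene_id = rownames(prep$m), base_mean = base_mean,
         log2fc = log2fc, stat = stat, df = df, pvalue = pvalue,
         padj = bh_adjust(pvalue), contrast = contrast_lab)
}

#' Call differentially expressed genes
#'
#' A gene is called `up` when `log2fc >= lfc_thresh` and `padj < alpha`,
#' `down` when `log2fc <= -lfc_thresh` and `padj < alpha` (the fold-change
#' boundary is inclusive, the FDR threshold strict).
#'
#' @param res a DE result tibble from [nb_wald()] or [nb_lrt()].
#' @param lfc_thresh absolute log2 fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the subset of `res` passing the thresholds, with a `direction`
#'   column (`"up"` / `"down"`).
#' @export
call_deg <- function(res, lfc_thresh = 1.5, alpha = 0.05) {
  res |>
    filter(!is.na(.data$padj), .data$padj < alpha,
           abs(.data$log2fc) >= lfc_thresh) |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
}
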