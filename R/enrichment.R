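#' CERNO rank-based gene-set enrichment
#'
#' Coincident Extreme Ranks in Numerical Observations: for each module the
#' statistic is `-2 * sum(log(rank_g / N))` over member genes found in the
#' ranking (rank 1 = most significant), chi-square distributed with
#' `2 * n_found` degrees of freedom under the null of random member ranks.
#' A per-module AUC is derived from the rank-sum of member genes
#' (1 means members occupy the very top of the ranking), and p-values are
#' Benjamini-Hochberg adjusted across modules.
#'
#' @param ranking either an ordered character vector of unique gene ids
#'   (most significant first) or a two-column data frame (gene, statistic)
#'   which is sorted by the statistic. Ties are broken by original order.
#' @param modules named list of character vectors of member gene ids
#'   (e.g. from [read_gmt()]).
#' @param descending if `ranking` is a data frame, sort the statistic
#'   descending instead of ascending (use for effect-size rankings; the
#'   default ascending order suits p-values).
#' @return a tibble with columns `module_id`, `n_found`, `cerno_stat`,
#'   `df`, `auc`, `pvalue`, `padj`. Modules with no member in the ranking
#'   get `n_found = 0` and `NaN` p-values; a module spanning the entire
#'   ranking has an undefined (`NA`) AUC.
#' @examples
#' cerno_test(letters[1:10], list(top = c("a", "b")))
#' @export
cerno_test <- function(ranking, modules, descending = FALSE) {
  if (is.data.frame(ranking)) {
    ord <- order(ranking[[2L]], decreasing = descending)
    ranking <- as.character(ranking[[1L]][ord])
  }
  if (anyDuplicated(ranking)) abort("ranking must contain unique genes.")
  N <- length(ranking)
  rank_of <- setNames(seq_len(N), ranking)
  res <- purrr::imap(modules, function(members, id) {
    r <- rank_of[unique(members)]
    r <- r[!is.na(r)]
    n <- length(r)
    if (n == 0L) {
      return(tibble(module_id = id, n_found = 0L, cerno_stat = NA_real_,
                    df = 0L, auc = NA_real_, pvalue = NaN))
    }
    stat <- -2 * sum(log(r / N))
    n_out <- N - n
    auc <- if (n_out == 0L) NA_real_ else {
      (n * n_out + n * (n + 1) / 2 - sum(r)) / (n * n_out)
    }
    tibble(module_id = id, n_found = n, cerno_stat = stat, df = 2L * n,
           auc = auc,
           pvalue = pchisq(stat, df = 2 * n, lower.tail = FALSE))
  }) |> list_rbind()
  res$padj <- bh_adjust(res$pvalue)
  res
}

#' Select positively enriched modules
#'
#' Keeps modules with `auc >= auc_min` and `padj < alpha`.
#'
#' @param res a [cerno_test()] result.
#' @param auc_min minimum AUC (default 0.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the qualifying subset of `res`.
#' @export
call_enriched <- function(res, auc_min = 0.5, alpha = 0.05) {
  res |>
    filter(!is.na(.data$auc), .data$auc >= auc_min,
           is.finite(.data$padj), .data$padj < alpha)
}
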