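#' Volcano plot of a DE contrast
#'
#' @param res DE tibble from [nb_wald()].
#' @param lfc_thresh,alpha thresholds drawn as dashed guides and used to
#'   colour called genes.
#' @return a ggplot object.
#' @export
plot_volcano <- function(res, lfc_thresh = 1.5, alpha = 0.05) {
  dat <- res |>
    filter(is.finite(.data$pvalue)) |>
    mutate(called = !is.na(.data$padj) & .data$padj < alpha &
             abs(.data$log2fc) >= lfc_thresh)
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, -log10(.data$padj),
                                    colour = .data$called)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_thresh, lfc_thresh),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 adjusted p",
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Step plot of one or more Kaplan-Meier curves
#'
#' @param object a `km_curve` tibble from [km_estimate()], or a grouped
#'   result with an extra grouping column named in `group`.
#' @param group optional column name distinguishing curves.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, group = NULL, ...) {
  aes <- if (!is.null(group) && group %in% names(object)) {
    ggplot2::aes(.data$time, .data$surv, colour = .data[[group]])
  } else {
    ggplot2::aes(.data$time, .data$surv)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Candidate-cut profile of a maxstat search
#'
#' @param object a `maxstat_cut` object.
#' @param ... unused.
#' @return a ggplot object showing |z| across candidate cuts with the
#'   selected cut marked.
#' @method autoplot maxstat_cut
#' @export
autoplot.maxstat_cut <- function(object, ...) {
  ggplot2::ggplot(object$candidates, ggplot2::aes(.data$cut, abs(.data$z))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutpoint, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "candidate cut", y = "|standardized log-rank z|") +
    ggplot2::theme_minimal()
}

#' Point-range plot of cluster proportion shifts
#'
#' Mirrors the usual presentation of condition-wise composition tests:
#' per-cluster observed log2 fold-change with its bootstrap interval,
#' highlighted when the FDR falls below `alpha`.
#'
#' @param prop a [proportion_test()] result.
#' @param alpha FDR highlight threshold (default 0.05).
#' @return a ggplot object.
#' @export
plot_proportions <- function(prop, alpha = 0.05) {
  dat <- prop |> mutate(significant = .data$fdr < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(.data$obs_log2fc,
                                    stats::reorder(.data$cluster, .data$obs_log2fc),
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "observed log2 fold-change", y = NULL,
                  colour = paste0("FDR < ", alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
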