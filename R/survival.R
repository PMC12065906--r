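#' Kaplan-Meier product-limit estimate
#'
#' @param data a data frame with survival columns.
#' @param time,event column names of follow-up time (>= 0) and event
#'   indicator (1 = event, 0 = censored).
#' @return a tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct observed time;
#'   S(0) = 1 implicitly, the curve is a right-continuous step function).
#' @examples
#' km_estimate(data.frame(time = 1:3, event = 1))$surv  # 2/3, 1/3, 0
#' @export
km_estimate <- function(data, time = "time", event = "event") {
  if (nrow(data) == 0L) abort("empty survival table.")
  if (any(data[[time]] < 0)) abort("negative survival times.")
  fit <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ 1,
    conf.type = "none"
  )
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (df 1), symmetric in the two groups. With
#' zero events the p-value is 1 by convention.
#'
#' @param data a data frame.
#' @param group column name of the two-level grouping variable.
#' @param time,event survival column names as in [km_estimate()].
#' @return a one-row tibble: `statistic`, `df`, `pvalue`.
#' @export
logrank_test <- function(data, group = "group", time = "time", event = "event") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    abort("`group` must have two non-empty levels.")
  }
  if (sum(data[[event]]) == 0) {
    return(tibble(statistic = 0, df = 1L, pvalue = 1))
  }
  sd <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ g
  )
  chi <- unname(sd$chisq)
  tibble(statistic = chi, df = 1L,
         pvalue = pchisq(chi, df = 1, lower.tail = FALSE))
}

## standardized log-rank scan over candidate cuts.
## Precomputes the risk-set structure once; the returned closure evaluates
## the per-cut z statistics for any expression vector over the same
## (time, event) data — which is what the permutation loop needs.
make_logrank_scanner <- function(time, event, cuts) {
  ord <- order(time)
  tt <- time[ord]
  ev <- event[ord]
  ut <- unique(tt)
  g <- match(tt, ut)
  G <- length(ut)
  d_t <- rowsum(ev, g)[, 1L]
  n_t <- rev(cumsum(rev(tabulate(g, G))))
  vcoef <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  function(x) {
    L <- (outer(x[ord], cuts, "<=")) * 1
    cnt <- rowsum(L, g)
    n1 <- apply(cnt[G:1, , drop = FALSE], 2L, cumsum)[G:1, , drop = FALSE]
    d1 <- rowsum(L * ev, g)
    U <- colSums(d1 - (d_t / n_t) * n1)
    V <- colSums(vcoef * n1 * (n_t - n1) / n_t^2)
    ifelse(V > 0, U / sqrt(V), 0)
  }
}

#' Maximally selected rank-statistic cut-point
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' candidate cut between adjacent distinct expression values (cut at the
#' midpoint; the "low" group is expression <= cut, ties share a side) that
#' leaves at least `minprop` of the samples on each side, and returns the
#' cut maximising |z|. The selection p-value is computed by permutation:
#' expression values are shuffled against the fixed survival data and the
#' fraction of permuted maxima at least as large as the observed one is
#' reported with add-one smoothing, `(b + 1) / (n_perm + 1)`.
#'
#' At any fixed cut the statistic coincides with the square root of the
#' two-group log-rank chi-square for that dichotomisation.
#'
#' @param data data frame with survival and expression columns.
#' @param expression column name of the expression values.
#' @param time,event survival column names.
#' @param minprop minimum proportion of samples per side (default 0.1).
#' @param n_perm number of label permutations (default 1000).
#' @param seed optional integer seed for the permutations.
#' @return an object of class `maxstat_cut`: a list with `cutpoint`,
#'   `max_statistic` (|z| at the cut), `pvalue`, `n_low`, `n_high`,
#'   `minprop`, `n_perm` and a `candidates` tibble (`cut`, `z`, `n_low`).
#' @export
maxstat_cutpoint <- function(data, expression = "expression", time = "time",
                             event = "event", minprop = 0.1, n_perm = 1000,
                             seed = NULL) {
  x <- data[[expression]]
  tt <- data[[time]]
  ev <- data[[event]]
  n <- length(x)
  if (n < 10L) abort("need at least 10 samples for cut-point selection.")
  ux <- sort(unique(x))
  if (length(ux) < 2L) abort("need at least 2 distinct expression values.")
  cuts <- (ux[-length(ux)] + ux[-1L]) / 2
  n_low <- vapply(cuts, function(cc) sum(x <= cc), integer(1))
  keep <- n_low / n >= minprop & (n - n_low) / n >= minprop
  if (!any(keep)) abort("no admissible cut satisfies `minprop`.")
  cuts <- cuts[keep]
  n_low <- n_low[keep]

  scan <- make_logrank_scanner(tt, ev, cuts)
  z <- scan(x)
  i <- which.max(abs(z))
  obs <- abs(z[i])

  pvalue <- NA_real_
  if (n_perm > 0) {
    perm_max <- with_seed_(seed, {
      vapply(seq_len(n_perm), function(b) max(abs(scan(sample(x)))), numeric(1))
    })
    pvalue <- (sum(perm_max >= obs) + 1) / (n_perm + 1)
  }

  structure(list(
    cutpoint = cuts[i],
    max_statistic = obs,
    pvalue = pvalue,
    n_low = n_low[i],
    n_high = n - n_low[i],
    minprop = minprop,
    n_perm = n_perm,
    candidates = tibble(cut = cuts, z = z, n_low = n_low)
  ), class = "maxstat_cut")
}

#' @export
print.maxstat_cut <- function(x, ...) {
  cat("Maximally selected rank statistic cut-point\n")
  cat(sprintf("  cut = %.4g  (|z| = %.3f, n_low = %d, n_high = %d)\n",
              x$cutpoint, x$max_statistic, x$n_low, x$n_high))
  cat(sprintf("  permutation p = %.4g (%d permutations, minprop %.2f)\n",
              x$pvalue, x$n_perm, x$minprop))
  invisible(x)
}

#' @rdname maxstat_cutpoint
#' @param x a `maxstat_cut` object.
#' @param ... unused.
#' @method tidy maxstat_cut
#' @export
tidy.maxstat_cut <- function(x, ...) x$candidates

#' @rdname maxstat_cutpoint
#' @method glance maxstat_cut
#' @export
glance.maxstat_cut <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, max_statistic = x$max_statistic,
         pvalue = x$pvalue, n_low = x$n_low, n_high = x$n_high,
         minprop = x$minprop, n_perm = x$n_perm)
}

#' Dichotomise samples at a cut-point
#'
#' @param data data frame with the expression column.
#' @param cut a `maxstat_cut` object or a numeric cut value.
#' @param expression expression column name.
#' @return `data` with an added `expression_group` column
#'   (`"low"` = value <= cut, `"high"` otherwise).
#' @export
cut_expression <- function(data, cut, expression = "expression") {
  cc <- if (inherits(cut, "maxstat_cut")) cut$cutpoint else cut
  data$expression_group <- ifelse(data[[expression]] <= cc, "low", "high")
  data
}
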