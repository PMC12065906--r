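#' Configuration for the tumour-cohort simulator
#'
#' Describes a colorectal-cancer-like cohort carrying per-sample pathway
#' variant flags, RSEM-like positive expression values for a small gene
#' panel, and right-censored survival whose hazard depends on one gene's
#' expression relative to a planted cut-point.
#'
#' Simulated genes fall into three classes (roughly equal thirds):
#' `dependent` genes are shifted by `dependent_gene_effect` (log2) in every
#' SMAD4-variant sample regardless of other pathway variants; `confounded`
#' genes are shifted by `context_gene_effect` only when a second-pathway
#' variant (cycling over RTK-RAS, TP53, PI3K) is present; `null` genes are
#' pure noise. One additional `survival_marker` gene drives the hazard:
#' samples whose value exceeds its `cut_quantile` quantile have their
#' exponential hazard multiplied by `hazard_ratio`. Censoring is
#' administrative (uniform), tuned to the requested `censor_rate`.
#'
#' @param n_samples cohort size (>= 8 so the four subgroups are fillable).
#' @param n_genes number of panel genes (excluding the survival marker).
#' @param variant_prevalence named per-pathway alteration probabilities.
#' @param dependent_gene_effect log2 shift of dependent genes in
#'   SMAD4-variant samples.
#' @param context_gene_effect log2 shift of confounded genes in samples
#'   carrying their second-pathway variant.
#' @param noise_scale sd of log2 expression noise.
#' @param survival_baseline_hazard exponential baseline hazard per day.
#' @param hazard_ratio hazard multiplier above the planted cut-point.
#' @param censor_rate target fraction of censored samples, in [0, 1).
#' @param cut_quantile quantile of the survival-marker expression at which
#'   the cut-point is planted.
#' @param seed integer seed.
#' @return a list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 400,
                              n_genes = 30,
                              variant_prevalence = c(
                                WNT = 0.98, SMAD4 = 0.30, TGFB_other = 0.08,
                                BMP = 0.05, RTK_RAS = 0.50, TP53 = 0.50,
                                PI3K = 0.40
                              ),
                              dependent_gene_effect = 2,
                              context_gene_effect = 2,
                              noise_scale = 1,
                              survival_baseline_hazard = 0.001,
                              hazard_ratio = 4,
                              censor_rate = 0.3,
                              cut_quantile = 0.4,
                              seed = 1L) {
  needed <- c("WNT", "SMAD4", "TGFB_other", "BMP", "RTK_RAS", "TP53", "PI3K")
  if (!all(needed %in% names(variant_prevalence))) {
    abort(paste0("variant_prevalence must name all of: ",
                 paste(needed, collapse = ", ")))
  }
  if (any(variant_prevalence < 0 | variant_prevalence > 1)) {
    abort("variant prevalences must lie in [0, 1].")
  }
  if (survival_baseline_hazard <= 0 || hazard_ratio <= 0) {
    abort("hazard parameters must be > 0.")
  }
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1).")
  if (n_samples < 8) abort("n_samples must be >= 8 (subgroups unfillable otherwise).")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    variant_prevalence = variant_prevalence[needed],
    dependent_gene_effect = dependent_gene_effect,
    context_gene_effect = context_gene_effect,
    noise_scale = noise_scale,
    survival_baseline_hazard = survival_baseline_hazard,
    hazard_ratio = hazard_ratio, censor_rate = censor_rate,
    cut_quantile = cut_quantile, seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Simulate a tumour cohort with pathway variants, expression and survival
#'
#' @param config a [cohort_sim_config()].
#' @return a list of class `cohort_sim` with elements
#'   `expression` (tibble: `sample_id` + one positive column per gene),
#'   `variants` (long tibble: `sample_id`, `gene`, `alteration`),
#'   `survival` (tibble: `sample_id`, `time`, `event`, plus the
#'   survival-marker expression column `expression`) and
#'   `truth` (tibble: `gene`, `class`, `effect`, `context_pathway`,
#'   `mouse_sign`, `cut_quantile`, `cutpoint`).
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_samples = 60, n_genes = 6, seed = 3))
#' head(sim$variants)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed_(config$seed, {
    n <- config$n_samples
    sample_id <- sprintf("S%04d", seq_len(n))
    prev <- config$variant_prevalence
    cat <- pathway_catalog()

    ## pathway-level alteration indicators, then a concrete altered gene
    flags <- vapply(names(prev), function(p) rbinom(n, 1, prev[[p]]) == 1,
                    logical(n))
    pick_gene <- function(pathway) {
      pool <- switch(pathway,
        SMAD4 = "SMAD4",
        TGFB_other = setdiff(cat$TGFB, "SMAD4"),
        cat[[pathway]]
      )
      sample(pool, 1L)
    }
    variants <- purrr::imap(
      as.data.frame(flags),
      function(f, pathway) {
        idx <- which(f)
        if (!length(idx)) return(NULL)
        tibble(sample_id = sample_id[idx],
               gene = vapply(idx, function(i) pick_gene(pathway), character(1)),
               alteration = "missense")
      }
    ) |>
      purrr::compact() |>
      list_rbind() |>
      arrange(.data$sample_id, .data$gene)

    ## gene panel: thirds dependent / confounded / null
    ng <- config$n_genes
    n_dep <- ceiling(ng / 3)
    n_conf <- ceiling((ng - n_dep) / 2)
    classes <- c(rep("dependent", n_dep), rep("confounded", n_conf),
                 rep("null", ng - n_dep - n_conf))
    contexts <- rep(NA_character_, ng)
    contexts[classes == "confounded"] <-
      rep_len(c("RTK_RAS", "TP53", "PI3K"), n_conf)
    gene <- sprintf("PANEL%03d", seq_len(ng))

    base <- runif(ng, 5, 10)          # log2 baseline per gene
    shift <- matrix(0, n, ng)
    dep_cols <- which(classes == "dependent")
    shift[, dep_cols] <- outer(as.numeric(flags[, "SMAD4"]),
                               rep(config$dependent_gene_effect, length(dep_cols)))
    for (j in which(classes == "confounded")) {
      shift[, j] <- as.numeric(flags[, contexts[j]]) * config$context_gene_effect
    }
    log2expr <- sweep(shift, 2, base, "+") + matrix(rnorm(n * ng, 0, config$noise_scale), n, ng)
    expr <- 2^log2expr
    colnames(expr) <- gene
    expression <- bind_cols(tibble(sample_id = sample_id), as_tibble(expr))

    ## survival marker and exponential survival with planted cut-point
    surv_expr <- 2^(8 + rnorm(n, 0, config$noise_scale))
    cutpoint <- unname(quantile(surv_expr, config$cut_quantile))
    high <- surv_expr > cutpoint
    rate <- config$survival_baseline_hazard * config$hazard_ratio^high
    t_event <- rexp(n, rate)
    if (config$censor_rate > 0) {
      ## administrative horizon b solving the exact mixture censor fraction
      ## P(C < T) = mean_i (1 - exp(-rate_i b)) / (rate_i b) for C ~ U(0, b)
      f <- function(b) mean((1 - exp(-rate * b)) / (rate * b)) - config$censor_rate
      upper <- uniroot(f, c(1e-6, 1e8 / mean(rate)))$root
      t_cens <- runif(n, 0, upper)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    truth <- tibble(
      gene = c(gene, "SURV001"),
      class = c(classes, "survival_marker"),
      effect = c(ifelse(classes == "dependent", config$dependent_gene_effect,
                        ifelse(classes == "confounded", config$context_gene_effect, 0)),
                 0),
      context_pathway = c(contexts, NA),
      mouse_sign = c(ifelse(classes == "dependent",
                            sign(config$dependent_gene_effect),
                            ifelse(classes == "confounded",
                                   sign(config$context_gene_effect), 0)), 0),
      cut_quantile = c(rep(NA_real_, ng), config$cut_quantile),
      cutpoint = c(rep(NA_real_, ng), cutpoint)
    )

    structure(list(
      expression = expression,
      variants = variants,
      survival = tibble(sample_id = sample_id, time = time, event = event,
                        expression = surv_expr),
      truth = truth
    ), class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Cohort simulation:", nrow(x$expression), "samples,",
      ncol(x$expression) - 1L, "panel genes\n")
  print(table(x$truth$class))
  invisible(x)
}
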