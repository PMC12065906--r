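#' Configuration for the bulk organoid time-course simulator
#'
#' Describes a two-genotype (WT / Smad4-null "KO") by three-timepoint
#' (0, 1, 12 h of TGF-beta1 exposure) by `n_reps` replicate RNA-seq design
#' and the classes of planted expression effects. The defaults emulate the
#' 18-sample organoid experiment the differential-expression and
#' classification machinery was designed around: three biological replicates
#' per genotype, log-normal baseline means, a constant negative-binomial
#' dispersion and a planted log2 effect size of 3.
#'
#' Planted classes (fractions in `class_fractions`, remainder null):
#' \describe{
#'   \item{early_up / early_down}{respond at 1 h in WT only and sustain the
#'     response to 12 h.}
#'   \item{transient}{respond (up) at 1 h in WT only, back to baseline by
#'     12 h, so the 12 h vs 1 h contrast reverses sign.}
#'   \item{late_up / late_down}{respond at 12 h only, in WT only.}
#'   \item{smad4_dependent}{early sustained response in WT only.}
#'   \item{smad4_independent}{early sustained response in both genotypes.}
#'   \item{baseline_shift}{constant genotype difference (KO above WT) at all
#'     timepoints, no TGF-beta response.}
#' }
#'
#' @param n_genes number of simulated genes.
#' @param n_reps replicates per genotype x time cell (>= 2).
#' @param timepoints ordered timepoint labels (hours).
#' @param genotypes genotype labels; the first is the TGF-beta-responsive
#'   wild type, the second the Smad4-deficient genotype.
#' @param mean_meanlog,mean_sdlog log-normal parameters of the per-gene
#'   baseline mean expression.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha mu^2); scalar or one value per gene.
#' @param effect_lfc planted log2 effect size.
#' @param class_fractions named numeric vector of class fractions; must sum
#'   to <= 1, the remainder is null.
#' @param size_factor_sdlog log-normal sd of per-sample library-size factors
#'   (0 for equal libraries).
#' @param seed integer seed for reproducibility.
#' @return a list of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_genes = 2000,
                            n_reps = 3,
                            timepoints = c(0, 1, 12),
                            genotypes = c("WT", "KO"),
                            mean_meanlog = log(200),
                            mean_sdlog = 1,
                            dispersion = 0.1,
                            effect_lfc = 3,
                            class_fractions = c(
                              early_up = 0.05, early_down = 0.05,
                              transient = 0.05,
                              late_up = 0.05, late_down = 0.05,
                              smad4_dependent = 0.05,
                              smad4_independent = 0.05,
                              baseline_shift = 0.05
                            ),
                            size_factor_sdlog = 0.1,
                            seed = 1L) {
  known <- c("early_up", "early_down", "transient", "late_up", "late_down",
             "smad4_dependent", "smad4_independent", "baseline_shift", "null")
  if (length(class_fractions) &&
      (is.null(names(class_fractions)) || !all(names(class_fractions) %in% known))) {
    abort(paste0("class_fractions names must be among: ",
                 paste(setdiff(known, "null"), collapse = ", ")))
  }
  class_fractions <- class_fractions[setdiff(names(class_fractions), "null")]
  if (sum(class_fractions) > 1 + 1e-12 || any(class_fractions < 0)) {
    abort("class_fractions must be non-negative and sum to <= 1.")
  }
  if (n_reps < 2) abort("n_reps must be >= 2.")
  if (any(dispersion <= 0)) abort("dispersion must be > 0.")
  if (length(timepoints) != 3L) abort("exactly three timepoints are expected.")
  if (length(genotypes) != 2L) abort("exactly two genotypes are expected.")
  structure(list(
    n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
    timepoints = timepoints, genotypes = genotypes,
    mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
    dispersion = dispersion, effect_lfc = effect_lfc,
    class_fractions = class_fractions,
    size_factor_sdlog = size_factor_sdlog,
    seed = as.integer(seed)
  ), class = "bulk_sim_config")
}

#' Simulate a genotype x time organoid count matrix with planted effects
#'
#' Draws negative-binomial counts for the design described by a
#' [bulk_sim_config()] and returns the count matrix, the sample metadata and
#' a ground-truth table recording each gene's planted class so that
#' downstream classification can be scored.
#'
#' The planted log2 effects enter multiplicatively: a gene of class
#' `early_up` has its mean multiplied by `2^effect_lfc` at 1 h (and 12 h,
#' the response is sustained) in the wild-type genotype only. Null genes
#' share the same marginal mean in every genotype x time cell.
#'
#' @param config a [bulk_sim_config()].
#' @return a list of class `bulk_sim` with elements
#'   `counts` (tibble: `gene_id` + one integer column per sample),
#'   `samples` (tibble: `sample_id`, `genotype`, `time`, `replicate`) and
#'   `truth` (tibble: `gene_id`, `class`, `effect_lfc`).
#' @examples
#' sim <- simulate_bulk_counts(bulk_sim_config(n_genes = 50, seed = 7))
#' dim(sim$counts)
#' @export
simulate_bulk_counts <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  with_seed_(config$seed, {
    ng <- config$n_genes
    wt <- config$genotypes[1L]
    ko <- config$genotypes[2L]
    samples <- tidyr::expand_grid(
      genotype = config$genotypes,
      time = config$timepoints,
      replicate = seq_len(config$n_reps)
    ) |>
      mutate(sample_id = paste0(.data$genotype, "_t", .data$time,
                                "_r", .data$replicate)) |>
      select("sample_id", "genotype", "time", "replicate")

    n_per_class <- floor(config$class_fractions * ng)
    classes <- rep("null", ng)
    if (length(n_per_class)) {
      assign_to <- rep(names(n_per_class), n_per_class)
      classes[seq_along(assign_to)] <- assign_to
    }
    gene_id <- sprintf("gene%05d", seq_len(ng))
    base_mu <- rlnorm(ng, config$mean_meanlog, config$mean_sdlog)
    e <- config$effect_lfc

    ## planted log2 offsets per class: rows gene, split by genotype/time
    lfc_at <- function(cls, genotype, time) {
      t1 <- config$timepoints[2L]
      t12 <- config$timepoints[3L]
      responsive <- genotype == wt
      out <- numeric(length(cls))
      late <- time == t12
      mid <- time == t1
      out[cls == "early_up" & responsive & (mid | late)] <- e
      out[cls == "early_down" & responsive & (mid | late)] <- -e
      out[cls == "transient" & responsive & mid] <- e
      out[cls == "late_up" & responsive & late] <- e
      out[cls == "late_down" & responsive & late] <- -e
      out[cls == "smad4_dependent" & responsive & (mid | late)] <- e
      out[cls == "smad4_independent" & (mid | late)] <- e
      out[cls == "baseline_shift" & genotype == ko] <- e
      out
    }

    sf <- rlnorm(nrow(samples), 0, config$size_factor_sdlog)
    alpha <- rep_len(config$dispersion, ng)
    counts <- matrix(0L, nrow = ng, ncol = nrow(samples))
    for (j in seq_len(nrow(samples))) {
      mu_j <- base_mu * 2^lfc_at(classes, samples$genotype[j], samples$time[j]) * sf[j]
      counts[, j] <- rnbinom(ng, mu = mu_j, size = 1 / alpha)
    }
    colnames(counts) <- samples$sample_id

    out <- list(
      counts = bind_cols(tibble(gene_id = gene_id), as_tibble(counts)),
      samples = samples,
      truth = tibble(gene_id = gene_id, class = classes,
                     effect_lfc = ifelse(classes == "null", 0, e))
    )
    structure(out, class = "bulk_sim")
  })
}

#' @export
print.bulk_sim <- function(x, ...) {
  cat("Bulk organoid simulation:", nrow(x$counts), "genes x",
      nrow(x$samples), "samples\n")
  cat("Planted classes:\n")
  print(table(x$truth$class))
  invisible(x)
}
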