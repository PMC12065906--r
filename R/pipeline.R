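#' Pipeline run configuration
#'
#' Collects every threshold, size and seed used by [run_pipeline()] so that
#' no stage relies on hidden constants. Stage toggles select which parts of
#' the all-synthetic demo are executed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; each stochastic stage derives its own sub-seed.
#' @param n_genes number of genes in the bulk simulation.
#' @param n_cohort_samples cohort size.
#' @param lfc_thresh DE log2 fold-change threshold.
#' @param alpha adjusted-p significance threshold.
#' @param baseline_lfc_thresh threshold of the baseline signature.
#' @param auc_min minimum enrichment AUC.
#' @param minprop maxstat minimum group proportion.
#' @param n_perm,n_boot permutation / bootstrap iterations.
#' @param stages character vector of stages to run, a subset of
#'   `c("de", "classify", "enrich", "cohort", "survival", "proportions")`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("smadsig_run_"),
                       seed = 1L,
                       n_genes = 500,
                       n_cohort_samples = 400,
                       lfc_thresh = 1.5,
                       alpha = 0.05,
                       baseline_lfc_thresh = 2,
                       auc_min = 0.5,
                       minprop = 0.1,
                       n_perm = 200,
                       n_boot = 200,
                       stages = c("de", "classify", "enrich", "cohort",
                                  "survival", "proportions")) {
  if (lfc_thresh <= 0 || alpha <= 0 || minprop <= 0) {
    abort("thresholds must be positive.")
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), n_genes = n_genes,
    n_cohort_samples = n_cohort_samples, lfc_thresh = lfc_thresh,
    alpha = alpha, baseline_lfc_thresh = baseline_lfc_thresh,
    auc_min = auc_min, minprop = minprop, n_perm = n_perm, n_boot = n_boot,
    stages = stages
  ), class = "run_config")
}

pipeline_write <- function(tab, dir, name, stage, manifest) {
  path <- file.path(dir, name)
  readr::write_tsv(tab, path, progress = FALSE)
  bind_rows(manifest, tibble(stage = stage, file = name,
                             md5 = unname(tools::md5sum(path))))
}

#' Run the all-synthetic demonstration pipeline
#'
#' Chains simulate -> filter/normalise -> Wald contrasts and time-course
#' LRT -> target classification and baseline signature -> CERNO enrichment
#' -> cohort subgroup analysis with the three-criterion SMAD4-dependence
#' decision -> maxstat/Kaplan-Meier survival -> cell QC and cluster
#' proportion testing, writing every artifact as TSV and returning a
#' manifest with md5 checksums. Rerunning with the same configuration
#' (including the seed) reproduces identical checksums.
#'
#' @param cfg a [run_config()].
#' @return a tibble manifest (`stage`, `file`, `md5`), invisibly also
#'   written to `manifest.tsv` in `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble(stage = character(), file = character(), md5 = character())
  run_stage <- function(name) name %in% cfg$stages

  ## --- bulk simulation (always needed by de/classify/enrich) -------------
  contrasts <- NULL
  if (any(c("de", "classify", "enrich") %in% cfg$stages)) {
    inform(sprintf("[sim_bulk] n_genes=%d seed=%d", cfg$n_genes,
                   stage_seed(cfg$seed, 1L)))
    sim <- simulate_bulk_counts(bulk_sim_config(
      n_genes = cfg$n_genes, seed = stage_seed(cfg$seed, 1L)
    ))
    manifest <- pipeline_write(sim$counts, cfg$out_dir, "bulk_counts.tsv", "sim_bulk", manifest)
    manifest <- pipeline_write(sim$samples, cfg$out_dir, "bulk_samples.tsv", "sim_bulk", manifest)
    manifest <- pipeline_write(sim$truth, cfg$out_dir, "bulk_truth.tsv", "sim_bulk", manifest)
  }

  if (run_stage("de")) {
    inform(sprintf("[de] filter >=5 reads in >=3 samples; lfc_thresh=%g alpha=%g",
                   cfg$lfc_thresh, cfg$alpha))
    counts <- filter_low_counts(sim$counts)
    samples <- sim$samples |>
      mutate(group = paste0(.data$genotype, "_", .data$time))
    sf <- estimate_size_factors(counts)
    disp <- estimate_dispersions(counts, samples, size_factors = sf)
    specs <- list(
      WT_t1_vs_t0 = c("WT_1", "WT_0"), WT_t12_vs_t0 = c("WT_12", "WT_0"),
      WT_t12_vs_t1 = c("WT_12", "WT_1"), KO_t1_vs_t0 = c("KO_1", "KO_0"),
      KO_t12_vs_t0 = c("KO_12", "KO_0"), KO_t12_vs_t1 = c("KO_12", "KO_1"),
      KO_vs_WT_t0 = c("KO_0", "WT_0")
    )
    contrasts <- purrr::imap(specs, function(sp, nm) {
      nb_wald(counts, samples, contrast = sp, size_factors = sf,
              dispersions = disp)
    })
    for (nm in names(contrasts)) {
      manifest <- pipeline_write(contrasts[[nm]], cfg$out_dir,
                                 paste0("de_", nm, ".tsv"), "de", manifest)
    }
    lrt <- nb_lrt(counts, samples, full = ~ genotype * factor(time),
                  reduced = ~ genotype + factor(time), size_factors = sf,
                  dispersions = disp)
    manifest <- pipeline_write(lrt, cfg$out_dir, "de_lrt_interaction.tsv", "de", manifest)
  }

  if (run_stage("classify")) {
    if (is.null(contrasts)) abort("stage `classify` requires stage `de`.")
    inform(sprintf("[classify] lfc_thresh=%g baseline_lfc_thresh=%g alpha=%g",
                   cfg$lfc_thresh, cfg$baseline_lfc_thresh, cfg$alpha))
    classes <- classify_targets(contrasts, lfc_thresh = cfg$lfc_thresh,
                                alpha = cfg$alpha)
    manifest <- pipeline_write(classes, cfg$out_dir, "gene_classes.tsv",
                               "classify", manifest)
    ## synthetic ortholog map: ~90% of genes map to an upper-case human id
    ids <- sim$truth$gene_id
    mapped <- as.integer(sub("gene", "", ids)) %% 10L != 0L
    orth <- tibble(mouse_id = ids,
                   human_id = ifelse(mapped, toupper(ids), NA_character_))
    signature <- baseline_signature(contrasts$KO_vs_WT_t0, orth,
                                    lfc_thresh = cfg$baseline_lfc_thresh,
                                    alpha = cfg$alpha)
    manifest <- pipeline_write(signature, cfg$out_dir, "baseline_signature.tsv",
                               "classify", manifest)
  }

  if (run_stage("enrich")) {
    if (is.null(contrasts)) abort("stage `enrich` requires stage `de`.")
    inform(sprintf("[enrich] auc_min=%g alpha=%g", cfg$auc_min, cfg$alpha))
    ranking <- contrasts$WT_t1_vs_t0 |>
      select("gene_id", "pvalue") |>
      filter(is.finite(.data$pvalue))
    modules <- split(sim$truth$gene_id, sim$truth$class)
    modules <- modules[names(modules) != "null"]
    gmt_path <- file.path(cfg$out_dir, "modules.gmt")
    write_gmt(modules, gmt_path)
    enr <- cerno_test(ranking, read_gmt(gmt_path))
    manifest <- bind_rows(manifest, tibble(stage = "enrich", file = "modules.gmt",
                                           md5 = unname(tools::md5sum(gmt_path))))
    manifest <- pipeline_write(enr, cfg$out_dir, "enrichment.tsv", "enrich", manifest)
    manifest <- pipeline_write(call_enriched(enr, cfg$auc_min, cfg$alpha),
                               cfg$out_dir, "enrichment_positive.tsv", "enrich", manifest)
  }

  cohort <- NULL
  if (any(c("cohort", "survival") %in% cfg$stages)) {
    inform(sprintf("[sim_cohort] n_samples=%d seed=%d", cfg$n_cohort_samples,
                   stage_seed(cfg$seed, 5L)))
    cohort <- simulate_cohort(cohort_sim_config(
      n_samples = cfg$n_cohort_samples, seed = stage_seed(cfg$seed, 5L)
    ))
    manifest <- pipeline_write(cohort$expression, cfg$out_dir, "cohort_expression.tsv",
                               "sim_cohort", manifest)
    manifest <- pipeline_write(cohort$variants, cfg$out_dir, "cohort_variants.tsv",
                               "sim_cohort", manifest)
    manifest <- pipeline_write(cohort$survival, cfg$out_dir, "cohort_survival.tsv",
                               "sim_cohort", manifest)
    manifest <- pipeline_write(cohort$truth, cfg$out_dir, "cohort_truth.tsv",
                               "sim_cohort", manifest)
  }

  if (run_stage("cohort")) {
    inform(sprintf("[cohort] alpha=%g; G1/G3 = context variant absent, G2/G4 = present",
                   cfg$alpha))
    flags <- assign_pathway_status(cohort$variants,
                                   samples = cohort$expression$sample_id)
    selection <- select_cohort(flags)
    panel <- setdiff(names(cohort$expression), "sample_id")
    volcano <- volcano_mut_vs_wt(cohort$expression, selection, panel)
    manifest <- pipeline_write(volcano, cfg$out_dir, "cohort_volcano.tsv",
                               "cohort", manifest)
    ctx_res <- purrr::map(c("RTK_RAS", "TP53", "PI3K"), function(ctx) {
      sg <- assemble_subgroups(flags, selection, ctx)
      context_test(cohort$expression, sg, panel)
    }) |> list_rbind()
    manifest <- pipeline_write(ctx_res, cfg$out_dir, "cohort_context_stats.tsv",
                               "cohort", manifest)
    decision <- smad4_dependence_decision(
      ctx_res,
      human_direction = volcano |> transmute(gene = .data$gene,
                                             human_sign = sign(.data$median_log2fc)),
      mouse_direction = cohort$truth |> filter(.data$class != "survival_marker") |>
        select("gene", "mouse_sign"),
      alpha = cfg$alpha
    )
    manifest <- pipeline_write(decision, cfg$out_dir, "cohort_decision.tsv",
                               "cohort", manifest)
  }

  if (run_stage("survival")) {
    inform(sprintf("[survival] minprop=%g n_perm=%d", cfg$minprop, cfg$n_perm))
    cut <- maxstat_cutpoint(cohort$survival, minprop = cfg$minprop,
                            n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, 6L))
    manifest <- pipeline_write(glance(cut), cfg$out_dir, "survival_cutpoint.tsv",
                               "survival", manifest)
    grouped <- cut_expression(cohort$survival, cut)
    km <- grouped |>
      group_by(.data$expression_group) |>
      group_modify(~ km_estimate(.x)) |>
      ungroup()
    manifest <- pipeline_write(km, cfg$out_dir, "survival_km.tsv", "survival", manifest)
    lr <- logrank_test(grouped, group = "expression_group")
    manifest <- pipeline_write(lr, cfg$out_dir, "survival_logrank.tsv",
                               "survival", manifest)
  }

  if (run_stage("proportions")) {
    inform(sprintf("[proportions] n_perm=%d n_boot=%d seed=%d", cfg$n_perm,
                   cfg$n_boot, stage_seed(cfg$seed, 7L)))
    csim <- simulate_cells(cell_sim_config(seed = stage_seed(cfg$seed, 7L)))
    manifest <- pipeline_write(csim$cells, cfg$out_dir, "cells.tsv",
                               "sim_cells", manifest)
    kept <- suppressMessages(qc_filter_cells(csim$cells))
    prop <- proportion_test(kept, n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                            seed = stage_seed(cfg$seed, 8L))
    manifest <- pipeline_write(prop, cfg$out_dir, "cluster_proportions.tsv",
                               "proportions", manifest)
  }

  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                   progress = FALSE)
  manifest
}
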