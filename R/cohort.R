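#' Colorectal-cancer pathway gene catalog
#'
#' The frequently mutated pathway gene lists used to flag per-sample
#' pathway variant status in the tumour cohort: Wnt/beta-catenin, TP53,
#' PI3K, RTK-RAS, TGF-beta and BMP.
#'
#' @return a named list of character vectors of HGNC symbols.
#' @export
pathway_catalog <- function() {
  list(
    WNT = c("APC", "CTNNB1", "DKK1", "DKK2", "DKK3", "DKK4", "LRP5",
            "FZD10", "AMER1", "AXIN2", "TCF7L2", "FBXW7", "ARID1A"),
    TP53 = c("ATM", "TP53"),
    PI3K = c("IGF2", "IRS2", "PTEN", "PIK3R1", "PIK3CA"),
    RTK_RAS = c("NRAS", "KRAS", "BRAF", "ERBB2", "ERBB3"),
    TGFB = c("ACVR1B", "ACVR2A", "SMAD2", "SMAD3", "SMAD4", "TGFBR1",
             "TGFBR2"),
    BMP = c("SMAD1", "SMAD9", "SMAD5", "BMPR1A", "BMPR1B", "ACVR1")
  )
}

#' Per-sample pathway variant flags
#'
#' A pathway flag is true iff any catalog gene of that pathway carries an
#' alteration in the sample. SMAD4 is flagged separately from the rest of
#' the TGF-beta pathway (`TGFB_other` = TGF-beta genes excluding SMAD4) so
#' that the cohort selection rules can distinguish them.
#'
#' @param variants long tibble of alteration calls with columns
#'   `sample_id`, `gene` (and optionally `alteration`).
#' @param catalog pathway catalog, by default [pathway_catalog()].
#' @param samples character vector of all sample ids (samples without any
#'   alteration otherwise would not appear); defaults to the samples seen
#'   in `variants`.
#' @return a tibble with `sample_id` and one logical column per pathway:
#'   `WNT`, `TP53`, `PI3K`, `RTK_RAS`, `SMAD4`, `TGFB_other`, `BMP`.
#' @export
assign_pathway_status <- function(variants, catalog = pathway_catalog(),
                                  samples = NULL) {
  needed <- c("WNT", "TP53", "PI3K", "RTK_RAS", "TGFB", "BMP")
  if (!all(needed %in% names(catalog))) {
    abort(paste0("unknown pathway catalog; needs: ",
                 paste(needed, collapse = ", ")))
  }
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  altered <- split(variants$gene, variants$sample_id)
  flag <- function(genes_of) {
    vapply(samples, function(s) {
      any(altered[[s]] %in% genes_of)
    }, logical(1), USE.NAMES = FALSE)
  }
  tibble(
    sample_id = samples,
    WNT = flag(catalog$WNT),
    TP53 = flag(catalog$TP53),
    PI3K = flag(catalog$PI3K),
    RTK_RAS = flag(catalog$RTK_RAS),
    SMAD4 = flag("SMAD4"),
    TGFB_other = flag(setdiff(catalog$TGFB, "SMAD4")),
    BMP = flag(catalog$BMP)
  )
}

#' Select the SMAD4-mutant and control cohorts
#'
#' Both groups are restricted to Wnt-pathway-variant samples (the
#' adenoma-initiating context). The mutant group carries a SMAD4 variant
#' and no other TGF-beta pathway variant; the control group carries no
#' TGF-beta pathway variant at all. All other samples are excluded.
#'
#' @param flags pathway-flag tibble from [assign_pathway_status()].
#' @return a tibble with `sample_id` and `smad4_status`
#'   (`"mutant"` / `"control"`).
#' @export
select_cohort <- function(flags) {
  sel <- flags |>
    filter(.data$WNT) |>
    mutate(smad4_status = case_when(
      .data$SMAD4 & !.data$TGFB_other ~ "mutant",
      !.data$SMAD4 & !.data$TGFB_other ~ "control",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$smad4_status)) |>
    select("sample_id", "smad4_status")
  if (!any(sel$smad4_status == "mutant") || !any(sel$smad4_status == "control")) {
    abort("cohort selection produced an empty mutant or control set.")
  }
  sel
}

#' Mutant-vs-control volcano statistics for a gene signature
#'
#' Per gene, a two-sided Mann-Whitney U test on expression between the
#' SMAD4-mutant and control samples, and a median log2 fold-change
#' `log2((median_mut + 1) / (median_ctrl + 1))` (pseudo-count 1 on the
#' RSEM-like medians). P-values are BH-adjusted across the supplied gene
#' list only.
#'
#' @param expr expression tibble (`sample_id` + one positive column per
#'   gene).
#' @param selection cohort selection from [select_cohort()].
#' @param genes character vector of signature genes to test.
#' @return a tibble with columns `gene`, `median_log2fc`, `pvalue`, `padj`.
#' @export
volcano_mut_vs_wt <- function(expr, selection, genes) {
  missing_genes <- setdiff(genes, names(expr))
  if (length(missing_genes)) {
    warn(paste0("gene(s) absent from expression, skipped: ",
                paste(missing_genes, collapse = ", ")))
    genes <- setdiff(genes, missing_genes)
  }
  dat <- expr |> inner_join(selection, by = "sample_id")
  mut <- dat$smad4_status == "mutant"
  if (!any(mut) || all(mut)) abort("both cohort groups must be non-empty.")
  res <- purrr::map(genes, function(g) {
    x <- dat[[g]][mut]; y <- dat[[g]][!mut]
    p <- if (all(x %in% y) && all(y %in% x) && length(x) == length(y)) {
      1
    } else {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    }
    tibble(gene = g,
           median_log2fc = log2((median(x) + 1) / (median(y) + 1)),
           pvalue = p)
  }) |> list_rbind()
  res$padj <- bh_adjust(res$pvalue)
  res
}

#' Assemble the G1-G4 context subgroups
#'
#' Crosses SMAD4 status with presence of a second-pathway (context)
#' variant: G1 = SMAD4-WT without, G2 = SMAD4-WT with, G3 = SMAD4-mutant
#' without, G4 = SMAD4-mutant with the context variant (odd groups =
#' variant absent).
#'
#' @param flags pathway-flag tibble from [assign_pathway_status()].
#' @param selection cohort selection from [select_cohort()].
#' @param context one of `"RTK_RAS"`, `"TP53"`, `"PI3K"`.
#' @return a tibble with `sample_id`, `smad4_status`, `context_pathway`
#'   and `group` (`G1`-`G4`).
#' @export
assemble_subgroups <- function(flags, selection, context = c("RTK_RAS", "TP53", "PI3K")) {
  context <- match.arg(context)
  out <- selection |>
    inner_join(flags |> select("sample_id", ctx = all_of(context)),
               by = "sample_id") |>
    mutate(
      context_pathway = context,
      group = case_when(
        .data$smad4_status == "control" & !.data$ctx ~ "G1",
        .data$smad4_status == "control" & .data$ctx ~ "G2",
        .data$smad4_status == "mutant" & !.data$ctx ~ "G3",
        .data$smad4_status == "mutant" & .data$ctx ~ "G4"
      )
    ) |>
    select("sample_id", "smad4_status", "context_pathway", "group")
  sizes <- table(factor(out$group, levels = paste0("G", 1:4)))
  if (any(sizes < 3L)) {
    abort(paste0("subgroup(s) with fewer than 3 samples in context ",
                 context, ": ",
                 paste(names(sizes)[sizes < 3], collapse = ", ")))
  }
  out
}

#' Kruskal-Wallis test with Dunn-Holm post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (chi-square, df = groups - 1) and Dunn's
#' z tests from pooled ranks for every group pair, two-sided and
#' Holm-adjusted within the call. When all values are identical the
#' p-value is 1 by convention.
#'
#' @param data a data frame.
#' @param value name of the numeric value column.
#' @param group name of the grouping column.
#' @return a list with `kw` (tibble: `statistic`, `df`, `pvalue`) and
#'   `pairs` (tibble: `group1`, `group2`, `z`, `pvalue`, `p_holm`).
#' @examples
#' d <- data.frame(v = 1:12, g = rep(paste0("G", 1:4), each = 3))
#' kw_dunn(d, "v", "g")$kw
#' @export
kw_dunn <- function(data, value = "value", group = "group") {
  x <- data[[value]]
  g <- factor(data[[group]])
  if (any(table(g) < 3L)) abort("each group needs at least 3 values.")
  if (length(unique(x)) == 1L) {
    lev <- levels(g)
    pairs <- utils::combn(lev, 2L)
    return(list(
      kw = tibble(statistic = 0, df = nlevels(g) - 1L, pvalue = 1),
      pairs = tibble(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = 0, pvalue = 1, p_holm = 1)
    ))
  }
  kw <- kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    (rbar[[i]] - rbar[[j]]) / sqrt(s2 * (1 / n[[i]] + 1 / n[[j]]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  list(
    kw = tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                pvalue = unname(kw$p.value)),
    pairs = tibble(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
                   pvalue = p, p_holm = p.adjust(p, method = "holm"))
  )
}

#' Per-gene context statistics across the G1-G4 subgroups
#'
#' For each gene: a Kruskal-Wallis test across the four subgroups
#' (BH-adjusted across genes) and Dunn-Holm p-values for the six group
#' pairs (Holm within the gene).
#'
#' @param expr expression tibble (`sample_id` + gene columns).
#' @param subgroups subgroup assignment from [assemble_subgroups()].
#' @param genes character vector of genes to test.
#' @return a tibble with one row per gene: `gene`, `context_pathway`,
#'   `kw_p`, `kw_padj` and `p_G1G2`, `p_G1G3`, `p_G1G4`, `p_G2G3`,
#'   `p_G2G4`, `p_G3G4` (Holm-adjusted).
#' @export
context_test <- function(expr, subgroups, genes) {
  dat <- expr |> inner_join(subgroups, by = "sample_id")
  res <- purrr::map(genes, function(g) {
    kd <- kw_dunn(dat, value = g, group = "group")
    pw <- kd$pairs |>
      mutate(pair = paste0("p_", .data$group1, .data$group2)) |>
      select("pair", "p_holm") |>
      pivot_wider(names_from = "pair", values_from = "p_holm")
    bind_cols(tibble(gene = g,
                     context_pathway = subgroups$context_pathway[1L],
                     kw_p = kd$kw$pvalue), pw)
  }) |> list_rbind()
  res$kw_padj <- bh_adjust(res$kw_p)
  relocate(res, "kw_padj", .after = "kw_p")
}

#' Three-criterion SMAD4-dependence decision
#'
#' A gene is called SMAD4-dependent in the human cohort when, with
#' significance meaning adjusted p < `alpha`:
#' \enumerate{
#'   \item every cross-status pair (G1-G3, G1-G4, G2-G3, G2-G4) differs
#'     significantly,
#'   \item neither within-status pair (G1-G2, G3-G4) differs significantly
#'     (the gene is insensitive to the second-pathway variant), and
#'   \item the human mutant-vs-control direction matches the direction
#'     observed in the mouse adenomas.
#' }
#' Criteria 1 and 2 must hold in every tested context pathway
#' (`mode = "all"`, the default) or in at least one (`mode = "any"`).
#' `failed_criterion` records the first failing criterion.
#'
#' @param context_results row-bound [context_test()] results over one or
#'   more context pathways.
#' @param human_direction tibble `gene`, `human_sign` (sign of the human
#'   mutant-vs-control shift, e.g. from [volcano_mut_vs_wt()]).
#' @param mouse_direction tibble `gene`, `mouse_sign` (sign observed in
#'   the mouse adenomas).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param mode `"all"` (criteria hold in every context) or `"any"`.
#' @return a tibble per gene: `gene`, `criterion1`, `criterion2`,
#'   `criterion3`, `smad4_dependent`, `failed_criterion`
#'   (`"none"`, `"1"`, `"2"` or `"3"`).
#' @export
smad4_dependence_decision <- function(context_results, human_direction,
                                      mouse_direction, alpha = 0.05,
                                      mode = c("all", "any")) {
  mode <- match.arg(mode)
  pair_cols <- c("p_G1G3", "p_G1G4", "p_G2G3", "p_G2G4", "p_G1G2", "p_G3G4")
  missing <- setdiff(pair_cols, names(context_results))
  if (length(missing)) {
    abort(paste0("missing pairwise p-value column(s): ",
                 paste(missing, collapse = ", ")))
  }
  agg <- if (mode == "all") all else any
  per_gene <- context_results |>
    group_by(.data$gene) |>
    summarise(
      criterion1 = agg(.data$p_G1G3 < alpha & .data$p_G1G4 < alpha &
                         .data$p_G2G3 < alpha & .data$p_G2G4 < alpha),
      criterion2 = agg(.data$p_G1G2 >= alpha & .data$p_G3G4 >= alpha),
      .groups = "drop"
    )
  out <- per_gene |>
    left_join(human_direction, by = "gene") |>
    left_join(mouse_direction, by = "gene") |>
    mutate(
      criterion3 = !is.na(.data$human_sign) & !is.na(.data$mouse_sign) &
        .data$human_sign == .data$mouse_sign & .data$mouse_sign != 0,
      smad4_dependent = .data$criterion1 & .data$criterion2 & .data$criterion3,
      failed_criterion = case_when(
        !.data$criterion1 ~ "1",
        !.data$criterion2 ~ "2",
        !.data$criterion3 ~ "3",
        TRUE ~ "none"
      )
    ) |>
    select("gene", "criterion1", "criterion2", "criterion3",
           "smad4_dependent", "failed_criterion")
  out
}
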