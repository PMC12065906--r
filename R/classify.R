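#' Canonical contrast names for target classification
#'
#' The classifier consumes seven Wald contrasts: the wild-type time course
#' (1 h vs 0 h, 12 h vs 0 h, 12 h vs 1 h), the same three contrasts in the
#' Smad4-deficient genotype, and the genotype contrast at baseline.
#'
#' @return character vector of the seven required contrast names.
#' @export
required_contrasts <- function() {
  c("WT_t1_vs_t0", "WT_t12_vs_t0", "WT_t12_vs_t1",
    "KO_t1_vs_t0", "KO_t12_vs_t0", "KO_t12_vs_t1",
    "KO_vs_WT_t0")
}

sig_dir <- function(de, genes, lfc_thresh, alpha) {
  de <- de[match(genes, de$gene_id), , drop = FALSE]
  sig <- !is.na(de$padj) & de$padj < alpha & abs(de$log2fc) >= lfc_thresh
  list(sig = sig, dir = ifelse(sig, sign(de$log2fc), 0))
}

#' Classify genes into TGF-beta target classes and Smad4-dependence status
#'
#' Rule system operating on a named list of DE contrast tables (names as in
#' [required_contrasts()]). Significance means `padj < alpha` together with
#' `|log2fc| >= lfc_thresh`, evaluated within each contrast separately.
#'
#' Rules, in order of precedence (transient > early > late):
#' \itemize{
#'   \item \emph{early}: significant in WT 1 h vs 0 h.
#'   \item \emph{transient}: early, and significantly changed in the
#'     opposite direction at a late contrast (WT 12 h vs 0 h and/or
#'     12 h vs 1 h).
#'   \item \emph{late}: not early, and significant at WT 12 h vs 0 h
#'     and/or 12 h vs 1 h.
#'   \item \emph{Smad4-independent}: a target gene whose KO genotype also
#'     shows a significant same-direction response vs its own baseline
#'     (1 h vs 0 h or 12 h vs 0 h); otherwise the target gene is
#'     \emph{Smad4-dependent}.
#'   \item \emph{baseline}: significant at KO vs WT, 0 h. A target gene
#'     whose baseline difference opposes its TGF-beta response direction is
#'     reassigned Smad4-dependent and removed from the baseline list.
#'   \item Genes significant only in the KO time course are reported as
#'     class `none`, status `not_applicable`.
#' }
#'
#' @param contrasts named list of DE tibbles covering all of
#'   [required_contrasts()] on a shared gene universe.
#' @param lfc_thresh absolute log2 fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return a tibble with columns `gene_id`, `target_class`
#'   (`early_up/early_down/transient_up/transient_down/late_up/late_down/none`),
#'   `smad4_status` (`dependent/independent/not_applicable`) and
#'   `baseline_deg` (`up/down/none`).
#' @export
classify_targets <- function(contrasts, lfc_thresh = 1.5, alpha = 0.05) {
  needed <- required_contrasts()
  missing <- setdiff(needed, names(contrasts))
  if (length(missing)) {
    abort(paste0("missing contrast(s): ", paste(missing, collapse = ", ")))
  }
  genes <- sort(unique(unlist(lapply(contrasts[needed], function(d) d$gene_id))))
  s <- lapply(contrasts[needed], sig_dir, genes = genes,
              lfc_thresh = lfc_thresh, alpha = alpha)

  early <- s$WT_t1_vs_t0$sig
  dir_early <- s$WT_t1_vs_t0$dir
  late0 <- s$WT_t12_vs_t0; late1 <- s$WT_t12_vs_t1

  transient <- early &
    ((late0$sig & late0$dir == -dir_early) |
     (late1$sig & late1$dir == -dir_early))
  late <- !early & (late0$sig | late1$sig)
  dir_late <- ifelse(late0$sig, late0$dir, late1$dir)

  target_class <- rep("none", length(genes))
  target_class[late] <- ifelse(dir_late[late] > 0, "late_up", "late_down")
  target_class[early] <- ifelse(dir_early[early] > 0, "early_up", "early_down")
  target_class[transient] <- ifelse(dir_early[transient] > 0,
                                    "transient_up", "transient_down")

  resp_dir <- ifelse(early, dir_early, ifelse(late, dir_late, 0))

  ko_resp <- (s$KO_t1_vs_t0$sig & s$KO_t1_vs_t0$dir == resp_dir) |
    (s$KO_t12_vs_t0$sig & s$KO_t12_vs_t0$dir == resp_dir)

  base <- s$KO_vs_WT_t0
  baseline_deg <- ifelse(base$sig, ifelse(base$dir > 0, "up", "down"), "none")

  is_target <- target_class != "none"
  smad4_status <- rep("not_applicable", length(genes))
  smad4_status[is_target] <- ifelse(ko_resp[is_target], "independent", "dependent")
  smad4_status[!is_target & baseline_deg != "none"] <- "dependent"

  ## baseline difference opposing the response direction: reassign dependent,
  ## drop from the baseline list
  oppose <- is_target & base$sig & base$dir == -resp_dir & resp_dir != 0
  smad4_status[oppose] <- "dependent"
  baseline_deg[oppose] <- "none"

  tibble(gene_id = genes, target_class = target_class,
         smad4_status = smad4_status, baseline_deg = baseline_deg)
}

#' Build the cross-species baseline candidate signature
#'
#' Selects baseline differentially expressed genes (KO vs WT at 0 h) at a
#' stricter fold-change threshold, annotates each with its human ortholog
#' and records the direction sign for later cross-species concordance
#' checks. Genes without an ortholog are retained but flagged out of the
#' signature.
#'
#' @param t0_contrast DE tibble for the KO vs WT baseline contrast.
#' @param orthologs tibble with columns `mouse_id`, `human_id`
#'   (unique mouse keys; `human_id` may be NA).
#' @param lfc_thresh absolute log2 fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return a tibble with columns `gene_id`, `human_id`, `direction`
#'   (+1 / -1) and `in_signature`.
#' @export
baseline_signature <- function(t0_contrast, orthologs, lfc_thresh = 2,
                               alpha = 0.05) {
  if (!all(c("mouse_id", "human_id") %in% names(orthologs))) {
    abort("`orthologs` needs columns mouse_id and human_id.")
  }
  if (anyDuplicated(orthologs$mouse_id)) {
    abort("duplicate mouse ids in the ortholog map.")
  }
  t0_contrast |>
    filter(!is.na(.data$padj), .data$padj < alpha,
           abs(.data$log2fc) >= lfc_thresh) |>
    transmute(gene_id = .data$gene_id,
              direction = sign(.data$log2fc)) |>
    left_join(orthologs, by = c(gene_id = "mouse_id")) |>
    mutate(in_signature = !is.na(.data$human_id)) |>
    select("gene_id", "human_id", "direction", "in_signature")
}
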