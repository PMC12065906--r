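test_that("pathway flags follow the catalog, with SMAD4 split out", {
  variants <- tibble::tibble(
    sample_id = c("p1", "p2", "p2"),
    gene = c("APC", "SMAD4", "TGFBR2"),
    alteration = "missense"
  )
  flags <- assign_pathway_status(variants, samples = c("p1", "p2", "p3"))
  p1 <- flags[flags$sample_id == "p1", ]
  expect_true(p1$WNT)
  expect_false(any(unlist(p1[c("TP53", "PI3K", "RTK_RAS", "SMAD4",
                               "TGFB_other", "BMP")])))
  p2 <- flags[flags$sample_id == "p2", ]
  expect_true(p2$SMAD4)
  expect_true(p2$TGFB_other)
  ## no alterations at all -> all flags false
  p3 <- flags[flags$sample_id == "p3", ]
  expect_false(any(unlist(p3[-1])))

  expect_error(assign_pathway_status(variants, catalog = list(WNT = "APC")),
               "pathway")
})

test_that("cohort selection applies the exclusion rules", {
  flags <- tibble::tibble(
    sample_id = c("mut_ok", "mut_smad2", "ctrl", "no_wnt", "ctrl2", "mut2"),
    WNT = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    TP53 = FALSE, PI3K = FALSE, RTK_RAS = FALSE,
    SMAD4 = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    TGFB_other = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    BMP = FALSE
  )
  sel <- select_cohort(flags)
  expect_setequal(sel$sample_id[sel$smad4_status == "mutant"],
                  c("mut_ok", "mut2"))
  expect_setequal(sel$sample_id[sel$smad4_status == "control"],
                  c("ctrl", "ctrl2"))
  ## SMAD4 + another TGF-beta variant and WNT-negative samples are dropped
  expect_false("mut_smad2" %in% sel$sample_id)
  expect_false("no_wnt" %in% sel$sample_id)

  empty <- flags[flags$sample_id == "ctrl", ]
  expect_error(select_cohort(empty), "empty")
})

test_that("volcano statistics match exact enumeration and scale shifts", {
  expr <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    g_exact = c(1, 2, 3, 4, 5, 6),
    g_same = rep(c(7, 8, 9), 2),
    g_big = c(400, 800, 1200, 100, 200, 300)
  )
  sel <- tibble::tibble(sample_id = paste0("s", 1:6),
                        smad4_status = rep(c("mutant", "control"), each = 3))
  res <- volcano_mut_vs_wt(expr, sel, c("g_exact", "g_same", "g_big"))
  ## {1,2,3} vs {4,5,6}: 2/choose(6,3) orderings as extreme, exact p = 0.1
  expect_equal(res$pvalue[res$gene == "g_exact"], 0.1)
  expect_equal(res$pvalue[res$gene == "g_same"], 1)
  expect_equal(res$median_log2fc[res$gene == "g_same"], 0)
  ## mutant medians 4x control: log2fc ~ +2 up to the +1 pseudo-count
  expect_equal(res$median_log2fc[res$gene == "g_big"], 2, tolerance = 0.02)

  expect_warning(volcano_mut_vs_wt(expr, sel, c("g_exact", "missing")),
                 "missing")
})

test_that("subgroup assembly crosses SMAD4 status with context variants", {
  n <- 24
  flags <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    WNT = TRUE, TP53 = rep(c(FALSE, TRUE), 12),
    PI3K = FALSE, RTK_RAS = rep(c(FALSE, TRUE), each = 12),
    SMAD4 = rep(c(FALSE, TRUE), each = 12) & TRUE,
    TGFB_other = FALSE, BMP = FALSE
  )
  sel <- select_cohort(flags)
  sg <- assemble_subgroups(flags, sel, "TP53")
  ## WT sample with the TP53 variant -> G2; mutant without -> G3
  expect_equal(sg$group[sg$sample_id == "s02"], "G2")
  expect_equal(sg$group[sg$sample_id == "s13"], "G3")
  expect_equal(nrow(sg), nrow(sel))            # partition
  expect_equal(sort(unique(sg$group)), paste0("G", 1:4))

  ## a context with <3 samples in one cell errors
  flags$PI3K <- c(TRUE, rep(FALSE, n - 1))
  expect_error(assemble_subgroups(flags, sel, "PI3K"), "fewer than 3")
})

test_that("Kruskal-Wallis worked example matches the brute-force rank formula", {
  d <- data.frame(v = 1:12, g = rep(paste0("G", 1:4), each = 3))
  out <- kw_dunn(d, "v", "g")
  ## independent oracle: H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1) on ranks
  r <- rank(d$v)
  Rj <- tapply(r, d$g, sum)
  H <- 12 / (12 * 13) * sum(Rj^2 / 3) - 3 * 13
  expect_equal(out$kw$statistic, H, tolerance = 1e-9)
  expect_equal(round(H, 3), 10.385)
  expect_equal(out$kw$pvalue, pchisq(H, 3, lower.tail = FALSE), tolerance = 1e-9)
  ## six pairwise Dunn tests, Holm-monotone
  expect_equal(nrow(out$pairs), 6L)
  expect_true(all(out$pairs$p_holm >= out$pairs$pvalue))

  ## constant data hit the p = 1 convention
  flat <- data.frame(v = rep(5, 12), g = d$g)
  expect_equal(kw_dunn(flat, "v", "g")$kw$pvalue, 1)
})

test_that("KW p-values are calibrated under the null", {
  pvals <- withr::with_seed(99, vapply(1:300, function(i) {
    d <- data.frame(v = rnorm(24), g = rep(paste0("G", 1:4), each = 6))
    kw_dunn(d, "v", "g")$kw$pvalue
  }, numeric(1)))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("three-criterion decision logic and failure bookkeeping", {
  base <- tibble::tibble(
    gene = "g", context_pathway = "TP53", kw_p = 0.001, kw_padj = 0.01,
    p_G1G2 = 0.5, p_G1G3 = 0.01, p_G1G4 = 0.02, p_G2G3 = 0.01,
    p_G2G4 = 0.03, p_G3G4 = 0.6
  )
  hd <- tibble::tibble(gene = "g", human_sign = -1)
  md <- tibble::tibble(gene = "g", mouse_sign = -1)

  ok <- smad4_dependence_decision(base, hd, md)
  expect_true(ok$smad4_dependent)
  expect_equal(ok$failed_criterion, "none")

  within_sig <- dplyr::mutate(base, p_G1G2 = 0.01)
  r2 <- smad4_dependence_decision(within_sig, hd, md)
  expect_false(r2$smad4_dependent)
  expect_equal(r2$failed_criterion, "2")

  flipped <- smad4_dependence_decision(base, dplyr::mutate(hd, human_sign = 1), md)
  expect_equal(flipped$failed_criterion, "3")

  cross_ns <- dplyr::mutate(base, p_G1G3 = 0.2)
  expect_equal(smad4_dependence_decision(cross_ns, hd, md)$failed_criterion, "1")

  expect_error(smad4_dependence_decision(base[, -5], hd, md), "p_G1G2")

  ## all-context mode: failing in one context fails the gene; any-context passes
  two_ctx <- dplyr::bind_rows(base, dplyr::mutate(base, context_pathway = "PI3K",
                                                  p_G1G3 = 0.9))
  expect_equal(smad4_dependence_decision(two_ctx, hd, md)$failed_criterion, "1")
  expect_true(smad4_dependence_decision(two_ctx, hd, md,
                                        mode = "any")$smad4_dependent)
})
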