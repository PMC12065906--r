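## Shared in-code fixtures. Everything is generated deterministically so no
## data files ship with the tests.

## minimal counts tibble: explicit values, 2 groups x 3 replicates
tiny_counts <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    s1 = c(100L, 5L, 0L), s2 = c(110L, 5L, 0L), s3 = c(90L, 5L, 0L),
    s4 = c(100L, 0L, 0L), s5 = c(95L, 0L, 0L), s6 = c(105L, 0L, 0L)
  )
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:6),
    group = rep(c("A", "B"), each = 3)
  )
}

## build a one-row-per-gene DE table for classifier tests
de_tbl <- function(genes, log2fc = 0, padj = 1) {
  tibble::tibble(
    gene_id = genes,
    base_mean = 100,
    log2fc = rep_len(log2fc, length(genes)),
    se_log2fc = 0.1,
    stat = 0,
    pvalue = rep_len(padj, length(genes)),
    padj = rep_len(padj, length(genes)),
    contrast = "x",
    note = ""
  )
}

## a full set of null contrasts for `genes`, to be overridden per test
null_contrasts <- function(genes) {
  stats::setNames(
    lapply(required_contrasts(), function(nm) de_tbl(genes)),
    required_contrasts()
  )
}

## set one gene's (log2fc, padj) inside a contrast table
set_gene <- function(tbl, gene, log2fc, padj) {
  i <- match(gene, tbl$gene_id)
  tbl$log2fc[i] <- log2fc
  tbl$padj[i] <- padj
  tbl$pvalue[i] <- padj
  tbl
}

## deterministic NB counts for a given per-sample mean matrix
nb_counts_from_means <- function(mu, dispersion, seed) {
  withr::with_seed(seed, {
    m <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      nrow = nrow(mu)
    )
    colnames(m) <- colnames(mu)
    m
  })
}
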