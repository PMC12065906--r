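## Internal helpers shared across modules.

#' Derive a stage-specific seed from a master seed
#'
#' Each stochastic stage of the pipeline draws its own sub-seed so that
#' toggling one stage on or off does not perturb the random stream of the
#' others. Kept below 2^31 - 1 so the result is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param stage integer stage index (>= 1).
#' @return an integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483647L)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

## Counts tibble accessors: first column is the gene id, remaining columns
## are samples. Used throughout the DE stack.
counts_genes <- function(counts) counts[[1L]]

counts_matrix <- function(counts) {
  m <- as.matrix(counts[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1L]])
  m
}

check_counts <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2L) {
    abort("`counts` must be a data frame with a gene-id column plus sample columns.")
  }
  m <- counts_matrix(counts)
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    abort("counts must be non-negative integers without missing values.")
  }
  dup <- duplicated(counts[[1L]])
  if (any(dup)) {
    abort(paste0("duplicated gene id: ", counts[[1L]][which(dup)[1L]]))
  }
  invisible(counts)
}

check_samples_align <- function(counts, samples) {
  ids <- colnames(counts)[-1L]
  if (!"sample_id" %in% names(samples)) {
    abort("`samples` must contain a `sample_id` column.")
  }
  if (!setequal(ids, samples$sample_id) || anyDuplicated(samples$sample_id)) {
    abort("sample metadata rows must align 1:1 with the sample columns of `counts`.")
  }
  samples[match(ids, samples$sample_id), , drop = FALSE]
}

## round a probability-like value into [0, 1]
clamp01 <- function(x) pmin(pmax(x, 0), 1)
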