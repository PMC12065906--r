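#' Read a count matrix from TSV
#'
#' Expects a tab-separated file with the gene id in the first column and
#' one integer column per sample (header row of sample ids). Duplicated
#' gene ids and non-integer counts are rejected with named errors.
#'
#' @param path file path.
#' @return a counts tibble.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(counts) < 2L) abort("count file needs a gene column plus samples.")
  names(counts)[1L] <- "gene_id"
  dup <- duplicated(counts$gene_id)
  if (any(dup)) {
    abort(paste0("duplicate gene id `", counts$gene_id[which(dup)[1L]],
                 "` at line ", which(dup)[1L] + 1L))
  }
  m <- as.matrix(counts[, -1L])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m))) {
    bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
    abort(paste0("non-integer or negative count at line ", bad[1L, 1L] + 1L))
  }
  counts |> mutate(across(-1L, as.integer))
}

#' Write a count matrix to TSV
#'
#' @param counts counts tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with at least a `sample_id` column.
#' @return a tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(meta)) abort("metadata needs a `sample_id` column.")
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicate sample id `",
                 meta$sample_id[duplicated(meta$sample_id)][1L], "`"))
  }
  meta
}

#' Read gene modules from a GMT file
#'
#' Standard GMT: one module per line, tab-separated
#' `module_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return a named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("the fgsea package is required to read GMT files.")
  }
  fgsea::gmtPathways(path)
}

#' Write gene modules to a GMT file
#'
#' @param modules named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of module descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(modules))
  lines <- vapply(seq_along(modules), function(i) {
    paste(c(names(modules)[i], descriptions[i], modules[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort (expression, variants, survival) from TSV files
#'
#' @param expr_path samples x genes expression TSV (`sample_id` first).
#' @param variants_path long-format alteration TSV
#'   (`sample_id`, `gene`, `alteration`).
#' @param survival_path survival TSV (`sample_id`, `time`, `event`, ...).
#' @return a list with tibbles `expression`, `variants`, `survival`.
#' @export
read_cohort <- function(expr_path, variants_path, survival_path) {
  expression <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  variants <- readr::read_tsv(variants_path, show_col_types = FALSE, progress = FALSE)
  surv <- readr::read_tsv(survival_path, show_col_types = FALSE, progress = FALSE)
  for (nm in list(c("expression", "sample_id"), c("variants", "sample_id"),
                  c("variants", "gene"), c("survival", "time"),
                  c("survival", "event"))) {
    tab <- switch(nm[1L], expression = expression, variants = variants,
                  survival = surv)
    if (!nm[2L] %in% names(tab)) {
      abort(paste0(nm[1L], " table is missing column `", nm[2L], "`"))
    }
  }
  if (any(surv$time < 0)) abort("negative survival times.")
  list(expression = expression, variants = variants, survival = surv)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value` (comments with `#` allowed). Values are
#' coerced to numeric or logical where possible.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(paste0("malformed config line: `", lines[bad][1L], "`"))
  vals <- lapply(kv, function(p) {
    v <- p[2L]
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  setNames(vals, vapply(kv, `[[`, character(1), 1L))
}
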