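# RPKM expression-matrix summarization: baseline tissue, expression
# threshold, expressed-gene set, per-gene peak tissue.

#' Read an RPKM matrix from TSV
#'
#' Expects a header row; the first column holds gene ids, the remaining
#' columns one tissue each. Values must be non-negative and gene ids
#' unique.
#'
#' @param path TSV path.
#' @return A tibble with `gene_id` plus one numeric column per tissue.
#' @export
read_rpkm <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  names(m)[1] <- "gene_id"
  validate_rpkm(m)
}

validate_rpkm <- function(m) {
  if (!"gene_id" %in% names(m)) abort("RPKM table needs a `gene_id` column")
  tissues <- setdiff(names(m), "gene_id")
  if (length(tissues) == 0L) abort("RPKM table has no tissue columns")
  if (anyDuplicated(m$gene_id)) abort("duplicate gene ids in RPKM table")
  if (nrow(m) > 0L) {
    vals <- as.matrix(m[tissues])
    if (!is.numeric(vals) || anyNA(vals) || any(vals < 0)) {
      abort("RPKM values must be non-negative numbers")
    }
  }
  m
}

rpkm_tissues <- function(m) setdiff(names(m), "gene_id")

#' Baseline tissue of an expression matrix
#'
#' The baseline is the tissue with the lowest mean expression across genes
#' (ties go to the first tissue in column order, with a message).
#'
#' @param m RPKM tibble ([read_rpkm()]).
#' @return A tibble in column order: `tissue`, `mean_rpkm`, `baseline`.
#' @export
baseline_tissue <- function(m) {
  validate_rpkm(m)
  tissues <- rpkm_tissues(m)
  if (nrow(m) < 1L || length(tissues) < 2L) {
    abort("baseline requires at least one gene and two tissues")
  }
  means <- vapply(tissues, function(t) mean(m[[t]]), numeric(1))
  base <- which.min(means)   # first minimum in column order
  if (sum(means == means[base]) > 1L) {
    inform(sprintf("baseline tie between tissues; keeping first in column order (%s)",
                   tissues[base]))
  }
  tibble(tissue = tissues, mean_rpkm = unname(means),
         baseline = seq_along(tissues) == base)
}

#' Fraction of genes below a threshold in one tissue
#'
#' Uses a strict `<` comparison.
#'
#' @param m RPKM tibble.
#' @param tissue Tissue column name.
#' @param threshold RPKM threshold.
#' @return A fraction in `[0, 1]`.
#' @export
fraction_below <- function(m, tissue, threshold) {
  if (!tissue %in% rpkm_tissues(m)) abort(sprintf("unknown tissue: %s", tissue))
  mean(m[[tissue]] < threshold)
}

#' Expressed-gene set
#'
#' Genes with at least `threshold` RPKM in at least one tissue, sorted
#' ascending by expression in `sort_tissue` (default: the tissue with the
#' highest mean, the convention for display); ties break by gene id.
#'
#' @param m RPKM tibble.
#' @param threshold RPKM threshold (default 50).
#' @param sort_tissue Tissue used for the ascending sort.
#' @return The filtered, sorted RPKM tibble.
#' @export
expressed_set <- function(m, threshold = 50, sort_tissue = NULL) {
  validate_rpkm(m)
  tissues <- rpkm_tissues(m)
  if (is.null(sort_tissue)) {
    means <- vapply(tissues, function(t) mean(m[[t]]), numeric(1))
    sort_tissue <- tissues[which.max(means)]
  }
  if (!sort_tissue %in% tissues) abort(sprintf("unknown tissue: %s", sort_tissue))
  keep <- apply(as.matrix(m[tissues]), 1L, max) >= threshold
  m[keep, , drop = FALSE] |>
    arrange(.data[[sort_tissue]], .data$gene_id)
}

#' Per-gene peak tissue
#'
#' @param m RPKM tibble.
#' @return A tibble: `gene_id`, `peak_tissue` (first tissue on ties, with
#'   `tie` flagged), `peak_rpkm`, `no_expression` (all-zero gene).
#' @export
peak_tissue <- function(m) {
  validate_rpkm(m)
  tissues <- rpkm_tissues(m)
  vals <- as.matrix(m[tissues])
  idx <- apply(vals, 1L, which.max)
  mx <- vals[cbind(seq_len(nrow(vals)), idx)]
  tibble(
    gene_id = m$gene_id,
    peak_tissue = tissues[idx],
    peak_rpkm = mx,
    tie = rowSums(vals == mx) > 1L,
    no_expression = mx == 0
  )
}

#' Reproduce the expression-threshold choice over a grid
#'
#' Reports, for each candidate threshold, the fraction of genes below it in
#' the baseline tissue, and selects the smallest grid value for which that
#' fraction exceeds `frac` — making the conventional "more than 95% of
#' genes sit below 50 RPKM in the baseline tissue" choice a computation.
#'
#' @param m RPKM tibble.
#' @param tissue Baseline tissue (default: computed by
#'   [baseline_tissue()]).
#' @param grid Candidate thresholds.
#' @param frac Required fraction below threshold (default 0.95, strict).
#' @return A list: `threshold` (chosen value or `NA`), `table` (tibble of
#'   `threshold`, `fraction`, `chosen`).
#' @export
expression_threshold_grid <- function(m, tissue = NULL, grid = c(10, 20, 50, 100),
                                      frac = 0.95) {
  if (is.null(tissue)) {
    bt <- baseline_tissue(m)
    tissue <- bt$tissue[bt$baseline]
  }
  fracs <- vapply(grid, function(v) fraction_below(m, tissue, v), numeric(1))
  ok <- which(fracs > frac)
  chosen <- if (length(ok) > 0L) grid[min(ok)] else NA_real_
  list(
    threshold = chosen,
    table = tibble(threshold = grid, fraction = fracs,
                   chosen = !is.na(chosen) & grid == chosen)
  )
}
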