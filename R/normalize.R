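#' Normalize the expression layer of a study
#'
#' Five methods are supported, all leaving the raw layer untouched and
#' storing the result in the normalized layer:
#'
#' * `logNormalize`: per cell, `ln(1 + count / cell_total * 1e4)` — the
#'   dominant single-cell convention (scale factor 1e4).
#' * `CPM`: counts per million, `count / cell_total * 1e6`.
#' * `TPM`: transcripts per million; counts are first divided by gene length
#'   in kb, then each cell is scaled to sum to 1e6. Requires a length for
#'   every gene.
#' * `DESeq`: counts divided by median-of-ratios size factors
#'   (see [deseq_size_factors()]).
#' * `limma`: quantile normalization of `log2(CPM + 0.5)` across cells
#'   (each cell's order statistics replaced by their cross-cell mean).
#'
#' Any cell with a zero total count is rejected: its size factor is
#' undefined under every method.
#'
#' @param study a `qtl_study` with a raw layer.
#' @param method normalization method name.
#' @param gene_lengths named numeric vector of gene lengths in bp, or a
#'   gene-annotation tibble with `gene_id` and `length_bp` columns
#'   (TPM only).
#' @return the study with `expression_normalized` set and the step logged.
#' @examples
#' sim <- simulate_qtl_data(sim_config(n_cells = 50, n_genes = 10, n_snps = 4,
#'                                     seed = 1))
#' study <- create_study(sim$expression, sim$genotype) |>
#'   normalize_expression("CPM")
#' colSums(study$expression_normalized)[1:3]  # each 1e6
#' @export
normalize_expression <- function(study,
                                 method = c("logNormalize", "CPM", "TPM",
                                            "DESeq", "limma"),
                                 gene_lengths = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(study, "qtl_study"))
  counts <- study$expression_raw
  if (is.null(counts)) stop("study has no raw expression layer to normalize", call. = FALSE)

  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("cell '%s' has zero total counts; size factor undefined",
                 colnames(counts)[which(totals == 0)[1]]), call. = FALSE)
  }

  norm <- switch(method,
    logNormalize = log1p(sweep(counts, 2, totals, "/") * 1e4),
    CPM = cpm_matrix(counts),
    TPM = {
      len <- resolve_gene_lengths(gene_lengths, rownames(counts))
      rpk <- counts / (len / 1000)
      sweep(rpk, 2, colSums(rpk), "/") * 1e6
    },
    DESeq = sweep(counts, 2, deseq_size_factors(counts), "/"),
    limma = limma_quantile(counts)
  )
  study$expression_normalized <- norm
  log_step(study, "normalize_expression", list(method = method))
}

cpm_matrix <- function(counts) {
  sweep(counts, 2, colSums(counts), "/") * 1e6
}

resolve_gene_lengths <- function(gene_lengths, genes) {
  if (is.null(gene_lengths)) {
    stop("TPM normalization requires gene lengths for every gene", call. = FALSE)
  }
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- stats::setNames(gene_lengths$length_bp, gene_lengths$gene_id)
  }
  missing <- setdiff(genes, names(gene_lengths))
  if (length(missing) > 0L) {
    stop(sprintf("no gene length for %d gene(s), e.g. '%s'",
                 length(missing), missing[1]), call. = FALSE)
  }
  len <- as.numeric(gene_lengths[genes])
  if (any(len < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  len
}

#' Median-of-ratios size factors
#'
#' For each cell j, the size factor is the median over genes of
#' `counts[g, j] / geomean_g`, where `geomean_g` is the gene's geometric
#' mean across cells; genes whose geometric mean is zero are excluded.
#' When no gene is expressed in every cell (so all geometric means are
#' zero), the geometric mean is computed over positive counts only and the
#' median is taken over genes with a positive count in that cell, with a
#' warning.
#'
#' @param counts genes x cells count matrix.
#' @return positive numeric vector of per-cell size factors, named by cell.
#' @export
deseq_size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))          # -Inf whenever a zero is present
  usable <- is.finite(loggeo)
  if (any(usable)) {
    lr <- log(counts[usable, , drop = FALSE]) - loggeo[usable]
    sf <- exp(apply(lr, 2, stats::median))
  } else {
    warning("no gene expressed in all cells; using positive counts only for size factors",
            call. = FALSE)
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    loggeo <- rowMeans(logc, na.rm = TRUE)
    ok <- is.finite(loggeo)
    lr <- logc[ok, , drop = FALSE] - loggeo[ok]
    sf <- exp(apply(lr, 2, stats::median, na.rm = TRUE))
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("size factor undefined for some cell", call. = FALSE)
  }
  stats::setNames(sf, colnames(counts))
}

#' Quantile normalization of log2(CPM + 0.5)
#'
#' Each cell's sorted values are replaced by the cross-cell mean of the order
#' statistics (ties averaged), making all cell-wise distributions identical.
#' With a single cell the matrix is returned unchanged with a warning.
#'
#' @param counts genes x cells count matrix.
#' @return normalized matrix on the log2 scale.
#' @export
limma_quantile <- function(counts) {
  logcpm <- log2(cpm_matrix(counts) + 0.5)
  if (ncol(logcpm) < 2L) {
    warning("quantile normalization needs >= 2 cells; returning log2(CPM + 0.5) unchanged",
            call. = FALSE)
    return(logcpm)
  }
  quantile_core(logcpm)
}

# Cross-cell quantile normalization (mean of order statistics, ties averaged);
# delegated to limma.
quantile_core <- function(mat) {
  requireNamespace("limma", quietly = TRUE) ||
    stop("limma is required for quantile normalization", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}
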