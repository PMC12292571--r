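#' Filtering parameters
#'
#' @param expression_min expression value a cell must exceed (strictly) for a
#'   gene to count as expressed there. Interpreted on the active layer
#'   (normalized if present, else raw). Default 0.
#' @param expression_cells_percent minimum percentage of cells, in (0, 100],
#'   in which a gene must be expressed to be retained. Default 10.
#' @param snp_cells_percent minimum percentage of non-missing cells, in
#'   (0, 100], in which each genotype class must occur for a SNP to be
#'   retained. Default 10.
#' @return a `filter_params` list.
#' @export
filter_params <- function(expression_min = 0,
                          expression_cells_percent = 10,
                          snp_cells_percent = 10) {
  stopifnot(expression_min >= 0,
            expression_cells_percent > 0, expression_cells_percent <= 100,
            snp_cells_percent > 0, snp_cells_percent <= 100)
  structure(list(expression_min = expression_min,
                 expression_cells_percent = expression_cells_percent,
                 snp_cells_percent = snp_cells_percent),
            class = "filter_params")
}

#' Gene-level expression filter
#'
#' A gene is retained when its expression exceeds `expression_min`
#' (strictly) in at least `expression_cells_percent` percent of cells.
#' Computed on the normalized layer when present, else on raw counts.
#'
#' @param study a `qtl_study`.
#' @param params a [filter_params()] list.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(study, params = filter_params()) {
  mat <- active_layer(study)
  frac <- rowMeans(mat > params$expression_min) * 100
  keep <- rownames(mat)[frac >= params$expression_cells_percent]
  if (length(keep) == 0L) warning("no genes survive the expression filter", call. = FALSE)
  keep
}

#' SNP-level genotype-class filter
#'
#' A SNP is retained when every genotype class required by the encoding mode
#' (ref hom / het / alt hom for `three_class`; absent / present for
#' `binary`) occurs in at least `snp_cells_percent` percent of the cells
#' with a non-missing genotype at that SNP. SNPs genotyped in no cell are
#' dropped with a warning.
#'
#' @inheritParams filter_genes
#' @return character vector of retained SNP ids.
#' @export
filter_snps <- function(study, params = filter_params()) {
  g <- study$genotype
  required <- setdiff(genotype_codes_allowed(study$encoding_mode), 0L)
  keep <- vapply(seq_len(nrow(g)), function(i) {
    codes <- g[i, ]
    codes <- codes[codes != 0L]
    if (length(codes) == 0L) return(NA)   # all-missing
    all(vapply(required, function(k) {
      sum(codes == k) / length(codes) * 100 >= params$snp_cells_percent
    }, logical(1)))
  }, logical(1))
  if (anyNA(keep)) {
    warning(sprintf("%d SNP(s) with all-missing genotypes dropped", sum(is.na(keep))),
            call. = FALSE)
    keep[is.na(keep)] <- FALSE
  }
  rownames(g)[keep]
}

#' Apply gene and SNP quality-control filters
#'
#' Runs [filter_genes()] and [filter_snps()] and records the retained id
#' lists on the study. Matrices are kept whole; downstream stages honour
#' the retained lists. Idempotent for fixed parameters.
#'
#' @inheritParams filter_genes
#' @return the study with `retained_genes` / `retained_snps` set and the
#'   step logged (including which layer the gene filter used).
#' @examples
#' sim <- simulate_qtl_data(sim_config(n_cells = 100, n_genes = 20, n_snps = 10,
#'                                     seed = 1))
#' study <- create_study(sim$expression, sim$genotype) |>
#'   filter_gene_snp(filter_params(snp_cells_percent = 10))
#' length(study$retained_snps)
#' @export
filter_gene_snp <- function(study, params = filter_params()) {
  stopifnot(inherits(study, "qtl_study"))
  study$retained_genes <- filter_genes(study, params)
  study$retained_snps <- filter_snps(study, params)
  log_step(study, "filter_gene_snp",
           list(expression_min = params$expression_min,
                expression_cells_percent = params$expression_cells_percent,
                snp_cells_percent = params$snp_cells_percent,
                layer = active_layer_tag(study),
                genes_retained = length(study$retained_genes),
                snps_retained = length(study$retained_snps)))
}
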