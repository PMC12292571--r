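#' eQTL-calling parameters
#'
#' @param upstream_bp,downstream_bp cis window sizes in bp around the gene
#'   body (default 100 kb each side).
#' @param model `"zinb"` (default), `"linear"`, or `"poisson"`. ZINB and
#'   Poisson run on raw counts; the linear model runs on the normalized
#'   layer.
#' @param p_adjust_method one of `"bonferroni"`, `"holm"`, `"hochberg"`,
#'   `"hommel"`, `"BH"`.
#' @param p_adjust_threshold adjusted-p cutoff for significance (default
#'   0.05).
#' @param logfc_threshold minimum absolute effect size (|log2 fold change|
#'   for ZINB, |coefficient| otherwise; default 0.1).
#' @param gene_subset optional gene ids to restrict testing to.
#' @param min_cells_per_class minimum cells per genotype class for the ZINB
#'   group test (default 10).
#' @return a `call_params` list.
#' @export
call_params <- function(upstream_bp = 100000, downstream_bp = 100000,
                        model = c("zinb", "linear", "poisson"),
                        p_adjust_method = c("BH", "bonferroni", "holm",
                                            "hochberg", "hommel"),
                        p_adjust_threshold = 0.05,
                        logfc_threshold = 0.1,
                        gene_subset = NULL,
                        min_cells_per_class = 10L) {
  model <- match.arg(model)
  p_adjust_method <- match.arg(p_adjust_method)
  stopifnot(upstream_bp >= 0, downstream_bp >= 0,
            p_adjust_threshold > 0, logfc_threshold >= 0)
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 model = model, p_adjust_method = p_adjust_method,
                 p_adjust_threshold = p_adjust_threshold,
                 logfc_threshold = logfc_threshold,
                 gene_subset = gene_subset,
                 min_cells_per_class = min_cells_per_class),
            class = "call_params")
}

#' Call cis-eQTLs per cell group
#'
#' For every cell group (from the study metadata, or all cells when no
#' metadata was given), tests each candidate cis SNP-gene pair for
#' genotype-expression association under the chosen model, adjusts p-values
#' across all tests within the group, and flags pairs with
#' `adjusted_p < p_adjust_threshold` and `|effect| >= logfc_threshold` as
#' significant. The full unthresholded table is kept on the study;
#' untestable pairs are recorded separately with a reason code.
#'
#' Model/layer contract: `zinb` and `poisson` require raw counts;
#' `linear` requires a normalized layer.
#'
#' @param study a `qtl_study`, filtered via [filter_gene_snp()] (unfiltered
#'   studies are tested over all ids, with a message).
#' @param gene_annotation,snp_annotation annotation tibbles (see
#'   [read_gene_annotation()], [read_snp_annotation()]); ids without
#'   annotation are skipped with a warning.
#' @param params a [call_params()] list.
#' @return the study with `$results` set (tibble, one row per tested pair x
#'   group) and `$skipped` (tibble of untestable pairs with reasons).
#' @examples
#' \donttest{
#' sim <- simulate_qtl_data(sim_config(n_cells = 300, n_genes = 10, n_snps = 6,
#'                                     n_true_eqtls = 2, seed = 7))
#' study <- create_study(sim$expression, sim$genotype) |>
#'   filter_gene_snp() |>
#'   call_qtl(sim$gene_annotation, sim$snp_annotation,
#'            call_params(model = "zinb"))
#' eqtl_results(study)
#' }
#' @export
call_qtl <- function(study, gene_annotation, snp_annotation,
                     params = call_params()) {
  stopifnot(inherits(study, "qtl_study"))
  model <- params$model
  if (model %in% c("zinb", "poisson") && is.null(study$expression_raw)) {
    stop(sprintf("model '%s' requires raw counts, but the study has no raw layer; ",
                 model),
         "load counts (not normalized values) or switch to the linear model",
         call. = FALSE)
  }
  if (model == "linear" && is.null(study$expression_normalized)) {
    stop("the linear model runs on the normalized layer; call normalize_expression() first",
         call. = FALSE)
  }

  genes <- study$retained_genes
  snps <- study$retained_snps
  if (is.null(genes) || is.null(snps)) {
    message("call_qtl: study is unfiltered; testing all genes and SNPs")
    genes <- gene_ids(study)
    snps <- rownames(study$genotype)
  }
  if (!is.null(params$gene_subset)) genes <- intersect(genes, params$gene_subset)

  miss_g <- setdiff(genes, gene_annotation$gene_id)
  if (length(miss_g) > 0L) {
    warning(sprintf("%d retained gene(s) lack annotation and are skipped (e.g. '%s')",
                    length(miss_g), miss_g[1]), call. = FALSE)
  }
  miss_s <- setdiff(snps, snp_annotation$snp_id)
  if (length(miss_s) > 0L) {
    warning(sprintf("%d retained SNP(s) lack annotation and are skipped (e.g. '%s')",
                    length(miss_s), miss_s[1]), call. = FALSE)
  }

  pairs <- pair_cis(dplyr::filter(gene_annotation, .data$gene_id %in% genes),
                    dplyr::filter(snp_annotation, .data$snp_id %in% snps),
                    params$upstream_bp, params$downstream_bp)
  groups <- study_groups(study)
  dosage <- recode_to_dosage(study)
  y_layer <- if (model == "linear") study$expression_normalized else study$expression_raw

  rows <- list(); skipped <- list()
  for (grp in groups) {
    cells <- group_barcodes(study, grp)
    grp_rows <- purrr::pmap(pairs, function(snp_id, gene_id, chrom, snp_pos,
                                            gene_start, gene_end, ...) {
      d <- dosage[snp_id, cells]
      y <- y_layer[gene_id, cells]
      fit <- switch(model,
        linear = fit_linear(y, d),
        poisson = fit_poisson(y, d),
        zinb = zinb_group_test(y, d, min_cells = params$min_cells_per_class,
                               seed = pair_seed(snp_id, gene_id))
      )
      base <- tibble::tibble(
        snp_id = snp_id, gene_id = gene_id, group_label = grp, model = model,
        snp_chrom = chrom, snp_pos = snp_pos,
        gene_start = gene_start, gene_end = gene_end,
        n_ref = sum(d == 0, na.rm = TRUE),
        n_het = sum(d == 1, na.rm = TRUE),
        n_alt = sum(d == 2, na.rm = TRUE)
      )
      if (is_skipped(fit)) {
        return(dplyr::mutate(base, reason = attr(fit, "reason"), tested = FALSE))
      }
      out <- if (model == "zinb") {
        dplyr::mutate(base, fold_change = fit$log2fc, effect = abs(fit$log2fc),
                      p_value = fit$p)
      } else {
        dplyr::mutate(base, coefficient = fit$beta, abs_effect = abs(fit$beta),
                      effect = abs(fit$beta), p_value = fit$p)
      }
      dplyr::mutate(out, tested = TRUE)
    })
    rows <- c(rows, grp_rows)
  }
  all_rows <- dplyr::bind_rows(rows)
  if (nrow(all_rows) == 0L) {
    warning("no testable cis pairs", call. = FALSE)
    study$results <- empty_results(model)
    study$skipped <- tibble::tibble()
    return(log_step(study, "call_qtl", call_log_params(params, 0L, 0L)))
  }
  tested <- dplyr::filter(all_rows, .data$tested)
  skipped <- dplyr::filter(all_rows, !.data$tested)

  # p-adjustment within each cell group across all of its tests
  tested <- tested |>
    dplyr::group_by(.data$group_label) |>
    dplyr::mutate(adjusted_p = adjust_pvalues(.data$p_value,
                                              params$p_adjust_method)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$adjusted_p < params$p_adjust_threshold &
                    .data$effect >= params$logfc_threshold) |>
    dplyr::select(-"tested") |>
    dplyr::arrange(.data$group_label, .data$gene_id, .data$snp_pos, .data$snp_id)

  study$results <- tested
  study$skipped <- if (nrow(skipped) > 0) {
    dplyr::select(skipped, "snp_id", "gene_id", "group_label", "reason")
  } else tibble::tibble()
  log_step(study, "call_qtl",
           call_log_params(params, nrow(tested), sum(tested$significant)))
}

call_log_params <- function(params, n_tested, n_significant) {
  list(model = params$model,
       upstream_bp = params$upstream_bp, downstream_bp = params$downstream_bp,
       p_adjust_method = params$p_adjust_method,
       p_adjust_threshold = params$p_adjust_threshold,
       logfc_threshold = params$logfc_threshold,
       n_tested = n_tested, n_significant = n_significant)
}

empty_results <- function(model) {
  cols <- result_columns(model)
  out <- tibble::as_tibble(stats::setNames(rep(list(character(0)), length(cols)), cols))
  attr(out, "model") <- model
  out
}

# Deterministic per-pair seed for optimizer restarts (reproducible across
# runs and cell orderings); kept well inside 32-bit integer range.
pair_seed <- function(snp_id, gene_id) {
  s <- paste0(snp_id, "\r", gene_id)
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2147483L + 1L
}

#' Results table of a study
#'
#' @param study a `qtl_study` after [call_qtl()].
#' @param significant_only keep only significant pairs?
#' @return tibble of per-pair, per-group association results.
#' @export
eqtl_results <- function(study, significant_only = FALSE) {
  if (is.null(study$results)) stop("no results; run call_qtl() first", call. = FALSE)
  res <- study$results
  if (significant_only) res <- dplyr::filter(res, .data$significant)
  res
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the association results of a study
#'
#' @param x a `qtl_study` after [call_qtl()].
#' @param ... unused.
#' @return the results tibble (one row per tested pair x group).
#' @method tidy qtl_study
#' @export
tidy.qtl_study <- function(x, ...) eqtl_results(x)

#' One-row summary of a study
#'
#' @param x a `qtl_study`.
#' @param ... unused.
#' @return tibble with dimensions, filtering state, and result counts.
#' @method glance qtl_study
#' @export
glance.qtl_study <- function(x, ...) {
  m <- if (!is.null(x$expression_raw)) x$expression_raw else x$expression_normalized
  tibble::tibble(
    n_genes = nrow(m),
    n_snps = nrow(x$genotype),
    n_cells = ncol(m),
    n_groups = length(study_groups(x)),
    n_genes_retained = length(x$retained_genes %||% character(0)),
    n_snps_retained = length(x$retained_snps %||% character(0)),
    n_tested = if (is.null(x$results)) 0L else nrow(x$results),
    n_significant = if (is.null(x$results)) 0L else
      sum(x$results$significant, na.rm = TRUE),
    model = if (is.null(x$results) || nrow(x$results) == 0) NA_character_ else
      x$results$model[1]
  )
}
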