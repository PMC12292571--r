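#' Robust outlier mask for expression values
#'
#' Flags cells whose expression exceeds `median + 4 * MAD`, where the MAD is
#' scaled by the usual normal-consistency constant 1.4826. With constant
#' input the MAD is zero and nothing exceeds the median, so everything is
#' kept.
#'
#' @param values numeric expression values.
#' @return logical keep-mask of the same length (`TRUE` = keep).
#' @examples
#' remove_outliers(c(1, 1, 2, 2, 3, 100))  # the 100 is flagged
#' @export
remove_outliers <- function(values) {
  stopifnot(length(values) >= 1L)
  med <- stats::median(values)
  mad_scaled <- stats::mad(values, constant = 1.4826)
  values <= med + 4 * mad_scaled
}

#' Underlying data table of a genotype-stratified plot
#'
#' One row per plotted cell: expression of `gene_id`, genotype class at
#' `snp_id` (dosage-ordered factor with display labels), and cell group.
#' Cells with missing genotype are excluded; optional MAD-based outlier
#' removal is applied within each (group, class) stratum.
#'
#' @param study a `qtl_study`.
#' @param snp_id,gene_id the pair to display.
#' @param group_names optional subset of cell groups.
#' @param remove_outlier apply [remove_outliers()] per stratum?
#' @param allele_labels optional length-3 (or 2, for binary encoding)
#'   character vector of genotype display labels ordered by dosage, e.g.
#'   `c("GG", "GT", "TT")`; defaults to ref-hom/het/alt-hom style labels.
#' @return tibble with columns `barcode, group_label, dosage, genotype,
#'   expression`.
#' @export
qtl_plot_data <- function(study, snp_id, gene_id, group_names = NULL,
                          remove_outlier = FALSE, allele_labels = NULL) {
  stopifnot(inherits(study, "qtl_study"))
  if (!snp_id %in% rownames(study$genotype)) {
    stop(sprintf("unknown SNP '%s'; available, e.g.: %s", snp_id,
                 paste(utils::head(rownames(study$genotype), 5), collapse = ", ")),
         call. = FALSE)
  }
  expr_mat <- active_layer(study)
  if (!gene_id %in% rownames(expr_mat)) {
    stop(sprintf("unknown gene '%s'; available, e.g.: %s", gene_id,
                 paste(utils::head(rownames(expr_mat), 5), collapse = ", ")),
         call. = FALSE)
  }
  groups <- study_groups(study)
  if (!is.null(group_names)) {
    bad <- setdiff(group_names, groups)
    if (length(bad) > 0L) {
      stop(sprintf("unknown group '%s'; available: %s", bad[1],
                   paste(groups, collapse = ", ")), call. = FALSE)
    }
    groups <- group_names
  }
  labels <- genotype_labels(study$encoding_mode, allele_labels)
  dosage <- recode_to_dosage(study)[snp_id, ]

  df <- purrr::map_dfr(groups, function(grp) {
    cells <- group_barcodes(study, grp)
    tibble::tibble(barcode = cells,
                   group_label = grp,
                   dosage = dosage[cells],
                   expression = expr_mat[gene_id, cells])
  }) |>
    dplyr::filter(!is.na(.data$dosage))
  if (remove_outlier) {
    df <- df |>
      dplyr::group_by(.data$group_label, .data$dosage) |>
      dplyr::filter(remove_outliers(.data$expression)) |>
      dplyr::ungroup()
  }
  df |>
    dplyr::mutate(genotype = factor(labels[as.character(.data$dosage)],
                                    levels = labels)) |>
    dplyr::select("barcode", "group_label", "dosage", "genotype", "expression") |>
    dplyr::arrange(.data$group_label, .data$dosage, .data$barcode)
}

genotype_labels <- function(encoding_mode, allele_labels = NULL) {
  if (encoding_mode == "three_class") {
    lab <- allele_labels %||% c("ref-hom", "het", "alt-hom")
    stopifnot(length(lab) == 3L)
    stats::setNames(lab, c("0", "1", "2"))
  } else {
    lab <- allele_labels %||% c("ref", "variant")
    stopifnot(length(lab) == 2L)
    stats::setNames(lab, c("0", "1"))
  }
}

#' Genotype-stratified plot of one SNP-gene association
#'
#' Draws expression against genotype class (dosage-ordered), one panel per
#' cell group composed side-by-side. Four layouts are available:
#' `QTLplot` (jittered points with class mean bars), `violin`, `boxplot`,
#' and `histplot` (per-class expression histograms). When `out_path` is
#' given, the figure is written in the format implied by the extension
#' (png/svg/pdf) and the underlying tidy table is written alongside as
#' `<out_path>.tsv`, so results can be checked on data rather than pixels.
#'
#' @inheritParams qtl_plot_data
#' @param plottype one of `"QTLplot"`, `"violin"`, `"boxplot"`, `"histplot"`.
#' @param out_path optional image path.
#' @param jitter_seed seed for the point jitter so plots are reproducible.
#' @return the ggplot/patchwork object, invisibly when writing to file. The
#'   plotted table is attached as attribute `plot_data`.
#' @export
plot_qtl <- function(study, snp_id, gene_id,
                     plottype = c("QTLplot", "violin", "boxplot", "histplot"),
                     group_names = NULL, remove_outlier = FALSE,
                     allele_labels = NULL, out_path = NULL, jitter_seed = 1L) {
  plottype <- match.arg(plottype)
  df <- qtl_plot_data(study, snp_id, gene_id, group_names = group_names,
                      remove_outlier = remove_outlier,
                      allele_labels = allele_labels)
  groups <- unique(df$group_label)
  panels <- lapply(groups, function(grp) {
    d <- dplyr::filter(df, .data$group_label == grp)
    counts <- d |> dplyr::count(.data$genotype, .drop = FALSE)
    xlabs <- sprintf("%s\n(n=%d)", counts$genotype, counts$n)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype,
                                         y = .data$expression,
                                         fill = .data$genotype))
    p <- switch(plottype,
      QTLplot = p +
        ggplot2::geom_point(ggplot2::aes(colour = .data$genotype),
                            size = 0.6,
                            position = ggplot2::position_jitter(
                              width = 0.2, height = 0, seed = jitter_seed)) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                              linewidth = 0.4, colour = "black"),
      violin = p + ggplot2::geom_violin(scale = "width", trim = TRUE),
      boxplot = p + ggplot2::geom_boxplot(outlier.size = 0.5),
      histplot = ggplot2::ggplot(d, ggplot2::aes(x = .data$expression,
                                                 fill = .data$genotype)) +
        ggplot2::geom_histogram(bins = 30) +
        ggplot2::facet_wrap(ggplot2::vars(.data$genotype), ncol = 1)
    )
    if (plottype != "histplot") {
      p <- p + ggplot2::scale_x_discrete(drop = FALSE, labels = xlabs)
    }
    p + ggplot2::labs(title = grp,
                      subtitle = sprintf("%s ~ %s", gene_id, snp_id),
                      x = NULL, y = "expression") +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none")
  })
  fig <- patchwork::wrap_plots(panels, nrow = 1)
  attr(fig, "plot_data") <- df
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, fig, width = 4 * length(panels), height = 4,
                    dpi = 150)
    readr::write_tsv(df, paste0(out_path, ".tsv"), progress = FALSE)
    return(invisible(fig))
  }
  fig
}
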