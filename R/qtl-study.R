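#' Create a single-cell eQTL study object
#'
#' Binds a genes-by-cells expression matrix to a SNPs-by-cells genotype matrix
#' over their shared cell barcodes. The returned `qtl_study` object is the
#' container that flows through the pipeline:
#' `create_study() |> normalize_expression() |> filter_gene_snp() |> call_qtl()`.
#'
#' Genotypes use integer storage codes. In `three_class` mode (the default):
#' 1 = homozygous reference, 2 = homozygous alternative, 3 = heterozygous,
#' 0 = missing. In `binary` mode: 1 = variant absent, 2 = variant present,
#' 0 = missing. Regression never sees the storage codes; they are recoded to
#' additive dosage (see [recode_to_dosage()]).
#'
#' Cells are restricted to the intersection of the two barcode sets, keeping
#' the expression matrix's barcode order; genotype columns are permuted to
#' match. Dropped barcodes are reported via a message.
#'
#' @param expression genes x cells numeric matrix (raw counts, typically) with
#'   gene ids as rownames and cell barcodes as colnames. A `dgCMatrix` is
#'   accepted and densified.
#' @param genotype SNPs x cells integer matrix of genotype codes with SNP ids
#'   as rownames and cell barcodes as colnames.
#' @param metadata optional data frame with columns `barcode` and
#'   `group_label` assigning each cell to a group (e.g., a cell type).
#' @param encoding_mode `"three_class"` or `"binary"`.
#' @param layer_tag `"raw"` if `expression` holds counts, `"normalized"`
#'   otherwise. Non-integer values force `"normalized"`.
#'
#' @return A `qtl_study` object: a list with elements `expression_raw`,
#'   `expression_normalized` (NULL until [normalize_expression()]),
#'   `genotype`, `encoding_mode`, `metadata` (tibble or NULL),
#'   `retained_genes`, `retained_snps` (NULL until [filter_gene_snp()]),
#'   `results` (tibble or NULL) and `params_log` (tibble, append-only).
#' @examples
#' sim <- simulate_qtl_data(sim_config(n_cells = 60, n_genes = 8, n_snps = 4,
#'                                     seed = 1))
#' study <- create_study(sim$expression, sim$genotype)
#' study
#' @export
create_study <- function(expression, genotype, metadata = NULL,
                         encoding_mode = c("three_class", "binary"),
                         layer_tag = c("raw", "normalized")) {
  encoding_mode <- match.arg(encoding_mode)
  layer_tag <- match.arg(layer_tag)
  expression <- as_dense_matrix(expression, "expression")
  genotype <- as_dense_matrix(genotype, "genotype")

  validate_expression(expression, layer_tag)
  if (layer_tag == "raw" && any(expression != floor(expression))) {
    warning("expression contains non-integer values; tagging layer as 'normalized'",
            call. = FALSE)
    layer_tag <- "normalized"
  }
  validate_genotype(genotype, encoding_mode)

  shared <- intersect(colnames(expression), colnames(genotype))
  if (length(shared) == 0L) {
    stop("expression and genotype share no cell barcodes", call. = FALSE)
  }
  # expression barcode order is canonical
  shared <- colnames(expression)[colnames(expression) %in% shared]
  n_drop_expr <- ncol(expression) - length(shared)
  n_drop_geno <- ncol(genotype) - length(shared)
  if (n_drop_expr + n_drop_geno > 0L) {
    message(sprintf("create_study: dropped %d expression-only and %d genotype-only barcodes; %d shared cells retained",
                    n_drop_expr, n_drop_geno, length(shared)))
  }
  expression <- expression[, shared, drop = FALSE]
  genotype <- genotype[, shared, drop = FALSE]

  md <- NULL
  if (!is.null(metadata)) {
    md <- tibble::as_tibble(metadata)
    if (!all(c("barcode", "group_label") %in% names(md))) {
      stop("metadata must have columns 'barcode' and 'group_label'", call. = FALSE)
    }
    if (anyDuplicated(md$barcode)) {
      stop("metadata barcodes are not unique", call. = FALSE)
    }
    md <- dplyr::filter(md, .data$barcode %in% shared)
  }

  study <- structure(
    list(
      expression_raw = if (layer_tag == "raw") expression else NULL,
      expression_normalized = if (layer_tag == "normalized") expression else NULL,
      genotype = genotype,
      encoding_mode = encoding_mode,
      metadata = md,
      retained_genes = NULL,
      retained_snps = NULL,
      results = NULL,
      params_log = tibble::tibble(step = character(), params = character())
    ),
    class = "qtl_study"
  )
  log_step(study, "create_study",
           list(encoding_mode = encoding_mode, layer_tag = layer_tag,
                n_cells = length(shared), dropped_expression = n_drop_expr,
                dropped_genotype = n_drop_geno))
}

as_dense_matrix <- function(x, what) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) stop(sprintf("%s must be a matrix", what), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("%s must carry rownames (ids) and colnames (cell barcodes)", what),
         call. = FALSE)
  }
  x
}

validate_expression <- function(x, layer_tag) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("expression matrix is empty", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate cell barcodes in expression matrix", call. = FALSE)
  if (any(x < 0)) stop("expression matrix has negative entries", call. = FALSE)
  invisible(x)
}

genotype_codes_allowed <- function(encoding_mode) {
  if (encoding_mode == "three_class") c(0L, 1L, 2L, 3L) else c(0L, 1L, 2L)
}

validate_genotype <- function(x, encoding_mode) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("genotype matrix is empty", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate SNP ids in genotype matrix", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate cell barcodes in genotype matrix", call. = FALSE)
  allowed <- genotype_codes_allowed(encoding_mode)
  bad <- which(matrix(!(x %in% allowed), nrow = nrow(x)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("genotype code %s not allowed in %s mode (SNP '%s', cell '%s')",
                 x[bad[1, 1], bad[1, 2]], encoding_mode,
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]),
         call. = FALSE)
  }
  invisible(x)
}

#' Recode stored genotype codes to additive allele dosage
#'
#' Storage codes order the classes for compactness, not biology; regression
#' needs the additive dosage scale. In `three_class` mode the map is
#' 1 -> 0 (ref hom), 3 -> 1 (het), 2 -> 2 (alt hom); in `binary` mode
#' 1 -> 0 (absent), 2 -> 1 (present). Code 0 (missing) becomes `NA` in both
#' modes, and missing cells are excluded pairwise per SNP downstream rather
#' than dropped globally.
#'
#' @param genotype integer matrix of storage codes, or a `qtl_study`.
#' @param encoding_mode ignored when `genotype` is a `qtl_study`.
#' @return numeric matrix of the same shape with entries in \{0, 1, 2, NA\}
#'   and attribute `dosage = TRUE`.
#' @examples
#' m <- matrix(c(1L, 3L, 2L, 0L), nrow = 1,
#'             dimnames = list("rs1", paste0("c", 1:4)))
#' recode_to_dosage(m, "three_class")
#' @export
recode_to_dosage <- function(genotype, encoding_mode = c("three_class", "binary")) {
  if (inherits(genotype, "qtl_study")) {
    encoding_mode <- genotype$encoding_mode
    genotype <- genotype$genotype
  } else {
    encoding_mode <- match.arg(encoding_mode)
  }
  if (isTRUE(attr(genotype, "dosage"))) {
    stop("matrix is already on the dosage scale; refusing to recode twice", call. = FALSE)
  }
  validate_genotype(genotype, encoding_mode)
  map <- if (encoding_mode == "three_class") {
    c(`0` = NA_real_, `1` = 0, `2` = 2, `3` = 1)
  } else {
    c(`0` = NA_real_, `1` = 0, `2` = 1)
  }
  out <- matrix(map[as.character(genotype)], nrow = nrow(genotype),
                dimnames = dimnames(genotype))
  attr(out, "dosage") <- TRUE
  out
}

# Append one step to the study's parameter log; every pipeline verb calls this.
log_step <- function(study, step, params) {
  study$params_log <- dplyr::bind_rows(
    study$params_log,
    tibble::tibble(step = step,
                   params = jsonless_serialize(params))
  )
  study
}

jsonless_serialize <- function(params) {
  paste(vapply(names(params), function(k) {
    v <- params[[k]]
    paste0(k, "=", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1)), collapse = "; ")
}

# Active expression layer: normalized when present, else raw.
active_layer <- function(study) {
  if (!is.null(study$expression_normalized)) study$expression_normalized else study$expression_raw
}

active_layer_tag <- function(study) {
  if (!is.null(study$expression_normalized)) "normalized" else "raw"
}

gene_ids <- function(study) {
  m <- if (!is.null(study$expression_raw)) study$expression_raw else study$expression_normalized
  rownames(m)
}

#' @export
print.qtl_study <- function(x, ...) {
  m <- if (!is.null(x$expression_raw)) x$expression_raw else x$expression_normalized
  cat("<qtl_study>\n")
  cat(sprintf("  expression: %d genes x %d cells (raw: %s, normalized: %s)\n",
              nrow(m), ncol(m),
              if (is.null(x$expression_raw)) "absent" else "present",
              if (is.null(x$expression_normalized)) "absent" else "present"))
  cat(sprintf("  genotype:   %d SNPs x %d cells [%s encoding]\n",
              nrow(x$genotype), ncol(x$genotype), x$encoding_mode))
  if (!is.null(x$metadata)) {
    cat(sprintf("  groups:     %s\n",
                paste(sort(unique(x$metadata$group_label)), collapse = ", ")))
  }
  if (!is.null(x$retained_genes)) {
    cat(sprintf("  filtered:   %d genes, %d SNPs retained\n",
                length(x$retained_genes), length(x$retained_snps)))
  }
  if (!is.null(x$results)) {
    cat(sprintf("  results:    %d tested pairs, %d significant\n",
                nrow(x$results), sum(x$results$significant, na.rm = TRUE)))
  }
  cat(sprintf("  log:        %d steps\n", nrow(x$params_log)))
  invisible(x)
}

#' Cell groups of a study
#'
#' Group labels from the metadata, or `"all"` when no metadata was supplied.
#' @param study a `qtl_study`.
#' @return character vector of group labels.
#' @export
study_groups <- function(study) {
  if (is.null(study$metadata)) "all" else sort(unique(study$metadata$group_label))
}

# Barcodes belonging to one group ("all" = every cell).
group_barcodes <- function(study, group) {
  cells <- colnames(study$genotype)
  if (is.null(study$metadata) || identical(group, "all")) return(cells)
  keep <- study$metadata$barcode[study$metadata$group_label == group]
  cells[cells %in% keep]
}
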