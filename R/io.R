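#' Read a CellRanger-style MatrixMarket expression triplet
#'
#' Loads a sparse genes x cells count matrix from the standard 10x triplet:
#' a MatrixMarket coordinate file plus one-column feature and barcode TSVs
#' (first column used when the files carry extra columns).
#'
#' @param matrix_path path to the `.mtx` file.
#' @param features_path path to the features/genes TSV (one gene per line).
#' @param barcodes_path path to the barcodes TSV (one barcode per line).
#' @return dense genes x cells matrix with ids as dimnames and attribute
#'   `layer_tag` (`"raw"`, or `"normalized"` with a warning when entries are
#'   non-integer).
#' @export
read_expression_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- readr::read_tsv(features_path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)[[1]]
  bcs <- readr::read_tsv(barcodes_path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)[[1]]
  if (length(feats) != nrow(m)) {
    stop(sprintf("features file has %d entries but matrix has %d rows",
                 length(feats), nrow(m)), call. = FALSE)
  }
  if (length(bcs) != ncol(m)) {
    stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                 length(bcs), ncol(m)), call. = FALSE)
  }
  out <- as.matrix(m)
  dimnames(out) <- list(feats, bcs)
  tag <- "raw"
  if (any(out != floor(out))) {
    warning("matrix contains non-integer entries; tagging as 'normalized'", call. = FALSE)
    tag <- "normalized"
  }
  attr(out, "layer_tag") <- tag
  out
}

#' Write an expression matrix as a MatrixMarket triplet
#'
#' Inverse of [read_expression_mtx()]; round-trips bit-exactly.
#'
#' @param mat genes x cells matrix with dimnames.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return invisibly, the three paths.
#' @export
write_expression_mtx <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix"), "generalMatrix"), paths[1])
  readr::write_lines(rownames(mat), paths[2])
  readr::write_lines(colnames(mat), paths[3])
  invisible(paths)
}

#' Read a dense SNPs x cells genotype matrix from TSV
#'
#' Expected layout: header row of cell barcodes, first column of SNP ids,
#' integer genotype codes in the body (VarTrix-style; see [create_study()]
#' for the code semantics).
#'
#' @param path TSV path.
#' @param encoding_mode `"three_class"` or `"binary"`; codes are validated
#'   against the mode.
#' @return integer matrix with SNP ids as rownames, barcodes as colnames.
#' @export
read_genotype_tsv <- function(path, encoding_mode = c("three_class", "binary")) {
  encoding_mode <- match.arg(encoding_mode)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0L) stop("no SNPs in genotype file", call. = FALSE)
  ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer genotype value '%s' at row %d ('%s'), column '%s'",
                 body[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 colnames(df)[-1][bad[1, 2]]), call. = FALSE)
  }
  m <- matrix(as.integer(num), nrow = nrow(num),
              dimnames = list(ids, colnames(df)[-1]))
  validate_genotype(m, encoding_mode)
  m
}

#' Read gene annotations (coordinates and lengths)
#'
#' Three dialects are accepted. `bed`: BED4 (`chrom start end name`),
#' half-open 0-based, converted to 1-based inclusive. `gff3`: gene records
#' (1-based inclusive, used as-is); the gene id is taken from the `ID`,
#' `gene_id` or `Name` attribute. `tsv`: header columns
#' `gene_id, chrom, start, end` with optional `strand` and `length_bp`.
#' When absent, `length_bp` defaults to the genomic span `end - start + 1`
#' (used by TPM normalization).
#'
#' @param path annotation file path.
#' @param dialect `"bed"`, `"gff3"` or `"tsv"`.
#' @return tibble with columns `gene_id, chrom, start, end, strand, length_bp`.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "bed", "gff3")) {
  dialect <- match.arg(dialect)
  ann <- switch(dialect,
    tsv = {
      df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
      need <- c("gene_id", "chrom", "start", "end")
      if (!all(need %in% names(df))) {
        stop("TSV gene annotation needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
      }
      tibble::tibble(
        gene_id = as.character(df$gene_id),
        chrom = as.character(df$chrom),
        start = check_coord(df$start, "start"),
        end = check_coord(df$end, "end"),
        strand = if ("strand" %in% names(df)) as.character(df$strand) else "unknown",
        length_bp = if ("length_bp" %in% names(df)) as.integer(df$length_bp) else NA_integer_
      )
    },
    bed = {
      requireNamespace("rtracklayer", quietly = TRUE) ||
        stop("rtracklayer is required for BED input", call. = FALSE)
      gr <- rtracklayer::import(path, format = "BED")
      tibble::tibble(
        gene_id = as.character(gr$name),
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr),   # rtracklayer already 1-based inclusive
        end = BiocGenerics::end(gr),
        strand = chartr("*", "u", as.character(BiocGenerics::strand(gr))),
        length_bp = NA_integer_
      )
    },
    gff3 = {
      requireNamespace("rtracklayer", quietly = TRUE) ||
        stop("rtracklayer is required for GFF3 input", call. = FALSE)
      gr <- rtracklayer::import(path, format = "GFF3")
      gr <- gr[gr$type %in% c("gene", "pseudogene") | is.na(gr$type)]
      id <- as.character(gr$ID)
      if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
        alt <- as.character(gr$gene_id)
        id[is.na(id)] <- alt[is.na(id)]
      }
      if ("Name" %in% names(S4Vectors::mcols(gr))) {
        alt <- as.character(gr$Name)
        id[is.na(id)] <- alt[is.na(id)]
      }
      tibble::tibble(
        gene_id = id,
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr),
        end = BiocGenerics::end(gr),
        strand = chartr("*", "u", as.character(BiocGenerics::strand(gr))),
        length_bp = NA_integer_
      )
    }
  )
  ann$strand[ann$strand %in% c("u", "", ".")] <- "unknown"
  if (any(ann$start > ann$end)) {
    bad <- ann$gene_id[which(ann$start > ann$end)[1]]
    stop(sprintf("gene '%s' has start > end after coordinate conversion", bad),
         call. = FALSE)
  }
  ann$length_bp <- ifelse(is.na(ann$length_bp),
                          as.integer(ann$end - ann$start + 1L),
                          ann$length_bp)
  ann
}

check_coord <- function(x, what) {
  n <- suppressWarnings(as.numeric(x))
  if (any(is.na(n)) || any(n != floor(n))) {
    stop(sprintf("malformed %s coordinate: '%s'", what, x[which(is.na(n) | n != floor(n))[1]]),
         call. = FALSE)
  }
  as.integer(n)
}

#' Read SNP positions
#'
#' `tsv` dialect: header columns `snp_id, chrom, pos` (1-based). `vcf`
#' dialect: a minimal VCF whose CHROM/POS/ID fields are used as-is.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return tibble with columns `snp_id, chrom, pos`.
#' @export
read_snp_annotation <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  ann <- switch(dialect,
    tsv = {
      df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
      need <- c("snp_id", "chrom", "pos")
      if (!all(need %in% names(df))) {
        stop("TSV SNP annotation needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
      }
      tibble::tibble(snp_id = as.character(df$snp_id),
                     chrom = as.character(df$chrom),
                     pos = check_coord(df$pos, "pos"))
    },
    vcf = {
      requireNamespace("vcfR", quietly = TRUE) ||
        stop("vcfR is required for VCF input", call. = FALSE)
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      fix <- vcfR::getFIX(v)
      if (is.null(dim(fix))) fix <- t(as.matrix(fix))
      tibble::tibble(snp_id = as.character(fix[, "ID"]),
                     chrom = as.character(fix[, "CHROM"]),
                     pos = check_coord(fix[, "POS"], "pos"))
    }
  )
  if (any(ann$pos < 1L)) stop("SNP position below 1", call. = FALSE)
  ann
}

# Columns written per model; shared suffix keeps round-trips schema-stable.
result_columns <- function(model) {
  eff <- if (model == "zinb") "fold_change" else c("coefficient", "abs_effect")
  c("snp_id", "gene_id", "group_label", "model",
    "snp_chrom", "snp_pos", "gene_start", "gene_end",
    "n_ref", "n_het", "n_alt", eff, "p_value", "adjusted_p", "significant")
}

#' Write an eQTL results table to TSV
#'
#' One row per tested (SNP, gene, group). Columns follow the model's schema:
#' ZINB results carry `fold_change` (log2 scale); linear and Poisson results
#' carry `coefficient` and `abs_effect`. An empty result set writes a
#' header-only file.
#'
#' @param results results tibble (from [call_qtl()] / [eqtl_results()]), or a
#'   `qtl_study` whose `$results` is used.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "qtl_study")) results <- results$results
  model <- if (!is.null(results) && nrow(results) > 0) results$model[1] else
    attr(results, "model") %||% "zinb"
  cols <- result_columns(model)
  if (is.null(results) || nrow(results) == 0L) {
    out <- tibble::as_tibble(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    out <- results[, cols[cols %in% names(results)], drop = FALSE]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path TSV path.
#' @return tibble of results.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
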