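#' Enumerate candidate cis SNP-gene pairs
#'
#' A SNP is paired with a gene when it lies on the same chromosome within
#' the window `[gene_start - upstream_bp, gene_end + downstream_bp]`
#' (1-based, boundaries inclusive; the lower bound is floored at 1).
#' Strand is ignored: "upstream" always means lower coordinates than the
#' gene start. Chromosome names are compared after stripping any leading
#' `chr` prefix, so `chr1` and `1` match.
#'
#' @param genes gene-annotation tibble ([read_gene_annotation()] schema).
#' @param snps SNP-annotation tibble ([read_snp_annotation()] schema).
#' @param upstream_bp,downstream_bp non-negative window sizes in bp.
#' @param gene_subset optional character vector restricting the genes
#'   considered.
#' @return tibble with one row per pair, ordered by gene id then SNP
#'   position: `snp_id, gene_id, chrom, snp_pos, gene_start, gene_end,
#'   window_start, window_end`.
#' @examples
#' genes <- tibble::tibble(gene_id = "G1", chrom = "chr1",
#'                         start = 10000L, end = 20000L,
#'                         strand = "+", length_bp = 10001L)
#' snps <- tibble::tibble(snp_id = c("rs1", "rs2"), chrom = "1",
#'                        pos = c(8000L, 7999L))
#' pair_cis(genes, snps, upstream_bp = 2000, downstream_bp = 1000)
#' @export
pair_cis <- function(genes, snps, upstream_bp = 100000, downstream_bp = 100000,
                     gene_subset = NULL) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  if (!is.null(gene_subset)) {
    genes <- dplyr::filter(genes, .data$gene_id %in% gene_subset)
  }
  g <- genes |>
    dplyr::mutate(chrom_key = strip_chr(.data$chrom),
                  window_start = pmax(1, .data$start - upstream_bp),
                  window_end = .data$end + downstream_bp)
  s <- snps |>
    dplyr::mutate(chrom_key = strip_chr(.data$chrom)) |>
    dplyr::select("snp_id", "chrom_key", "pos")
  pairs <- dplyr::inner_join(g, s, by = "chrom_key",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$window_start,
                  .data$pos <= .data$window_end) |>
    dplyr::transmute(snp_id = .data$snp_id,
                     gene_id = .data$gene_id,
                     chrom = .data$chrom,
                     snp_pos = .data$pos,
                     gene_start = .data$start,
                     gene_end = .data$end,
                     window_start = .data$window_start,
                     window_end = .data$window_end) |>
    dplyr::arrange(.data$gene_id, .data$snp_pos, .data$snp_id)
  if (nrow(pairs) == 0L) {
    warning("no cis SNP-gene pairs found for these windows", call. = FALSE)
  }
  pairs
}

strip_chr <- function(x) sub("^chr", "", as.character(x))
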