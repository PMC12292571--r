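#' Simulation configuration
#'
#' Defines a synthetic single-cell genotype + expression dataset with known
#' ground truth. Defaults describe a sparse UMI-count regime with per-cell
#' genotypes (clonal-mosaic style, as produced by per-cell variant callers
#' on a single sample): common variants in Hardy-Weinberg proportions,
#' moderate zero inflation and overdispersion, and a handful of planted
#' cis effects.
#'
#' @param n_cells,n_genes,n_snps dataset dimensions.
#' @param maf_range range the per-SNP minor-allele frequency is drawn from.
#' @param missing_rate fraction of genotype entries set to missing (code 0).
#' @param pi_range per-gene zero-inflation probability range.
#' @param theta_range per-gene NB dispersion (size) range.
#' @param base_mu_range per-gene baseline NB mean range.
#' @param n_true_eqtls number of planted SNP-gene effects (each on its own
#'   gene; must not exceed `n_genes` or `n_snps`).
#' @param effect_log2fc planted log2 fold change between the extreme dosage
#'   classes (alt-hom vs ref-hom overall means).
#' @param n_groups number of cell groups (cells split evenly at random);
#'   effects are planted in every group.
#' @param seed integer seed; mandatory, the dataset is a pure function of
#'   the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000, n_genes = 100, n_snps = 80,
                       maf_range = c(0.2, 0.4), missing_rate = 0.05,
                       pi_range = c(0.2, 0.4), theta_range = c(1, 3),
                       base_mu_range = c(1, 10),
                       n_true_eqtls = 10, effect_log2fc = 1,
                       n_groups = 1, seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L || is.na(seed)) {
    stop("sim_config requires an explicit integer seed", call. = FALSE)
  }
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            all(pi_range >= 0), all(pi_range < 1),
            all(maf_range > 0), all(maf_range < 0.5 + 1e-9),
            is.finite(effect_log2fc), n_groups >= 1)
  if (n_true_eqtls > n_genes || n_true_eqtls > n_snps) {
    stop("n_true_eqtls cannot exceed n_genes or n_snps", call. = FALSE)
  }
  structure(list(n_cells = n_cells, n_genes = n_genes, n_snps = n_snps,
                 maf_range = maf_range, missing_rate = missing_rate,
                 pi_range = pi_range, theta_range = theta_range,
                 base_mu_range = base_mu_range, n_true_eqtls = n_true_eqtls,
                 effect_log2fc = effect_log2fc, n_groups = n_groups,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Named RNG substreams derived from the config seed: component i gets
# seed + fixed offset, so adding cells to one component never perturbs another.
sub_seed <- function(config, component) {
  offsets <- c(genotype = 11L, expression = 23L, annotation = 37L,
               groups = 53L, params = 71L)
  (config$seed + offsets[[component]]) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate a genotype + expression dataset with known truth
#'
#' Per SNP, a minor-allele frequency q is drawn from `maf_range` and
#' genotypes sampled under Hardy-Weinberg proportions
#' ((1-q)^2, 2q(1-q), q^2), stored in three-class codes (1 = ref-hom,
#' 3 = het, 2 = alt-hom); `missing_rate` entries are set to 0. Per gene,
#' counts are drawn from a ZINB with gene-specific (pi, mu, theta). For the
#' planted pairs, the NB mean is scaled per dosage class
#' (`mu_d = mu * 2^(effect_log2fc * d / 2)`), so the ratio of overall means
#' between the extreme classes equals `2^effect_log2fc`. Annotations place
#' every truth SNP inside its gene's default cis window; null SNPs are
#' scattered both inside windows and on a separate chromosome (never
#' paired).
#'
#' @param config a [sim_config()] list.
#' @return list with elements `expression` (genes x cells integer matrix),
#'   `genotype` (SNPs x cells codes), `metadata` (tibble or NULL),
#'   `gene_annotation`, `snp_annotation` (tibbles), and `truth` (tibble:
#'   `snp_id, gene_id, group_label, true_log2fc`, plus the generating
#'   parameters as attribute `config`).
#' @examples
#' sim <- simulate_qtl_data(sim_config(n_cells = 100, n_genes = 10, n_snps = 5,
#'                                     n_true_eqtls = 1, seed = 42))
#' sim$truth
#' @export
simulate_qtl_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_cells <- config$n_cells; n_genes <- config$n_genes; n_snps <- config$n_snps
  cells <- sprintf("cell%04d", seq_len(n_cells))
  genes <- sprintf("gene%03d", seq_len(n_genes))
  snps <- sprintf("snp%03d", seq_len(n_snps))

  # per-gene / per-SNP generative parameters
  pars <- with_seed(sub_seed(config, "params"), {
    list(maf = stats::runif(n_snps, config$maf_range[1], config$maf_range[2]),
         pi = stats::runif(n_genes, config$pi_range[1], config$pi_range[2]),
         theta = stats::runif(n_genes, config$theta_range[1], config$theta_range[2]),
         mu = stats::runif(n_genes, config$base_mu_range[1], config$base_mu_range[2]))
  })

  geno <- with_seed(sub_seed(config, "genotype"), {
    m <- vapply(seq_len(n_snps), function(i) {
      q <- pars$maf[i]
      dos <- sample(0:2, n_cells, replace = TRUE,
                    prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
      codes <- c(1L, 3L, 2L)[dos + 1L]
      miss <- stats::runif(n_cells) < config$missing_rate
      codes[miss] <- 0L
      codes
    }, integer(n_cells))
    t(m)
  })
  dimnames(geno) <- list(snps, cells)

  md <- NULL
  if (config$n_groups > 1) {
    md <- with_seed(sub_seed(config, "groups"), {
      tibble::tibble(barcode = cells,
                     group_label = sample(sprintf("group%d", seq_len(config$n_groups)),
                                          n_cells, replace = TRUE))
    })
  }

  # planted pairs: truth SNP i regulates gene i
  truth_idx <- seq_len(config$n_true_eqtls)
  dosage <- recode_to_dosage(geno, "three_class")

  expr <- with_seed(sub_seed(config, "expression"), {
    m <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    for (g in seq_len(n_genes)) {
      mu_cell <- rep(pars$mu[g], n_cells)
      if (g %in% truth_idx && config$effect_log2fc != 0) {
        d <- dosage[g, ]
        d[is.na(d)] <- 1  # missing genotypes get the mid-class mean
        mu_cell <- pars$mu[g] * 2^(config$effect_log2fc * d / 2)
      }
      counts <- stats::rnbinom(n_cells, size = pars$theta[g], mu = mu_cell)
      drop <- stats::runif(n_cells) < pars$pi[g]
      counts[drop] <- 0L
      m[g, ] <- counts
    }
    m
  })

  ann <- with_seed(sub_seed(config, "annotation"), {
    gene_start <- 1e6 * seq_len(n_genes)
    gene_end <- gene_start + 1999L
    gene_ann <- tibble::tibble(gene_id = genes, chrom = "chr1",
                               start = as.integer(gene_start),
                               end = as.integer(gene_end),
                               strand = "+",
                               length_bp = as.integer(gene_end - gene_start + 1L))
    # truth SNPs inside their gene body; half of the null SNPs near random
    # genes (inside default windows), the rest on chr2 (never paired)
    snp_chrom <- character(n_snps); snp_pos <- integer(n_snps)
    for (i in seq_len(n_snps)) {
      if (i <= config$n_true_eqtls) {
        snp_chrom[i] <- "chr1"
        snp_pos[i] <- as.integer(gene_start[i] + 500L)
      } else if (i %% 2 == 0) {
        g <- sample(n_genes, 1)
        snp_chrom[i] <- "chr1"
        snp_pos[i] <- as.integer(gene_start[g] + sample(-5000:5000, 1))
      } else {
        snp_chrom[i] <- "chr2"
        snp_pos[i] <- as.integer(1e6 * i)
      }
    }
    list(gene = gene_ann,
         snp = tibble::tibble(snp_id = snps, chrom = snp_chrom,
                              pos = pmax(snp_pos, 1L)))
  })

  truth_groups <- if (is.null(md)) "all" else sort(unique(md$group_label))
  truth <- if (config$n_true_eqtls == 0) {
    tibble::tibble(snp_id = character(0), gene_id = character(0),
                   group_label = character(0), true_log2fc = numeric(0))
  } else {
    grid <- tidyr::expand_grid(idx = truth_idx, group_label = truth_groups)
    tibble::tibble(snp_id = snps[grid$idx], gene_id = genes[grid$idx],
                   group_label = grid$group_label,
                   true_log2fc = config$effect_log2fc)
  }
  attr(truth, "config") <- config

  list(expression = expr, genotype = geno, metadata = md,
       gene_annotation = ann$gene, snp_annotation = ann$snp, truth = truth)
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits exactly the formats the readers consume: a MatrixMarket expression
#' triplet (`matrix.mtx`, `features.tsv`, `barcodes.tsv`), a dense genotype
#' TSV (`genotype.tsv`), optional `metadata.tsv`, annotation TSVs
#' (`gene_annotation.tsv`, `snp_annotation.tsv`) and the ground-truth table
#' (`truth.tsv`).
#'
#' @param dataset result of [simulate_qtl_data()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_mtx(dataset$expression, dir)
  geno_df <- tibble::as_tibble(dataset$genotype, rownames = "snp_id")
  readr::write_tsv(geno_df, file.path(dir, "genotype.tsv"), progress = FALSE)
  if (!is.null(dataset$metadata)) {
    readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  }
  readr::write_tsv(dataset$gene_annotation, file.path(dir, "gene_annotation.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$snp_annotation, file.path(dir, "snp_annotation.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
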