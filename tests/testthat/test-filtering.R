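study_from <- function(expr, geno, encoding = "three_class") {
  create_study(expr, geno, encoding_mode = encoding)
}

named_mat <- function(values, nr, prefix_r, prefix_c) {
  matrix(values, nrow = nr,
         dimnames = list(paste0(prefix_r, seq_len(nr)),
                         paste0(prefix_c, seq_len(length(values) / nr))))
}

test_that("gene filter counts cells strictly above the expression minimum", {
  expr <- rbind(gA = c(0, 0, 2, 3),   # 2/4 = 50% above 1 -> retained at 50
                gB = c(0, 0, 0, 2))   # 25% -> dropped
  colnames(expr) <- paste0("c", 1:4)
  geno <- named_mat(rep(1L, 4), 1, "s", "c")
  study <- study_from(expr, geno)
  keep <- filter_genes(study, filter_params(expression_min = 1,
                                            expression_cells_percent = 50))
  expect_equal(keep, "gA")
  # value equal to the minimum does not count ("exceeds" is strict)
  expr2 <- rbind(gA = c(1, 1, 1, 1)); colnames(expr2) <- paste0("c", 1:4)
  study2 <- study_from(expr2, geno)
  expect_warning(
    keep2 <- filter_genes(study2, filter_params(expression_min = 1,
                                                expression_cells_percent = 1)),
    "no genes")
  expect_length(keep2, 0)
  # near-zero percent keeps any gene with a positive cell
  keep3 <- filter_genes(study, filter_params(expression_min = 0,
                                             expression_cells_percent = 1e-9))
  expect_equal(keep3, c("gA", "gB"))
})

test_that("SNP filter requires every class in enough non-missing cells", {
  expr <- named_mat(rep(1, 10), 1, "g", "c")
  # 5x code1, 4x code2, 1x code3 over 10 cells: class 3 at exactly 10%
  geno <- named_mat(c(rep(1L, 5), rep(2L, 4), 3L), 1, "s", "c")
  study <- study_from(expr, geno)
  expect_equal(filter_snps(study, filter_params(snp_cells_percent = 10)), "s1")
  # with a missing cell the denominator shrinks: 1/9 = 11.1% still passes
  geno2 <- named_mat(c(rep(1L, 5), rep(2L, 3), 3L, 0L), 1, "s", "c")
  expect_equal(filter_snps(study_from(expr, geno2),
                           filter_params(snp_cells_percent = 10)), "s1")
  # a class absent entirely -> dropped
  geno3 <- named_mat(c(rep(1L, 5), rep(3L, 5)), 1, "s", "c")
  expect_length(filter_snps(study_from(expr, geno3),
                            filter_params(snp_cells_percent = 10)), 0)
  # all-missing SNP dropped with warning
  geno4 <- named_mat(rep(0L, 10), 1, "s", "c")
  expect_warning(keep <- filter_snps(study_from(expr, geno4),
                                     filter_params(snp_cells_percent = 10)),
                 "all-missing")
  expect_length(keep, 0)
})

test_that("binary encoding needs only its two classes", {
  expr <- named_mat(rep(1, 10), 1, "g", "c")
  geno <- named_mat(c(rep(1L, 8), rep(2L, 2)), 1, "s", "c")
  study <- study_from(expr, geno, "binary")
  expect_equal(filter_snps(study, filter_params(snp_cells_percent = 10)), "s1")
  expect_length(filter_snps(study, filter_params(snp_cells_percent = 25)), 0)
})

test_that("filters agree with the brute-force oracle on random instances", {
  set.seed(202)
  for (rep in 1:30) {
    n_cells <- sample(20:100, 1)
    expr <- matrix(rpois(50 * n_cells, 0.8), 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%03d", seq_len(n_cells))))
    geno <- matrix(sample(0:3, 20 * n_cells, replace = TRUE,
                          prob = c(0.1, 0.4, 0.2, 0.3)), 20,
                   dimnames = list(sprintf("s%02d", 1:20),
                                   sprintf("c%03d", seq_len(n_cells))))
    study <- suppressWarnings(study_from(expr, geno))
    emin <- sample(c(0, 1, 2), 1)
    ep <- runif(1, 1, 90)
    sp <- runif(1, 1, 40)
    params <- filter_params(expression_min = emin,
                            expression_cells_percent = ep,
                            snp_cells_percent = sp)
    expect_identical(suppressWarnings(filter_genes(study, params)),
                     oracle_filter_genes(expr, emin, ep))
    expect_identical(suppressWarnings(filter_snps(study, params)),
                     oracle_filter_snps(geno, "three_class", sp))
  }
})

test_that("filtering is monotone in its thresholds and commutes with cell permutation", {
  toy <- make_toy_study(n_cells = 150, n_genes = 30, n_snps = 15, seed = 77)
  study <- toy$study
  prev_g <- Inf; prev_s <- Inf
  for (pct in c(5, 20, 50, 80)) {
    params <- filter_params(expression_cells_percent = pct,
                            snp_cells_percent = pct)
    g <- suppressWarnings(filter_genes(study, params))
    s <- suppressWarnings(filter_snps(study, params))
    expect_lte(length(g), prev_g)
    expect_lte(length(s), prev_s)
    prev_g <- length(g); prev_s <- length(s)
  }
  perm <- sample(ncol(study$expression_raw))
  study_p <- create_study(study$expression_raw[, perm],
                          study$genotype[, perm])
  params <- filter_params(expression_cells_percent = 30, snp_cells_percent = 10)
  expect_identical(sort(suppressWarnings(filter_genes(study, params))),
                   sort(suppressWarnings(filter_genes(study_p, params))))
  expect_identical(sort(suppressWarnings(filter_snps(study, params))),
                   sort(suppressWarnings(filter_snps(study_p, params))))
})

test_that("filter_gene_snp records retained ids, is idempotent, honours boundaries", {
  toy <- make_toy_study(n_cells = 100, n_genes = 20, n_snps = 10, seed = 13)
  params <- filter_params(expression_cells_percent = 20, snp_cells_percent = 10)
  s1 <- suppressWarnings(filter_gene_snp(toy$study, params))
  s2 <- suppressWarnings(filter_gene_snp(s1, params))
  expect_identical(s1$retained_genes, s2$retained_genes)
  expect_identical(s1$retained_snps, s2$retained_snps)
  # percent = 100 keeps only genes expressed in every cell
  all_cells <- suppressWarnings(
    filter_genes(toy$study, filter_params(expression_cells_percent = 100)))
  expr <- toy$study$expression_raw
  expect_identical(all_cells, rownames(expr)[rowSums(expr > 0) == ncol(expr)])
})

test_that("low-MAF planted SNPs are removed by the default class filter", {
  sim <- simulate_qtl_data(sim_config(n_cells = 400, n_genes = 10, n_snps = 6,
                                      maf_range = c(0.05, 0.08),
                                      n_true_eqtls = 2, seed = 21))
  study <- create_study(sim$expression, sim$genotype)
  keep <- suppressWarnings(filter_snps(study, filter_params()))
  # hom-alt frequency q^2 < 1% can never reach the 10% class requirement
  expect_length(intersect(keep, sim$truth$snp_id), 0)
})
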