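# Independent brute-force oracles used across the suite. These are written
# from the definitions and never share code with the package internals.

# Gene filter: loop over genes, count cells exceeding the threshold.
oracle_filter_genes <- function(mat, expression_min, percent) {
  keep <- character(0)
  for (g in rownames(mat)) {
    n_expr <- 0
    for (j in seq_len(ncol(mat))) {
      if (mat[g, j] > expression_min) n_expr <- n_expr + 1
    }
    if (n_expr / ncol(mat) * 100 >= percent) keep <- c(keep, g)
  }
  keep
}

# SNP filter: per SNP, check every required class against non-missing cells.
oracle_filter_snps <- function(geno, encoding_mode, percent) {
  required <- if (encoding_mode == "three_class") c(1, 2, 3) else c(1, 2)
  keep <- character(0)
  for (s in rownames(geno)) {
    codes <- geno[s, ]
    codes <- codes[codes != 0]
    if (length(codes) == 0) next
    ok <- TRUE
    for (k in required) {
      if (sum(codes == k) / length(codes) * 100 < percent) ok <- FALSE
    }
    if (ok) keep <- c(keep, s)
  }
  keep
}

# Cis pairing: scan every (gene, snp) combination.
oracle_pair_cis <- function(genes, snps, upstream, downstream) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(snps))) {
      gc <- sub("^chr", "", genes$chrom[i])
      sc <- sub("^chr", "", snps$chrom[j])
      if (gc != sc) next
      ws <- max(1, genes$start[i] - upstream)
      we <- genes$end[i] + downstream
      if (snps$pos[j] >= ws && snps$pos[j] <= we) {
        out[[length(out) + 1]] <- data.frame(gene_id = genes$gene_id[i],
                                             snp_id = snps$snp_id[j])
      }
    }
  }
  if (length(out) == 0) return(data.frame(gene_id = character(0), snp_id = character(0)))
  df <- do.call(rbind, out)
  df[order(df$gene_id, df$snp_id), , drop = FALSE]
}

# p-adjustment from the textbook definitions.
oracle_bonferroni <- function(p) pmin(1, p * length(p))

oracle_holm <- function(p) {
  m <- length(p); o <- order(p)
  adj <- numeric(m); run <- 0
  for (r in seq_len(m)) {
    run <- max(run, (m - r + 1) * p[o[r]])
    adj[o[r]] <- min(1, run)
  }
  adj
}

oracle_hochberg <- function(p) {
  m <- length(p); o <- order(p, decreasing = TRUE)
  adj <- numeric(m); run <- Inf
  for (r in seq_len(m)) {
    rank_asc <- m - r + 1
    run <- min(run, (m - rank_asc + 1) * p[o[r]])
    adj[o[r]] <- min(1, run)
  }
  adj
}

oracle_bh <- function(p) {
  m <- length(p); o <- order(p, decreasing = TRUE)
  adj <- numeric(m); run <- Inf
  for (r in seq_len(m)) {
    rank_asc <- m - r + 1
    run <- min(run, m / rank_asc * p[o[r]])
    adj[o[r]] <- min(1, run)
  }
  adj
}

# Hommel via exhaustive closed testing with Simes local tests (valid for
# small m): adjusted p_i = max over subsets S containing i of the Simes
# p-value of S.
oracle_hommel <- function(p) {
  m <- length(p)
  stopifnot(m <= 12)
  simes <- function(ps) {
    k <- length(ps); min(sort(ps) * k / seq_len(k))
  }
  adj <- numeric(m)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  for (i in seq_len(m)) {
    worst <- 0
    for (r in seq_len(nrow(subsets))) {
      sel <- unlist(subsets[r, ])
      if (!sel[i]) next
      worst <- max(worst, simes(p[sel]))
    }
    adj[i] <- min(1, worst)
  }
  adj
}

# MAD outlier rule recomputed directly.
oracle_outlier_keep <- function(v) {
  med <- median(v)
  mad_scaled <- 1.4826 * median(abs(v - med))
  v <= med + 4 * mad_scaled
}

# Newton-Raphson MLE for log-link Poisson regression with intercept.
oracle_poisson_newton <- function(y, d, tol = 1e-12, maxit = 200) {
  X <- cbind(1, d)
  beta <- c(log(mean(y) + 0.1), 0)
  for (it in seq_len(maxit)) {
    eta <- X %*% beta
    mu <- exp(eta)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * as.numeric(mu))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# ZINB log-likelihood from the pmf, term by term.
oracle_zinb_loglik <- function(y, pi, mu, theta) {
  nb <- function(k) {
    exp(lgamma(k + theta) - lgamma(theta) - lfactorial(k)) *
      (theta / (theta + mu))^theta * (mu / (theta + mu))^k
  }
  sum(sapply(y, function(k) log(pi * (k == 0) + (1 - pi) * nb(k))))
}

# Small deterministic study used by several files.
make_toy_study <- function(n_cells = 60, n_genes = 6, n_snps = 3, seed = 42,
                           n_true_eqtls = min(2L, n_genes, n_snps), ...) {
  sim <- simulate_qtl_data(sim_config(n_cells = n_cells, n_genes = n_genes,
                                      n_snps = n_snps, seed = seed,
                                      n_true_eqtls = n_true_eqtls, ...))
  list(sim = sim, study = create_study(sim$expression, sim$genotype,
                                       metadata = sim$metadata))
}

# Draws from a ZINB for recovery and calibration tests.
rzinb <- function(n, pi, mu, theta) {
  y <- stats::rnbinom(n, size = theta, mu = mu)
  y[stats::runif(n) < pi] <- 0L
  y
}
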