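test_that("linear slope matches the closed form and lm on hand examples", {
  d <- c(0, 0, 1, 1, 2, 2)
  y <- c(1.0, 1.2, 1.5, 1.7, 2.0, 2.2)
  fit <- fit_linear(y, d)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  ref <- summary(lm(y ~ d))$coefficients
  expect_equal(fit$beta, ref[2, 1], tolerance = 1e-12)
  expect_equal(fit$p, ref[2, 4], tolerance = 1e-12)
  # constant response: slope 0, p 1
  flat <- fit_linear(rep(2, 6), d)
  expect_equal(flat$beta, 0)
  expect_equal(flat$p, 1)
  # exact identity fit: slope 1, zero residuals
  ident <- fit_linear(d, d)
  expect_equal(ident$beta, 1, tolerance = 1e-12)
  expect_equal(ident$p, 0)
})

test_that("linear fit drops missing dosages pairwise and skips degenerate designs", {
  d <- c(0, 1, 2, NA, NA)
  y <- c(1, 2, 3, 100, 200)
  fit <- fit_linear(y, d)
  expect_equal(fit$n, 3)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_s3_class(fit_linear(y[1:2], d[1:2]), "skipped_fit")
  skip <- fit_linear(c(1, 2, 3), c(1, 1, 1))
  expect_s3_class(skip, "skipped_fit")
  expect_match(attr(skip, "reason"), "constant dosage")
})

test_that("two-group Poisson slope equals the log mean ratio", {
  d <- c(0, 0, 1, 1)
  y <- c(2, 4, 6, 6)
  fit <- fit_poisson(y, d)
  expect_equal(fit$beta, log(6 / 3), tolerance = 1e-8)
  expect_s3_class(fit_poisson(c(0, 0, 0, 0), d), "skipped_fit")
})

test_that("Poisson MLE agrees with glm and a Newton oracle on random instances", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(30:100, 1)
    d <- sample(0:2, n, replace = TRUE)
    y <- rpois(n, exp(0.3 + 0.4 * d))
    if (all(y == 0) || length(unique(d)) < 2) next
    fit <- fit_poisson(y, d)
    newton <- oracle_poisson_newton(y, d)
    expect_equal(fit$beta, newton[2], tolerance = 1e-6)
    ref <- summary(glm(y ~ d, family = poisson()))$coefficients
    expect_equal(fit$beta, ref[2, 1], tolerance = 1e-8)
    expect_equal(fit$p, ref[2, 4], tolerance = 1e-6)
  }
})

test_that("ZINB log-likelihood matches hand-computed and oracle values", {
  # P(Y=0) = pi + (1-pi) * (theta/(theta+mu))^theta = 0.5 + 0.5/3
  expect_equal(zinb_loglik(0, pi = 0.5, mu = 2, theta = 1), log(2 / 3),
               tolerance = 1e-12)
  # pi = 0 reduces to the plain NB log-likelihood
  y <- c(0, 1, 3, 7)
  expect_equal(zinb_loglik(y, 0, 2.5, 1.5),
               sum(dnbinom(y, size = 1.5, mu = 2.5, log = TRUE)),
               tolerance = 1e-12)
  # additivity over observations
  expect_equal(zinb_loglik(c(y, y), 0.3, 2.5, 1.5),
               2 * zinb_loglik(y, 0.3, 2.5, 1.5), tolerance = 1e-12)
  # pmf-based oracle on random counts/parameters
  set.seed(9)
  for (rep in 1:10) {
    yy <- rpois(20, 3)
    pi <- runif(1, 0, 0.8); mu <- runif(1, 0.5, 10); theta <- runif(1, 0.2, 5)
    expect_equal(zinb_loglik(yy, pi, mu, theta),
                 oracle_zinb_loglik(yy, pi, mu, theta), tolerance = 1e-9)
  }
  expect_error(zinb_loglik(y, pi = 1, mu = 2, theta = 1), "invalid ZINB")
  expect_error(zinb_loglik(y, pi = 0.2, mu = -1, theta = 1), "invalid ZINB")
})

test_that("fit_zinb recovers parameters and honours its optimizer contract", {
  set.seed(101)
  y <- rzinb(2000, pi = 0.3, mu = 5, theta = 2)
  fit <- fit_zinb(y)
  expect_lt(abs(fit$mu - 5) / 5, 0.10)
  expect_lt(abs(fit$pi - 0.3), 0.05)
  # no zero inflation -> pi pushed to the boundary
  y_pos <- rnbinom(2000, size = 5, mu = 20) + 1L
  expect_lte(fit_zinb(y_pos)$pi, 0.02)
  # reported loglik never below the moment initialization
  for (seed in 1:5) {
    set.seed(seed)
    yy <- rzinb(300, pi = runif(1, 0, 0.6), mu = runif(1, 1, 8),
                theta = runif(1, 0.5, 4))
    if (all(yy == 0)) next
    f <- fit_zinb(yy)
    zf <- mean(yy == 0); mu0 <- mean(yy[yy > 0])
    v <- var(yy); m <- mean(yy)
    th0 <- min(max(if (v > m) m^2 / (v - m) else 10, 0.01), 100)
    pi0 <- min(max(zf - dnbinom(0, size = th0, mu = mu0), 0.01), 0.95)
    expect_gte(f$loglik, zinb_loglik(yy, pi0, mu0, th0) - 1e-6)
  }
  # all-zero input is flagged degenerate
  degen <- fit_zinb(rep(0L, 50))
  expect_true(degen$degenerate)
  expect_equal(degen$pi, 1)
})

test_that("fit_zinb is deterministic for a fixed restart seed", {
  set.seed(55)
  y <- rzinb(500, 0.25, 4, 1.5)
  f1 <- fit_zinb(y, seed = 99L)
  f2 <- fit_zinb(y, seed = 99L)
  expect_identical(f1, f2)
})

test_that("ZINB group test recovers a planted two-fold effect", {
  set.seed(606)
  y0 <- rzinb(1000, 0.3, 2, 2)
  y1 <- rzinb(1000, 0.3, 4, 2)
  res <- zinb_group_test(c(y0, y1), rep(c(0, 2), each = 1000))
  expect_lt(res$p, 1e-6)
  expect_equal(res$log2fc, 1, tolerance = 0.2)
  expect_equal(res$df, 3L)
  expect_equal(unname(res$n_per_class), c(1000L, 1000L))
})

test_that("ZINB group test respects nesting, class minima, and missing dosages", {
  set.seed(707)
  y <- rzinb(300, 0.3, 3, 2)
  cl <- sample(c(0, 1, 2), 300, replace = TRUE)
  res <- zinb_group_test(y, cl)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 6L)
  # a class below min_cells is dropped; df shrinks accordingly
  cl2 <- c(rep(0, 150), rep(1, 145), rep(2, 5))
  res2 <- zinb_group_test(y, cl2, min_cells = 10)
  expect_equal(res2$df, 3L)
  # fewer than two usable classes -> skip
  expect_s3_class(zinb_group_test(y, rep(0, 300)), "skipped_fit")
  expect_s3_class(zinb_group_test(y[1:15], c(rep(0, 10), rep(1, 5))),
                  "skipped_fit")
  # missing dosages are excluded pairwise
  cl3 <- cl; cl3[1:50] <- NA
  res3 <- zinb_group_test(y, cl3)
  expect_equal(sum(res3$n_per_class), 250L)
})

test_that("p-value adjustment matches hand-derived step procedures", {
  expect_equal(adjust_pvalues(c(0.005, 0.011, 0.02, 0.04), "BH"),
               c(0.02, 0.022, 0.02667, 0.04), tolerance = 1e-3)
  expect_equal(adjust_pvalues(c(0.01, 0.3), "bonferroni"), c(0.02, 0.6))
  expect_equal(adjust_pvalues(c(0.01, 0.02), "holm"), c(0.02, 0.02))
})

test_that("adjustment preserves order, clips to [0,1], and excludes NaN from m", {
  p <- c(0.04, NA, 0.01, NaN, 0.9)
  adj <- adjust_pvalues(p, "bonferroni")
  expect_true(all(is.na(adj[c(2, 4)])))
  # m = 3 finite entries, not 5
  expect_equal(adj[c(1, 3, 5)], pmin(1, c(0.04, 0.01, 0.9) * 3))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
})

test_that("all five adjustment methods agree with independent oracles", {
  set.seed(808)
  for (rep in 1:50) {
    m <- sample(2:40, 1)
    p <- round(runif(m), 4)
    expect_equal(adjust_pvalues(p, "bonferroni"), oracle_bonferroni(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "holm"), oracle_holm(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "hochberg"), oracle_hochberg(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  for (rep in 1:20) {
    p <- round(runif(sample(2:8, 1)), 4)
    expect_equal(adjust_pvalues(p, "hommel"), oracle_hommel(p), tolerance = 1e-10)
  }
})

test_that("adding null tests never reorders BH significance among existing tests", {
  set.seed(12)
  p <- runif(20)
  base <- adjust_pvalues(p, "BH")
  grown <- adjust_pvalues(c(p, runif(10)), "BH")[1:20]
  # BH is rank-preserving: the relative ordering of the original tests'
  # adjusted p-values cannot change when independent tests are appended
  expect_true(all(diff(base[order(p)]) >= -1e-12))
  expect_true(all(diff(grown[order(p)]) >= -1e-12))
  # bonferroni adjusted p-values are literally non-decreasing in m
  bonf20 <- adjust_pvalues(p, "bonferroni")
  bonf30 <- adjust_pvalues(c(p, runif(10)), "bonferroni")[1:20]
  expect_true(all(bonf30 >= bonf20 - 1e-12))
})
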