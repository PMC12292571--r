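#' Ordinary least-squares association of expression with dosage
#'
#' Fits `y = a + b * d` by OLS and returns the slope with a two-sided
#' p-value from the t statistic on `n - 2` degrees of freedom. Intended for
#' normalized, approximately continuous expression values.
#'
#' @param y numeric expression values per cell (normalized layer).
#' @param d additive allele dosage per cell (0/1/2); `NA` dosages are
#'   dropped pairwise together with their cells.
#' @return list with `beta`, `p`, `n`, or `NULL` with attribute `reason`
#'   when the pair is untestable (fewer than 3 informative cells, or
#'   constant dosage).
#' @export
fit_linear <- function(y, d) {
  ok <- !is.na(d) & !is.na(y)
  y <- y[ok]; d <- d[ok]
  n <- length(y)
  if (n < 3L) return(skip_fit("fewer than 3 cells with genotype"))
  if (length(unique(d)) < 2L) return(skip_fit("constant dosage"))
  if (stats::var(y) == 0) {
    return(list(beta = 0, p = 1, n = n))  # no expression variance to explain
  }
  dbar <- mean(d); ybar <- mean(y)
  sxx <- sum((d - dbar)^2)
  beta <- sum((d - dbar) * (y - ybar)) / sxx
  resid <- y - ybar - beta * (d - dbar)
  sse <- sum(resid^2)
  if (sse <= 0) {
    p <- if (beta == 0) 1 else 0          # exact fit
  } else {
    se <- sqrt(sse / (n - 2) / sxx)
    p <- 2 * stats::pt(abs(beta / se), df = n - 2, lower.tail = FALSE)
  }
  list(beta = beta, p = p, n = n)
}

#' Poisson regression of counts on dosage
#'
#' Maximum-likelihood log-link Poisson regression of raw counts on dosage
#' with an intercept; the slope's two-sided Wald p-value is reported.
#'
#' @param y raw integer counts per cell.
#' @param d additive dosage per cell; `NA` dropped pairwise.
#' @return list with `beta`, `p`, `n`, or `NULL` with attribute `reason`
#'   (constant dosage, all-zero counts, or non-convergence).
#' @export
fit_poisson <- function(y, d) {
  ok <- !is.na(d) & !is.na(y)
  y <- y[ok]; d <- d[ok]
  n <- length(y)
  if (n < 3L) return(skip_fit("fewer than 3 cells with genotype"))
  if (length(unique(d)) < 2L) return(skip_fit("constant dosage"))
  if (all(y == 0)) return(skip_fit("all counts zero"))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, d), y, family = stats::poisson(),
                   control = list(maxit = 50))
  )
  if (!fit$converged) return(skip_fit("Poisson fit did not converge"))
  beta <- fit$coefficients[2]
  # Wald SE from the unscaled covariance of the IRLS fit
  cov <- tryCatch(chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(cov)) return(skip_fit("singular information matrix"))
  se <- sqrt(cov[2, 2])
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  list(beta = unname(beta), p = unname(p), n = n)
}

skip_fit <- function(reason) structure(list(), reason = reason, class = "skipped_fit")

is_skipped <- function(x) inherits(x, "skipped_fit")

#' Zero-inflated negative binomial log-likelihood
#'
#' Evaluates the ZINB log-likelihood
#' `sum_i log( pi * 1(y_i = 0) + (1 - pi) * NB(y_i; mu, theta) )`,
#' where `NB` is the negative binomial pmf with mean `mu` and dispersion
#' (size) `theta`, so `P(Y = 0) = pi + (1 - pi) * (theta / (theta + mu))^theta`.
#'
#' @param y non-negative integer counts.
#' @param pi zero-inflation probability in \[0, 1).
#' @param mu NB mean, > 0.
#' @param theta NB dispersion (size), > 0.
#' @return scalar log-likelihood.
#' @examples
#' zinb_loglik(0, pi = 0.5, mu = 2, theta = 1)  # log(2/3)
#' @export
zinb_loglik <- function(y, pi, mu, theta) {
  if (!(pi >= 0 && pi < 1 && mu > 0 && theta > 0)) {
    stop("invalid ZINB parameters: need 0 <= pi < 1, mu > 0, theta > 0", call. = FALSE)
  }
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers", call. = FALSE)
  lnb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  ll <- log1p(-pi) + lnb
  if (pi > 0) {
    iz <- y == 0
    if (any(iz)) {
      # log(pi + (1-pi) * nb0) via log-sum-exp for stability
      a <- log(pi)
      b <- ll[iz]
      m <- pmax(a, b)
      ll[iz] <- m + log(exp(a - m) + exp(b - m))
    }
  }
  sum(ll)
}

# Aggregated negative log-likelihood over unique count values; same value as
# zinb_loglik but O(#unique counts) per evaluation.
zinb_negll_factory <- function(y) {
  tab <- table(y)
  vals <- as.integer(names(tab))
  wts <- as.numeric(tab)
  function(par) {
    pi <- stats::plogis(par[1]); mu <- exp(par[2]); theta <- exp(par[3])
    if (!is.finite(mu) || !is.finite(theta) || mu <= 0 || theta <= 0) return(1e10)
    lnb <- stats::dnbinom(vals, size = theta, mu = mu, log = TRUE)
    ll <- log1p(-pi) + lnb
    iz <- vals == 0L
    if (pi > 0 && any(iz)) {
      a <- log(pi); b <- ll[iz]; m <- pmax(a, b)
      ll[iz] <- m + log(exp(a - m) + exp(b - m))
    }
    v <- -sum(wts * ll)
    if (!is.finite(v)) 1e10 else v
  }
}

#' Fit a zero-inflated negative binomial by maximum likelihood
#'
#' Parameters are transformed for unconstrained quasi-Newton search
#' (logit for `pi`, log for `mu` and `theta`). Initialization: `mu0` is the
#' mean of the positive counts; `theta0` comes from the method of moments,
#' clipped to \[0.01, 100\]; `pi0` is the excess zero fraction over the NB
#' prediction, clipped to \[0.01, 0.95\]. Two restarts with jittered
#' starting values guard against local optima; the best local maximum is
#' returned and is never below the likelihood at initialization.
#'
#' @param y non-negative integer counts (>= 10 cells recommended).
#' @param restarts number of jittered restarts beyond the moment start.
#' @param seed integer seed for the restart jitter (fixed internally when
#'   `NULL`), so fits are reproducible.
#' @return list with `pi`, `mu`, `theta`, `loglik`, `converged`, and
#'   `degenerate` (TRUE for all-zero input, where `pi -> 1` and the group
#'   is unusable).
#' @examples
#' y <- stats::rnbinom(500, size = 2, mu = 5)
#' y[sample(500, 150)] <- 0L
#' fit_zinb(y)[c("pi", "mu", "theta")]
#' @export
fit_zinb <- function(y, restarts = 2L, seed = NULL) {
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (all(y == 0)) {
    return(list(pi = 1, mu = NA_real_, theta = NA_real_,
                loglik = 0, converged = TRUE, degenerate = TRUE))
  }
  zero_frac <- mean(y == 0)
  mu0 <- mean(y[y > 0])
  v <- stats::var(y); m <- mean(y)
  theta0 <- if (is.finite(v) && v > m) m^2 / (v - m) else 10
  theta0 <- min(max(theta0, 0.01), 100)
  nb0 <- stats::dnbinom(0, size = theta0, mu = mu0)
  pi0 <- min(max(zero_frac - nb0, 0.01), 0.95)

  negll <- zinb_negll_factory(y)
  start <- c(stats::qlogis(pi0), log(mu0), log(theta0))
  starts <- list(start)
  if (restarts > 0L) {
    jit <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
                suppressWarnings(rm(".Random.seed", envir = globalenv())))
      set.seed(seed %||% 104729L)
      lapply(seq_len(restarts), function(i) start + stats::rnorm(3, sd = 0.5))
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(pi = pi0, mu = mu0, theta = theta0, loglik = -negll(start),
                converged = FALSE, degenerate = FALSE))
  }
  # never report a fit worse than the moment initialization
  if (best$value > negll(start)) best <- list(par = start, value = negll(start),
                                              convergence = 1L)
  list(pi = stats::plogis(best$par[1]),
       mu = exp(best$par[2]),
       theta = exp(best$par[3]),
       loglik = -best$value,
       converged = best$convergence == 0L,
       degenerate = FALSE)
}

#' ZINB likelihood-ratio test of expression against genotype classes
#'
#' Null model: one ZINB fit pooled over all cells. Alternative: an
#' independent ZINB fit per genotype class. The statistic
#' `2 * (loglik_alt - loglik_null)` is referred to a chi-square with
#' `3 * (G - 1)` degrees of freedom, G the number of classes, since each
#' class frees all three parameters. The effect size is the log2 ratio of
#' model-implied overall means `(1 - pi) * mu` between the highest- and
#' lowest-dosage classes.
#'
#' Classes with fewer than `min_cells` cells are dropped; the pair is
#' skipped when fewer than two classes remain.
#'
#' @param y raw integer counts per cell.
#' @param classes dosage class per cell (0/1/2); `NA` (missing genotype)
#'   dropped pairwise.
#' @param min_cells minimum cells per class (default 10).
#' @param seed seed forwarded to [fit_zinb()] restarts.
#' @return list with `log2fc`, `p`, `statistic`, `df`, `n_per_class`
#'   (named by class), or a skip marker with attribute `reason`.
#' @export
zinb_group_test <- function(y, classes, min_cells = 10L, seed = NULL) {
  ok <- !is.na(classes) & !is.na(y)
  y <- y[ok]; classes <- classes[ok]
  tab <- table(classes)
  keep_classes <- names(tab)[tab >= min_cells]
  if (length(keep_classes) < 2L) {
    return(skip_fit(sprintf("fewer than 2 genotype classes with >= %d cells", min_cells)))
  }
  sel <- classes %in% keep_classes
  y <- y[sel]; classes <- classes[sel]
  if (all(y == 0)) return(skip_fit("all counts zero"))

  null_fit <- fit_zinb(y, seed = seed)
  if (null_fit$degenerate) return(skip_fit("degenerate pooled fit"))
  lv <- sort(as.numeric(keep_classes))
  fits <- lapply(lv, function(k) {
    yk <- y[classes == k]
    f <- fit_zinb(yk, seed = seed)
    # enforce nesting: a class fit can never be worse than the pooled params
    null_ll <- zinb_loglik_safe(yk, null_fit)
    if (!f$degenerate && f$loglik < null_ll) {
      f <- list(pi = null_fit$pi, mu = null_fit$mu, theta = null_fit$theta,
                loglik = null_ll, converged = TRUE, degenerate = FALSE)
    }
    f
  })
  if (any(vapply(fits, `[[`, logical(1), "degenerate"))) {
    return(skip_fit("all-zero genotype class"))
  }
  alt_ll <- sum(vapply(fits, `[[`, numeric(1), "loglik"))
  stat <- max(0, 2 * (alt_ll - null_fit$loglik))
  G <- length(lv)
  df <- 3L * (G - 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  cm <- vapply(fits, function(f) (1 - f$pi) * f$mu, numeric(1))
  log2fc <- log2(cm[which.max(lv)] / cm[which.min(lv)])
  list(log2fc = unname(log2fc), p = p, statistic = stat, df = df,
       n_per_class = stats::setNames(as.integer(tab[as.character(lv)]),
                                     as.character(lv)))
}

zinb_loglik_safe <- function(y, fit) {
  zinb_loglik(y, pi = min(max(fit$pi, 0), 1 - 1e-12), mu = fit$mu, theta = fit$theta)
}

#' Multiple-testing adjustment
#'
#' Textbook adjustment via the named method, with two contract guarantees:
#' input order is preserved, and non-finite p-values propagate as `NA`
#' without counting toward the number of tests `m`. P-values are floored at
#' 1e-300 before adjustment so numerical zeros survive the step-up/step-down
#' arithmetic.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NA/NaN allowed).
#' @param method one of `"bonferroni"`, `"holm"`, `"hochberg"`, `"hommel"`,
#'   `"BH"`.
#' @return adjusted p-values, same length and order, clipped to \[0, 1\].
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm", "hochberg", "hommel")) {
  method <- match.arg(method)
  out <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  out[ok] <- stats::p.adjust(pmax(p[ok], 1e-300), method = method)
  pmin(out, 1)
}
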