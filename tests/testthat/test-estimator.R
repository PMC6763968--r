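# ML discrepancy, gradients, fitting, SEs, derived quantities, LRT

test_that("ml_discrepancy has its closed-form values and lower bound", {
  S <- random_pd_matrix(5, 1)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  # p = 1 closed form: ln 1 + 2 - ln 2 - 1
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2))
  for (seed in 1:8) {
    S <- random_pd_matrix(4, seed)
    Sig <- random_pd_matrix(4, seed + 100)
    expect_gte(ml_discrepancy(S, Sig), 0)
  }
  expect_identical(ml_discrepancy(S, matrix(0, 4, 4)), Inf)
})

test_that("ml_discrepancy equals -2/n times the loglik ratio to the saturated model", {
  # independent oracle: per-observation normal log-densities of whitened data
  set.seed(42)
  n <- 200; p <- 3
  X <- matrix(rnorm(n * p), n, p) %*% chol(random_pd_matrix(p, 7))
  S_mle <- crossprod(X) / n                      # known zero mean
  dimnames(S_mle) <- list(paste0("v", 1:p), paste0("v", 1:p))
  Sig <- random_pd_matrix(p, 9)
  loglik <- function(Sigma) {
    L <- chol(Sigma)
    Z <- X %*% solve(L)                          # whiten: rows ~ N(0, I)
    sum(dnorm(Z, log = TRUE)) - n * sum(log(diag(L)))
  }
  expect_equal(ml_discrepancy(S_mle, Sig),
               -2 / n * (loglik(Sig) - loglik(S_mle)),
               tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  S <- random_pd_matrix(6, 5)
  dimnames(S) <- list(cycled6_layout()$name, cycled6_layout()$name)
  spec <- build_ar_cfa(cycled6_layout(), "adjacent_plus_construct")
  for (seed in 1:3) {
    th <- random_theta(spec, seed)
    g <- discrepancy_gradient(spec, th, S)
    h <- 1e-6
    fd <- vapply(seq_along(th), function(j) {
      up <- th; up[j] <- up[j] + h
      dn <- th; dn[j] <- dn[j] - h
      (ml_discrepancy(S, implied_covariance(spec, up)$sigma) -
         ml_discrepancy(S, implied_covariance(spec, dn)$sigma)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g), fd, tolerance = 1e-5)
  }
})

test_that("refitting a model to its own implied covariance recovers the truth", {
  spec <- build_ar_cfa(cycled8_layout(), "adjacent_plus_construct")
  th <- random_theta(spec, 21)
  # keep the synthetic truth well inside the admissible region
  th[grepl("^ar", names(th))] <- th[grepl("^ar", names(th))] * 0.5
  sigma <- implied_covariance(spec, th)$sigma
  mom <- sample_moments(sigma, 1000)
  fit <- fit_cfa(spec, mom, se = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$F_min, 1e-8)
  expect_equal(fit$theta, th[names(fit$theta)], tolerance = 1e-4)
})

test_that("chi-square scales as (N-1) * F and SEs shrink as 1/sqrt(N)", {
  spec <- build_ic_cfa(cycled6_layout())
  pop <- make_population(0, loading = 0.7, factor_corr = 0.3,
                         layout = cycled6_layout(), topology = "adjacent")
  dat <- simulate_dataset(pop, 400, seed = 5)
  S <- cov(as.matrix(dat))
  f1 <- fit_cfa(spec, sample_moments(S, 400))
  f2 <- fit_cfa(spec, sample_moments(S, 799))
  expect_equal(f1$chi2, 399 * f1$F_min)
  expect_equal(f1$F_min, f2$F_min, tolerance = 1e-8)
  expect_equal(unname(f2$se / f1$se), rep(sqrt(399 / 798), length(f1$se)),
               tolerance = 1e-4)
})

test_that("non-convergence is reported, never silent", {
  # one-factor model on anti-structural moments: force a hard problem by
  # giving the optimizer a single iteration
  mom <- sample_moments(random_pd_matrix(3, 3), 100)
  rownames(mom$S) <- colnames(mom$S) <- tiny_layout()$name
  mom$names <- rownames(mom$S)
  spec <- build_ic_cfa(tiny_layout())
  expect_warning(
    f <- fit_cfa(spec, mom, se = FALSE, max_iter = 1L, n_starts = 1L,
                 grad_tol = 1e-300),
    "did not fully converge")
  expect_false(f$converged)
})

test_that("standardized solution is scale-consistent", {
  fit <- minipip_ic_fit()
  std <- fit$standardized
  # standardized loading = raw loading / implied SD
  lam_raw <- fit$matrices$Lambda[cbind(std$loadings$item, std$loadings$trait)]
  expect_equal(std$loadings$loading,
               unname(lam_raw / sqrt(diag(fit$sigma)[std$loadings$item])))
  # with unit factor variances the factor correlations are the raw psi
  expect_equal(std$factor_correlations$correlation,
               fit$matrices$Psi[cbind(std$factor_correlations$trait1,
                                      std$factor_correlations$trait2)])
  expect_true(all(abs(std$factor_correlations$correlation) <= 1))
  # IC-CFA: no AR input, so every item keeps its full innovation
  expect_equal(std$loadings$innovation_share, rep(1, 20))
  expect_equal(std$loadings$resid_total, 1 - std$loadings$loading^2,
               tolerance = 1e-12)
})

test_that("delta-method group means reduce to single coefficients and average correctly", {
  fit <- minipip_ar_fit()
  single <- derived_group_mean(fit, "ar.e2.a2")
  expect_equal(single$estimate, unname(fit$theta["ar.e2.a2"]))
  expect_equal(single$se, unname(fit$se["ar.e2.a2"]), tolerance = 1e-10)
  grp <- c("ar.e2.a2", "ar.e3.a3", "ar.e4.a4")
  avg <- derived_group_mean(fit, grp, label = "e->a")
  expect_equal(avg$estimate, mean(fit$theta[grp]))
  expect_equal(avg$t, avg$estimate / avg$se)
  expect_error(derived_group_mean(fit, character(0)), "empty")
  expect_error(derived_group_mean(fit, "loading.e1"), "AR parameters")
  expect_error(derived_group_mean(fit, "ar.bogus.x"), "not free parameters")
})

test_that("likelihood-ratio tests respect nesting structure", {
  ic <- minipip_ic_fit()
  ar <- minipip_ar_fit()
  lrt <- likelihood_ratio_test(ic, ar)
  expect_true(lrt$nested)
  expect_equal(lrt$delta_df, 34L)
  expect_equal(lrt$delta_chi2, ic$chi2 - ar$chi2)
  expect_lt(lrt$p_value, 0.001)
  # identical fits
  self <- likelihood_ratio_test(ic, ic)
  expect_equal(self$delta_chi2, 0)
  expect_equal(self$delta_df, 0L)
  # RC-CFA has the same df but a different parameter space: refused
  rc <- cached("rc_fit", function()
    fit_cfa(build_rc_cfa(build_ar_cfa(minipip_layout())), minipip_moments(),
            se = FALSE))
  cmp <- likelihood_ratio_test(rc, ar)
  expect_false(cmp$nested)
  expect_true(is.na(cmp$p_value))
  expect_equal(cmp$delta_df, 0L)
})

test_that("fitting an AR-CFA to AR-free data does no harm", {
  pop <- make_population(0, loading = 0.8, factor_corr = 0.2)
  dat <- simulate_dataset(pop, 20000, seed = 314)
  mom <- read_raw(dat)
  fit <- fit_cfa(build_ar_cfa(minipip_layout()), mom, se = FALSE)
  expect_true(fit$converged)
  std <- fit$standardized
  # individual AR terms differ widely in precision (within-construct terms
  # are weakly identified); the ensemble must be centered at zero
  expect_lt(abs(mean(std$ar$estimate)), 0.02)
  expect_lt(max(abs(std$ar$estimate)), 0.15)
  expect_equal(mean(std$loadings$loading), 0.8, tolerance = 0.02)
  expect_equal(mean(std$factor_correlations$correlation), 0.2,
               tolerance = 0.03)
})
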