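#' Population model for simulation
#'
#' Fixes every parameter of an AR-CFA (or IC-CFA when `ar = 0`) to a true
#' value: all loadings equal, all factor correlations equal, all AR
#' coefficients of the chosen topology equal, and residual (innovation)
#' variances solved item-by-item so every implied item variance is exactly 1
#' -- which makes the supplied loading the standardized loading. The solve
#' proceeds in administration order because earlier items' innovations feed
#' later items' totals through the AR propagator.
#'
#' @param ar true AR coefficient (|ar| < 1), applied to every AR entry.
#' @param loading true standardized loading, default 0.8.
#' @param factor_corr true factor correlation, default 0.2.
#' @param layout an [item_layout()], default [minipip_layout()].
#' @param topology AR topology as in [build_ar_cfa()]; irrelevant when
#'   `ar = 0` apart from which entries exist.
#' @return object of class `population_model`: the generating matrices, the
#'   implied covariance `sigma` (unit diagonal) and the layout.
#' @export
make_population <- function(ar, loading = 0.8, factor_corr = 0.2,
                            layout = minipip_layout(),
                            topology = "adjacent_plus_construct") {
  stopifnot(abs(ar) < 1)
  spec <- build_ar_cfa(layout, topology)
  items <- layout$name[order(layout$position)]
  traits <- layout_traits(layout)
  p <- length(items); m <- length(traits)
  Lambda <- matrix(0, p, m, dimnames = list(items, traits))
  trait_of <- stats::setNames(layout$trait, layout$name)
  Lambda[cbind(items, trait_of[items])] <- loading
  Psi <- matrix(factor_corr, m, m, dimnames = list(traits, traits))
  diag(Psi) <- 1
  if (min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor correlation ", factor_corr, " makes Psi non-PD for m = ", m)
  kappa <- matrix(0, p, p, dimnames = list(items, items))
  pr <- ar_pairs(layout, topology)
  kappa[cbind(pr$row, pr$col)] <- ar
  B <- ar_propagator(kappa)
  common_diag <- diag(Lambda %*% Psi %*% t(Lambda))
  # forward solve: sigma_ii = common_ii + theta_ii + sum_{j<i} B_ij^2 theta_jj
  theta <- numeric(p)
  for (i in seq_len(p)) {
    prior <- if (i > 1) sum(B[i, 1:(i - 1)]^2 * theta[1:(i - 1)]) else 0
    theta[i] <- 1 - common_diag[i] - prior
    if (theta[i] <= 0)
      stop("no admissible residual variance for item ", items[i],
           " (needs ", format(theta[i]), "); reduce |ar| or the loading")
  }
  Theta <- diag(theta); dimnames(Theta) <- list(items, items)
  imp <- implied_from_matrices(list(Lambda = Lambda, Psi = Psi,
                                    Theta = Theta, kappa = kappa))
  structure(list(layout = layout, topology = topology,
                 Lambda = Lambda, Psi = Psi, Theta = Theta, kappa = kappa,
                 sigma = imp$sigma, propagator = imp$propagator,
                 truth = c(loading = loading, factor_corr = factor_corr,
                           ar = ar)),
            class = "population_model")
}

#' Simulate item responses from a population model
#'
#' Draws latent traits `eta ~ MVN(0, Psi)` and innovations `u ~ MVN(0,
#' Theta)`, propagates the innovations through the AR structure
#' (`eps = (I - kappa)^-1 u`) and assembles `y = Lambda eta + eps`. With
#' `likert = k` the continuous responses are additionally discretized into
#' `k` ordered categories by equal-probability thresholds of the standard
#' normal (items have unit variance by construction).
#'
#' @param pop a [make_population()] object.
#' @param n number of respondents.
#' @param seed integer seed; same seed, same table.
#' @param likert `NULL` (continuous, default) or an integer >= 2.
#' @return data frame, `n` rows, one numeric column per item in
#'   administration order.
#' @export
simulate_dataset <- function(pop, n, seed = NULL, likert = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(pop$Lambda); m <- ncol(pop$Lambda)
  eta <- matrix(stats::rnorm(n * m), n, m) %*% chol(pop$Psi)
  u <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(diag(pop$Theta)))
  eps <- u %*% t(pop$propagator)
  y <- eta %*% t(pop$Lambda) + eps
  colnames(y) <- rownames(pop$Lambda)
  if (!is.null(likert)) {
    k <- as.integer(likert)
    stopifnot(k >= 2)
    cuts <- stats::qnorm(seq_len(k - 1) / k)
    y <- apply(y, 2, function(col) findInterval(col, cuts) + 1L)
  }
  as.data.frame(y)
}

#' Monte Carlo parameter-recovery study
#'
#' Runs the full factorial of sample sizes by true AR values: in each cell,
#' `replications` datasets are simulated from [make_population()] and each
#' requested model is fitted. Per-replication seeds are derived
#' deterministically from the master seed, so the whole summary is
#' reproducible bit for bit. Non-converged replications are recorded,
#' excluded from bias/RMSE, and counted against the convergence rate.
#'
#' @param sample_sizes integer vector, e.g. `c(250, 500, 1000)`.
#' @param ar_values numeric vector of true AR coefficients, e.g.
#'   `c(0, 0.1, 0.2, 0.3)`.
#' @param replications per cell; default 500, with 100 as the documented
#'   reduced desk-scale mode.
#' @param seed master seed.
#' @param models subset of `c("ic_cfa", "ar_cfa")` to fit.
#' @param layout,topology,loading,factor_corr population settings, see
#'   [make_population()].
#' @return object of class `mc_summary`: data frame with one row per
#'   (N, ar, model, parameter class) holding mean estimate, bias, RMSE, and
#'   per (N, ar, model) convergence rate and mean CFI/RMSEA.
#' @export
run_monte_carlo <- function(sample_sizes, ar_values, replications = 500L,
                            seed = 1L, models = c("ic_cfa", "ar_cfa"),
                            layout = minipip_layout(),
                            topology = "adjacent_plus_construct",
                            loading = 0.8, factor_corr = 0.2) {
  stopifnot(replications >= 1, all(sample_sizes > n_items(layout)))
  models <- match.arg(models, several.ok = TRUE)
  specs <- list(ic_cfa = build_ic_cfa(layout),
                ar_cfa = build_ar_cfa(layout, topology))[models]
  rows <- list()
  cell_id <- 0L
  for (ar in ar_values) {
    pop <- make_population(ar, loading, factor_corr, layout, topology)
    truth <- pop$truth
    for (N in sample_sizes) {
      cell_id <- cell_id + 1L
      acc <- list()
      for (mdl in models)
        acc[[mdl]] <- list(loading = c(), factor_corr = c(), ar = c(),
                           cfi = c(), rmsea = c(), conv = logical(0))
      for (r in seq_len(replications)) {
        rep_seed <- (seed * 10007L + cell_id * 211L + r) %% 2147483647L
        dat <- simulate_dataset(pop, N, seed = rep_seed)
        mom <- sample_moments(stats::cov(as.matrix(dat)), N)
        base <- baseline_fit(mom, layout)
        for (mdl in models) {
          f <- suppressWarnings(
            tryCatch(fit_cfa(specs[[mdl]], mom, se = FALSE),
                     error = function(e) NULL))
          ok <- !is.null(f) && f$converged
          acc[[mdl]]$conv <- c(acc[[mdl]]$conv, ok)
          if (!ok) next
          std <- f$standardized
          acc[[mdl]]$loading <- c(acc[[mdl]]$loading,
                                  mean(std$loadings$loading))
          acc[[mdl]]$factor_corr <- c(acc[[mdl]]$factor_corr,
                                      mean(std$factor_correlations$correlation))
          if (!is.null(std$ar))
            acc[[mdl]]$ar <- c(acc[[mdl]]$ar, mean(std$ar$estimate))
          ix <- fit_indices(f, base)
          acc[[mdl]]$cfi <- c(acc[[mdl]]$cfi, ix$cfi)
          acc[[mdl]]$rmsea <- c(acc[[mdl]]$rmsea, ix$rmsea)
        }
      }
      for (mdl in models) {
        a <- acc[[mdl]]
        tr <- c(loading = truth[["loading"]],
                factor_corr = truth[["factor_corr"]],
                ar = truth[["ar"]])
        vals <- list(loading = a$loading, factor_corr = a$factor_corr)
        if (mdl == "ar_cfa") vals$ar <- a$ar
        for (cls in names(vals)) {
          v <- vals[[cls]]
          rows[[length(rows) + 1L]] <- data.frame(
            N = N, ar_true = ar, model = mdl, class = cls,
            n_converged = sum(a$conv), replications = replications,
            convergence_rate = mean(a$conv),
            mean_estimate = if (length(v)) mean(v) else NA_real_,
            bias = if (length(v)) mean(v) - tr[[cls]] else NA_real_,
            rmse = if (length(v)) sqrt(mean((v - tr[[cls]])^2)) else NA_real_,
            mc_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
            mean_cfi = if (length(a$cfi)) mean(a$cfi) else NA_real_,
            mean_rmsea = if (length(a$rmsea)) mean(a$rmsea) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mc_summary", "data.frame")
  out
}
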