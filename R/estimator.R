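#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The standard normal-theory ML fit function
#' \deqn{F = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p,}
#' which is zero iff `Sigma == S` and equals `-2/(N-1)` times the
#' log-likelihood ratio to the saturated model. A non-positive-definite
#' `Sigma` is an inadmissible point and returns `Inf` rather than an error so
#' optimizers can retreat from it.
#'
#' @param S sample covariance matrix (symmetric positive definite).
#' @param Sigma model-implied covariance matrix of the same order.
#' @return the discrepancy value (non-negative at admissible points).
#' @export
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p, ncol(S) == p)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet_sigma <- 2 * sum(log(diag(ch)))
  logdet_s <- 2 * sum(log(diag(chol(S))))
  sigma_inv <- chol2inv(ch)
  logdet_sigma + sum(S * sigma_inv) - logdet_s - p
}

# ---- internal parameterization -------------------------------------------
# Residual variances travel on the log scale inside the optimizer so Theta's
# diagonal stays positive; everything else is unconstrained. Psi inherits
# admissibility from the PD check on Sigma plus an explicit eigenvalue floor.

slot_info <- function(spec) {
  idx <- parameter_index(spec)
  e <- spec$entries
  mat_by_slot <- rep(NA_character_, length(idx$labels))
  for (k in seq_len(nrow(e))) {
    s <- idx$slot[k]
    if (!is.na(s) && is.na(mat_by_slot[s])) mat_by_slot[s] <- e$matrix[k]
  }
  list(labels = idx$labels, slot = idx$slot, matrix = mat_by_slot,
       is_var = mat_by_slot == "residual_var")
}

to_internal <- function(theta, info) {
  x <- theta
  x[info$is_var] <- log(theta[info$is_var])
  x
}

from_internal <- function(x, info) {
  theta <- x
  theta[info$is_var] <- exp(x[info$is_var])
  theta
}

#' Default start values
#'
#' Loadings start at 0.7 times the item's sample SD, factor correlations at
#' 0.2, AR coefficients and residual covariances at 0, residual variances at
#' half the item's sample variance. These conventional values keep the
#' initial implied covariance positive definite.
#'
#' @param spec a `cfa_model`.
#' @param moments a [sample_moments()] object.
#' @return named numeric vector over the distinct free parameters.
#' @export
start_values <- function(spec, moments) {
  info <- slot_info(spec)
  e <- spec$entries
  idx <- parameter_index(spec)
  s_var <- diag(moments$S)
  start <- numeric(length(info$labels))
  seen <- logical(length(info$labels))
  for (k in seq_len(nrow(e))) {
    s <- idx$slot[k]
    if (is.na(s) || seen[s]) next
    seen[s] <- TRUE
    start[s] <- switch(e$matrix[k],
      loading = 0.7 * sqrt(s_var[[e$row[k]]]),
      factor_cov = 0.2,
      ar = 0,
      residual_var = 0.5 * s_var[[e$row[k]]],
      residual_cov = 0
    )
    if (!is.na(e$start[k])) start[s] <- e$start[k]
  }
  stats::setNames(start, info$labels)
}

# discrepancy and its analytic gradient w.r.t. the natural parameters
# dF = tr(G dSigma), G = Sigma^-1 (Sigma - S) Sigma^-1
objective_and_gradient <- function(spec, theta, S, eig_floor = 1e-8) {
  mats <- materialize(spec, theta)
  if (any(mats$Lambda != 0)) {  # Psi only enters Sigma through Lambda
    psi_eig <- eigen(mats$Psi, symmetric = TRUE, only.values = TRUE)$values
    if (min(psi_eig) < eig_floor)
      return(list(F = 1e10 + sum(theta^2), grad = 2 * theta,
                  admissible = FALSE))
  }
  imp <- implied_from_matrices(mats)
  ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
  if (is.null(ch))
    return(list(F = 1e10 + sum(theta^2), grad = 2 * theta, admissible = FALSE))
  sigma_inv <- chol2inv(ch)
  Fval <- 2 * sum(log(diag(ch))) + sum(S * sigma_inv) -
    attr(S, "logdet") - nrow(S)
  G <- sigma_inv %*% (imp$sigma - S) %*% sigma_inv
  G <- (G + t(G)) / 2
  dimnames(G) <- dimnames(imp$sigma)

  B <- imp$propagator
  R <- imp$residual
  GLP <- G %*% mats$Lambda %*% mats$Psi      # p x m
  LGL <- t(mats$Lambda) %*% G %*% mats$Lambda # m x m
  BGB <- t(B) %*% G %*% B                     # p x p
  BGR <- t(B) %*% G %*% R                     # p x p

  e <- spec$entries
  idx <- parameter_index(spec)
  grad <- numeric(length(idx$labels))
  for (k in seq_len(nrow(e))) {
    s <- idx$slot[k]
    if (is.na(s)) next
    r <- e$row[k]; cc <- e$col[k]
    g <- switch(e$matrix[k],
      loading = 2 * GLP[r, cc],
      factor_cov = if (r == cc) LGL[r, r] else 2 * LGL[r, cc],
      ar = 2 * BGR[r, cc],
      residual_var = BGB[r, r],
      residual_cov = 2 * BGB[r, cc]
    )
    grad[s] <- grad[s] + g
  }
  list(F = Fval, grad = grad, admissible = TRUE,
       sigma = imp$sigma, propagator = B, residual = R, matrices = mats)
}

#' Gradient of the ML discrepancy
#'
#' Analytic gradient of [ml_discrepancy()] composed with
#' [implied_covariance()], with respect to the distinct free parameters on
#' their natural scale. Exposed mainly so it can be cross-checked against
#' finite differences.
#'
#' @param spec a `cfa_model`.
#' @param theta free-parameter vector.
#' @param S sample covariance (dimnames matching the layout).
#' @return named numeric gradient vector.
#' @export
discrepancy_gradient <- function(spec, theta, S) {
  S <- align_S(spec, S)
  og <- objective_and_gradient(spec, theta, S)
  stats::setNames(og$grad, parameter_index(spec)$labels)
}

align_S <- function(spec, S) {
  items <- spec$layout$name[order(spec$layout$position)]
  if (!all(items %in% rownames(S)))
    stop("sample moments do not cover all layout items")
  S <- S[items, items]
  attr(S, "logdet") <- 2 * sum(log(diag(chol(S))))
  S
}

#' Fit a CFA specification by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance and the
#' model-implied covariance with a quasi-Newton optimizer (PORT routines via
#' [stats::nlminb()]), using analytic gradients. Residual variances are
#' log-parameterized internally so the innovation covariance stays positive;
#' reported estimates are on the natural scale. On failure to meet the
#' gradient tolerance the fit is restarted from up to `n_starts - 1` jittered
#' start vectors and the best admissible solution is kept; a fit that still
#' fails is returned with `converged = FALSE`, never as a silent success.
#'
#' @param spec a `cfa_model`.
#' @param moments a [sample_moments()] object with matching item names.
#' @param se compute standard errors (observed-information; default TRUE).
#' @param start optional named start vector overriding [start_values()].
#' @param grad_tol convergence tolerance on the largest absolute component of
#'   the gradient of the discrepancy on the optimization (internal) scale,
#'   where log-parameterized residual variances make a boundary (Heywood)
#'   solution a genuine stationary point.
#' @param n_starts total number of starts attempted on non-convergence.
#' @param max_iter iteration cap passed to the optimizer.
#' @return object of class `cfa_fit`: estimates, SEs, parameter covariance,
#'   `F_min`, `chi2 = (N-1) F_min`, df, log-likelihood, convergence
#'   diagnostics, materialized matrices, implied covariance and the
#'   standardized solution.
#' @export
fit_cfa <- function(spec, moments, se = TRUE, start = NULL,
                    grad_tol = 1e-6, n_starts = 3L, max_iter = 1000L) {
  stopifnot(inherits(moments, "sample_moments"))
  S <- align_S(spec, moments$S)
  N <- moments$N
  info <- slot_info(spec)
  q <- length(info$labels)
  if (q == 0) stop("spec has no free parameters")
  theta0 <- if (is.null(start)) start_values(spec, moments) else start[info$labels]

  obj <- function(x) {
    og <- objective_and_gradient(spec, from_internal(x, info), S)
    og$F
  }
  grad <- function(x) {
    theta <- from_internal(x, info)
    og <- objective_and_gradient(spec, theta, S)
    g <- og$grad
    g[info$is_var] <- g[info$is_var] * theta[info$is_var]  # chain rule
    g
  }

  best <- NULL
  set_jitter <- function(attempt) {
    if (attempt == 1) return(theta0)
    scale <- 0.25 * pmax(abs(theta0), 0.1) * ifelse(info$is_var, 0.2, 1)
    theta0 + stats::rnorm(q, 0, scale)
  }
  # gradient on the internal scale: the chain rule turns the natural-scale
  # gradient of log-parameterized variances into theta * dF/dtheta, which
  # also vanishes at a boundary (Heywood) optimum with a variance pinned at 0
  grad_internal <- function(x) {
    theta <- from_internal(x, info)
    g <- objective_and_gradient(spec, theta, S)$grad
    g[info$is_var] <- g[info$is_var] * theta[info$is_var]
    g
  }
  for (attempt in seq_len(n_starts)) {
    th_start <- set_jitter(attempt)
    th_start[info$is_var] <- pmax(th_start[info$is_var], 1e-3)
    opt <- stats::nlminb(to_internal(th_start, info), obj, grad,
                         control = list(iter.max = max_iter,
                                        eval.max = 4 * max_iter,
                                        rel.tol = 1e-14, x.tol = 1e-12))
    # quasi-Newton optimizers stop on relative progress, a hair short of the
    # gradient tolerance; a few safeguarded Newton steps finish the job
    pol <- newton_polish(opt$par, obj, grad_internal, grad_tol)
    theta_hat <- from_internal(pol$x, info)
    og <- objective_and_gradient(spec, theta_hat, S)
    gnorm <- max(abs(pol$grad))
    cand <- list(opt = opt, theta = theta_hat, og = og, grad_norm = gnorm)
    if (is.null(best) || og$F < best$og$F) best <- cand
    if (og$admissible && gnorm < grad_tol) { best <- cand; break }
  }

  theta_hat <- stats::setNames(best$theta, info$labels)
  og <- best$og
  F_min <- og$F
  df <- model_df(spec)
  chi2 <- (N - 1) * F_min
  p <- nrow(S)
  loglik <- -(N - 1) / 2 *
    (p * log(2 * pi) + 2 * sum(log(diag(chol(og$sigma)))) +
       sum(S * chol2inv(chol(og$sigma))))

  # the Hessian also feeds the convergence diagnosis (must be PD at optimum)
  vc <- NULL; se_vec <- rep(NA_real_, q)
  hess <- f_hessian(spec, theta_hat, S)
  eh <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
  hess_pd <- min(eh) > 0
  if (se && hess_pd) {
    vc <- tryCatch(solve((N - 1) / 2 * hess), error = function(e) NULL)
    if (!is.null(vc)) {
      dimnames(vc) <- list(info$labels, info$labels)
      dv <- diag(vc)
      se_vec <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
    }
  }

  boundary <- info$is_var & theta_hat < 1e-6
  if (any(boundary))
    warning("residual variance(s) at the zero boundary (Heywood case): ",
            paste(info$labels[boundary], collapse = ", "), call. = FALSE)
  converged <- og$admissible && best$grad_norm < grad_tol &&
    (hess_pd || any(boundary))
  if (!converged)
    warning("fit did not fully converge (grad norm = ",
            format(best$grad_norm, digits = 3),
            if (!hess_pd) ", Hessian not positive definite" else "",
            "); inspect diagnostics before interpreting", call. = FALSE)

  fit <- structure(list(
    spec = spec, theta = theta_hat,
    se = stats::setNames(se_vec, info$labels), vcov = vc,
    F_min = F_min, chi2 = chi2, df = df, n_free = q, N = N,
    loglik = loglik, converged = converged, grad_norm = best$grad_norm,
    hessian_pd = hess_pd, iterations = best$opt$iterations,
    matrices = og$matrices, sigma = og$sigma, S = S,
    propagator = og$propagator, residual_cov_implied = og$residual
  ), class = "cfa_fit")
  fit$standardized <- standardize(fit)
  fit
}

# safeguarded Newton refinement on the internal scale (so positivity of the
# log-parameterized variances is preserved); accepts a step only if it lowers
# F or the gradient norm (with halving), stops at the gradient tolerance
newton_polish <- function(x, fn, gr, grad_tol, max_steps = 25L, h_rel = 1e-5) {
  g <- gr(x)
  Fval <- fn(x)
  for (step in seq_len(max_steps)) {
    if (!is.finite(Fval) || max(abs(g)) < grad_tol) break
    q <- length(x)
    H <- matrix(0, q, q)
    for (j in seq_len(q)) {
      h <- h_rel * max(1, abs(x[j]))
      up <- x; up[j] <- up[j] + h
      dn <- x; dn[j] <- dn[j] - h
      H[, j] <- (gr(up) - gr(dn)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    dir <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(dir)) break
    improved <- FALSE
    scale <- 1
    for (half in 1:8) {
      cand <- x - scale * dir
      F_c <- fn(cand)
      if (is.finite(F_c) && F_c < 1e9) {
        g_c <- gr(cand)
        if (F_c < Fval || max(abs(g_c)) < max(abs(g))) {
          x <- cand; Fval <- F_c; g <- g_c; improved <- TRUE
          break
        }
      }
      scale <- scale / 2
    }
    if (!improved) break
  }
  list(x = x, grad = g, F = Fval)
}

# central-difference Hessian of F on the natural scale, built from the
# analytic gradient (accurate to O(h^2) in second derivatives)
f_hessian <- function(spec, theta, S, h_rel = 1e-5) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    h <- h_rel * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    gu <- objective_and_gradient(spec, up, S)$grad
    gd <- objective_and_gradient(spec, dn, S)$grad
    H[, j] <- (gu - gd) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("ML fit of %s: chi2(%d) = %.2f, N = %d\n",
              x$spec$model, x$df, x$chi2, x$N))
  if (!x$converged)
    cat("  *** WARNING: NOT CONVERGED (grad norm ",
        format(x$grad_norm, digits = 3), ") ***\n", sep = "")
  cat(sprintf("  F_min = %.6f, logLik = %.2f, free parameters = %d\n",
              x$F_min, x$loglik, x$n_free))
  invisible(x)
}

#' Parameter table of a fitted model
#'
#' One row per distinct free parameter with estimate, SE, t (estimate/SE)
#' and two-sided normal p-value, matching the reporting conventions of SEM
#' software.
#'
#' @param fit a `cfa_fit`.
#' @return data frame.
#' @export
parameter_table <- function(fit) {
  info <- slot_info(fit$spec)
  est <- fit$theta
  se <- fit$se
  t <- est / se
  data.frame(label = info$labels, matrix = info$matrix,
             estimate = unname(est), se = unname(se), t = unname(t),
             p_value = 2 * stats::pnorm(-abs(unname(t))),
             stringsAsFactors = FALSE)
}

#' Standardized solution
#'
#' Loadings are rescaled to the unit-variance observed metric (latent
#' variances are already fixed at 1, so standardized factor correlations are
#' the raw Psi off-diagonals). For each item the table reports the total
#' residual proportion of variance (`resid_total`, 1 minus the squared
#' standardized loading under a single-factor-per-item structure) and the
#' innovation share `innovation_share` = Theta_ii over the full residual
#' variance (1 for items receiving no AR input). AR coefficients are
#' standardized to the unit-variance residual metric.
#'
#' @param fit a `cfa_fit`.
#' @return list with data frames `loadings`, `factor_correlations`, `ar`.
#' @export
standardize <- function(fit) {
  m <- fit$matrices
  sig <- diag(fit$sigma)
  R <- fit$residual_cov_implied
  items <- rownames(m$Lambda)
  loadings <- NULL
  if (any(m$Lambda != 0)) {
    tr_of <- apply(m$Lambda != 0, 1,
                   function(z) colnames(m$Lambda)[which(z)[1]])
    # scale by sqrt(psi)/sd(item); psi is fixed at 1 here but keep general
    lam <- m$Lambda[cbind(items, unname(tr_of))]
    psi_d <- diag(m$Psi)[unname(tr_of)]
    loadings <- data.frame(
      item = items, trait = unname(tr_of),
      loading = unname(lam * sqrt(psi_d) / sqrt(sig[items])),
      resid_total = unname(diag(R)[items] / sig[items]),
      innovation_share = unname(diag(m$Theta)[items] / diag(R)[items]),
      stringsAsFactors = FALSE
    )
  }

  traits <- colnames(m$Psi)
  fc <- NULL
  if (length(traits) > 1 && any(m$Psi != 0)) {
    pr <- utils::combn(traits, 2)
    d <- sqrt(diag(m$Psi))
    fc <- data.frame(
      trait1 = pr[1, ], trait2 = pr[2, ],
      correlation = m$Psi[cbind(pr[1, ], pr[2, ])] /
        (d[pr[1, ]] * d[pr[2, ]]),
      stringsAsFactors = FALSE
    )
    rownames(fc) <- NULL
  }

  e <- fit$spec$entries
  are <- e[e$matrix == "ar", , drop = FALSE]
  ar <- NULL
  if (nrow(are)) {
    raw <- m$kappa[cbind(are$row, are$col)]
    ar <- data.frame(
      source = are$col, target = are$row, estimate = raw,
      std = raw * sqrt(diag(R)[are$col] / diag(R)[are$row]),
      stringsAsFactors = FALSE
    )
  }
  list(loadings = loadings, factor_correlations = fc, ar = ar)
}

#' Delta-method average of a group of AR effects
#'
#' Omnibus summaries of similar AR effects: the arithmetic mean of the named
#' coefficients, with its standard error propagated through the fitted
#' parameter covariance matrix (for a mean `a'theta` the variance is
#' `a' V a`), a normal t statistic and two-sided p-value.
#'
#' @param fit a converged `cfa_fit` with a parameter covariance matrix.
#' @param group character vector of free AR parameter labels, e.g.
#'   `c("ar.e2.a2", "ar.e3.a3", "ar.e4.a4")` (source.target naming), or of
#'   equality labels.
#' @param label optional name for the derived quantity.
#' @return data frame with one row: label, estimate, se, t, p_value.
#' @export
derived_group_mean <- function(fit, group, label = NULL) {
  if (length(group) == 0) stop("empty group")
  info <- slot_info(fit$spec)
  miss <- setdiff(group, info$labels)
  if (length(miss))
    stop("not free parameters of this fit: ", paste(miss, collapse = ", "))
  if (!all(info$matrix[match(group, info$labels)] == "ar"))
    stop("group members must be AR parameters")
  if (is.null(fit$vcov)) stop("fit has no parameter covariance matrix")
  a <- stats::setNames(numeric(length(info$labels)), info$labels)
  a[group] <- 1 / length(group)
  est <- sum(a * fit$theta)
  se <- sqrt(drop(t(a) %*% fit$vcov %*% a))
  t <- est / se
  data.frame(label = if (is.null(label)) paste(group, collapse = "+") else label,
             estimate = est, se = se, t = t,
             p_value = 2 * stats::pnorm(-abs(t)),
             stringsAsFactors = FALSE)
}

# structural nesting check: every free entry of the restricted spec is free
# in the full spec, and the full spec ties no pair of entries that the
# restricted spec leaves untied
is_nested_spec <- function(restricted, full) {
  key <- function(s) {
    e <- s$entries[s$entries$free, , drop = FALSE]
    paste(e$matrix, e$row, e$col)
  }
  if (!identical(restricted$layout$name, full$layout$name)) return(FALSE)
  kr <- key(restricted); kf <- key(full)
  if (!all(kr %in% kf)) return(FALSE)
  # equality partition of full must be at least as fine on shared entries
  lab_of <- function(s) {
    e <- s$entries
    stats::setNames(entry_labels(s), paste(e$matrix, e$row, e$col))
  }
  lr <- lab_of(restricted); lf <- lab_of(full)
  shared <- intersect(names(lr)[!is.na(lr)], names(lf)[!is.na(lf)])
  for (g in unique(lf[shared])) {
    members <- shared[lf[shared] == g]
    if (length(unique(lr[members])) > 1) return(FALSE)
  }
  TRUE
}

#' Likelihood-ratio (chi-square difference) test of nested fits
#'
#' For structurally nested specifications the test statistic is
#' `chi2_restricted - chi2_full` on `df_restricted - df_full` degrees of
#' freedom. Non-nested pairs (e.g. AR-CFA vs RC-CFA, which have equal df but
#' different parameter spaces) are refused the chi-square test and reported
#' descriptively through AIC/BIC differences.
#'
#' @param fit_restricted,fit_full `cfa_fit` objects on the same moments.
#' @return data frame with `delta_chi2`, `delta_df`, `p_value` (NA when not
#'   nested), `delta_aic`, `delta_bic` (restricted minus full) and `nested`.
#' @export
likelihood_ratio_test <- function(fit_restricted, fit_full) {
  nested <- is_nested_spec(fit_restricted$spec, fit_full$spec)
  d_chi2 <- fit_restricted$chi2 - fit_full$chi2
  d_df <- fit_restricted$df - fit_full$df
  aic <- function(f) -2 * f$loglik + 2 * f$n_free
  bic <- function(f) -2 * f$loglik + f$n_free * log(f$N)
  out <- data.frame(
    delta_chi2 = d_chi2, delta_df = d_df,
    p_value = if (nested && d_df > 0)
      stats::pchisq(d_chi2, d_df, lower.tail = FALSE)
    else if (nested && d_df == 0) NA_real_ else NA_real_,
    delta_aic = aic(fit_restricted) - aic(fit_full),
    delta_bic = bic(fit_restricted) - bic(fit_full),
    nested = nested
  )
  if (!nested)
    attr(out, "note") <-
      "models are not nested; chi-square test refused, use delta AIC/BIC"
  out
}
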