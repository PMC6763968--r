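#' Fit the independence baseline model
#'
#' The baseline behind the incremental indices CFI and TLI: item variances
#' free, every covariance fixed at zero (`df = p(p-1)/2`). Its ML solution is
#' `Sigma = diag(S)`, reached immediately by the optimizer.
#'
#' @param moments a [sample_moments()] object.
#' @param layout optional [item_layout()]; a single-trait dummy layout over
#'   the moment names is built when omitted.
#' @return a `cfa_fit`.
#' @export
baseline_fit <- function(moments, layout = NULL) {
  if (is.null(layout))
    layout <- item_layout(name = rownames(moments$S),
                          trait = "g")
  fit_cfa(build_independence(layout), moments, se = FALSE)
}

#' Fit indices for model evaluation
#'
#' Computes the usual ML fit battery from a fitted model and its
#' independence baseline:
#' \itemize{
#'   \item `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`
#'   \item `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`
#'   \item `RMSEA = sqrt(max(chi2 - df, 0) / (df (N - 1)))`
#'   \item `SRMR`: root mean square of residual correlations
#'     (`s_ij/sqrt(s_ii s_jj) - sigma_ij/sqrt(sigma_ii sigma_jj)`), averaged
#'     over the `p(p+1)/2` lower-triangle-plus-diagonal cells by default, or
#'     over the `p(p-1)/2` off-diagonal cells with
#'     `srmr_diagonal = FALSE`.
#'   \item `AIC = -2 logLik + 2q`, `BIC = -2 logLik + q log N`, using the
#'     multivariate-normal covariance likelihood without a mean block, so
#'     only differences and orderings between models fitted to the same
#'     moments are meaningful, not absolute values.
#' }
#' CFI is clamped to `[0, 1]`; TLI is clamped to 1 from above unless
#' `clamp_tli = FALSE`. With `df = 0` RMSEA and TLI are undefined and
#' reported as `NA`.
#'
#' @param fit a `cfa_fit`.
#' @param baseline the independence `cfa_fit` on the same moments (computed
#'   via [baseline_fit()] when omitted).
#' @param moments the [sample_moments()] both models were fitted to; only
#'   needed when `baseline` must be computed here.
#' @param srmr_diagonal include diagonal residuals in SRMR (default TRUE).
#' @param clamp_tli cap TLI at 1 (default TRUE).
#' @return object of class `fit_indices`: a one-row data frame with chi2,
#'   df, p_value, cfi, tli, rmsea, srmr, aic, bic, n.
#' @export
fit_indices <- function(fit, baseline = NULL, moments = NULL,
                        srmr_diagonal = TRUE, clamp_tli = TRUE) {
  if (is.null(baseline)) {
    if (is.null(moments))
      stop("supply either a baseline fit or the sample moments")
    baseline <- baseline_fit(moments, fit$spec$layout)
  }
  stopifnot(baseline$N == fit$N)
  chi2 <- fit$chi2; df <- fit$df; N <- fit$N
  chi2_b <- baseline$chi2; df_b <- baseline$df
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  tli <- if (df == 0 || df_b == 0) NA_real_ else {
    t <- ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
    if (clamp_tli) min(t, 1) else t
  }
  rmsea <- if (df == 0) NA_real_ else sqrt(max(chi2 - df, 0) / (df * (N - 1)))
  srmr <- srmr_value(fit$S, fit$sigma, include_diagonal = srmr_diagonal)
  q <- fit$n_free
  structure(data.frame(
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr,
    aic = -2 * fit$loglik + 2 * q,
    bic = -2 * fit$loglik + q * log(N),
    n = N
  ), class = c("fit_indices", "data.frame"))
}

srmr_value <- function(S, Sigma, include_diagonal = TRUE) {
  ds <- sqrt(diag(S)); dsig <- sqrt(diag(Sigma))
  rS <- S / tcrossprod(ds)
  rSig <- Sigma / tcrossprod(dsig)
  resid <- rS - rSig
  sel <- lower.tri(resid, diag = include_diagonal)
  sqrt(mean(resid[sel]^2))
}

#' Side-by-side model comparison table
#'
#' Fits (or takes pre-fitted) models on one set of sample moments and lays
#' out their fit statistics as a table with statistics in rows and models in
#' columns, the conventional layout of SEM comparison tables.
#'
#' @param fits named list of `cfa_fit` objects on the same moments.
#' @param baseline optional shared independence fit (computed once when
#'   omitted, from the first fit's layout).
#' @param moments the shared [sample_moments()] (needed when `baseline` is
#'   omitted).
#' @param file optional path; when given the table is also written as CSV.
#' @return data frame, rows = statistics, columns = models.
#' @export
comparison_table <- function(fits, baseline = NULL, moments = NULL,
                             file = NULL) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  if (is.null(baseline))
    baseline <- baseline_fit(moments, fits[[1]]$spec$layout)
  cols <- lapply(fits, function(f) {
    ix <- fit_indices(f, baseline)
    c(AIC = ix$aic, BIC = ix$bic, CFI = ix$cfi, TLI = ix$tli,
      RMSEA = ix$rmsea, SRMR = ix$srmr, `Chi-square` = ix$chi2,
      df = ix$df, converged = as.numeric(f$converged))
  })
  tab <- as.data.frame(cols, check.names = FALSE)
  if (!is.null(file))
    utils::write.csv(cbind(statistic = rownames(tab), tab), file,
                     row.names = FALSE)
  tab
}
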