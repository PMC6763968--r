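#' Materialize parameter matrices from a free-parameter vector
#'
#' Expands a `cfa_model` plus a vector of distinct free parameter values into
#' the four model matrices. Equality-labeled entries all receive the value of
#' their shared slot.
#'
#' @param spec a `cfa_model`.
#' @param theta numeric vector, length `n_free_parameters(spec)`, ordered as
#'   `parameter_index(spec)$labels`.
#' @return list with `Lambda` (p x m), `Psi` (m x m), `Theta` (p x p),
#'   `kappa` (p x p), all dimnamed, items in administration order.
#' @export
materialize <- function(spec, theta) {
  idx <- parameter_index(spec)
  if (length(theta) != length(idx$labels))
    stop("theta has length ", length(theta), ", expected ",
         length(idx$labels))
  lay <- spec$layout
  items <- lay$name[order(lay$position)]
  traits <- layout_traits(lay)
  p <- length(items); m <- length(traits)
  Lambda <- matrix(0, p, m, dimnames = list(items, traits))
  Psi <- matrix(0, m, m, dimnames = list(traits, traits))
  Theta <- matrix(0, p, p, dimnames = list(items, items))
  kappa <- matrix(0, p, p, dimnames = list(items, items))
  e <- spec$entries
  val <- ifelse(e$free, theta[idx$slot], e$value)
  for (k in seq_len(nrow(e))) {
    r <- e$row[k]; cc <- e$col[k]; v <- val[k]
    switch(e$matrix[k],
      loading = { Lambda[r, cc] <- v },
      factor_cov = { Psi[r, cc] <- v; Psi[cc, r] <- v },
      ar = { kappa[r, cc] <- v },
      residual_var = { Theta[r, r] <- v },
      residual_cov = { Theta[r, cc] <- v; Theta[cc, r] <- v }
    )
  }
  list(Lambda = Lambda, Psi = Psi, Theta = Theta, kappa = kappa)
}

#' Accumulated autoregressive paths: the propagator (I - kappa)^-1
#'
#' For a strictly lower-triangular AR matrix the propagator entry `(r, c)` is
#' the sum over all directed AR paths from item `c` to item `r` of the
#' product of coefficients along the path. It is computed by forward
#' substitution on the unit-triangular system, never by dense inversion, so
#' the unit determinant is exact.
#'
#' @param kappa p x p strictly lower-triangular matrix (administration
#'   order).
#' @return the p x p unit lower-triangular propagator.
#' @export
ar_propagator <- function(kappa) {
  p <- nrow(kappa)
  if (!isTRUE(all.equal(dim(kappa), c(p, p))) ||
      any(kappa[upper.tri(kappa, diag = TRUE)] != 0))
    stop("kappa must be strictly lower triangular (no feedback loops)")
  B <- diag(p)
  dimnames(B) <- dimnames(kappa)
  # row r of B solves (I - kappa) B = I given rows 1..r-1
  for (r in seq_len(p)[-1]) {
    krow <- kappa[r, 1:(r - 1), drop = FALSE]
    B[r, 1:(r - 1)] <- krow %*% B[1:(r - 1), 1:(r - 1), drop = FALSE]
  }
  B
}

#' Model-implied covariance matrix
#'
#' \deqn{\Sigma = \Lambda \Psi \Lambda' + B \Theta B', \quad B = (I-\kappa)^{-1}.}
#' With `kappa = 0` this reduces to the ordinary IC-CFA structure
#' \eqn{\Lambda\Psi\Lambda' + \Theta}. Symmetry is exact by construction
#' (both summands are formed as `X %*% t(X)`-style products).
#'
#' @param spec a `cfa_model`.
#' @param theta free-parameter vector (see [materialize()]).
#' @return list of class `implied_moments`: `sigma` (p x p), `propagator`,
#'   plus the materialized matrices.
#' @export
implied_covariance <- function(spec, theta) {
  mats <- materialize(spec, theta)
  implied_from_matrices(mats)
}

implied_from_matrices <- function(mats) {
  B <- ar_propagator(mats$kappa)
  common <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda)
  resid <- B %*% mats$Theta %*% t(B)
  common <- (common + t(common)) / 2
  resid <- (resid + t(resid)) / 2
  structure(c(list(sigma = common + resid, propagator = B,
                   common = common, residual = resid), mats),
            class = "implied_moments")
}

#' Indirect context effect along a chain of AR links
#'
#' The effect of an early item's residual on a later one through a chain of
#' AR coefficients is the product of the coefficients along the chain, so
#' indirect effects fade geometrically with chain length.
#'
#' @param kappa_or_fit a p x p AR matrix, a `cfa_model` fit (`cfa_fit`), or
#'   a list with a `kappa` element.
#' @param chain character vector of item names, earliest first; consecutive
#'   members must be connected by an AR entry.
#' @return the product of the AR coefficients along the chain.
#' @export
path_effect <- function(kappa_or_fit, chain) {
  obj <- kappa_or_fit
  spec <- NULL
  if (is.matrix(obj)) {
    kappa <- obj
  } else if (!is.null(obj$matrices)) {   # a cfa_fit
    kappa <- obj$matrices$kappa
    spec <- obj$spec
  } else if (!is.null(obj$kappa)) {      # materialized matrices
    kappa <- obj$kappa
  } else stop("cannot extract an AR matrix from this object")
  if (length(chain) < 2) stop("chain must contain at least two items")
  if (!all(chain %in% rownames(kappa)))
    stop("unknown item(s): ",
         paste(setdiff(chain, rownames(kappa)), collapse = ", "))
  eff <- 1
  for (k in seq_len(length(chain) - 1)) {
    src <- chain[k]; tgt <- chain[k + 1]
    ok <- if (!is.null(spec)) {
      e <- spec$entries
      any(e$matrix == "ar" & e$row == tgt & e$col == src)
    } else {
      which(rownames(kappa) == tgt) > which(colnames(kappa) == src)
    }
    if (!ok) stop("no AR link from ", src, " to ", tgt)
    eff <- eff * kappa[tgt, src]
  }
  eff
}
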