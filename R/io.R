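#' Sample moments
#'
#' Container for the observed covariance matrix `S` (with item names) and
#' the sample size `N`. Symmetry and positive definiteness are verified at
#' construction; the smallest eigenvalue is kept so near-singular inputs are
#' diagnosable.
#'
#' @param S symmetric positive-definite covariance matrix with dimnames.
#' @param N sample size (must exceed the number of items).
#' @return object of class `sample_moments`.
#' @export
sample_moments <- function(S, N) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (is.null(rownames(S)) && is.null(colnames(S)))
    stop("S must carry item names")
  if (is.null(rownames(S))) rownames(S) <- colnames(S)
  if (is.null(colnames(S))) colnames(S) <- rownames(S)
  if (max(abs(S - t(S))) > 1e-9)
    stop("S is asymmetric beyond tolerance (max |S - t(S)| = ",
         format(max(abs(S - t(S)))), ")")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("S is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  p <- nrow(S)
  if (N < p + 1)
    stop("N must be at least p + 1 = ", p + 1)
  structure(list(S = S, names = rownames(S), N = as.integer(N),
                 min_eigenvalue = min(ev)),
            class = "sample_moments")
}

#' @export
print.sample_moments <- function(x, ...) {
  cat(sprintf("Sample moments: %d variables, N = %d (min eigenvalue %.4g)\n",
              nrow(x$S), x$N, x$min_eigenvalue))
  invisible(x)
}

#' Read published moments from CSV
#'
#' Accepts the layout in which correlation tables are usually printed: a
#' first column of item names, an optional `sd` column, and one column per
#' item holding a full or lower-triangular matrix (upper cells empty). A
#' lower-triangular input is mirrored exactly; a full matrix must be
#' symmetric within 1e-9. When SDs are present the matrix is taken as
#' correlations and the covariance is built as `D R D` with `D = diag(sd)`;
#' without SDs it is taken as a covariance matrix directly.
#'
#' @param path CSV file path.
#' @param n sample size.
#' @return a [sample_moments()] object.
#' @export
read_moments <- function(path, n) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- as.character(raw[[1]])
  has_sd <- "sd" %in% tolower(names(raw))
  sd_col <- if (has_sd) which(tolower(names(raw)) == "sd") else integer(0)
  mat_cols <- setdiff(seq_along(raw)[-1], sd_col)
  M <- as.matrix(raw[, mat_cols, drop = FALSE])
  storage.mode(M) <- "double"
  if (!identical(colnames(M), nm))
    stop("matrix column names must match the item-name column")
  dimnames(M) <- list(nm, nm)
  lower_only <- all(is.na(M[upper.tri(M)]))
  if (lower_only) {
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
  } else if (anyNA(M)) {
    stop("matrix has missing cells that are not an upper triangle")
  }
  if (max(abs(M - t(M))) > 1e-9)
    stop("full matrix is asymmetric beyond 1e-9")
  M <- (M + t(M)) / 2
  if (has_sd) {
    if (max(abs(diag(M) - 1)) > 1e-9)
      stop("a correlation matrix (sd column present) must have unit diagonal")
    sds <- as.numeric(raw[[sd_col]])
    M <- M * tcrossprod(sds)
    dimnames(M) <- list(nm, nm)
  }
  sample_moments(M, n)
}

#' Sample moments from raw case-level data
#'
#' Reads a CSV of numeric item responses (one row per respondent), applies
#' listwise deletion with a message, optionally removes cluster fixed
#' effects by centering every item at its cluster mean (`group` names the
#' clustering column), and returns the covariance matrix with the `N - 1`
#' denominator.
#'
#' @param path CSV path, or a data frame.
#' @param group optional name of a clustering column for group-mean
#'   centering; the column is excluded from the items.
#' @return a [sample_moments()] object.
#' @export
read_raw <- function(path, group = NULL) {
  dat <- if (is.data.frame(path)) path
         else utils::read.csv(path, check.names = FALSE)
  gvals <- NULL
  if (!is.null(group)) {
    if (!group %in% names(dat)) stop("no such grouping column: ", group)
    gvals <- dat[[group]]
    dat <- dat[, setdiff(names(dat), group), drop = FALSE]
  }
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    bad <- names(dat)[!vapply(dat, is.numeric, logical(1))]
    stop("non-numeric item column(s): ", paste(bad, collapse = ", "))
  }
  cc <- stats::complete.cases(dat)
  if (any(!cc)) {
    message(sum(!cc), " incomplete case(s) removed (listwise deletion)")
    dat <- dat[cc, , drop = FALSE]
    gvals <- gvals[cc]
  }
  X <- as.matrix(dat)
  if (!is.null(gvals)) {
    for (g in unique(gvals)) {
      rows <- gvals == g
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                         colMeans(X[rows, , drop = FALSE]))
    }
  }
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  sample_moments(stats::cov(X), nrow(X))
}

#' The embedded mini-IPIP sample moments
#'
#' The published 20-item correlation matrix with standard deviations for the
#' multi-site student sample (N = 8,569), stored at the 2-decimal precision
#' at which it was printed. Refitted statistics therefore reproduce the
#' published values at printed precision, not beyond.
#'
#' @return a [sample_moments()] object (covariance built as `D R D`).
#' @export
minipip_fixture <- function() {
  path <- system.file("extdata", "minipip_table1.csv", package = "arcfa",
                      mustWork = TRUE)
  read_moments(path, n = 8569L)
}

#' Build a model specification from a configuration list or file
#'
#' Configuration dialect (YAML or JSON): `items` is either the reserved name
#' `"minipip"` or a list of `{name, trait, position, scoring}`; `model` is
#' one of `ic_cfa`, `ar_cfa`, `rc_cfa`; `topology` (for ar/rc models) is
#' `adjacent` or `adjacent_plus_construct`; `constraints` is `none`,
#' `by_type`, or `by_type_and_scoring`.
#'
#' @param config a list, or path to a `.yaml`/`.yml`/`.json` file.
#' @return a `cfa_model`.
#' @export
model_from_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  layout <- if (identical(config$items, "minipip")) minipip_layout()
  else {
    it <- config$items
    item_layout(
      name = vapply(it, `[[`, "", "name"),
      trait = vapply(it, `[[`, "", "trait"),
      position = vapply(it, function(x) as.integer(x$position), 0L),
      scoring = vapply(it, function(x)
        if (is.null(x$scoring)) "normal" else x$scoring, "")
    )
  }
  model <- match.arg(config$model, c("ic_cfa", "ar_cfa", "rc_cfa"))
  topology <- if (is.null(config$topology)) "adjacent_plus_construct"
              else config$topology
  spec <- switch(model,
    ic_cfa = build_ic_cfa(layout),
    ar_cfa = build_ar_cfa(layout, topology),
    rc_cfa = build_rc_cfa(build_ar_cfa(layout, topology))
  )
  constraints <- if (is.null(config$constraints)) "none" else config$constraints
  if (!identical(constraints, "none"))
    spec <- apply_equality_constraints(spec, constraints)
  spec
}

#' Write a structured fit report
#'
#' Serializes a fitted model to JSON (parameter table with estimates, SEs,
#' t and p values and the standardized solution, plus a fit block) and a
#' plain-text summary next to it.
#'
#' @param fit a `cfa_fit`.
#' @param indices optional [fit_indices()] row to embed.
#' @param dir output directory (created if missing).
#' @param name basename for the two files.
#' @return invisibly, the JSON path.
#' @export
write_fit_report <- function(fit, indices = NULL, dir = ".", name = fit$spec$model) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    model = fit$spec$model,
    topology = fit$spec$topology,
    constraints = fit$spec$constraints,
    converged = fit$converged,
    grad_norm = fit$grad_norm,
    fit = c(list(F_min = fit$F_min, chi2 = fit$chi2, df = fit$df,
                 loglik = fit$loglik, N = fit$N),
            if (!is.null(indices)) as.list(indices)),
    parameters = parameter_table(fit),
    standardized = fit$standardized
  )
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  txt_path <- file.path(dir, paste0(name, ".txt"))
  con <- file(txt_path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("Model: %s   chi2(%d) = %.3f   N = %d   converged: %s",
            fit$spec$model, fit$df, fit$chi2, fit$N, fit$converged),
    if (!fit$converged)
      c(strrep("*", 60),
        "*** WARNING: model did NOT converge; estimates unreliable ***",
        strrep("*", 60)),
    "", "Parameter estimates:",
    utils::capture.output(print(parameter_table(fit), digits = 4))
  ), con)
  invisible(json_path)
}
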