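#' Model specifications for CFA models with autoregressive residuals
#'
#' A `cfa_model` is an explicit parameter table over four matrices:
#' \describe{
#'   \item{loading}{factor loadings \eqn{\Lambda} (item x trait);}
#'   \item{factor_cov}{latent covariance matrix \eqn{\Psi} (trait x trait),
#'     with variances fixed at 1 for identification so off-diagonals are
#'     correlations;}
#'   \item{ar}{autoregressive coefficients \eqn{\kappa} among item residuals,
#'     strictly lower triangular under administration order (column = earlier
#'     source item, row = later target item);}
#'   \item{residual_var / residual_cov}{the innovation covariance matrix
#'     \eqn{\Theta}.}
#' }
#' The model-implied covariance is
#' \deqn{\Sigma = \Lambda \Psi \Lambda' + (I-\kappa)^{-1} \Theta (I-\kappa)^{-T}.}
#' Entries are free, fixed at a value, or tied together by an equality label
#' (all entries sharing a label occupy one free-parameter slot).
#'
#' @name cfa_model
NULL

param_entry <- function(matrix, row, col, free = TRUE, value = NA_real_,
                        eq_label = NA_character_, start = NA_real_) {
  data.frame(matrix = matrix, row = row, col = col, free = free,
             value = value, eq_label = eq_label, start = start,
             stringsAsFactors = FALSE)
}

new_cfa_model <- function(layout, entries, model, topology = NA_character_,
                          constraints = "none") {
  validate_entries(layout, entries)
  structure(list(layout = layout, entries = entries, model = model,
                 topology = topology, constraints = constraints),
            class = "cfa_model")
}

validate_entries <- function(layout, entries) {
  pos <- stats::setNames(layout$position, layout$name)
  ar <- entries[entries$matrix == "ar", , drop = FALSE]
  if (nrow(ar) && !all(pos[ar$col] < pos[ar$row]))
    stop("ar entries must run from an earlier to a strictly later position")
  if (nrow(ar) && anyDuplicated(ar[, c("row", "col")]))
    stop("duplicate ar entries")
  rv <- entries[entries$matrix == "residual_var", , drop = FALSE]
  if (nrow(rv) && !all(rv$row == rv$col))
    stop("residual_var entries must have row == col")
  rc <- entries[entries$matrix == "residual_cov", , drop = FALSE]
  if (nrow(rc) && any(rc$row == rc$col))
    stop("residual_cov entries must connect two distinct items")
  if (any(!entries$free & !is.na(entries$eq_label)))
    stop("an entry cannot be both fixed and equality-labeled")
  invisible(TRUE)
}

#' @export
print.cfa_model <- function(x, ...) {
  cat(sprintf("CFA model spec: %s", x$model))
  if (!is.na(x$topology)) cat(sprintf(" (topology: %s)", x$topology))
  if (!identical(x$constraints, "none"))
    cat(sprintf(" [constraints: %s]", x$constraints))
  cat("\n")
  tab <- table(x$entries$matrix[x$entries$free])
  cat(sprintf("  items: %d   free parameters: %d (distinct %d)   df: %d\n",
              n_items(x$layout), sum(x$entries$free),
              n_free_parameters(x), model_df(x)))
  for (m in names(tab)) cat(sprintf("    %-13s %d\n", m, tab[[m]]))
  invisible(x)
}

#' Parameter naming
#'
#' Free parameters receive stable labels: the equality label where present,
#' otherwise `loading.<item>`, `fcor.<t1>.<t2>`, `ar.<source>.<target>`,
#' `theta.<item>`, `thcov.<i>.<j>`.
#' @param spec a `cfa_model`.
#' @return character vector, one label per entry (NA for fixed entries).
#' @keywords internal
entry_labels <- function(spec) {
  e <- spec$entries
  auto <- character(nrow(e))
  auto[e$matrix == "loading"] <- paste0("loading.", e$row[e$matrix == "loading"])
  auto[e$matrix == "factor_cov"] <-
    paste0("fcor.", e$row[e$matrix == "factor_cov"], ".",
           e$col[e$matrix == "factor_cov"])
  auto[e$matrix == "ar"] <- paste0("ar.", e$col[e$matrix == "ar"], ".",
                                   e$row[e$matrix == "ar"])
  auto[e$matrix == "residual_var"] <-
    paste0("theta.", e$row[e$matrix == "residual_var"])
  auto[e$matrix == "residual_cov"] <-
    paste0("thcov.", e$row[e$matrix == "residual_cov"], ".",
           e$col[e$matrix == "residual_cov"])
  lab <- ifelse(is.na(e$eq_label), auto, e$eq_label)
  lab[!e$free] <- NA_character_
  lab
}

#' Free-parameter bookkeeping
#'
#' `parameter_index()` maps every free entry of a spec to a slot in the free
#' parameter vector; equality-labeled entries share a slot.
#'
#' @param spec a `cfa_model`.
#' @return list with `labels` (distinct slot names, in first-appearance
#'   order) and `slot` (integer per entry; NA for fixed entries).
#' @export
parameter_index <- function(spec) {
  lab <- entry_labels(spec)
  distinct <- unique(lab[!is.na(lab)])
  list(labels = distinct, slot = match(lab, distinct))
}

#' Number of distinct free parameters
#' @param spec a `cfa_model`.
#' @return integer count, each equality group counted once.
#' @export
n_free_parameters <- function(spec) length(parameter_index(spec)$labels)

#' Model degrees of freedom
#'
#' `df = p(p+1)/2 - q` where `q` counts distinct free parameters (each
#' equality group once). Covariance-only fitting: the mean structure is
#' saturated and contributes nothing.
#'
#' @param spec a `cfa_model`.
#' @return integer degrees of freedom.
#' @export
model_df <- function(spec) {
  p <- n_items(spec$layout)
  df <- p * (p + 1) / 2 - n_free_parameters(spec)
  if (df < 0)
    stop("over-parameterized model: df = ", df)
  as.integer(df)
}

ic_entries <- function(layout) {
  traits <- layout_traits(layout)
  e <- list(
    param_entry("loading", layout$name, layout$trait),
    param_entry("residual_var", layout$name, layout$name)
  )
  # fixed unit factor variances identify the model; covariances free
  e <- c(e, list(param_entry("factor_cov", traits, traits,
                             free = FALSE, value = 1)))
  if (length(traits) > 1) {
    pairs <- utils::combn(traits, 2)
    e <- c(e, list(param_entry("factor_cov", pairs[2, ], pairs[1, ])))
  }
  do.call(rbind, e)
}

#' Build an independent-clusters CFA specification
#'
#' Each item loads on exactly one trait; no cross-loadings, no residual
#' covariances, no autoregressive terms. Factor variances are fixed at 1 (so
#' all loadings are free and latent covariances are correlations).
#'
#' @param layout an [item_layout()].
#' @return a `cfa_model`.
#' @export
build_ic_cfa <- function(layout) {
  new_cfa_model(layout, ic_entries(layout), model = "ic_cfa")
}

ar_pairs <- function(layout, topology) {
  ord <- layout[order(layout$position), ]
  p <- nrow(ord)
  src <- ord$name[-p]
  tgt <- ord$name[-1]
  pairs <- data.frame(row = tgt, col = src, stringsAsFactors = FALSE)
  if (topology == "adjacent_plus_construct") {
    for (tr in layout_traits(layout)) {
      its <- ord$name[ord$trait == tr]
      if (length(its) > 1) {
        extra <- data.frame(row = its[-1], col = its[-length(its)],
                            stringsAsFactors = FALSE)
        # a within-trait pair that is also adjacent is emitted once
        dup <- paste(extra$row, extra$col) %in% paste(pairs$row, pairs$col)
        pairs <- rbind(pairs, extra[!dup, ])
      }
    }
  }
  if (anyDuplicated(pairs))
    stop("duplicate ar entries generated for this layout")
  pairs
}

#' Build an AR-CFA specification
#'
#' Starts from the IC-CFA of the same layout and adds free autoregressive
#' coefficients among item residuals. With `topology = "adjacent"` every
#' consecutive administration pair gets one AR term (`p - 1` terms); with
#' `"adjacent_plus_construct"` each item additionally receives an AR term
#' from the previous item of its own trait (a pair that is already adjacent
#' is emitted once, which matters for blocked layouts).
#'
#' @param layout an [item_layout()].
#' @param topology `"adjacent"` or `"adjacent_plus_construct"`.
#' @return a `cfa_model` with `ar` entries.
#' @export
build_ar_cfa <- function(layout,
                         topology = c("adjacent_plus_construct", "adjacent")) {
  topology <- match.arg(topology)
  pairs <- ar_pairs(layout, topology)
  entries <- rbind(ic_entries(layout),
                   param_entry("ar", pairs$row, pairs$col, start = 0))
  new_cfa_model(layout, entries, model = "ar_cfa", topology = topology)
}

#' Reparameterize AR terms as residual covariances (RC-CFA)
#'
#' The comparison model with equivalent degrees of freedom: every AR entry
#' `(target, source)` becomes a free residual covariance between the same two
#' items. Residual correlations carry the same first-order dependence but no
#' indirect, fading effects along AR paths.
#'
#' @param ar_spec a `cfa_model` containing `ar` entries.
#' @return a `cfa_model` with the AR entries replaced by `residual_cov`
#'   entries; all other entries (and the free-parameter count) unchanged.
#' @export
build_rc_cfa <- function(ar_spec) {
  e <- ar_spec$entries
  is_ar <- e$matrix == "ar"
  if (!any(is_ar)) return(ar_spec)
  e$matrix[is_ar] <- "residual_cov"
  e$start[is_ar] <- 0
  new_cfa_model(ar_spec$layout, e, model = "rc_cfa",
                topology = ar_spec$topology)
}

#' The saturated and independence companion specs
#'
#' `build_saturated()` frees every variance and covariance (df = 0);
#' `build_independence()` frees only the item variances (the baseline model
#' behind CFI/TLI).
#'
#' @param layout an [item_layout()].
#' @return a `cfa_model` without loadings.
#' @export
build_independence <- function(layout) {
  entries <- param_entry("residual_var", layout$name, layout$name)
  new_cfa_model(layout, entries, model = "independence")
}

#' @rdname build_independence
#' @export
build_saturated <- function(layout) {
  nm <- layout$name[order(layout$position)]
  pairs <- utils::combn(nm, 2)
  entries <- rbind(
    param_entry("residual_var", nm, nm),
    param_entry("residual_cov", pairs[2, ], pairs[1, ])
  )
  new_cfa_model(layout, entries, model = "saturated")
}

#' Equality constraints on AR effects
#'
#' Groups AR coefficients that represent "the same kind" of context effect
#' and ties each group to a single free parameter. Two schemes:
#' \describe{
#'   \item{by_type}{AR terms grouped by (source trait -> target trait);}
#'   \item{by_type_and_scoring}{each type group split into similarly scored
#'     pairs (normal->normal pooled with reversed->reversed) and differently
#'     scored pairs (normal->reversed pooled with reversed->normal).}
#' }
#' AR terms whose target item has no within-trait predecessor (the first
#' administration cycle on a cycled layout, e.g. e1 -> a1) are exempt: those
#' targets are not hit by both a between- and a within-construct effect, so
#' their coefficients are not comparable with later ones and stay free.
#'
#' @param spec a `cfa_model` with `ar` entries.
#' @param scheme `"by_type"` or `"by_type_and_scoring"`.
#' @return the spec with `eq_label`s set on the grouped AR entries.
#' @export
apply_equality_constraints <- function(spec,
                                       scheme = c("by_type",
                                                  "by_type_and_scoring")) {
  scheme <- match.arg(scheme)
  e <- spec$entries
  is_ar <- e$matrix == "ar" & e$free
  if (!any(is_ar))
    stop("spec has no free ar entries to constrain")
  lay <- spec$layout
  trait <- stats::setNames(lay$trait, lay$name)
  scoring <- stats::setNames(lay$scoring, lay$name)
  pos <- stats::setNames(lay$position, lay$name)

  # exempt: target item has no earlier item of its own trait
  has_within_pred <- function(tgt) {
    any(lay$trait == trait[tgt] & lay$position < pos[tgt])
  }
  ar_rows <- which(is_ar)
  exempt <- !vapply(e$row[ar_rows], has_within_pred, logical(1))

  grp <- paste0("eq.", trait[e$col[ar_rows]], ".", trait[e$row[ar_rows]])
  if (scheme == "by_type_and_scoring") {
    sim <- scoring[e$col[ar_rows]] == scoring[e$row[ar_rows]]
    grp <- paste0(grp, ".", ifelse(sim, "sim", "diff"))
  }
  lab <- ifelse(exempt, NA_character_, grp)
  # a group of one needs no label (same free-parameter count either way)
  singleton <- names(which(table(lab) == 1))
  lab[lab %in% singleton] <- NA_character_
  e$eq_label[ar_rows] <- lab
  new_cfa_model(lay, e, model = spec$model, topology = spec$topology,
                constraints = scheme)
}
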