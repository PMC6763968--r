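# shared layouts and lazily cached fixture fits (computed once per test run)

tiny_layout <- function() {
  item_layout(name = c("y1", "y2", "y3"), trait = "g")
}

# blocked administration: all extraversion items, then all agreeableness
blocked_layout <- function() {
  item_layout(name = c("e1", "e2", "e3", "a1", "a2", "a3"),
              trait = rep(c("E", "A"), each = 3),
              scoring = c("normal", "reversed", "normal",
                          "normal", "reversed", "normal"))
}

# 6-item cycled two-trait layout, cheap stand-in for the full instrument
# (large enough for covariance algebra; too few moments to FIT the
# adjacent_plus_construct model, which needs cycled8_layout)
cycled6_layout <- function() {
  item_layout(name = c("e1", "a1", "e2", "a2", "e3", "a3"),
              trait = rep(c("E", "A"), 3))
}

# 8-item cycled layout: 36 moments vs 30 free parameters for the
# adjacent_plus_construct AR-CFA, so fits are identified
cycled8_layout <- function() {
  item_layout(name = c("e1", "a1", "e2", "a2", "e3", "a3", "e4", "a4"),
              trait = rep(c("E", "A"), 4))
}

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fit_cache[[key]])) assign(key, builder(), envir = .fit_cache)
  .fit_cache[[key]]
}

minipip_moments <- function() cached("moments", minipip_fixture)

minipip_ic_fit <- function() cached("ic_fit", function() {
  fit_cfa(build_ic_cfa(minipip_layout()), minipip_moments())
})

minipip_ar_fit <- function() cached("ar_fit", function() {
  fit_cfa(build_ar_cfa(minipip_layout(), "adjacent_plus_construct"),
          minipip_moments())
})

minipip_baseline <- function() cached("baseline", function() {
  baseline_fit(minipip_moments(), minipip_layout())
})

# small admissible AR model + a random-but-fixed parameter vector for
# property tests
random_theta <- function(spec, seed) {
  set.seed(seed)
  info <- arcfa:::slot_info(spec)
  th <- numeric(length(info$labels))
  th[info$matrix == "loading"] <- stats::runif(sum(info$matrix == "loading"),
                                               0.4, 0.9)
  th[info$matrix == "factor_cov"] <-
    stats::runif(sum(info$matrix == "factor_cov"), -0.3, 0.3)
  th[info$matrix == "ar"] <- stats::runif(sum(info$matrix == "ar"),
                                          -0.4, 0.4)
  th[info$matrix == "residual_var"] <-
    stats::runif(sum(info$matrix == "residual_var"), 0.3, 1.2)
  th[info$matrix == "residual_cov"] <-
    stats::runif(sum(info$matrix == "residual_cov"), -0.05, 0.05)
  stats::setNames(th, info$labels)
}

random_pd_matrix <- function(p, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p)
  S <- crossprod(A) / p + diag(p) * 0.5
  dimnames(S) <- list(paste0("v", 1:p), paste0("v", 1:p))
  S
}

random_strict_lower <- function(p, seed) {
  set.seed(seed)
  K <- matrix(0, p, p)
  K[lower.tri(K)] <- stats::runif(p * (p - 1) / 2, -0.5, 0.5)
  K
}
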