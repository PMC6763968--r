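# model specification builders, parameter counting, df arithmetic

test_that("mini-IPIP layout encodes administration order and scoring", {
  lay <- minipip_layout()
  expect_s3_class(lay, "item_layout")
  expect_equal(attr(lay, "p"), 20L)
  expect_equal(length(attr(lay, "traits")), 5L)
  expect_equal(lay$name[lay$position == 6], "e2")
  # cycled order: positions 1..5 are the first item of each trait
  expect_equal(lay$name[1:5], c("e1", "a1", "c1", "n1", "o1"))
  expect_equal(lay$scoring[lay$name == "o3"], "reversed")
  expect_equal(lay$scoring[lay$name == "n3"], "normal")
  expect_equal(sum(lay$scoring == "reversed"), 11L)
})

test_that("layout validation rejects malformed inputs", {
  expect_error(item_layout(c("a", "a"), c("T", "T")), "unique")
  expect_error(item_layout(c("a", "b"), c("T", "T"), position = c(1, 3)),
               "permutation")
  expect_error(item_layout("a", "T", scoring = "inverted"), "scoring")
})

test_that("IC-CFA construction yields the expected free parameters", {
  ic <- build_ic_cfa(minipip_layout())
  expect_equal(n_free_parameters(ic), 50L)   # 20 loadings + 10 fcor + 20 theta
  expect_equal(sum(ic$entries$matrix == "ar"), 0L)
  ic3 <- build_ic_cfa(tiny_layout())
  expect_equal(n_free_parameters(ic3), 6L)   # 3 + 0 + 3
})

test_that("AR topologies generate the documented term counts", {
  lay <- minipip_layout()
  adj <- build_ar_cfa(lay, "adjacent")
  expect_equal(sum(adj$entries$matrix == "ar"), 19L)
  apc <- build_ar_cfa(lay, "adjacent_plus_construct")
  e <- apc$entries[apc$entries$matrix == "ar", ]
  trait <- setNames(lay$trait, lay$name)
  between <- sum(trait[e$row] != trait[e$col])
  within <- sum(trait[e$row] == trait[e$col])
  expect_equal(between, 19L)
  expect_equal(within, 15L)
})

test_that("blocked layouts carry both AR types on adjacent terms, deduplicated", {
  lay <- blocked_layout()
  adj <- build_ar_cfa(lay, "adjacent")
  e <- adj$entries[adj$entries$matrix == "ar", ]
  expect_equal(nrow(e), 5L)
  trait <- setNames(lay$trait, lay$name)
  # the 5 adjacent terms include within-construct (e1->e2) and
  # between-construct (e3->a1) dependence
  expect_true(any(trait[e$row] == trait[e$col]))
  expect_true(any(trait[e$row] != trait[e$col]))
  # adding construct-specific terms must not duplicate the adjacent ones
  apc <- build_ar_cfa(lay, "adjacent_plus_construct")
  expect_equal(sum(apc$entries$matrix == "ar"), 5L)
})

test_that("AR entries are strictly lower triangular under administration order", {
  for (lay in list(minipip_layout(), blocked_layout(), cycled6_layout())) {
    pos <- setNames(lay$position, lay$name)
    for (topo in c("adjacent", "adjacent_plus_construct")) {
      e <- build_ar_cfa(lay, topo)$entries
      e <- e[e$matrix == "ar", ]
      expect_true(all(pos[e$col] < pos[e$row]))
    }
  }
})

test_that("RC-CFA reparameterization preserves df and entries", {
  ar <- build_ar_cfa(minipip_layout())
  rc <- build_rc_cfa(ar)
  expect_equal(sum(rc$entries$matrix == "residual_cov"), 34L)
  expect_equal(sum(rc$entries$matrix == "ar"), 0L)
  expect_identical(model_df(rc), model_df(ar))
  expect_identical(n_free_parameters(rc), n_free_parameters(ar))
  # row/col carried over unchanged
  ea <- ar$entries[ar$entries$matrix == "ar", c("row", "col")]
  er <- rc$entries[rc$entries$matrix == "residual_cov", c("row", "col")]
  expect_equal(ea, er, ignore_attr = TRUE)
  # no AR entries: unchanged spec
  ic <- build_ic_cfa(minipip_layout())
  expect_identical(build_rc_cfa(ic)$entries, ic$entries)
})

test_that("model df matches saturated-moment arithmetic", {
  lay <- minipip_layout()
  expect_equal(model_df(build_ic_cfa(lay)), 160L)
  expect_equal(model_df(build_ar_cfa(lay, "adjacent_plus_construct")), 126L)
  expect_equal(model_df(build_saturated(lay)), 0L)
  expect_equal(model_df(build_independence(lay)), 190L)
  # over-parameterized: 2 items, 1 trait needs 4 parameters for 3 moments
  lay2 <- item_layout(c("y1", "y2"), "g")
  expect_error(model_df(build_ic_cfa(lay2)), "over-parameterized")
})

test_that("freeing AR terms lowers df by exactly the number of AR entries", {
  for (lay in list(minipip_layout(), cycled8_layout())) {
    ic <- build_ic_cfa(lay)
    ar <- build_ar_cfa(lay, "adjacent_plus_construct")
    expect_equal(model_df(ic) - model_df(ar),
                 sum(ar$entries$matrix == "ar"))
  }
})

test_that("equality-constraint schemes group AR terms as documented", {
  ar <- build_ar_cfa(minipip_layout(), "adjacent_plus_construct")
  by_type <- apply_equality_constraints(ar, "by_type")
  by_ts <- apply_equality_constraints(ar, "by_type_and_scoring")
  free_ar <- function(s) {
    lab <- arcfa:::entry_labels(s)
    length(unique(lab[s$entries$matrix == "ar" & !is.na(lab)]))
  }
  expect_equal(free_ar(ar), 34L)
  expect_equal(free_ar(by_type), 14L)       # 10 groups + 4 exempt
  expect_equal(free_ar(by_ts), 17L)         # 13 scoring cells + 4 exempt
  expect_equal(model_df(by_type) - model_df(ar), 20L)
  expect_equal(model_df(by_ts) - model_df(ar), 17L)
  # monotone free-parameter counts
  expect_lte(n_free_parameters(by_type), n_free_parameters(by_ts))
  expect_lte(n_free_parameters(by_ts), n_free_parameters(ar))
  # constraints touch only labels, never matrices
  expect_identical(by_type$entries$matrix, ar$entries$matrix)
  # scheme needs AR entries to act on
  expect_error(apply_equality_constraints(build_ic_cfa(minipip_layout()),
                                          "by_type"), "no free ar")
})

test_that("first-cycle AR terms are exempt from equality constraints", {
  ar <- build_ar_cfa(minipip_layout(), "adjacent_plus_construct")
  ct <- apply_equality_constraints(ar, "by_type")
  e <- ct$entries[ct$entries$matrix == "ar", ]
  first_cycle <- e$row %in% c("a1", "c1", "n1", "o1")
  expect_true(all(is.na(e$eq_label[first_cycle])))
  expect_true(all(!is.na(e$eq_label[!first_cycle])))
})
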