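#' Item layout for an ordered multi-item scale
#'
#' An item layout records everything the measurement model needs to know
#' about the instrument itself: the item names, which latent trait each item
#' measures, the (1-based) position at which each item was administered, and
#' whether the item is reverse-scored. Administration order is what defines
#' the topology of the autoregressive residual structure, so positions must
#' form a gap-free permutation of `1..p`.
#'
#' @param name character vector of unique item names.
#' @param trait character vector assigning each item to one latent trait.
#' @param position integer vector, administration order; a permutation of
#'   `1..p`. Defaults to the order in which items are supplied.
#' @param scoring `"normal"` or `"reversed"` per item; scoring does not alter
#'   the data (moments are analysed as supplied) but drives the
#'   scoring-sensitive equality-constraint scheme.
#' @param text optional item wording.
#'
#' @return An object of class `item_layout`: a data frame with one row per
#'   item, sorted by administration position, with attributes `p` (number of
#'   items) and `traits` (trait labels in order of first appearance).
#' @seealso [minipip_layout()] for the built-in 20-item Big Five layout.
#' @export
item_layout <- function(name, trait, position = seq_along(name),
                        scoring = "normal", text = NA_character_) {
  p <- length(name)
  stopifnot(p >= 1L, length(position) == p)
  trait <- rep_len(trait, p)
  scoring <- rep_len(scoring, p)
  text <- rep_len(text, p)
  if (anyDuplicated(name))
    stop("item names must be unique")
  if (!setequal(position, seq_len(p)))
    stop("positions must be a permutation of 1..", p, " with no gaps")
  if (!all(scoring %in% c("normal", "reversed")))
    stop("scoring must be 'normal' or 'reversed'")
  items <- data.frame(
    name = as.character(name), trait = as.character(trait),
    position = as.integer(position), scoring = scoring, text = text,
    stringsAsFactors = FALSE
  )
  items <- items[order(items$position), , drop = FALSE]
  rownames(items) <- NULL
  structure(items,
            p = p,
            traits = unique(items$trait),
            class = c("item_layout", "data.frame"))
}

#' @export
print.item_layout <- function(x, ...) {
  cat(sprintf("Item layout: %d items, %d traits (%s)\n",
              attr(x, "p"), length(attr(x, "traits")),
              paste(attr(x, "traits"), collapse = ", ")))
  print(as.data.frame(x)[, c("position", "name", "trait", "scoring")], ...)
  invisible(x)
}

n_items <- function(layout) attr(layout, "p")
layout_traits <- function(layout) attr(layout, "traits")

#' The mini-IPIP item layout
#'
#' The 20-item mini-IPIP Big Five inventory administers four items per trait
#' (Extraversion, Agreeableness, Conscientiousness, Neuroticism, Openness) in
#' a repeating e, a, c, n, o cycle: e1; a1; c1; n1; o1; e2; a2; ...; o4.
#' Eleven items are reverse-scored (e2, e4, a2, a4, c2, c4, n2, n4, o2, o3,
#' o4).
#'
#' @return An [item_layout()] with `p = 20` items and `m = 5` traits.
#' @export
minipip_layout <- function() {
  texts <- c(
    e1 = "Am the life of the party",
    e2 = "Don't talk a lot. R",
    e3 = "Talk to a lot of different people at parties",
    e4 = "Keep in the background. R",
    a1 = "Sympathize with others' feelings",
    a2 = "Am not interested in other people's problems. R",
    a3 = "Feel others' emotions",
    a4 = "Am not really interested in others. R",
    c1 = "Get chores done right away",
    c2 = "Often forget to put things back in their proper place. R",
    c3 = "Like order",
    c4 = "Make a mess of things. R",
    n1 = "Have frequent mood swings",
    n2 = "Am relaxed most of the time. R",
    n3 = "Get upset easily",
    n4 = "Seldom feel blue. R",
    o1 = "Have a vivid imagination",
    o2 = "Am not interested in abstract ideas. R",
    o3 = "Have difficulty understanding abstract ideas. R",
    o4 = "Do not have a good imagination. R"
  )
  traits <- c(e = "E", a = "A", c = "C", n = "N", o = "O")
  # administration cycles e, a, c, n, o four times
  nm <- paste0(rep(names(traits), 4), rep(1:4, each = 5))
  reversed <- c("e2", "e4", "a2", "a4", "c2", "c4", "n2", "n4",
                "o2", "o3", "o4")
  item_layout(
    name = nm,
    trait = traits[substr(nm, 1, 1)],
    position = seq_along(nm),
    scoring = ifelse(nm %in% reversed, "reversed", "normal"),
    text = unname(texts[nm])
  )
}
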