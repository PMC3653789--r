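#' @keywords internal
"_PACKAGE"

#' The three sorting dimensions of the card sorting task
#'
#' Every card varies on color, shape and number, and every sorting rule is one
#' of these three dimensions.
#'
#' @format A character vector: `"COLOR"`, `"SHAPE"`, `"NUMBER"`.
#' @export
bcst_dimensions <- c("COLOR", "SHAPE", "NUMBER")

# Attribute domains. The level order is the canonical key-card order: the
# attribute at position i sits on key pile i.
bcst_colors  <- c("red", "green", "yellow", "blue")
bcst_shapes  <- c("triangle", "star", "cross", "circle")
bcst_numbers <- 1:4

#' Construct a single stimulus card
#'
#' A card is one combination of a color, a shape and a quantity, each from a
#' four-level domain.
#'
#' @param color One of `"red"`, `"green"`, `"yellow"`, `"blue"`.
#' @param shape One of `"triangle"`, `"star"`, `"cross"`, `"circle"`.
#' @param number Integer 1 to 4.
#' @return A one-row data frame with columns `color`, `shape`, `number`.
#' @examples
#' card("green", "circle", 3)
#' @export
card <- function(color, shape, number) {
  color <- match.arg(color, bcst_colors)
  shape <- match.arg(shape, bcst_shapes)
  number <- as.integer(number)
  if (length(number) != 1L || is.na(number) || number < 1L || number > 4L)
    stop("`number` must be a single integer in 1..4", call. = FALSE)
  data.frame(color = color, shape = shape, number = number,
             stringsAsFactors = FALSE)
}

#' Build the canonical key-card set
#'
#' The four key cards anchor the four sorting piles: pile 1 shows one red
#' triangle, pile 2 two green stars, pile 3 three yellow crosses and pile 4
#' four blue circles. Across the piles every color, shape and number appears
#' exactly once, so under any rule each card has a unique correct pile.
#'
#' @return A data frame of class `bcst_keycards` with columns `pile`, `color`,
#'   `shape`, `number`.
#' @examples
#' build_key_cards()
#' @export
build_key_cards <- function() {
  keys <- data.frame(
    pile = 1:4,
    color = bcst_colors,
    shape = bcst_shapes,
    number = bcst_numbers,
    stringsAsFactors = FALSE
  )
  class(keys) <- c("bcst_keycards", "data.frame")
  validate_key_cards(keys)
}

#' @noRd
validate_key_cards <- function(keys) {
  stopifnot(is.data.frame(keys), nrow(keys) == 4L)
  if (anyDuplicated(keys$color) || anyDuplicated(keys$shape) ||
      anyDuplicated(keys$number))
    stop("key cards must show each color, shape and number exactly once",
         call. = FALSE)
  if (!identical(sort(keys$pile), 1:4))
    stop("key cards must occupy piles 1..4", call. = FALSE)
  keys
}

#' Build the standard 128-card deck
#'
#' The deck holds each of the 64 distinct color x shape x number combinations
#' exactly twice, shuffled deterministically from `seed`.
#'
#' @param seed Integer shuffle seed.
#' @param exclude_key_identical If `TRUE`, the four cards identical to the key
#'   cards are dropped before duplication (a 120-card deck). Off by default;
#'   the standard deck keeps all 64 combinations.
#' @return A data frame of class `bcst_deck` with columns `color`, `shape`,
#'   `number` and attribute `seed`.
#' @examples
#' deck <- build_deck(seed = 1)
#' nrow(deck)  # 128
#' @export
build_deck <- function(seed, exclude_key_identical = FALSE) {
  combos <- expand.grid(
    number = bcst_numbers,
    shape = bcst_shapes,
    color = bcst_colors,
    stringsAsFactors = FALSE
  )[, c("color", "shape", "number")]
  if (isTRUE(exclude_key_identical)) {
    keys <- build_key_cards()
    keep <- !(combos$color == bcst_colors[match(combos$shape, bcst_shapes)] &
                combos$number == match(combos$shape, bcst_shapes))
    combos <- combos[keep, , drop = FALSE]
  }
  deck <- rbind(combos, combos)
  ord <- with_seed(seed, sample.int(nrow(deck)))
  deck <- deck[ord, , drop = FALSE]
  rownames(deck) <- NULL
  attr(deck, "seed") <- as.integer(seed)
  class(deck) <- c("bcst_deck", "data.frame")
  deck
}

#' Find the correct pile for a card under a sorting rule
#'
#' Returns the pile whose key card shares the card's attribute on the given
#' dimension. Uniqueness is guaranteed by the key-card invariant. Vectorised
#' over the rows of `cards`.
#'
#' @param cards A card (from [card()]) or a data frame of cards.
#' @param rule One of `"COLOR"`, `"SHAPE"`, `"NUMBER"` (recycled to the number
#'   of cards if scalar).
#' @param keys A key-card set, by default [build_key_cards()].
#' @return Integer pile index (or vector of indices) in 1..4.
#' @examples
#' correct_pile(card("green", "circle", 3), "SHAPE")  # 4: circles sit on pile 4
#' @export
correct_pile <- function(cards, rule, keys = build_key_cards()) {
  validate_key_cards(keys)
  n <- nrow(cards)
  rule <- match_rule(rule)
  if (length(rule) == 1L) rule <- rep(rule, n)
  if (length(rule) != n)
    stop("`rule` must be scalar or match the number of cards", call. = FALSE)
  pile <- integer(n)
  for (r in unique(rule)) {
    i <- rule == r
    pile[i] <- switch(r,
      COLOR  = keys$pile[match(cards$color[i], keys$color)],
      SHAPE  = keys$pile[match(cards$shape[i], keys$shape)],
      NUMBER = keys$pile[match(cards$number[i], keys$number)]
    )
  }
  pile
}

# Fast single-card lookup without key validation; for use in per-trial loops
# where `keys` has already been validated once.
#' @noRd
pile_lookup <- function(card, rule, keys) {
  switch(rule,
    COLOR  = keys$pile[match(card$color, keys$color)],
    SHAPE  = keys$pile[match(card$shape, keys$shape)],
    NUMBER = keys$pile[match(card$number, keys$number)]
  )
}

#' @noRd
match_rule <- function(rule) {
  rule <- toupper(as.character(rule))
  bad <- !rule %in% bcst_dimensions
  if (any(bad))
    stop("unknown dimension: ", paste(unique(rule[bad]), collapse = ", "),
         call. = FALSE)
  rule
}

#' Successor rule in the sorting-rule cycle
#'
#' Rules change silently each time a set is completed, following a fixed
#' cycle; after the last element the cycle wraps.
#'
#' @param current The dimension currently in force.
#' @param order The rule cycle, default `COLOR -> SHAPE -> NUMBER`.
#' @return The next dimension.
#' @examples
#' next_rule("NUMBER")  # "COLOR"
#' @export
next_rule <- function(current, order = bcst_dimensions) {
  order <- match_rule(order)
  if (anyDuplicated(order) || length(order) < 2L)
    stop("`order` must be a cycle of distinct dimensions", call. = FALSE)
  current <- match_rule(current)
  i <- match(current, order)
  if (is.na(i)) stop("`current` is not in `order`", call. = FALSE)
  order[(i %% length(order)) + 1L]
}
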