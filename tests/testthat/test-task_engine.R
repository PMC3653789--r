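test_that("key cards use the canonical geometry and cover every attribute once", {
  keys <- build_key_cards()
  expect_equal(keys[keys$pile == 1, c("color", "shape", "number")],
               data.frame(color = "red", shape = "triangle", number = 1L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(keys$color) > 0)
  expect_false(anyDuplicated(keys$shape) > 0)
  expect_false(anyDuplicated(keys$number) > 0)
  expect_equal(correct_pile(card("blue", "triangle", 2), "COLOR"), 4L)
})

test_that("the standard deck holds each of the 64 combinations exactly twice", {
  for (seed in c(0, 1, 42)) {
    deck <- build_deck(seed)
    expect_equal(nrow(deck), 128L)
    combo <- paste(deck$color, deck$shape, deck$number)
    counts <- table(combo)
    expect_length(counts, 64L)
    expect_true(all(counts == 2L))
  }
  # full enumeration oracle: the multiset equals {4 colors x 4 shapes x 4 numbers} x 2
  all_combos <- expand.grid(color = c("red", "green", "yellow", "blue"),
                            shape = c("triangle", "star", "cross", "circle"),
                            number = 1:4, stringsAsFactors = FALSE)
  expected <- sort(rep(paste(all_combos$color, all_combos$shape,
                             all_combos$number), 2))
  deck <- build_deck(7)
  expect_equal(sort(paste(deck$color, deck$shape, deck$number)), expected)
})

test_that("deck shuffling is a deterministic function of the seed", {
  expect_identical(build_deck(5), build_deck(5))
  expect_false(identical(build_deck(5)$color, build_deck(6)$color))
})

test_that("the key-identical exclusion drops exactly the four key cards", {
  deck <- build_deck(1, exclude_key_identical = TRUE)
  expect_equal(nrow(deck), 120L)
  combo <- paste(deck$color, deck$shape, deck$number)
  expect_false(any(c("red triangle 1", "green star 2",
                     "yellow cross 3", "blue circle 4") %in% combo))
})

test_that("correct_pile resolves the unique matching pile per rule", {
  expect_equal(correct_pile(card("red", "triangle", 1), "COLOR"), 1L)
  expect_equal(correct_pile(card("green", "circle", 3), "SHAPE"), 4L)
  expect_equal(correct_pile(card("yellow", "star", 2), "NUMBER"), 2L)
  # vectorised over a deck: always in 1..4 and matches the keyed attribute
  deck <- build_deck(3)
  keys <- build_key_cards()
  for (rule in bcst_dimensions) {
    piles <- correct_pile(deck, rule, keys)
    expect_true(all(piles %in% 1:4))
    attr_col <- switch(rule, COLOR = "color", SHAPE = "shape",
                       NUMBER = "number")
    expect_equal(keys[[attr_col]][match(piles, keys$pile)], deck[[attr_col]])
  }
})

test_that("rule cycle advances with wraparound and period 3", {
  expect_equal(next_rule("COLOR"), "SHAPE")
  expect_equal(next_rule("NUMBER"), "COLOR")
  for (start in bcst_dimensions) {
    r <- start
    for (i in 1:3) r <- next_rule(r)
    expect_equal(r, start)
  }
  expect_equal(next_rule("SHAPE", c("NUMBER", "SHAPE", "COLOR")), "COLOR")
  expect_error(next_rule("COLOR", c("SHAPE", "NUMBER")), "not in")
})

test_that("a session records contiguous 1-based trials and respects hard bounds", {
  sessions <- generate_test_sessions(n_each = 2, seed0 = 300)
  for (s in sessions) {
    expect_lte(nrow(s$trials), 128L)
    expect_lte(s$categories_completed, 9L)
    expect_identical(s$trials$trial, seq_len(nrow(s$trials)))
    if (s$categories_completed == 9L) expect_gte(nrow(s$trials), 90L)
  }
})

test_that("within each completed set the final criterion run is all correct", {
  sessions <- generate_test_sessions(n_each = 2, seed0 = 400)
  for (s in sessions) {
    tr <- s$trials
    for (k in seq_len(s$categories_completed)) {
      in_set <- which(tr$set == k)
      tail10 <- utils::tail(in_set, 10)
      expect_length(tail10, 10L)
      expect_true(all(tr$correct[tail10]))
    }
  }
})

test_that("previous_rule chains to the prior set's active rule", {
  sessions <- generate_test_sessions(n_each = 2, seed0 = 500)
  for (s in sessions) {
    tr <- s$trials
    expect_true(all(is.na(tr$previous_rule[tr$set == 1])))
    for (k in seq_len(max(tr$set))[-1]) {
      prev_active <- unique(tr$active_rule[tr$set == k - 1])
      expect_length(prev_active, 1L)
      expect_true(all(tr$previous_rule[tr$set == k] == prev_active))
    }
  }
})

test_that("a policy returning an out-of-range pile is rejected with the trial index", {
  bad <- function(state) if (state$trial == 3) 7L else 1L
  expect_error(run_session(bad, session_config(deck_seed = 1)),
               "invalid pile on trial 3")
})

test_that("a fixed-pile responder never completes the test and exhausts the deck", {
  s <- run_session(fixed_pile_policy(1), session_config(deck_seed = 9))
  expect_equal(nrow(s$trials), 128L)
  expect_lt(s$categories_completed, 9L)
})

test_that("the starting rule is drawn from the seed and sessions replay exactly", {
  cfg <- session_config(deck_seed = 2, start_rule_seed = 77)
  s1 <- run_session(random_policy(5), cfg)
  s2 <- run_session(random_policy(5), cfg)
  expect_identical(s1, s2)
  starts <- vapply(1:30, function(i)
    run_session(oracle_policy(),
                session_config(deck_seed = 1, start_rule_seed = i)
    )$trials$active_rule[1], character(1))
  expect_setequal(unique(starts), bcst_dimensions)
})

test_that("error-free play terminates at run_criterion x max_categories trials", {
  cfg <- session_config(max_categories = 4, run_criterion = 6, deck_seed = 3)
  s <- run_session(oracle_policy(), cfg)
  expect_equal(nrow(s$trials), 24L)
  expect_equal(s$categories_completed, 4L)
})
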