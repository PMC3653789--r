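#' Session configuration
#'
#' Bundles the parameters that govern one test administration: the set
#' completion criterion (consecutive correct responses), the maximum number of
#' sets, the deck shuffle seed, the seed for the random starting rule, and the
#' rule cycle.
#'
#' @param max_categories Sets to complete before the test ends (default 9).
#' @param run_criterion Consecutive correct responses that complete a set
#'   (default 10). The counter resets on any error and at every rule change.
#' @param deck_seed Seed for the deck shuffle.
#' @param start_rule_seed Seed for the uniformly random starting dimension.
#' @param rule_order Fixed rule cycle, entered at the random start
#'   (default `COLOR -> SHAPE -> NUMBER`).
#' @param exclude_key_identical Passed to [build_deck()].
#' @return A list of class `bcst_config`.
#' @export
session_config <- function(max_categories = 9L, run_criterion = 10L,
                           deck_seed = 1L, start_rule_seed = 1L,
                           rule_order = bcst_dimensions,
                           exclude_key_identical = FALSE) {
  max_categories <- as.integer(max_categories)
  run_criterion <- as.integer(run_criterion)
  if (is.na(run_criterion) || run_criterion < 1L)
    stop("`run_criterion` must be >= 1", call. = FALSE)
  if (is.na(max_categories) || max_categories < 1L)
    stop("`max_categories` must be >= 1", call. = FALSE)
  structure(
    list(max_categories = max_categories, run_criterion = run_criterion,
         deck_seed = as.integer(deck_seed),
         start_rule_seed = as.integer(start_rule_seed),
         rule_order = match_rule(rule_order),
         exclude_key_identical = isTRUE(exclude_key_identical)),
    class = "bcst_config")
}

#' Run one card sorting session against a respondent policy
#'
#' Cards are presented in deck order. The active rule is hidden from the
#' respondent; after each sort the policy receives correct/incorrect feedback.
#' A run of `run_criterion` consecutive correct responses completes the set,
#' silently advances the rule along the cycle and resets the run counter. The
#' session ends when `max_categories` sets are completed or the deck is
#' exhausted, whichever comes first.
#'
#' The policy is a function of the visible state, a list with elements
#' `keys`, `card` (a list with `color`, `shape`, `number`), `trial`
#' (1-based index), and `history`
#' (a list of parallel vectors `color`, `shape`, `number`, `chosen_pile`,
#' `correct`, valid up to element `n`). Policies never see the active rule;
#' the oracle policy is the single test-harness exception (see
#' [oracle_policy()]).
#'
#' @param policy A respondent policy function.
#' @param config A [session_config()].
#' @param keys Key cards, default canonical.
#' @return A list of class `bcst_session` with elements `trials` (data frame:
#'   `trial`, `set`, `active_rule`, `previous_rule`, `color`, `shape`,
#'   `number`, `chosen_pile`, `correct`), `categories_completed`, `config`.
#' @examples
#' s <- run_session(oracle_policy(), session_config(deck_seed = 1))
#' nrow(s$trials)            # 90, the theoretical minimum
#' s$categories_completed    # 9
#' @export
run_session <- function(policy, config = session_config(),
                        keys = build_key_cards()) {
  stopifnot(is.function(policy))
  validate_key_cards(keys)
  deck <- build_deck(config$deck_seed, config$exclude_key_identical)
  n_deck <- nrow(deck)

  active <- with_seed(config$start_rule_seed,
                      sample(config$rule_order, 1L))
  previous <- NA_character_

  # Pre-resolve correct piles for all three rules over the whole deck: the
  # inner loop then only does lookups.
  pile_by_rule <- vapply(bcst_dimensions, function(r)
    correct_pile(deck, r, keys), integer(n_deck))

  privileged <- isTRUE(attr(policy, "privileged"))
  deck_color <- deck$color; deck_shape <- deck$shape; deck_number <- deck$number

  col <- character(n_deck); shp <- character(n_deck); num <- integer(n_deck)
  act <- character(n_deck); prv <- character(n_deck)
  cho <- integer(n_deck); cor <- logical(n_deck); set <- integer(n_deck)

  history <- list(color = col, shape = shp, number = num,
                  chosen_pile = cho, correct = cor, n = 0L)
  run <- 0L
  categories <- 0L
  set_idx <- 1L
  t <- 0L

  while (t < n_deck && categories < config$max_categories) {
    t <- t + 1L
    this_card <- list(color = deck_color[t], shape = deck_shape[t],
                      number = deck_number[t])
    state <- list(keys = keys, card = this_card, trial = t, history = history)
    if (privileged) state$active_rule <- active
    choice <- policy(state)
    if (!is.numeric(choice) || length(choice) != 1L || is.na(choice) ||
        choice != as.integer(choice) || choice < 1L || choice > 4L)
      stop(sprintf("policy returned an invalid pile on trial %d", t),
           call. = FALSE)
    choice <- as.integer(choice)
    ok <- choice == pile_by_rule[t, active]

    col[t] <- this_card$color; shp[t] <- this_card$shape
    num[t] <- this_card$number
    act[t] <- active; prv[t] <- previous
    cho[t] <- choice; cor[t] <- ok; set[t] <- set_idx

    history$color[t] <- this_card$color
    history$shape[t] <- this_card$shape
    history$number[t] <- this_card$number
    history$chosen_pile[t] <- choice
    history$correct[t] <- ok
    history$n <- t

    if (ok) {
      run <- run + 1L
      if (run == config$run_criterion) {
        categories <- categories + 1L
        previous <- active
        active <- next_rule(active, config$rule_order)
        run <- 0L
        set_idx <- set_idx + 1L
      }
    } else {
      run <- 0L
    }
  }

  trials <- data.frame(
    trial = seq_len(t), set = set[seq_len(t)],
    active_rule = act[seq_len(t)], previous_rule = prv[seq_len(t)],
    color = col[seq_len(t)], shape = shp[seq_len(t)],
    number = num[seq_len(t)], chosen_pile = cho[seq_len(t)],
    correct = cor[seq_len(t)], stringsAsFactors = FALSE
  )
  structure(
    list(trials = trials, categories_completed = categories, config = config),
    class = "bcst_session")
}

#' @export
print.bcst_session <- function(x, ...) {
  cat(sprintf(
    "<bcst_session> %d trials, %d categories completed, %d errors\n",
    nrow(x$trials), x$categories_completed, sum(!x$trials$correct)))
  invisible(x)
}
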