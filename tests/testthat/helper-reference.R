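# Independent, deliberately simple reference scorer: a plain loop over trials
# that rediscovers the correct pile for both the active and the previous rule
# by scanning the key cards, with no shared code path with the package's
# vectorised classifier.
naive_rescore <- function(session, keys = build_key_cards()) {
  tr <- session$trials
  n <- nrow(tr)
  find_pile <- function(color, shape, number, rule) {
    for (p in 1:4) {
      k <- keys[keys$pile == p, ]
      hit <- switch(rule,
        COLOR = k$color == color,
        SHAPE = k$shape == shape,
        NUMBER = k$number == number)
      if (hit) return(p)
    }
    stop("no pile found")
  }
  correct <- tr$correct
  pr <- logical(n); pe <- logical(n)
  for (i in seq_len(n)) {
    prev <- tr$previous_rule[i]
    if (!is.na(prev) && prev != "") {
      prev_pile <- find_pile(tr$color[i], tr$shape[i], tr$number[i], prev)
      pr[i] <- tr$chosen_pile[i] == prev_pile
      pe[i] <- pr[i] && !correct[i]
    }
  }
  data.frame(correct = correct, error = !correct,
             perseverative_response = pr, perseverative_error = pe)
}

# A mixed bag of deterministic sessions for property tests.
generate_test_sessions <- function(n_each = 5, seed0 = 100) {
  out <- list()
  for (i in seq_len(n_each)) {
    s <- seed0 + i
    cfg <- session_config(deck_seed = s, start_rule_seed = s + 1)
    out[[length(out) + 1]] <- run_session(random_policy(s + 2), cfg)
    out[[length(out) + 1]] <- run_session(
      parametric_policy(agent_params(0.5, 0.05, 0.9, seed = s + 3)), cfg)
    out[[length(out) + 1]] <- run_session(
      parametric_policy(agent_params(0.1, 0.01, 1, seed = s + 4)), cfg)
  }
  out[[length(out) + 1]] <- run_session(oracle_policy(),
                                        session_config(deck_seed = seed0))
  out
}
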