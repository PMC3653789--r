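#' Oracle policy: always sorts correctly
#'
#' A test-harness respondent that chooses the correct pile on every trial and
#' therefore realises the theoretical minimum session length of
#' `run_criterion * max_categories` trials (90 under defaults). It is the only
#' policy allowed to see the active rule; every other policy must infer the
#' rule from feedback.
#'
#' @return A policy function for [run_session()].
#' @export
oracle_policy <- function() {
  f <- function(state) {
    pile_lookup(state$card, state$active_rule, state$keys)
  }
  attr(f, "privileged") <- TRUE
  class(f) <- c("bcst_policy", class(f))
  f
}

#' Uniform random policy
#'
#' Chooses each pile with probability 1/4, independently of the cards and
#' feedback. Since every card has a unique correct pile, the per-trial
#' probability of a correct response is exactly 1/4.
#'
#' @param seed Integer seed; the same seed replays the same choice sequence.
#' @return A policy function for [run_session()].
#' @export
random_policy <- function(seed) {
  rng <- rng_stream(seed)
  f <- function(state) {
    1L + as.integer(floor(rng_unif(rng) * 4)) %% 4L
  }
  class(f) <- c("bcst_policy", class(f))
  f
}

#' Policy that always chooses one fixed pile
#'
#' A degenerate baseline: a fixed pile is correct only when the up-card
#' happens to share the active attribute with that key card, so the set
#' criterion is essentially never met and the session runs the whole deck.
#'
#' @param pile Pile index 1..4.
#' @return A policy function for [run_session()].
#' @export
fixed_pile_policy <- function(pile = 1L) {
  pile <- as.integer(pile)
  stopifnot(pile >= 1L, pile <= 4L)
  f <- function(state) pile
  class(f) <- c("bcst_policy", class(f))
  f
}

#' Behavioral parameters of a simulated respondent
#'
#' @param persev_prob Probability in \[0,1\] of continuing to sort by the
#'   previously reinforced dimension after feedback turns negative (the
#'   perseveration tendency).
#' @param lapse_prob Probability in \[0,1\] that any trial's choice is replaced
#'   by a uniformly random pile.
#' @param learning_rate Multiplicative decay in \[0,1\] applied to
#'   `persev_prob` after each completed set; values below 1 emulate
#'   respondents who perseverate less as they learn the task mechanics.
#' @param seed Integer seed driving all of the agent's randomness.
#' @return A list of class `bcst_agent_params`.
#' @export
agent_params <- function(persev_prob, lapse_prob, learning_rate = 1,
                         seed = 1L) {
  for (nm in c("persev_prob", "lapse_prob", "learning_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a probability in [0,1]", nm), call. = FALSE)
  }
  structure(list(persev_prob = persev_prob, lapse_prob = lapse_prob,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "bcst_agent_params")
}

#' Win-stay/lose-shift respondent with tunable perseveration
#'
#' The minimal agent family that reproduces the qualitative error signatures
#' of human card sorting: perseverative runs after rule switches, one or two
#' non-perseverative search errors per switch, and (with `learning_rate < 1`)
#' declining perseveration across sets.
#'
#' Behavior: while feedback is positive the agent repeats the dimension last
#' reinforced (win-stay). On negative feedback, with probability
#' `persev_prob` it returns to the previously reinforced dimension (a
#' perseverative response); otherwise it shifts to a dimension not yet ruled
#' out in the current search episode (lose-shift, elimination without
#' replacement, so at most two incorrect trials are needed to find the new
#' rule among three dimensions). With probability `lapse_prob` any trial is
#' replaced by a uniform random pile; lapse trials neither reinforce nor rule
#' out a dimension, since the intended dimension was not expressed. After each
#' completed set `persev_prob` is multiplied by `learning_rate`. Ambiguous
#' positive feedback (the chosen pile consistent with several dimensions)
#' reinforces the dimension the agent intended, not all consistent ones.
#'
#' @param params An [agent_params()] object.
#' @return A policy function for [run_session()].
#' @examples
#' p <- parametric_policy(agent_params(0.4, 0.02, 0.9, seed = 7))
#' run_session(p, session_config(deck_seed = 7, start_rule_seed = 7))
#' @export
parametric_policy <- function(params) {
  if (!inherits(params, "bcst_agent_params"))
    params <- do.call(agent_params, params)
  rng <- rng_stream(params$seed)

  st <- new.env(parent = emptyenv())
  st$persev_prob <- params$persev_prob
  st$reinforced <- NA_character_   # last dimension confirmed by feedback
  st$current <- NA_character_      # dimension the agent intends to sort by
  st$ruled_out <- character(0)     # eliminated this search episode
  st$last_lapse <- FALSE
  st$run <- 0L

  f <- function(state) {
    # Process feedback from the previous trial before choosing.
    h <- state$history
    if (h$n > 0L) {
      ok <- h$correct[h$n]
      # The agent knows the standard completion criterion (ten consecutive
      # correct) and decays its perseveration tendency once per completed set.
      if (ok) {
        st$run <- st$run + 1L
        if (st$run == 10L) {
          st$run <- 0L
          st$persev_prob <- st$persev_prob * params$learning_rate
        }
      } else st$run <- 0L
      if (!st$last_lapse) {
        if (ok) {
          st$reinforced <- st$current
          st$ruled_out <- character(0)
        } else {
          st$ruled_out <- union(st$ruled_out, st$current)
          if (!is.na(st$reinforced) && rng_unif(rng) < st$persev_prob) {
            st$current <- st$reinforced        # perseverate
          } else {
            cand <- setdiff(bcst_dimensions, st$ruled_out)
            if (length(cand) == 0L) {          # everything eliminated: restart
              st$ruled_out <- character(0)
              cand <- setdiff(bcst_dimensions, st$current)
            }
            st$current <- rng_pick(rng, cand)
          }
        }
      }
    }
    if (is.na(st$current)) st$current <- rng_pick(rng, bcst_dimensions)

    if (rng_unif(rng) < params$lapse_prob) {
      st$last_lapse <- TRUE
      return(1L + as.integer(floor(rng_unif(rng) * 4)) %% 4L)
    }
    st$last_lapse <- FALSE
    pile_lookup(state$card, st$current, state$keys)
  }
  class(f) <- c("bcst_policy", class(f))
  attr(f, "params") <- params
  f
}

#' Draw heterogeneous agent parameters for a simulated cohort
#'
#' Per-subject parameters are drawn from configurable distributions; the
#' defaults (`persev_prob ~ Beta(2,3)`, `lapse_prob ~ Beta(1,20)`,
#' `learning_rate ~ Uniform(0.7, 1)`) give a cohort with wide, stable
#' between-subject variation in perseveration and accuracy.
#'
#' @param n Number of subjects.
#' @param distributions A list as returned by [default_agent_distributions()],
#'   or a path to a YAML file with the same structure.
#' @param seed Integer seed.
#' @return A data frame with one row per subject: `subject`, `persev_prob`,
#'   `lapse_prob`, `learning_rate`, `seed`.
#' @export
draw_agent_params <- function(n, distributions = default_agent_distributions(),
                              seed = 1L) {
  if (is.character(distributions) && length(distributions) == 1L)
    distributions <- read_agent_distributions(distributions)
  d <- distributions
  with_seed(seed, {
    data.frame(
      subject = seq_len(n),
      persev_prob = stats::rbeta(n, d$persev_prob$shape1, d$persev_prob$shape2),
      lapse_prob = stats::rbeta(n, d$lapse_prob$shape1, d$lapse_prob$shape2),
      learning_rate = stats::runif(n, d$learning_rate$min, d$learning_rate$max),
      seed = sample.int(.Machine$integer.max, n)
    )
  })
}

#' Default agent parameter distributions
#' @return A nested list giving the population distribution of each agent
#'   parameter.
#' @export
default_agent_distributions <- function() {
  list(
    persev_prob = list(dist = "beta", shape1 = 2, shape2 = 3),
    lapse_prob = list(dist = "beta", shape1 = 1, shape2 = 20),
    learning_rate = list(dist = "uniform", min = 0.7, max = 1.0)
  )
}

#' Read agent parameter distributions from a YAML config
#' @param path Path to a YAML file mirroring [default_agent_distributions()].
#' @return A distributions list; missing entries fall back to the defaults.
#' @export
read_agent_distributions <- function(path) {
  if (!file.exists(path))
    stop_io(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  out <- default_agent_distributions()
  for (nm in intersect(names(cfg), names(out)))
    out[[nm]] <- utils::modifyList(out[[nm]], cfg[[nm]])
  out
}
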