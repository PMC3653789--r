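#' Classify every response in a session
#'
#' Applies the Berg/PEBL perseveration criterion: a response is
#' *perseverative* when a previous rule exists (set 2 onward) and the chosen
#' pile is the pile that would be correct under the rule of the immediately
#' preceding set. A *perseverative error* is a perseverative response that is
#' also incorrect under the active rule. This criterion is deliberately more
#' liberal than the Heaton/WCST-manual rules: whether the response is also
#' correct under the active rule does not block the perseverative flag, so
#' perseverative responses can outnumber total errors.
#'
#' @param session A `bcst_session` (or any compatible trial data frame wrapped
#'   in one).
#' @param keys Key cards, default canonical.
#' @return A data frame with one row per trial: `correct`, `error`,
#'   `perseverative_response`, `perseverative_error`.
#' @export
classify_responses <- function(session, keys = build_key_cards()) {
  tr <- session_trials(session)
  validate_key_cards(keys)
  has_prev <- !is.na(tr$previous_rule) & tr$previous_rule != ""
  prev_pile <- rep(NA_integer_, nrow(tr))
  if (any(has_prev))
    prev_pile[has_prev] <- correct_pile(tr[has_prev, , drop = FALSE],
                                        tr$previous_rule[has_prev], keys)
  pr <- has_prev & tr$chosen_pile == prev_pile
  data.frame(
    correct = tr$correct,
    error = !tr$correct,
    perseverative_response = pr,
    perseverative_error = pr & !tr$correct
  )
}

#' Classify a single trial
#'
#' Single-trial convenience wrapper around [classify_responses()].
#'
#' @param trial A one-row trial data frame (or list) with fields `color`,
#'   `shape`, `number`, `chosen_pile`, `correct`, `active_rule`,
#'   `previous_rule` (`NA` or `""` in set 1).
#' @param keys Key cards, default canonical.
#' @return A one-row data frame of response flags.
#' @examples
#' # A choice matching the previous set's rule but not the active one:
#' classify_response(list(color = "green", shape = "circle", number = 3,
#'                        chosen_pile = 4, correct = FALSE,
#'                        active_rule = "COLOR", previous_rule = "SHAPE"))
#' @export
classify_response <- function(trial, keys = build_key_cards()) {
  tr <- as.data.frame(trial, stringsAsFactors = FALSE)
  classify_responses(structure(list(trials = tr), class = "bcst_session"),
                     keys)
}

#' @noRd
session_trials <- function(session) {
  if (inherits(session, "bcst_session")) return(session$trials)
  if (is.data.frame(session)) return(session)
  stop("`session` must be a bcst_session or a trial data frame",
       call. = FALSE)
}

#' Score an inclusive trial range
#'
#' Counts total errors, perseverative responses and perseverative errors over
#' trials `first_trial..last_trial`, plus the number of categories whose
#' completing trial (the one carrying the criterion-th consecutive correct
#' response) falls inside the range; a set in progress at a range boundary
#' counts for neither side. Percent measures divide by the number of trials
#' scored, matching the convention of reporting each measure as a percentage
#' of the trials completed.
#'
#' @param session A `bcst_session`.
#' @param first_trial,last_trial 1-based inclusive range bounds.
#' @param keys Key cards, default canonical.
#' @return A list of class `bcst_scores`: `scope`, `trials_scored`,
#'   `total_errors_raw`, `persev_responses_raw`, `persev_errors_raw`,
#'   `categories_completed`, `total_errors_pct`, `persev_responses_pct`,
#'   `persev_errors_pct`.
#' @export
score_range <- function(session, first_trial, last_trial,
                        keys = build_key_cards()) {
  tr <- session_trials(session)
  n <- nrow(tr)
  first_trial <- as.integer(first_trial)
  last_trial <- as.integer(last_trial)
  if (is.na(first_trial) || is.na(last_trial) ||
      first_trial < 1L || last_trial > n || first_trial > last_trial)
    stop(sprintf("invalid trial range [%s, %s] for a %d-trial session",
                 first_trial, last_trial, n), call. = FALSE)

  flags <- classify_responses(session, keys)
  idx <- first_trial:last_trial
  scored <- length(idx)

  completing <- set_completion_trials(session)
  cats <- sum(completing >= first_trial & completing <= last_trial)

  te <- sum(flags$error[idx])
  pr <- sum(flags$perseverative_response[idx])
  pe <- sum(flags$perseverative_error[idx])

  structure(list(
    scope = sprintf("trials %d-%d", first_trial, last_trial),
    trials_scored = scored,
    total_errors_raw = te,
    persev_responses_raw = pr,
    persev_errors_raw = pe,
    categories_completed = cats,
    total_errors_pct = 100 * te / scored,
    persev_responses_pct = 100 * pr / scored,
    persev_errors_pct = 100 * pe / scored
  ), class = "bcst_scores")
}

#' Trial indices on which each completed set's criterion run ended
#'
#' A set ends exactly on the trial carrying its criterion-th consecutive
#' correct response, so the completing trial of set s is the last trial
#' labelled with set s (for completed sets only).
#' @noRd
set_completion_trials <- function(session) {
  tr <- session_trials(session)
  k <- if (inherits(session, "bcst_session")) session$categories_completed
  else infer_categories_completed(tr)
  if (k == 0L) return(integer(0))
  vapply(seq_len(k), function(s) max(tr$trial[tr$set == s]), integer(1))
}

#' Completed-set count from a bare trial table (e.g. a parsed log): every set
#' followed by another set completed; the final set completed iff it ends in
#' `run_criterion` consecutive correct responses.
#' @noRd
infer_categories_completed <- function(tr, run_criterion = 10L) {
  last_set <- max(tr$set)
  tail_ok <- tr$correct[tr$set == last_set]
  n_tail <- length(tail_ok)
  last_done <- n_tail >= run_criterion &&
    all(tail_ok[(n_tail - run_criterion + 1L):n_tail])
  (last_set - 1L) + as.integer(last_done)
}

#' Score a full session plus the 64-trial short form
#'
#' Produces the three standard summaries: the full-length session, the first
#' 64 trials (the short form) and the remaining trials (65 to end).
#'
#' @param session A `bcst_session` with at least 65 trials (any session run
#'   to termination under default settings has at least 90).
#' @param keys Key cards, default canonical.
#' @return A named list of class `bcst_score_set` with elements `full`,
#'   `first_half`, `second_half`, each a `bcst_scores`.
#' @examples
#' s <- run_session(oracle_policy(), session_config(deck_seed = 1))
#' score_session(s)$full$categories_completed  # 9
#' @export
score_session <- function(session, keys = build_key_cards()) {
  tr <- session_trials(session)
  n <- nrow(tr)
  if (n < 65L)
    stop(sprintf("session has %d trials; at least 65 are required to score the short form", n),
         call. = FALSE)
  out <- list(
    full = score_range(session, 1L, n, keys),
    first_half = score_range(session, 1L, 64L, keys),
    second_half = score_range(session, 65L, n, keys)
  )
  out$full$scope <- "full"
  out$first_half$scope <- "first64"
  out$second_half$scope <- "remainder"
  class(out) <- "bcst_score_set"
  out
}

#' @export
print.bcst_scores <- function(x, ...) {
  cat(format_scores(x), sep = "\n")
  invisible(x)
}

#' @export
print.bcst_score_set <- function(x, ...) {
  for (s in x) cat(format_scores(s), "", sep = "\n")
  invisible(x)
}

#' Format a score summary as a human-readable text block
#' @param scores A `bcst_scores` object.
#' @return A character vector of lines.
#' @export
format_scores <- function(scores) {
  c(sprintf("Scope: %s (%d trials scored)", scores$scope,
            scores$trials_scored),
    sprintf("  Total errors:        %3d  (%.1f%%)",
            scores$total_errors_raw, scores$total_errors_pct),
    sprintf("  Persev. responses:   %3d  (%.1f%%)",
            scores$persev_responses_raw, scores$persev_responses_pct),
    sprintf("  Persev. errors:      %3d  (%.1f%%)",
            scores$persev_errors_raw, scores$persev_errors_pct),
    sprintf("  Categories completed:%3d", scores$categories_completed))
}

#' Flatten score summaries to a data frame
#'
#' @param scores A `bcst_scores`, a `bcst_score_set`, or a list of either.
#' @return A data frame with one row per summary.
#' @export
scores_to_df <- function(scores) {
  if (inherits(scores, "bcst_scores")) scores <- list(scores)
  if (inherits(scores, "bcst_score_set")) scores <- unclass(scores)
  do.call(rbind, lapply(scores, function(s)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)))
}
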