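# Error conditions carrying the CLI exit-code taxonomy:
# 2 validation, 3 parse, 4 I/O.

#' @noRd
stop_validation <- function(msg) {
  stop(structure(class = c("bcst_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @noRd
stop_parse <- function(msg) {
  stop(structure(class = c("bcst_parse_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @noRd
stop_io <- function(msg) {
  stop(structure(class = c("bcst_io_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

session_log_header <- c("trial", "set", "active_rule", "previous_rule",
                        "color", "shape", "number", "chosen_pile", "correct")

#' Write a session trial log as CSV
#'
#' One row per trial with columns `trial`, `set`, `active_rule`,
#' `previous_rule` (empty in set 1), `color`, `shape`, `number`,
#' `chosen_pile`, `correct` (0/1). UTF-8, comma-separated, unquoted.
#'
#' @param session A `bcst_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  tr <- session_trials(session)
  out <- data.frame(
    trial = tr$trial, set = tr$set, active_rule = tr$active_rule,
    previous_rule = ifelse(is.na(tr$previous_rule), "", tr$previous_rule),
    color = tr$color, shape = tr$shape, number = tr$number,
    chosen_pile = tr$chosen_pile, correct = as.integer(tr$correct),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io(sprintf("cannot write session log to %s", path))
  invisible(path)
}

#' Read a session trial log from CSV
#'
#' Parses the dialect written by [write_session()] and reconstructs a
#' `bcst_session`. Each row is validated; a malformed row raises a parse
#' error naming its line number. The completed-category count is inferred
#' from the run structure (a terminal set counts as completed when it ends in
#' `run_criterion` consecutive correct responses).
#'
#' @param path Path to a trial-log CSV.
#' @param sep Field separator (a reader shim for alternative delimiters).
#' @param run_criterion Consecutive-correct criterion used to infer terminal
#'   set completion (default 10).
#' @return A `bcst_session` (with `config = NULL`).
#' @export
read_session <- function(path, sep = ",", run_criterion = 10L) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  tr <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      stringsAsFactors = FALSE, fill = TRUE,
                      colClasses = "character"),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))))
  if (!identical(names(tr), session_log_header))
    stop_parse(sprintf("%s: header must be '%s'", path,
                       paste(session_log_header, collapse = ",")))
  n <- nrow(tr)
  num_cols <- c("trial", "set", "number", "chosen_pile", "correct")
  for (cc in num_cols) {
    v <- suppressWarnings(as.integer(tr[[cc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_parse(sprintf("%s: line %d: field '%s' is not an integer",
                         path, bad[1] + 1L, cc))
    tr[[cc]] <- v
  }
  check_domain <- function(cc, domain) {
    bad <- which(!(tr[[cc]] %in% domain))
    if (length(bad))
      stop_parse(sprintf("%s: line %d: invalid %s '%s'",
                         path, bad[1] + 1L, cc, tr[[cc]][bad[1]]))
  }
  check_domain("color", bcst_colors)
  check_domain("shape", bcst_shapes)
  check_domain("number", bcst_numbers)
  check_domain("chosen_pile", 1:4)
  check_domain("correct", 0:1)
  check_domain("active_rule", bcst_dimensions)
  check_domain("previous_rule", c("", bcst_dimensions))
  if (!identical(tr$trial, seq_len(n)))
    stop_parse(sprintf("%s: trial indices must be 1-based and contiguous",
                       path))
  trials <- data.frame(
    trial = tr$trial, set = tr$set, active_rule = tr$active_rule,
    previous_rule = ifelse(tr$previous_rule == "", NA_character_,
                           tr$previous_rule),
    color = tr$color, shape = tr$shape, number = tr$number,
    chosen_pile = tr$chosen_pile, correct = tr$correct == 1L,
    stringsAsFactors = FALSE)
  structure(list(
    trials = trials,
    categories_completed = infer_categories_completed(trials, run_criterion),
    config = NULL
  ), class = "bcst_session")
}

#' Write score summaries as CSV
#'
#' One row per summary (scope, trials scored, raw and percent measures,
#' categories completed).
#'
#' @param scores A `bcst_scores`, `bcst_score_set`, or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scores, path) {
  df <- scores_to_df(scores)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io(sprintf("cannot write score report to %s", path))
  invisible(path)
}

#' Generate the canned reference sessions used by golden tests
#'
#' Writes four deterministic session logs to `dir`: an error-free oracle
#' session (90 trials), a uniform random-responder session (128 trials), a
#' maximal perseverator (`persev_prob = 1`, 128 trials, one category) and a
#' mixed moderate agent, plus a `manifest.csv` recording seeds and agent
#' parameters.
#'
#' @param seed Integer master seed.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the session log paths, invisibly.
#' @export
make_fixtures <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- function(k) session_config(deck_seed = seed + k,
                                    start_rule_seed = seed + 100L + k)
  specs <- list(
    oracle = list(policy = oracle_policy(), params = NA),
    random = list(policy = random_policy(seed + 201L), params = NA),
    perseverator = list(
      policy = parametric_policy(agent_params(1, 0, 1, seed = seed + 202L)),
      params = "persev_prob=1,lapse_prob=0,learning_rate=1"),
    mixed = list(
      policy = parametric_policy(agent_params(0.4, 0.05, 0.9,
                                              seed = seed + 203L)),
      params = "persev_prob=0.4,lapse_prob=0.05,learning_rate=0.9")
  )
  paths <- character(0)
  manifest <- list()
  for (k in seq_along(specs)) {
    nm <- names(specs)[k]
    s <- run_session(specs[[k]]$policy, cfg(k))
    p <- file.path(dir, paste0(nm, "_session.csv"))
    write_session(s, p)
    paths[nm] <- p
    manifest[[nm]] <- data.frame(
      fixture = nm, deck_seed = seed + k, start_rule_seed = seed + 100L + k,
      agent = specs[[k]]$params, n_trials = nrow(s$trials),
      categories = s$categories_completed, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}
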