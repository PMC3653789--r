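#' Pearson product-moment correlation with strict input checks
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return The correlation coefficient in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant vector", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Two-sided p-value for a Pearson correlation via the t transform
#' @param r Correlation coefficient.
#' @param n Number of paired observations (df = n - 2).
#' @return Two-sided p-value.
#' @export
pearson_p <- function(r, n) {
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

# The four measures of the validation battery. The three error measures enter
# the correlations as percentages; categories completed as a raw count.
cohort_measures <- c("total_errors_pct", "persev_responses_pct",
                     "persev_errors_pct", "categories_completed")
measure_labels <- c(total_errors_pct = "Total errors (%)",
                    persev_responses_pct = "Persev. responses (%)",
                    persev_errors_pct = "Persev. errors (%)",
                    categories_completed = "Categories completed")

#' Simulate a cohort and run the short-form validation battery
#'
#' Draws `n` heterogeneous win-stay/lose-shift agents, runs one full session
#' each (independent deck shuffles and starting rules), scores the full
#' session, the first 64 trials and the remainder, and computes two Pearson
#' correlation batteries per measure: short-vs-long (first 64 vs full, a
#' part-whole correlation) and first-vs-second-half (first 64 vs trials 65+).
#' Everything is reproducible from `master_seed`.
#'
#' @param n Number of simulated subjects (at least 10).
#' @param param_distributions Agent parameter distributions; see
#'   [default_agent_distributions()]. May be a YAML file path.
#' @param master_seed Integer seed for the whole cohort.
#' @param groups Optional vector of length `n` of group labels; the
#'   correlation battery is additionally computed within each group with at
#'   least 3 members (smaller groups are skipped with a warning).
#' @param config_template A [session_config()] whose non-seed settings are
#'   applied to every session.
#' @param policy_factory Optional function of one row of drawn parameters
#'   returning a policy; overrides the default win-stay/lose-shift agent.
#'   A factory ignoring its argument (e.g. always the oracle) produces a
#'   zero-variance cohort, which is flagged degenerate and reported with
#'   undefined correlations rather than fabricated ones.
#' @return A list of class `bcst_cohort`: `n_subjects`, `subjects` (tibble of
#'   per-subject measures, wide: `<measure>_full`, `<measure>_first64`,
#'   `<measure>_second`), `params` (drawn agent parameters), `correlations`
#'   (tibble: `measure`, `r_short_long`, `r_halves`, `df`, `p_short_long`,
#'   `p_halves`), `summary` (mean/SD tibble), `degenerate` (logical),
#'   `group_correlations` (list, if `groups` given).
#' @export
simulate_cohort <- function(n, param_distributions = default_agent_distributions(),
                            master_seed = 1L, groups = NULL,
                            config_template = session_config(),
                            policy_factory = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L)
    stop("`n` must be at least 10", call. = FALSE)
  if (!is.null(groups) && length(groups) != n)
    stop("`groups` must have length `n`", call. = FALSE)

  params <- draw_agent_params(n, param_distributions, seed = master_seed)
  session_seeds <- with_seed(master_seed + 1L,
                             matrix(sample.int(.Machine$integer.max, 2L * n),
                                    ncol = 2L))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config_template
    cfg$deck_seed <- session_seeds[i, 1L]
    cfg$start_rule_seed <- session_seeds[i, 2L]
    pol <- if (is.null(policy_factory))
      parametric_policy(agent_params(
        params$persev_prob[i], params$lapse_prob[i], params$learning_rate[i],
        seed = params$seed[i]))
    else policy_factory(params[i, , drop = FALSE])
    sc <- score_session(run_session(pol, cfg))
    rows[[i]] <- c(
      subject = i, n_trials = sc$full$trials_scored,
      stats::setNames(unlist(lapply(sc$full[cohort_measures], identity)),
                      paste0(cohort_measures, "_full")),
      stats::setNames(unlist(lapply(sc$first_half[cohort_measures], identity)),
                      paste0(cohort_measures, "_first64")),
      stats::setNames(unlist(lapply(sc$second_half[cohort_measures], identity)),
                      paste0(cohort_measures, "_second")),
      stats::setNames(unlist(lapply(sc$full[paste0(sub("_pct$", "", cohort_measures[1:3]), "_raw")], identity)),
                      paste0(sub("_pct$", "_raw", cohort_measures[1:3]), "_full")),
      stats::setNames(unlist(lapply(sc$first_half[paste0(sub("_pct$", "", cohort_measures[1:3]), "_raw")], identity)),
                      paste0(sub("_pct$", "_raw", cohort_measures[1:3]), "_first64")),
      stats::setNames(unlist(lapply(sc$second_half[paste0(sub("_pct$", "", cohort_measures[1:3]), "_raw")], identity)),
                      paste0(sub("_pct$", "_raw", cohort_measures[1:3]), "_second"))
    )
  }
  subjects <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))

  batt <- correlation_battery(subjects)
  res <- list(
    n_subjects = n,
    subjects = subjects,
    params = tibble::as_tibble(params),
    correlations = batt$table,
    summary = cohort_summary_table(subjects),
    degenerate = batt$degenerate
  )
  if (!is.null(groups)) {
    res$groups <- groups
    res$group_correlations <- lapply(split(seq_len(n), groups), function(idx) {
      if (length(idx) < 3L) {
        warning(sprintf("group with %d member(s) skipped: correlation undefined",
                        length(idx)), call. = FALSE)
        return(NULL)
      }
      correlation_battery(subjects[idx, , drop = FALSE])$table
    })
  }
  class(res) <- "bcst_cohort"
  res
}

#' @noRd
correlation_battery <- function(subjects) {
  degenerate <- FALSE
  safe_r <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      degenerate <<- TRUE
      return(NA_real_)
    }
    pearson_r(x, y)
  }
  nn <- nrow(subjects)
  rows <- lapply(cohort_measures, function(m) {
    full <- subjects[[paste0(m, "_full")]]
    f64 <- subjects[[paste0(m, "_first64")]]
    sec <- subjects[[paste0(m, "_second")]]
    r1 <- safe_r(f64, full)
    r2 <- safe_r(f64, sec)
    tibble::tibble(
      measure = m, label = unname(measure_labels[m]),
      r_short_long = r1, r_halves = r2, df = nn - 2L,
      p_short_long = if (is.na(r1)) NA_real_ else pearson_p(r1, nn),
      p_halves = if (is.na(r2)) NA_real_ else pearson_p(r2, nn)
    )
  })
  list(table = do.call(rbind, rows), degenerate = degenerate)
}

#' @noRd
cohort_summary_table <- function(subjects) {
  scopes <- c(full = "_full", first64 = "_first64", second = "_second")
  meas <- c("total_errors", "persev_responses", "persev_errors")
  rows <- list()
  for (m in meas) for (s in names(scopes)) {
    raw <- subjects[[paste0(m, "_raw", scopes[s])]]
    pct <- subjects[[paste0(m, "_pct", scopes[s])]]
    rows[[paste(m, s)]] <- tibble::tibble(
      measure = m, scope = s,
      raw_mean = mean(raw), raw_sd = stats::sd(raw),
      pct_mean = mean(pct), pct_sd = stats::sd(pct))
  }
  for (s in names(scopes)) {
    cc <- subjects[[paste0("categories_completed", scopes[s])]]
    rows[[paste("categories", s)]] <- tibble::tibble(
      measure = "categories_completed", scope = s,
      raw_mean = mean(cc), raw_sd = stats::sd(cc),
      pct_mean = NA_real_, pct_sd = NA_real_)
  }
  do.call(rbind, rows)
}

#' @export
print.bcst_cohort <- function(x, ...) {
  cat(sprintf("<bcst_cohort> %d subjects%s\n", x$n_subjects,
              if (x$degenerate) " (degenerate: some correlations undefined)"
              else ""))
  print(x$correlations[, c("label", "r_short_long", "r_halves", "df")])
  invisible(x)
}

#' Format a cohort validation report
#'
#' Produces a plain-text report: a mean (SD) grid over the full form, the
#' first 64 trials and the remaining trials (raw and percent), followed by the
#' correlation battery (short-vs-long and first-vs-second-half) with
#' df = n - 2 and two-sided p-values.
#'
#' @param result A `bcst_cohort` from [simulate_cohort()].
#' @return A character vector of report lines.
#' @export
validation_report <- function(result) {
  stopifnot(inherits(result, "bcst_cohort"))
  fmt_ms <- function(m, s) sprintf("%.1f (%.1f)", m, s)
  sm <- result$summary
  lines <- c(
    sprintf("Cohort validation report (n = %d subjects)", result$n_subjects),
    "",
    sprintf("%-22s %-18s %-18s %-18s", "Measure",
            "Full-length", "First 64", "Remainder"),
    sprintf("%-22s %-18s %-18s %-18s", "", "Raw / %", "Raw / %", "Raw / %"))
  for (m in c("total_errors", "persev_responses", "persev_errors")) {
    cells <- vapply(c("full", "first64", "second"), function(s) {
      r <- sm[sm$measure == m & sm$scope == s, ]
      sprintf("%s / %s", fmt_ms(r$raw_mean, r$raw_sd),
              fmt_ms(r$pct_mean, r$pct_sd))
    }, character(1))
    lines <- c(lines, sprintf("%-22s %-18s %-18s %-18s", m,
                              cells[1], cells[2], cells[3]))
  }
  cc <- vapply(c("full", "first64", "second"), function(s) {
    r <- sm[sm$measure == "categories_completed" & sm$scope == s, ]
    fmt_ms(r$raw_mean, r$raw_sd)
  }, character(1))
  lines <- c(lines, sprintf("%-22s %-18s %-18s %-18s", "categories_completed",
                            cc[1], cc[2], cc[3]), "")
  ct <- result$correlations
  fmt_r <- function(r, df, p) {
    if (is.na(r)) "undefined (degenerate cohort)"
    else sprintf("r(%d) = %.3f, p = %.3g", df, r, p)
  }
  lines <- c(lines, "Short form (first 64) vs full-length:")
  for (i in seq_len(nrow(ct)))
    lines <- c(lines, sprintf("  %-22s %s", ct$label[i],
                              fmt_r(ct$r_short_long[i], ct$df[i],
                                    ct$p_short_long[i])))
  lines <- c(lines, "First 64 vs remaining trials:")
  for (i in seq_len(nrow(ct)))
    lines <- c(lines, sprintf("  %-22s %s", ct$label[i],
                              fmt_r(ct$r_halves[i], ct$df[i], ct$p_halves[i])))
  lines
}
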