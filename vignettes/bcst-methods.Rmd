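---
title: "Card sorting simulation and short-form validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Card sorting simulation and short-form validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcst)
```

## The task model

The Berg Card Sorting Test presents a shuffled 128-card deck — every
combination of four colors, four shapes and quantities one to four, each
combination appearing exactly twice — to be sorted onto four fixed key piles
(one red triangle, two green stars, three yellow crosses, four blue
circles). Because each attribute value appears on exactly one key card, every
card has a unique correct pile under each of the three possible rules, and a
uniformly random responder is correct with probability exactly 1/4.

The engine's contract with a respondent policy is deliberately narrow: the
policy sees the key cards, the current card and the full feedback history,
and returns a pile index. It never sees the active rule, when the rule
changes, or what the rule changed to — rule discovery must run through
feedback, as in the administered test. The single exception is the oracle
policy, a test-harness device that realises the 90-trial theoretical minimum
and anchors several exact expectations (90 trials, 9 categories, 0 errors).

Two readings of the completion criterion were possible; the package reads
"ten cards successfully matched" as ten *consecutive* correct responses,
with the counter reset on every error and at every rule change. This is the
standard convention for card sorting tasks and the only reading under which
90 trials is a best case rather than a typical case. The starting rule is
drawn uniformly from the three dimensions using its own seed; subsequent
rules follow a fixed configurable cycle (default color → shape → number)
entered at the random start. The cycle successor order is not observable
from published descriptions of the task, so it is a configuration knob
rather than a constant. Likewise, whether the original implementation
excludes cards identical to key cards from the deck is unknown; a
`exclude_key_identical` flag exists and defaults to off (the full 64 × 2
deck).

## Scoring

The scorer implements the liberal Berg/PEBL perseveration criterion: the
perseverative dimension is the rule of the immediately preceding set,
updating at every rule change, and a response is perseverative exactly when
that previous-set rule exists and the chosen pile is the card's pile under
it. Correctness under the active rule does not veto the flag, which has two
consequences worth stating plainly:

- correct responses can be perseverative (card lands on the same pile under
  both rules), so raw perseverative responses may exceed raw total errors;
- in set 1 nothing is perseverative, because no prior rule exists.

The multi-clause Heaton-manual rules are intentionally not implemented —
they answer a different question and would change every downstream number.

Range scoring (`score_range`) counts flags over an inclusive trial window.
A category is attributed to the trial on which its tenth consecutive correct
response lands; a set in progress at a window boundary counts for neither
side, which makes the three standard windows (full, trials 1–64, trials
65–end) exactly additive measure-by-measure. Percentages divide by the
number of trials scored in the window — the full form therefore uses trials
actually taken (90–128), and the short form uses 64.

## The agent family

No respondent model ships with the administered test, so the package
provides the minimal family that produces the qualitative error signatures
seen in humans: win-stay/lose-shift with a perseveration parameter. While
feedback is positive the agent repeats the dimension last reinforced. On an
error it either returns to the previously reinforced dimension with
probability `persev_prob` (a perseverative response by construction) or
eliminates: it shifts to a dimension not yet ruled out in the current search
episode. Elimination without replacement over three dimensions bounds every
consecutive-error run at two for a non-perseverating, lapse-free agent — the
"one or two non-perseverative errors after a rule change" signature. A
per-trial `lapse_prob` substitutes a uniformly random pile; lapse trials
neither reinforce nor rule out a dimension, since the intended dimension was
not expressed. Ambiguous positive feedback (a pile consistent with several
dimensions) reinforces only the dimension the agent intended; the
ruled-out memory resets whenever feedback turns positive.

`learning_rate` multiplies `persev_prob` after each completed set, emulating
respondents who perseverate less as they learn the task's mechanics. Cohort
heterogeneity comes from per-subject parameter draws, by default
`persev_prob ~ Beta(2, 3)` (mean 0.4, broad), `lapse_prob ~ Beta(1, 20)`
(mostly attentive, occasional lapses) and `learning_rate ~ Uniform(0.7, 1)`
(from strong learners to non-learners). These defaults were fixed once as a
plausible normative-population profile: they yield cohorts in which most
subjects finish most of the nine sets within the deck while a perseverative
tail does not, with wide stable between-subject variance on all four
measures.

### The first-half/second-half perseveration contrast

One directional claim deserves care. One might expect learning agents
(`learning_rate < 1`) to show lower perseverative-response percentages in
trials 65–end than in trials 1–64. Simulation shows the opposite for every
parameterization we examined, for a structural reason: set 1 has no
perseverative dimension, so a sizable slice of the first window cannot
contribute perseverative responses at all, deflating the first-half
percentage for every agent. That measurement artifact (worth roughly five
points) dominates the decay — which is the same excess of raw second-half
perseveration over first-half that human cohorts show. The test suite
therefore asserts two separate properties: (i) the artifact direction
(second-half PR% exceeds first-half on average), and (ii) the learning
effect proper, isolated by a seed-matched contrast — a learner
(`learning_rate = 0.5`) versus a non-learning twin on identical decks,
starting rules and agent seeds shows second-half PR% lower by roughly 20
points. Conflating the two comparisons would test nothing.

## Cohort analysis

`simulate_cohort` draws `n` agents, plays one full session each (independent
deck shuffles and starting rules derived from the master seed), scores the
three windows and computes two Pearson batteries per measure: short-vs-long
(first 64 against full, a part–whole correlation) and first-vs-second-half
(a part–part correlation). The three error measures enter as percentages,
categories completed as a count. p-values use the t transform with
df = n − 2, two-sided, uncorrected. Part–whole correlations structurally
dominate part–part correlations (the part is contained in the whole), and
the simulated cohorts reproduce that ordinal pattern robustly; the
magnitudes of human samples are sample statistics and are not a target of
the simulation. A cohort in which any measure is constant across subjects is
flagged degenerate and the affected correlations are reported as undefined
rather than silently propagated as NaN — an all-oracle cohort, for example,
has zero variance in errors and categories (undefined) but retains
deck-driven variance in perseverative responses (defined).

Grouped batteries (`groups =`) recompute the correlations within each group
of at least three subjects; smaller groups are skipped with a warning since
the correlation is undefined below df = 1.

## Numerical and design choices

- **Determinism.** Every stochastic component (deck shuffle, starting rule,
  agent choices, cohort parameter draws) has an explicit integer seed;
  policies own private buffered RNG streams, so replays are bit-identical
  and independent of the caller's RNG state. All derived seeds stay within
  32-bit integer range.
- **Problem sizes.** Property tests run on batches of tens of generated
  sessions; the scorer-equivalence check uses 1,000 random-policy sessions
  against an independently written naive rescorer; the validation-pattern
  check uses 20 cohorts of n = 200. These sizes give stable medians and
  tight binomial intervals while keeping the default test run fast.
- **Chance level.** The random-policy calibration uses the exact binomial
  99% interval around 1/4 over 10,000+ trials.
- **Degenerate inputs.** Inverted or out-of-range scoring windows, invalid
  pile choices (with the offending trial index), out-of-range agent
  probabilities (named), malformed log rows (with line numbers) and
  sub-65-trial sessions all fail loudly with typed conditions, which the
  command-line layer maps to distinct exit codes.
- **Logs are plain CSV** with a fixed header; previous rule is empty in
  set 1 and correctness is 0/1. Round-tripping a session through disk is
  lossless, and the completed-category count of a parsed log is inferred
  from the run structure of its final set.

## What the simulations do and do not show

The agent family reproduces choice-level mechanics: chance-level baselines,
perseverative runs after switches, bounded search errors, learning across
sets, and the part–whole correlation structure of short-form validation. It
does not model response times, age or sex effects, fatigue, strategy shifts
other than exponential perseveration decay, or any clinical population; mean
levels of errors in simulated cohorts sit below typical human normative
samples because lapses are the only non-strategic error source. Passing
cohort-level tests therefore supports the scoring and analysis machinery and
the ordinal part–whole pattern — not any claim about human short-form
equivalence, which only human data can establish.
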