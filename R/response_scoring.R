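#' Keypress acceptance window for a task
#'
#' The window, relative to target onset, within which a keypress may count
#' as a response to that target: one stimulus before to two stimuli after
#' onset, i.e. `(-soa, +2 * soa)`. For the standard designs this gives
#' (-480, +960) ms for the auditory tasks and (-1000, +2000) ms for the
#' visual tasks, so both anticipations and delayed responses are accepted.
#'
#' @param config An [task_config()] object.
#' @return Numeric vector `c(lower, upper)` in ms.
#' @examples
#' accept_window(task_config("syllable")) # -480  960
#' @export
accept_window <- function(config) {
  stopifnot(inherits(config, "sl_task_config"))
  if (!config$modality %in% c("visual", "auditory")) {
    stop("unknown modality: ", config$modality, call. = FALSE)
  }
  c(lower = -config$soa_ms, upper = 2 * config$soa_ms)
}

# Core matcher on bare vectors (also used by the cohort scorer).
# target_onsets must be sorted. Returns hit target indices (into
# target_onsets), latencies, and indices of unassigned keypresses.
match_keypresses <- function(target_onsets, keypresses, window) {
  nt <- length(target_onsets)
  nk <- length(keypresses)
  if (nt == 0L || nk == 0L) {
    return(list(hit_target = integer(0), latency = numeric(0),
                unassigned = seq_len(nk)))
  }
  # Candidate targets for each keypress: the two targets bracketing it.
  j0 <- findInterval(keypresses, target_onsets)
  cand_kp <- c(seq_len(nk), seq_len(nk))
  cand_tg <- c(j0, j0 + 1L)
  keep <- cand_tg >= 1L & cand_tg <= nt
  cand_kp <- cand_kp[keep]; cand_tg <- cand_tg[keep]
  lat <- keypresses[cand_kp] - target_onsets[cand_tg]
  keep <- lat >= window[1] & lat <= window[2]
  cand_kp <- cand_kp[keep]; cand_tg <- cand_tg[keep]; lat <- lat[keep]
  # Greedy one-to-one assignment: smallest |latency| first; ties go to the
  # earlier target, then the earlier keypress.
  ord <- order(abs(lat), cand_tg, cand_kp)
  kp_taken <- logical(nk)
  tg_taken <- logical(nt)
  hit_tg <- integer(length(ord)); hit_lat <- numeric(length(ord))
  nh <- 0L
  for (r in ord) {
    k <- cand_kp[r]; j <- cand_tg[r]
    if (!kp_taken[k] && !tg_taken[j]) {
      kp_taken[k] <- TRUE
      tg_taken[j] <- TRUE
      nh <- nh + 1L
      hit_tg[nh] <- j
      hit_lat[nh] <- lat[r]
    }
  }
  hit_tg <- hit_tg[seq_len(nh)]; hit_lat <- hit_lat[seq_len(nh)]
  o <- order(hit_tg)
  list(hit_target = hit_tg[o], latency = hit_lat[o],
       unassigned = which(!kp_taken))
}

#' Assign keypresses to targets and false alarms
#'
#' Matches a sorted keypress log against the target occurrences of a
#' familiarization stream. Each keypress is assigned to at most one target
#' and each target claims at most one keypress; contested keypresses are
#' resolved by minimal absolute latency, with ties going to the earlier
#' target. Keypresses that end up in no target's window are false alarms,
#' attributed to the stimulus event whose onset interval contains them.
#'
#' @param stream An `sl_stream`.
#' @param keypresses Numeric vector of keypress times in ms from stream
#'   onset, sorted increasingly.
#' @param window Acceptance window `c(lower, upper)`; defaults to
#'   [accept_window()] of the stream's config.
#' @return A list with `hits` (tibble: `target_occurrence_index`,
#'   `latency_ms`), `false_alarms` (tibble: `time_ms`, `event_index`), and
#'   `n_false_alarms`.
#' @export
assign_keypresses <- function(stream, keypresses, window = NULL) {
  config <- attr(stream, "config")
  window <- window %||% accept_window(config)
  if (is.unsorted(keypresses)) {
    stop("keypress log must be sorted in time", call. = FALSE)
  }
  target_onsets <- stream$onset_ms[stream$is_target]
  m <- match_keypresses(target_onsets, keypresses, window)
  fa_times <- keypresses[m$unassigned]
  ev <- pmax(findInterval(fa_times, stream$onset_ms), 1L)
  list(
    hits = tibble(target_occurrence_index = m$hit_target,
                  latency_ms = m$latency),
    false_alarms = tibble(time_ms = fa_times, event_index = ev),
    n_false_alarms = length(fa_times)
  )
}

#' Grier's A' nonparametric sensitivity
#'
#' Nonparametric signal-detection sensitivity from hit rate H and
#' false-alarm rate F: 0.5 at chance (H = F), 1 for perfect detection.
#' For H >= F, `A' = 0.5 + ((H - F)(1 + H - F)) / (4 H (1 - F))`;
#' for H < F the symmetric form `0.5 - ((F - H)(1 + F - H)) / (4 F (1 - H))`.
#'
#' @param hit_rate,fa_rate Rates in `[0, 1]` (vectorized).
#' @return A' values in `[0, 1]`.
#' @examples
#' compute_a_prime(0.8, 0.1) # 0.9132
#' @export
compute_a_prime <- function(hit_rate, fa_rate) {
  check_that(
    "hit_rate must be in [0, 1]" = all(hit_rate >= 0 & hit_rate <= 1),
    "fa_rate must be in [0, 1]" = all(fa_rate >= 0 & fa_rate <= 1),
    .prefix = "invalid rates"
  )
  n <- max(length(hit_rate), length(fa_rate))
  h <- rep_len(hit_rate, n); f <- rep_len(fa_rate, n)
  out <- rep(0.5, n)
  up <- h > f
  dn <- h < f
  out[up] <- 0.5 + ((h[up] - f[up]) * (1 + h[up] - f[up])) /
    (4 * h[up] * (1 - f[up]))
  out[dn] <- 0.5 - ((f[dn] - h[dn]) * (1 + f[dn] - h[dn])) /
    (4 * f[dn] * (1 - h[dn]))
  out
}

#' Score one participant's target detection
#'
#' Runs [assign_keypresses()] and summarizes hits, false alarms, rates and
#' A' for one participant x task. The false-alarm denominator is the number
#' of non-target stimulus events.
#'
#' @param stream An `sl_stream`.
#' @param keypresses Sorted keypress times (ms).
#' @param participant_id,task Identifiers copied into the summary.
#' @return A list with `summary` (one-row tibble: `participant_id`, `task`,
#'   `n_targets`, `n_events`, `n_hits`, `n_false_alarms`, `hit_rate`,
#'   `fa_rate`, `a_prime`, `excluded_rt` = NA, `exclusion_reason` = NA;
#'   exclusion flags are filled by [apply_exclusions()]) and `hits` (the
#'   hit table with identifiers).
#' @export
score_detection <- function(stream, keypresses, participant_id = "P1",
                            task = NULL) {
  config <- attr(stream, "config")
  task <- task %||% config$task_name
  asg <- assign_keypresses(stream, keypresses)
  n_targets <- sum(stream$is_target)
  n_events <- nrow(stream)
  n_hits <- nrow(asg$hits)
  hr <- n_hits / n_targets
  fr <- asg$n_false_alarms / (n_events - n_targets)
  fr <- min(fr, 1) # a flood of keypresses cannot exceed a rate of 1
  list(
    summary = tibble(
      participant_id = participant_id, task = task,
      n_targets = n_targets, n_events = n_events,
      n_hits = n_hits, n_false_alarms = asg$n_false_alarms,
      hit_rate = hr, fa_rate = fr,
      a_prime = compute_a_prime(hr, fr),
      excluded_rt = NA, exclusion_reason = NA_character_
    ),
    hits = dplyr::bind_cols(
      tibble(participant_id = participant_id, task = task)[rep(1, n_hits), ],
      asg$hits
    )
  )
}

#' Apply the RT-analysis exclusion rules
#'
#' Flags participants to be excluded from reaction-time analyses, per task
#' and diagnostic group: first, participants with fewer than `min_hits`
#' valid keypresses (assigned hits) in a task; second, among the remaining
#' participants, extreme outliers whose A' falls strictly below the group
#' mean minus `a_prime_sd` standard deviations (computed within group x
#' task on the survivors of the first rule). Exclusion affects RT analyses
#' only, never 2-AFC accuracy. The operation is idempotent: flags are
#' recomputed from the counts and A' values, so re-applying it changes
#' nothing.
#'
#' @param summaries Detection summaries (rows per participant x task) with
#'   columns `n_hits`, `a_prime`, `task`, and the grouping columns.
#' @param min_hits Minimum number of valid keypresses (default 6).
#' @param a_prime_sd SD multiplier of the A' outlier rule (default 3).
#' @param group_cols Columns defining the exclusion strata (default
#'   `c("task", "group")`; falls back to `"task"` when no `group` column is
#'   present).
#' @return `summaries` with `excluded_rt` (logical) and `exclusion_reason`
#'   (`"too_few_keypresses"`, `"a_prime_outlier"`, or `"none"`) filled in.
#' @export
apply_exclusions <- function(summaries, min_hits = 6, a_prime_sd = 3,
                             group_cols = c("task", "group")) {
  group_cols <- intersect(group_cols, names(summaries))
  too_few <- summaries$n_hits < min_hits
  summaries$excluded_rt <- too_few
  summaries$exclusion_reason <- ifelse(too_few, "too_few_keypresses", "none")
  strata <- interaction(summaries[group_cols], drop = TRUE)
  for (s in levels(strata)) {
    in_s <- strata == s
    surv <- in_s & !too_few
    if (sum(surv) < 2) {
      if (sum(in_s) > 0) {
        warning("A' outlier rule skipped for stratum '", s,
                "': fewer than 2 surviving participants", call. = FALSE)
      }
      next
    }
    m <- mean(summaries$a_prime[surv])
    sdev <- sd(summaries$a_prime[surv])
    out <- surv & summaries$a_prime < m - a_prime_sd * sdev
    summaries$excluded_rt[out] <- TRUE
    summaries$exclusion_reason[out] <- "a_prime_outlier"
  }
  summaries
}
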