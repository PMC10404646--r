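#' Ground-truth behavioral parameters for one simulated participant
#'
#' Describes keypress and 2-AFC behavior in one task. The reaction-time
#' model is linear in target occurrence index on a latent z scale:
#' `latency = baseline + rt_scale_ms * (slope_adj * (t - mean(t)) + noise)`,
#' with `noise ~ N(0, rt_noise_sd_z)` and `slope_adj` calibrated so that
#' the expected OLS slope of the *sample-z-normed* latencies on `t` equals
#' `true_rt_slope` (sample standardization divides by the total trend+noise
#' SD, which a naive parameterization would ignore).
#'
#' @param participant_id,group,age_years,sex Metadata (`group` is `"TD"` or
#'   `"ASD"`, `sex` is `"F"`/`"M"`).
#' @param baseline_rt_ms Mean latency at the middle target occurrence.
#' @param true_rt_slope Target slope of z-normed RT per target occurrence
#'   (negative = learning-driven acceleration).
#' @param rt_noise_sd_z Latent-scale trial-to-trial RT noise SD (z units).
#' @param rt_scale_ms Conversion from latent z units to milliseconds.
#' @param hit_prob Probability of responding to a target.
#' @param anticipation_prob Probability that a hit is an anticipation
#'   (latency drawn uniformly between the window's lower edge and 0).
#' @param fa_rate_per_nontarget Probability of a spurious keypress on each
#'   non-target stimulus (uniform within its SOA interval).
#' @param afc_accuracy_prob Per-trial probability of a correct 2-AFC
#'   response.
#' @param language_level `"at_above"`, `"below"`, or `NA`.
#' @param sentence_recall_raw Integer 0-32 or `NA`.
#' @return A validated list of class `sl_participant_params`.
#' @export
participant_params <- function(participant_id = "P001", group = "TD",
                               age_years = 8.5, sex = "M",
                               baseline_rt_ms = 450, true_rt_slope = -0.01,
                               rt_noise_sd_z = 0.4, rt_scale_ms = 150,
                               hit_prob = 0.85, anticipation_prob = 0.05,
                               fa_rate_per_nontarget = 0.02,
                               afc_accuracy_prob = 0.6,
                               language_level = NA_character_,
                               sentence_recall_raw = NA_real_) {
  p <- list(
    participant_id = participant_id, group = group, age_years = age_years,
    sex = sex, baseline_rt_ms = baseline_rt_ms, true_rt_slope = true_rt_slope,
    rt_noise_sd_z = rt_noise_sd_z, rt_scale_ms = rt_scale_ms,
    hit_prob = hit_prob, anticipation_prob = anticipation_prob,
    fa_rate_per_nontarget = fa_rate_per_nontarget,
    afc_accuracy_prob = afc_accuracy_prob,
    language_level = language_level,
    sentence_recall_raw = sentence_recall_raw
  )
  check_that(
    "hit_prob must be in [0, 1]" = p$hit_prob >= 0 && p$hit_prob <= 1,
    "anticipation_prob must be in [0, 1]" =
      p$anticipation_prob >= 0 && p$anticipation_prob <= 1,
    "fa_rate_per_nontarget must be in [0, 1]" =
      p$fa_rate_per_nontarget >= 0 && p$fa_rate_per_nontarget <= 1,
    "afc_accuracy_prob must be in [0, 1]" =
      p$afc_accuracy_prob >= 0 && p$afc_accuracy_prob <= 1,
    "rt_noise_sd_z must be > 0" = p$rt_noise_sd_z > 0,
    "rt_scale_ms must be > 0" = p$rt_scale_ms > 0,
    "group must be TD or ASD" = p$group %in% c("TD", "ASD"),
    .prefix = "invalid participant parameters"
  )
  structure(p, class = "sl_participant_params")
}

# Latent z-scale latencies for targets 1..T with the slope calibration
# described in ?participant_params.
simulate_latencies <- function(T, true_slope, noise_sd, baseline, scale_ms) {
  t_idx <- seq_len(T)
  v <- var(t_idx) # sample variance, matching the z-norming denominator
  shrink <- max(1 - true_slope^2 * v, 0.05)
  slope_adj <- true_slope * noise_sd / sqrt(shrink)
  y <- slope_adj * (t_idx - mean(t_idx)) + rnorm(T, 0, noise_sd)
  baseline + scale_ms * y
}

# Vectorized keypress generator on bare onset vectors; the engine behind
# simulate_keypresses() and the cohort simulator.
sim_keypress_times <- function(tg_onsets, nt_onsets, soa, win,
                               baseline, true_slope, noise_sd, scale_ms,
                               hit_prob, anticipation_prob, fa_rate) {
  T <- length(tg_onsets)
  lat <- simulate_latencies(T, true_slope, noise_sd, baseline, scale_ms)
  ant <- runif(T) < anticipation_prob
  lat[ant] <- runif(sum(ant), win[1], 0)
  lat <- pmin(pmax(lat, win[1] + 1), win[2] - 1)
  hit <- runif(T) < hit_prob
  times <- tg_onsets[hit] + lat[hit]
  fa <- runif(length(nt_onsets)) < fa_rate
  if (any(fa)) {
    times <- c(times, nt_onsets[fa] + runif(sum(fa), 0, soa))
  }
  sort(times)
}

#' Simulate a keypress log for one participant and stream
#'
#' Emits a sorted vector of keypress times: for each target occurrence,
#' with probability `hit_prob`, a keypress at onset plus a latency from the
#' linear-acceleration RT model (see [participant_params()]); with
#' probability `anticipation_prob` that latency is replaced by an
#' anticipation uniformly inside the negative half of the acceptance
#' window. Latencies are clamped just inside the window. Each non-target
#' stimulus independently triggers a false alarm with probability
#' `fa_rate_per_nontarget`, uniform within its SOA interval.
#'
#' @param stream An `sl_stream`.
#' @param params An [participant_params()] object.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of keypress times (ms).
#' @export
simulate_keypresses <- function(stream, params, seed = NULL) {
  stopifnot(inherits(params, "sl_participant_params"))
  config <- attr(stream, "config")
  win <- accept_window(config)
  with_seed_(seed, {
    sim_keypress_times(
      stream$onset_ms[stream$is_target], stream$onset_ms[!stream$is_target],
      config$soa_ms, win,
      params$baseline_rt_ms, params$true_rt_slope, params$rt_noise_sd_z,
      params$rt_scale_ms, params$hit_prob, params$anticipation_prob,
      params$fa_rate_per_nontarget)
  })
}

#' Simulate 2-AFC test responses for one participant
#'
#' Each test trial is answered correctly with probability
#' `afc_accuracy_prob`, independently across trials.
#'
#' @param test_trials Test phase tibble from [generate_test_phase()].
#' @param params An [participant_params()] object.
#' @param seed Optional integer seed.
#' @return `test_trials` with an added 0/1 `correct` column.
#' @export
simulate_afc <- function(test_trials, params, seed = NULL) {
  stopifnot(inherits(params, "sl_participant_params"))
  with_seed_(seed, {
    test_trials$correct <- rbinom(nrow(test_trials), 1,
                                  params$afc_accuracy_prob)
    test_trials
  })
}

#' Default group x domain effect map for simulated cohorts
#'
#' Cell means of the true RT slope (z per occurrence) and 2-AFC accuracy
#' emulating the qualitative pattern reported for school-aged TD and ASD
#' children: a TD advantage concentrated in the linguistic domain, with
#' comparable nonlinguistic performance. `slope_age_coef` and
#' `accuracy_age_coef` shift the cell mean per year of age (centered at
#' 8.5 years); zero by default.
#'
#' @return Tibble with columns `group`, `domain`, `mean_slope`,
#'   `mean_accuracy`, `slope_age_coef`, `accuracy_age_coef`.
#' @export
default_effects <- function() {
  tibble(
    group = c("TD", "TD", "ASD", "ASD"),
    domain = c("linguistic", "nonlinguistic", "linguistic", "nonlinguistic"),
    mean_slope = c(-0.012, -0.004, -0.004, -0.006),
    mean_accuracy = c(0.61, 0.63, 0.55, 0.61),
    slope_age_coef = 0,
    accuracy_age_coef = 0
  )
}

#' Specification of a simulated cohort
#'
#' Collects the group sizes, effect map, individual-difference dispersions,
#' demographics, and nuisance parameters from which [simulate_cohort()]
#' draws a full synthetic dataset. Defaults emulate the published study
#' conditions: 50 TD / 55 ASD children aged about 6-12.6 years, girls
#' overrepresented in TD, roughly one child in eight stopping after three
#' of the four tasks, and sentence-recall scores collected for about
#' two-thirds of each group.
#'
#' @param n_td,n_asd Participants per group (each >= 2).
#' @param effects Effect map as in [default_effects()].
#' @param slope_sd Between-participant SD of the true RT slope
#'   (z/occurrence).
#' @param accuracy_kappa Concentration of the Beta distribution of
#'   per-participant 2-AFC accuracy around its cell mean.
#' @param baseline_rt_mean,baseline_rt_sd Baseline RT distribution (ms).
#' @param rt_noise_sd_z,rt_scale_ms,hit_prob,anticipation_prob,fa_rate
#'   Keypress model parameters shared by all participants (see
#'   [participant_params()]).
#' @param age_mean_td,age_sd_td,age_mean_asd,age_sd_asd,age_range Age
#'   distributions (normal, truncated to `age_range`).
#' @param p_girl_td,p_girl_asd Probability of `sex == "F"` per group.
#' @param missing_task_prob Probability that a participant stops after
#'   three tasks (one task dropped at random, completely at random).
#' @param p_assessment_td,p_assessment_asd Probability that sentence-recall
#'   scores are available.
#' @param recall_mean_td,recall_sd_td,recall_mean_asd,recall_sd_asd
#'   Sentence-recall raw score distributions (0-32 scale).
#' @param ability_cor_td,ability_cor_asd Within-participant correlation of
#'   the two linguistic tasks' true abilities (slope and accuracy draws
#'   share a latent linguistic-ability factor with this coupling). Emulates
#'   the stronger coupling of written- and spoken-language SL observed in
#'   typical development versus its absence in ASD.
#' @param recall_coupling_td,recall_coupling_asd Correlation between a
#'   participant's latent linguistic SL ability and their sentence-recall
#'   score.
#' @param p_below_language_asd Proportion of ASD children with below-age
#'   parent-rated language level.
#' @param stream_mode `"per_participant"` (each participant gets their own
#'   randomized stream order) or `"shared"` (one stream per task per
#'   cohort; the target triplet is still randomized per participant).
#'   Stream order is response-independent, so `"shared"` leaves all test
#'   statistics distributionally unchanged and is used for large
#'   Monte-Carlo runs.
#' @param tasks Character vector of task names to simulate.
#' @param seed Integer seed for the whole cohort.
#' @return A validated list of class `sl_cohort_spec`.
#' @export
cohort_spec <- function(n_td = 50, n_asd = 55,
                        effects = default_effects(),
                        slope_sd = 0.02, accuracy_kappa = 40,
                        baseline_rt_mean = 450, baseline_rt_sd = 80,
                        rt_noise_sd_z = 0.4, rt_scale_ms = 150,
                        hit_prob = 0.85, anticipation_prob = 0.05,
                        fa_rate = 0.02,
                        age_mean_td = 8.63, age_sd_td = 1.89,
                        age_mean_asd = 8.28, age_sd_asd = 1.20,
                        age_range = c(6, 12.6),
                        p_girl_td = 28 / 50, p_girl_asd = 10 / 55,
                        missing_task_prob = 13 / 105,
                        ability_cor_td = 0.7, ability_cor_asd = 0,
                        p_assessment_td = 34 / 50, p_assessment_asd = 33 / 55,
                        recall_mean_td = 27.26, recall_sd_td = 4.61,
                        recall_mean_asd = 19.91, recall_sd_asd = 8.18,
                        recall_coupling_td = 0.2, recall_coupling_asd = 0.5,
                        p_below_language_asd = 26 / 46,
                        stream_mode = c("per_participant", "shared"),
                        tasks = c("image", "letter", "tone", "syllable"),
                        seed = NULL) {
  stream_mode <- match.arg(stream_mode)
  spec <- as.list(environment())
  check_that(
    "n_td and n_asd must each be >= 2" = n_td >= 2 && n_asd >= 2,
    "effects must cover all group x domain cells" =
      nrow(dplyr::distinct(effects[, c("group", "domain")])) == 4,
    "effect accuracies must be probabilities" =
      all(effects$mean_accuracy > 0 & effects$mean_accuracy < 1),
    "probabilities must be in [0, 1]" =
      all(c(hit_prob, anticipation_prob, fa_rate, missing_task_prob,
            p_girl_td, p_girl_asd, p_assessment_td, p_assessment_asd,
            p_below_language_asd) >= 0) &&
      all(c(hit_prob, anticipation_prob, fa_rate, missing_task_prob,
            p_girl_td, p_girl_asd, p_assessment_td, p_assessment_asd,
            p_below_language_asd) <= 1),
    "slope_sd must be > 0" = slope_sd > 0,
    "accuracy_kappa must be > 0" = accuracy_kappa > 0,
    "ability correlations must be in [0, 1]" =
      all(c(ability_cor_td, ability_cor_asd) >= 0 &
            c(ability_cor_td, ability_cor_asd) <= 1),
    .prefix = "invalid cohort spec"
  )
  structure(spec, class = "sl_cohort_spec")
}

rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Simulate a full cohort dataset
#'
#' Draws participants, task designs, familiarization streams, keypress
#' logs, and 2-AFC responses for every participant x task, with known
#' ground-truth learning parameters, forming a complete synthetic stand-in
#' for a real multi-task SL study. Some participants are missing one task
#' when `missing_task_prob > 0`.
#'
#' @param spec An [cohort_spec()] object.
#' @return A list of class `sl_cohort` with elements `participants`,
#'   `params` (ground truth per participant x task), `streams` (named list
#'   `streams[[task]]` for shared mode, `streams[[task]][[participant]]`
#'   otherwise), `targets` (assigned target triplet per participant x
#'   task), `keypresses` (tibble: participant_id, task, time_ms), `afc`
#'   (tibble: participant_id, task, trial_id, item, correct), `inventories`,
#'   `foils`, `test_phases`, and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sl_cohort_spec"))
  with_seed_(spec$seed, {
    n <- spec$n_td + spec$n_asd
    participants <- tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = rep(c("TD", "ASD"), c(spec$n_td, spec$n_asd)),
      age_years = c(
        rtruncnorm_(spec$n_td, spec$age_mean_td, spec$age_sd_td,
                    spec$age_range[1], spec$age_range[2]),
        rtruncnorm_(spec$n_asd, spec$age_mean_asd, spec$age_sd_asd,
                    spec$age_range[1], spec$age_range[2])
      ),
      sex = ifelse(
        runif(n) < ifelse(rep(c(TRUE, FALSE), c(spec$n_td, spec$n_asd)),
                          spec$p_girl_td, spec$p_girl_asd),
        "F", "M")
    )

    configs <- lapply(setNames(spec$tasks, spec$tasks), task_config)
    inventories <- lapply(configs, function(cfg) {
      build_triplet_inventory(
        sprintf("%s_%02d", cfg$task_name, seq_len(cfg$n_stimuli)))
    })
    foils <- lapply(spec$tasks, function(tk) build_foils(inventories[[tk]]))
    names(foils) <- spec$tasks
    test_phases <- lapply(spec$tasks, function(tk) {
      generate_test_phase(inventories[[tk]], foils[[tk]], configs[[tk]])
    })
    names(test_phases) <- spec$tasks

    # Which tasks each participant completed (missing completely at random,
    # at most one task dropped).
    drops <- runif(n) < spec$missing_task_prob
    dropped_task <- ifelse(drops, sample(spec$tasks, n, replace = TRUE),
                           NA_character_)
    grid <- tidyr::expand_grid(
      participant_id = participants$participant_id, task = spec$tasks) %>%
      left_join(tibble(participant_id = participants$participant_id,
                       dropped = dropped_task), by = "participant_id") %>%
      filter(is.na(.data$dropped) | .data$task != .data$dropped) %>%
      select(-"dropped")

    # Ground-truth per participant x task parameters.
    task_meta <- tibble(
      task = spec$tasks,
      domain = vapply(configs, `[[`, "", "domain")[spec$tasks],
      modality = vapply(configs, `[[`, "", "modality")[spec$tasks]
    )
    params <- grid %>%
      left_join(participants, by = "participant_id") %>%
      left_join(task_meta, by = "task") %>%
      left_join(spec$effects, by = c("group", "domain"))
    age_c <- params$age_years - 8.5
    mu_acc <- pmin(pmax(
      params$mean_accuracy + params$accuracy_age_coef * age_c, 0.02), 0.98)
    # A latent linguistic-ability factor per participant couples the two
    # linguistic tasks' draws; nonlinguistic draws stay independent.
    lat <- tibble(participant_id = participants$participant_id,
                  ability = rnorm(n))
    params <- params %>% left_join(lat, by = "participant_id")
    rho <- ifelse(params$group == "TD", spec$ability_cor_td,
                  spec$ability_cor_asd)
    rho <- ifelse(params$domain == "linguistic", rho, 0)
    # slope: higher ability -> more negative slope; accuracy: Gaussian
    # copula onto the Beta marginal so cell means are untouched
    z_slope <- sqrt(rho) * (-params$ability) +
      sqrt(1 - rho) * rnorm(nrow(params))
    z_acc <- sqrt(rho) * params$ability + sqrt(1 - rho) * rnorm(nrow(params))
    params <- params %>%
      mutate(
        true_rt_slope = .data$mean_slope + .data$slope_age_coef * age_c +
          spec$slope_sd * z_slope,
        afc_accuracy_prob = stats::qbeta(pnorm(z_acc),
                                         mu_acc * spec$accuracy_kappa,
                                         (1 - mu_acc) * spec$accuracy_kappa),
        baseline_rt_ms = rtruncnorm_(dplyr::n(), spec$baseline_rt_mean,
                                     spec$baseline_rt_sd, 150, 1200)
      ) %>%
      select(-"mean_slope", -"mean_accuracy", -"slope_age_coef",
             -"accuracy_age_coef", -"ability")

    # Target triplet assignment: uniformly random per participant per task.
    params$target_triplet_id <- vapply(params$task, function(tk) {
      sample(inventories[[tk]]$triplet_id, 1L)
    }, character(1))

    # Familiarization streams.
    streams <- list()
    if (spec$stream_mode == "shared") {
      for (tk in spec$tasks) {
        streams[[tk]] <- generate_familiarization_stream(
          inventories[[tk]], configs[[tk]],
          target_triplet_id = inventories[[tk]]$triplet_id[1])
      }
    } else {
      for (tk in spec$tasks) streams[[tk]] <- list()
      for (r in seq_len(nrow(params))) {
        tk <- params$task[r]
        streams[[tk]][[params$participant_id[r]]] <-
          generate_familiarization_stream(
            inventories[[tk]], configs[[tk]],
            target_triplet_id = params$target_triplet_id[r])
      }
    }

    # Keypress logs. Target/non-target onsets per (task, target triplet) are
    # cached: in shared mode there are only n_tasks x n_triplets combinations.
    onset_cache <- new.env(parent = emptyenv())
    get_onsets <- function(tk, pid, tgt) {
      if (spec$stream_mode == "shared") {
        key <- paste(tk, tgt)
        if (is.null(onset_cache[[key]])) {
          st <- retarget_stream(streams[[tk]], tgt)
          onset_cache[[key]] <- list(tg = st$onset_ms[st$is_target],
                                     nt = st$onset_ms[!st$is_target])
        }
        onset_cache[[key]]
      } else {
        st <- streams[[tk]][[pid]]
        list(tg = st$onset_ms[st$is_target], nt = st$onset_ms[!st$is_target])
      }
    }
    kp_times <- vector("list", nrow(params))
    for (r in seq_len(nrow(params))) {
      tk <- params$task[r]
      on <- get_onsets(tk, params$participant_id[r],
                       params$target_triplet_id[r])
      kp_times[[r]] <- sim_keypress_times(
        on$tg, on$nt, configs[[tk]]$soa_ms, configs[[tk]]$hit_window_ms,
        params$baseline_rt_ms[r], params$true_rt_slope[r],
        spec$rt_noise_sd_z, spec$rt_scale_ms, spec$hit_prob,
        spec$anticipation_prob, spec$fa_rate)
    }
    n_kp <- lengths(kp_times)
    keypresses <- tibble(
      participant_id = rep(params$participant_id, n_kp),
      task = rep(params$task, n_kp),
      time_ms = unlist(kp_times)
    )

    # 2-AFC responses: one grid for the whole cohort; the item label pairs
    # the two repetitions of each target x foil combination.
    n_trials <- nrow(test_phases[[1]])
    afc <- tidyr::expand_grid(
      params[, c("participant_id", "task", "afc_accuracy_prob")],
      trial_id = seq_len(n_trials)
    ) %>%
      mutate(
        item = sprintf("%s_item%02d", .data$task,
                       ((.data$trial_id - 1L) %% (n_trials %/% 2L)) + 1L),
        correct = rbinom(dplyr::n(), 1, .data$afc_accuracy_prob)
      ) %>%
      select(-"afc_accuracy_prob")

    # Latent linguistic SL ability (standardized), used to couple language
    # measures to linguistic task performance.
    ling <- params %>%
      filter(.data$domain == "linguistic") %>%
      group_by(.data$participant_id) %>%
      summarise(z_ling = mean(-.data$true_rt_slope / spec$slope_sd +
                                (.data$afc_accuracy_prob - 0.5) * 4) / 2,
                .groups = "drop")
    ling$z_ling <- as.numeric(scale(ling$z_ling))
    participants <- left_join(participants, ling, by = "participant_id")
    participants$z_ling[is.na(participants$z_ling)] <- 0

    is_asd <- participants$group == "ASD"
    lang_latent <- 0.8 * participants$z_ling + rnorm(n)
    below <- lang_latent < stats::quantile(lang_latent[is_asd],
                                           spec$p_below_language_asd)
    participants$language_level <- ifelse(
      is_asd, ifelse(below, "below", "at_above"), NA_character_)

    has_assess <- runif(n) < ifelse(is_asd, spec$p_assessment_asd,
                                    spec$p_assessment_td)
    rho <- ifelse(is_asd, spec$recall_coupling_asd, spec$recall_coupling_td)
    mu_r <- ifelse(is_asd, spec$recall_mean_asd, spec$recall_mean_td)
    sd_r <- ifelse(is_asd, spec$recall_sd_asd, spec$recall_sd_td)
    recall <- mu_r + rho * sd_r * participants$z_ling +
      sqrt(1 - rho^2) * sd_r * rnorm(n)
    participants$sentence_recall_raw <-
      ifelse(has_assess, pmin(pmax(round(recall), 0), 32), NA_real_)
    participants$z_ling <- NULL

    structure(list(
      participants = participants,
      params = params,
      configs = configs,
      inventories = inventories,
      foils = foils,
      test_phases = test_phases,
      streams = streams,
      keypresses = keypresses,
      afc = afc,
      spec = spec
    ), class = "sl_cohort")
  })
}

#' @export
print.sl_cohort <- function(x, ...) {
  cat(sprintf(
    "<sl_cohort> %d participants (%d TD, %d ASD), tasks: %s\n  %d keypress rows, %d 2-AFC rows, stream mode '%s'\n",
    nrow(x$participants), sum(x$participants$group == "TD"),
    sum(x$participants$group == "ASD"),
    paste(x$spec$tasks, collapse = ", "),
    nrow(x$keypresses), nrow(x$afc), x$spec$stream_mode
  ))
  invisible(x)
}

#' Score a simulated or loaded cohort
#'
#' Runs keypress assignment and detection scoring for every participant x
#' task in a cohort (or bundle read back from disk), then applies the
#' RT-exclusion rules per task and diagnostic group.
#'
#' @param cohort An `sl_cohort` (or `sl_bundle`).
#' @param min_hits,a_prime_sd Exclusion thresholds, see
#'   [apply_exclusions()].
#' @return A list with `summaries` (detection summaries incl. `group` and
#'   exclusion flags) and `hits` (tibble: participant_id, task,
#'   target_occurrence_index, latency_ms).
#' @export
score_cohort <- function(cohort, min_hits = 6, a_prime_sd = 3) {
  shared <- cohort$spec$stream_mode == "shared"
  params <- cohort$params
  kp_split <- split(cohort$keypresses$time_ms,
                    list(cohort$keypresses$participant_id,
                         cohort$keypresses$task), drop = TRUE)
  # Target onsets / window per (task, target triplet) are cached in shared
  # mode; the matcher itself is the same one assign_keypresses() uses.
  cache <- new.env(parent = emptyenv())
  geom_for <- function(r) {
    tk <- params$task[r]
    if (shared) {
      key <- paste(tk, params$target_triplet_id[r])
      if (is.null(cache[[key]])) {
        st <- retarget_stream(cohort$streams[[tk]],
                              params$target_triplet_id[r])
        cfg <- attr(st, "config")
        cache[[key]] <- list(tg = st$onset_ms[st$is_target],
                             n_events = nrow(st), win = accept_window(cfg))
      }
      cache[[key]]
    } else {
      st <- cohort$streams[[tk]][[params$participant_id[r]]]
      list(tg = st$onset_ms[st$is_target], n_events = nrow(st),
           win = accept_window(attr(st, "config")))
    }
  }
  n_rows <- nrow(params)
  n_targets <- integer(n_rows); n_events <- integer(n_rows)
  n_hits <- integer(n_rows); n_fa <- integer(n_rows)
  hit_idx <- vector("list", n_rows); hit_lat <- vector("list", n_rows)
  for (r in seq_len(n_rows)) {
    g <- geom_for(r)
    kp <- kp_split[[paste(params$participant_id[r], params$task[r],
                          sep = ".")]] %||% numeric(0)
    m <- match_keypresses(g$tg, kp, g$win)
    n_targets[r] <- length(g$tg)
    n_events[r] <- g$n_events
    n_hits[r] <- length(m$hit_target)
    n_fa[r] <- length(m$unassigned)
    hit_idx[[r]] <- m$hit_target
    hit_lat[[r]] <- m$latency
  }
  hr <- n_hits / n_targets
  fr <- pmin(n_fa / (n_events - n_targets), 1)
  summaries <- tibble(
    participant_id = params$participant_id, task = params$task,
    n_targets = n_targets, n_events = n_events,
    n_hits = n_hits, n_false_alarms = n_fa,
    hit_rate = hr, fa_rate = fr, a_prime = compute_a_prime(hr, fr),
    excluded_rt = NA, exclusion_reason = NA_character_
  ) %>%
    left_join(cohort$participants[, c("participant_id", "group")],
              by = "participant_id")
  summaries <- apply_exclusions(summaries, min_hits = min_hits,
                                a_prime_sd = a_prime_sd)
  hits <- tibble(
    participant_id = rep(params$participant_id, n_hits),
    task = rep(params$task, n_hits),
    target_occurrence_index = unlist(hit_idx),
    latency_ms = unlist(hit_lat)
  )
  list(summaries = summaries, hits = hits)
}

#' Individual SL measures and composites for a cohort
#'
#' Computes per participant x task z-normed RT slopes (excluded
#' participants and degenerate latency sets yield `NA`), 2-AFC accuracies,
#' and the composite and domain-composite scores.
#'
#' @param cohort An `sl_cohort` (or `sl_bundle`).
#' @param scored Output of [score_cohort()].
#' @param norm_within_group Passed to [composite_scores()].
#' @return A list with `measures` (per participant x task, incl. z-normed
#'   components and `composite`) and `domains` (domain composites).
#' @export
cohort_measures <- function(cohort, scored, norm_within_group = FALSE) {
  task_meta <- tibble(
    task = cohort$spec$tasks,
    domain = vapply(cohort$configs, `[[`, "", "domain")[cohort$spec$tasks],
    modality = vapply(cohort$configs, `[[`, "", "modality")[cohort$spec$tasks]
  )
  excl <- scored$summaries[, c("participant_id", "task", "excluded_rt",
                               "n_hits")]
  slopes <- scored$hits %>%
    group_by(.data$participant_id, .data$task) %>%
    summarise(
      rt_slope = {
        idx <- .data$target_occurrence_index
        lat <- .data$latency_ms
        if (length(lat) < 2 || length(unique(idx)) < 2 || sd(lat) == 0) {
          NA_real_
        } else {
          fit_rt_slope(znorm(lat), idx)
        }
      },
      n_rt_observations = dplyr::n(),
      .groups = "drop"
    )
  acc <- cohort$afc %>%
    group_by(.data$participant_id, .data$task) %>%
    summarise(afc_accuracy = afc_accuracy(.data$correct), .groups = "drop")
  measures <- excl %>%
    left_join(slopes, by = c("participant_id", "task")) %>%
    left_join(acc, by = c("participant_id", "task")) %>%
    mutate(
      rt_slope = ifelse(.data$excluded_rt %in% TRUE, NA_real_,
                        .data$rt_slope),
      n_rt_observations = dplyr::coalesce(.data$n_rt_observations, 0L)
    ) %>%
    left_join(task_meta, by = "task") %>%
    left_join(cohort$participants, by = "participant_id")
  composite_scores(measures, norm_within_group = norm_within_group)
}
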