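#' Task configuration for a triplet statistical-learning experiment
#'
#' Builds the design parameters of one statistical-learning (SL) task. The
#' four standard tasks cross sensory modality (visual/auditory) with domain
#' (linguistic/nonlinguistic): `image` (visual nonlinguistic), `letter`
#' (visual linguistic), `tone` (auditory nonlinguistic) and `syllable`
#' (auditory linguistic). Visual tasks present 12 stimuli at a 1000 ms
#' stimulus onset asynchrony (SOA) with each of the four triplets repeated
#' 24 times; auditory tasks use a 480 ms SOA with 48 repetitions per
#' triplet. Any preset value can be overridden, e.g. to build reduced
#' designs for simulation studies.
#'
#' @param task One of `"image"`, `"letter"`, `"tone"`, `"syllable"`.
#' @param n_triplets Number of embedded triplets (default 4; the stimulus
#'   inventory size is always `3 * n_triplets`).
#' @param reps_per_triplet Number of repetitions of each triplet in the
#'   familiarization stream (preset: 24 visual, 48 auditory).
#' @param soa_ms Stimulus onset asynchrony in ms (preset: 1000 visual, 480
#'   auditory).
#' @param stim_duration_ms Stimulus duration in ms (preset: 800 visual, 328
#'   tone, 350 syllable).
#' @param test_pause_ms Pause between the two test-trial options in ms.
#' @param test_reps Repetitions of the full target x foil crossing in the
#'   test phase.
#' @param allow_immediate_repeat Logical; may the same triplet occur twice
#'   in a row in the familiarization stream? Defaults to `FALSE`, which
#'   keeps the transitional probability across triplet boundaries below 1.
#'
#' @return An object of class `sl_task_config`: a named list with fields
#'   `task_name`, `modality`, `domain`, `n_stimuli`, `n_triplets`,
#'   `reps_per_triplet`, `soa_ms`, `stim_duration_ms`, `hit_window_ms`,
#'   `test_pause_ms`, `test_reps`, `allow_immediate_repeat`.
#' @examples
#' task_config("syllable")
#' task_config("image", reps_per_triplet = 2) # a toy design
#' @export
task_config <- function(task = c("image", "letter", "tone", "syllable"),
                        n_triplets = 4,
                        reps_per_triplet = NULL,
                        soa_ms = NULL,
                        stim_duration_ms = NULL,
                        test_pause_ms = 1000,
                        test_reps = 2,
                        allow_immediate_repeat = FALSE) {
  task <- match.arg(task)
  preset <- list(
    image    = list(modality = "visual",   domain = "nonlinguistic", reps = 24, soa = 1000, dur = 800),
    letter   = list(modality = "visual",   domain = "linguistic",    reps = 24, soa = 1000, dur = 800),
    tone     = list(modality = "auditory", domain = "nonlinguistic", reps = 48, soa = 480,  dur = 328),
    syllable = list(modality = "auditory", domain = "linguistic",    reps = 48, soa = 480,  dur = 350)
  )[[task]]
  reps <- reps_per_triplet %||% preset$reps
  soa <- soa_ms %||% preset$soa
  dur <- stim_duration_ms %||% preset$dur
  check_that(
    "n_triplets must be a single integer >= 1" = length(n_triplets) == 1 && n_triplets >= 1,
    "reps_per_triplet must be >= 1" = length(reps) == 1 && reps >= 1,
    "soa_ms must be > 0" = length(soa) == 1 && soa > 0,
    "stim_duration_ms must be > 0" = dur > 0,
    "test_pause_ms must be > 0" = test_pause_ms > 0,
    "test_reps must be >= 1" = test_reps >= 1,
    .prefix = "invalid task design"
  )
  cfg <- structure(list(
    task_name = task,
    modality = preset$modality,
    domain = preset$domain,
    n_stimuli = 3L * as.integer(n_triplets),
    n_triplets = as.integer(n_triplets),
    reps_per_triplet = as.integer(reps),
    soa_ms = as.numeric(soa),
    stim_duration_ms = as.numeric(dur),
    test_pause_ms = as.numeric(test_pause_ms),
    test_reps = as.integer(test_reps),
    allow_immediate_repeat = isTRUE(allow_immediate_repeat)
  ), class = "sl_task_config")
  cfg$hit_window_ms <- accept_window(cfg)
  cfg
}

#' @export
print.sl_task_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sl_task_config> %s (%s, %s)\n",
      "  %d stimuli in %d triplets x %d reps; SOA %g ms; stim %g ms\n",
      "  hit window [%g, %g] ms; test: %d x crossing, %g ms pause\n"
    ),
    x$task_name, x$modality, x$domain,
    x$n_stimuli, x$n_triplets, x$reps_per_triplet, x$soa_ms,
    x$stim_duration_ms, x$hit_window_ms[1], x$hit_window_ms[2],
    x$test_reps, x$test_pause_ms
  ))
  invisible(x)
}

#' Partition a stimulus set into target triplets
#'
#' Randomly partitions a set of stimulus identifiers into ordered triplets.
#' Element order within a triplet is fixed and meaningful (positions 1-3).
#'
#' @param stimulus_ids Character (or coercible) vector of distinct stimulus
#'   identifiers; the length must be divisible by 3.
#' @param seed Optional integer seed; the partition is deterministic given
#'   the seed.
#' @return A tibble with one row per triplet and columns `triplet_id`
#'   (`"T1"`, `"T2"`, ...) and `s1`, `s2`, `s3` (the elements at positions
#'   1-3).
#' @examples
#' build_triplet_inventory(sprintf("img%02d", 1:12), seed = 7)
#' @export
build_triplet_inventory <- function(stimulus_ids, seed = NULL) {
  stimulus_ids <- as.character(stimulus_ids)
  check_that(
    "stimulus_ids must be non-empty" = length(stimulus_ids) > 0,
    "stimulus_ids count must be divisible by 3" = length(stimulus_ids) %% 3 == 0,
    "stimulus_ids must be distinct" = !anyDuplicated(stimulus_ids),
    .prefix = "invalid stimulus set"
  )
  n_trip <- length(stimulus_ids) %/% 3
  shuffled <- with_seed_(seed, sample(stimulus_ids))
  m <- matrix(shuffled, nrow = n_trip, ncol = 3, byrow = TRUE)
  tibble(
    triplet_id = paste0("T", seq_len(n_trip)),
    s1 = m[, 1], s2 = m[, 2], s3 = m[, 3]
  )
}

# Draw a triplet presentation order: each of n triplets occurs `reps` times,
# optionally with immediate repetitions disallowed. Sequential weighted
# sampling with restarts on the (rare) dead ends.
sample_triplet_sequence <- function(n, reps, allow_repeat = FALSE,
                                    max_restarts = 200L) {
  total <- n * reps
  if (n == 1L && !allow_repeat && reps > 1L) {
    stop("cannot avoid immediate repetition with a single triplet", call. = FALSE)
  }
  for (attempt in seq_len(max_restarts)) {
    counts <- rep.int(reps, n)
    out <- integer(total)
    last <- 0L
    ok <- TRUE
    for (i in seq_len(total)) {
      avail <- which(counts > 0L)
      if (!allow_repeat && last > 0L) avail <- avail[avail != last]
      if (!length(avail)) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else {
        avail[sample.int(length(avail), 1L, prob = counts[avail])]
      }
      out[i] <- pick
      counts[pick] <- counts[pick] - 1L
      last <- pick
    }
    if (ok) return(out)
  }
  stop("could not generate a triplet order satisfying the adjacency constraint",
       call. = FALSE)
}

#' Generate a familiarization stream
#'
#' Lays the triplet inventory out as a continuous, onset-timed stimulus
#' stream. Each triplet occurs exactly `reps_per_triplet` times; triplet
#' order is randomized (by default with immediate repetitions of the same
#' triplet disallowed); onsets are `(index - 1) * soa_ms`. One triplet is
#' designated the target triplet and its third element is annotated as the
#' tracked target, numbered `1..reps_per_triplet` in order of occurrence.
#'
#' @param inventory A triplet inventory from [build_triplet_inventory()].
#' @param config An [task_config()] object with `n_triplets` equal to the
#'   inventory size.
#' @param seed Optional integer seed (same seed, same stream).
#' @param target_triplet_id Optional triplet id to use as the target;
#'   default: drawn uniformly at random (as when each participant is
#'   assigned their own target).
#' @return A tibble of class `sl_stream` with columns `index`,
#'   `stimulus_id`, `onset_ms`, `triplet_id`, `position` (1-3),
#'   `is_target`, `target_occurrence_index` (NA on non-targets), and
#'   attributes `config` and `target_triplet_id`.
#' @examples
#' inv <- build_triplet_inventory(sprintf("s%02d", 1:12), seed = 1)
#' st <- generate_familiarization_stream(inv, task_config("image"), seed = 2)
#' nrow(st) # 288 events = 4 triplets x 24 reps x 3
#' @export
generate_familiarization_stream <- function(inventory, config, seed = NULL,
                                            target_triplet_id = NULL) {
  stopifnot(inherits(config, "sl_task_config"))
  check_that(
    "inventory size must equal config$n_triplets" =
      nrow(inventory) == config$n_triplets,
    .prefix = "invalid stream request"
  )
  with_seed_(seed, {
    ord <- sample_triplet_sequence(config$n_triplets, config$reps_per_triplet,
                                   config$allow_immediate_repeat)
    tgt <- target_triplet_id %||% sample(inventory$triplet_id, 1L)
    if (!tgt %in% inventory$triplet_id) {
      stop("target_triplet_id not found in inventory", call. = FALSE)
    }
    m <- as.matrix(inventory[, c("s1", "s2", "s3")])
    len <- length(ord) * 3L
    stream <- tibble(
      index = seq_len(len),
      stimulus_id = as.vector(t(m[ord, , drop = FALSE])),
      onset_ms = (seq_len(len) - 1) * config$soa_ms,
      triplet_id = rep(inventory$triplet_id[ord], each = 3L),
      position = rep_len(1:3, len)
    )
    stream$is_target <- stream$triplet_id == tgt & stream$position == 3L
    occ <- cumsum(stream$is_target)
    stream$target_occurrence_index <- ifelse(stream$is_target, occ, NA_integer_)
    attr(stream, "config") <- config
    attr(stream, "target_triplet_id") <- tgt
    class(stream) <- c("sl_stream", class(stream))
    stream
  })
}

#' Re-annotate a stream for a different target triplet
#'
#' Keeps the stimulus order and onsets of an existing familiarization stream
#' but marks the third element of `target_triplet_id` as the tracked target.
#' Used when several participants see the same stream but track different
#' targets.
#'
#' @param stream An `sl_stream` from [generate_familiarization_stream()].
#' @param target_triplet_id Triplet id present in the stream.
#' @return The stream with updated target annotations and attribute.
#' @export
retarget_stream <- function(stream, target_triplet_id) {
  if (!target_triplet_id %in% stream$triplet_id) {
    stop("target_triplet_id not present in stream", call. = FALSE)
  }
  stream$is_target <- stream$triplet_id == target_triplet_id & stream$position == 3L
  occ <- cumsum(stream$is_target)
  stream$target_occurrence_index <- ifelse(stream$is_target, occ, NA_integer_)
  attr(stream, "target_triplet_id") <- target_triplet_id
  stream
}

#' Construct foil triplets by positional recombination
#'
#' Builds one foil per target triplet. Each foil element keeps its
#' within-triplet position (the position-k element of a foil was the
#' position-k element of some target triplet), and the three elements of a
#' foil are drawn from three different target triplets, so no foil ever
#' equals a target triplet, no two foils are identical, and no foil occurs
#' as a contiguous subsequence of the familiarization stream.
#'
#' Concretely, foil i takes its position-k element from target
#' `(i + shift_k) mod n`, with the three shifts drawn (seeded) as distinct
#' values, so that no foil shares the source triplet of two or more of its
#' elements with any single target.
#'
#' @param inventory A triplet inventory with at least 3 triplets.
#' @param seed Optional integer seed.
#' @return A tibble like the inventory with `triplet_id` `"F1"`, `"F2"`, ...
#' @examples
#' inv <- build_triplet_inventory(sprintf("s%02d", 1:12), seed = 1)
#' build_foils(inv, seed = 2)
#' @export
build_foils <- function(inventory, seed = NULL) {
  n <- nrow(inventory)
  check_that(
    "inventory must contain at least 3 triplets" = n >= 3,
    .prefix = "invalid foil request"
  )
  with_seed_(seed, {
    shifts <- sample(0:(n - 1), 3L) # distinct by construction
    idx <- function(k) ((seq_len(n) - 1L + shifts[k]) %% n) + 1L
    tibble(
      triplet_id = paste0("F", seq_len(n)),
      s1 = inventory$s1[idx(1)],
      s2 = inventory$s2[idx(2)],
      s3 = inventory$s3[idx(3)]
    )
  })
}

#' Generate the 2-AFC test phase
#'
#' Crosses every target triplet with every foil triplet, `test_reps` times,
#' in random order. Whether the target or the foil is presented first in a
#' trial is balanced 50/50 across trials (the extra trial goes to
#' target-first when the count is odd) and randomized.
#'
#' @param inventory Target triplet inventory.
#' @param foils Foil tibble from [build_foils()].
#' @param config An [task_config()]; uses `test_reps`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial_id`, `target_triplet_id`,
#'   `foil_id`, `presentation_order` (`"target_first"`/`"foil_first"`),
#'   `rep`.
#' @examples
#' inv <- build_triplet_inventory(sprintf("s%02d", 1:12), seed = 1)
#' tp <- generate_test_phase(inv, build_foils(inv, 2), task_config("image"), 3)
#' nrow(tp) # 32
#' @export
generate_test_phase <- function(inventory, foils, config, seed = NULL) {
  check_that(
    "foil set must be non-empty" = nrow(foils) > 0,
    "inventory must be non-empty" = nrow(inventory) > 0,
    .prefix = "invalid test phase request"
  )
  with_seed_(seed, {
    trials <- tidyr::expand_grid(
      target_triplet_id = inventory$triplet_id,
      foil_id = foils$triplet_id,
      rep = seq_len(config$test_reps)
    )
    n <- nrow(trials)
    trials <- trials[sample.int(n), ]
    trials$presentation_order <- sample(
      rep(c("target_first", "foil_first"), length.out = n)
    )
    trials$trial_id <- seq_len(n)
    trials[, c("trial_id", "target_triplet_id", "foil_id",
               "presentation_order", "rep")]
  })
}
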