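#' z-score a vector of reaction times
#'
#' Standardizes latencies within one participant x task (mean 0, sample SD
#' 1) so that baseline RT differences between participants, domains, and
#' modalities are controlled before slope fitting.
#'
#' @param x Numeric vector with at least 2 values.
#' @return z-scored vector; all-`NA` (with a warning) if the variance is
#'   zero, in which case the participant cannot contribute a slope.
#' @examples
#' znorm(c(400, 500, 600)) # -1 0 1
#' @export
znorm <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to z-score", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning("zero variance: z-scores undefined", call. = FALSE)
    return(rep(NA_real_, length(x)))
  }
  (x - mean(x)) / s
}

#' Fit the reaction-time slope for one participant and task
#'
#' Ordinary-least-squares coefficient of z-normed RT regressed on the
#' target occurrence index (1..24 for visual, 1..48 for auditory tasks).
#' A negative slope indicates accelerating target detection, i.e. online
#' statistical learning.
#'
#' @param z_latencies z-scored hit latencies.
#' @param target_occurrence_indices Matching occurrence indices.
#' @return The OLS slope (z units per target occurrence).
#' @examples
#' fit_rt_slope(znorm(c(550, 500, 450)), c(1, 2, 3)) # negative
#' @export
fit_rt_slope <- function(z_latencies, target_occurrence_indices) {
  x <- as.numeric(target_occurrence_indices)
  y <- as.numeric(z_latencies)
  check_that(
    "latencies and indices must have equal length" = length(x) == length(y),
    "need at least 2 observations" = length(x) >= 2,
    "no missing values allowed" = !anyNA(x) && !anyNA(y),
    .prefix = "invalid slope input"
  )
  if (length(unique(x)) < 2) {
    stop("slope undefined: all occurrence indices equal", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  unname(fit$coefficients[2])
}

#' 2-AFC accuracy for one participant and task
#'
#' @param correct Vector of 0/1 (or logical) trial outcomes; `NA`s
#'   (unanswered trials) are dropped.
#' @return Proportion correct among answered trials, in `[0, 1]`.
#' @examples
#' afc_accuracy(c(1, 1, 0, 1)) # 0.75
#' @export
afc_accuracy <- function(correct) {
  correct <- correct[!is.na(correct)]
  if (!length(correct)) stop("no answered trials", call. = FALSE)
  mean(as.numeric(correct))
}

#' Composite SL scores and domain composites
#'
#' For each task, z-norms the reversed RT slope (so that quicker learning is
#' more positive) and the 2-AFC accuracy across the whole pooled sample, and
#' averages the two into a per-task composite. Domain composites average a
#' participant's four z-normed components (two reversed slopes, two
#' accuracies) within the linguistic and nonlinguistic domains; components
#' missing for a participant (missing task, or RT exclusion) are dropped
#' from the average, so RT-excluded participants still contribute accuracy.
#'
#' @param measures Tibble with one row per participant x task and columns
#'   `participant_id`, `task`, `domain`, `rt_slope`, `afc_accuracy` (either
#'   measure may be `NA`), plus optionally `group` and other metadata
#'   carried through.
#' @param norm_within_group If `TRUE`, z-norms are computed within
#'   diagnostic group instead of on the pooled sample (sensitivity
#'   analysis; requires a `group` column). Default `FALSE`, pooled norms.
#' @return A list with `measures` (input plus `z_neg_rt_slope`,
#'   `z_afc_accuracy`, `composite`) and `domains` (tibble: participant,
#'   metadata, `domain`, `score`, `n_components`).
#' @export
composite_scores <- function(measures, norm_within_group = FALSE) {
  check_that(
    "measures must contain participant_id, task, domain, rt_slope, afc_accuracy" =
      all(c("participant_id", "task", "domain", "rt_slope", "afc_accuracy")
          %in% names(measures)),
    .prefix = "invalid measures table"
  )
  if (norm_within_group && !"group" %in% names(measures)) {
    stop("norm_within_group = TRUE requires a 'group' column", call. = FALSE)
  }
  zcol <- function(x) {
    if (length(x) < 2) {
      stop("norming error: need at least 2 participants per task",
           call. = FALSE)
    }
    n_ok <- sum(!is.na(x))
    s <- sd(x, na.rm = TRUE)
    if (n_ok < 2 || s == 0) {
      # a component unavailable (e.g. everyone RT-excluded) or constant
      # cannot be normed; composites fall back to the other component
      warning("norming column with zero variance or all missing: ",
              "z-scores undefined", call. = FALSE)
      return(rep(NA_real_, length(x)))
    }
    (x - mean(x, na.rm = TRUE)) / s
  }
  norm_cols <- if (norm_within_group) c("task", "group") else "task"
  measures <- measures %>%
    group_by(across(all_of(norm_cols))) %>%
    mutate(
      z_neg_rt_slope = zcol(-.data$rt_slope),
      z_afc_accuracy = zcol(.data$afc_accuracy)
    ) %>%
    ungroup()
  comp <- rowMeans(cbind(measures$z_neg_rt_slope, measures$z_afc_accuracy),
                   na.rm = TRUE)
  measures$composite <- ifelse(is.nan(comp), NA_real_, comp)

  meta_cols <- intersect(c("group", "sex", "age_years", "language_level",
                           "sentence_recall_raw"), names(measures))
  domains <- measures %>%
    tidyr::pivot_longer(c("z_neg_rt_slope", "z_afc_accuracy"),
                        names_to = "component", values_to = "z") %>%
    group_by(across(all_of(c("participant_id", meta_cols, "domain")))) %>%
    summarise(
      score = mean(.data$z, na.rm = TRUE),
      n_components = sum(!is.na(.data$z)),
      .groups = "drop"
    ) %>%
    mutate(score = ifelse(.data$n_components == 0, NA_real_, .data$score))
  list(measures = measures, domains = domains)
}
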