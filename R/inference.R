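#' @title Model-fit container helpers
#' @description Every inference operation returns an `sl_model_fit`: the
#'   model name, formula, a tidy coefficient table (term, estimate, SE,
#'   statistic, df where available, p), convergence/singularity flags, and
#'   the underlying fitted object.
#' @param model_name Short name of the analysis.
#' @param formula Model formula (character or formula).
#' @param fit Fitted model object (or `NULL` for degenerate cases).
#' @param coefficients Tidy coefficient tibble.
#' @param singular,converged Fit diagnostics.
#' @param n_obs,n_participants Sample sizes.
#' @param re_structure Random-effects structure actually used (after any
#'   fallback).
#' @param notes Character notes (e.g. `"separation"`).
#' @return An object of class `sl_model_fit`.
#' @keywords internal
new_model_fit <- function(model_name, formula, fit, coefficients,
                          singular = FALSE, converged = TRUE,
                          n_obs = NA_integer_, n_participants = NA_integer_,
                          re_structure = NA_character_, notes = character(0)) {
  structure(list(
    model_name = model_name,
    formula = paste(deparse(formula), collapse = " "),
    coefficients = coefficients,
    singular = singular, converged = converged,
    n_obs = n_obs, n_participants = n_participants,
    re_structure = re_structure, notes = notes, fit = fit
  ), class = "sl_model_fit")
}

#' @export
print.sl_model_fit <- function(x, ...) {
  cat(sprintf("<sl_model_fit> %s\n  %s\n", x$model_name, x$formula))
  cat(sprintf("  n_obs = %s, n_participants = %s%s%s\n",
              x$n_obs, x$n_participants,
              if (isTRUE(x$singular)) ", singular fit" else "",
              if (length(x$notes)) paste0(" [", paste(x$notes, collapse = ", "), "]") else ""))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

# Sum-to-zero (or treatment) coding with fixed, documented level orders so
# coefficient signs are reproducible: group TD first, domain linguistic
# first, modality auditory first, sex F first.
code_factors <- function(df, coding = c("sum", "treatment")) {
  coding <- match.arg(coding)
  lev <- list(group = c("TD", "ASD"),
              domain = c("linguistic", "nonlinguistic"),
              modality = c("auditory", "visual"),
              sex = c("F", "M"))
  for (nm in intersect(names(lev), names(df))) {
    f <- factor(df[[nm]], levels = lev[[nm]])
    if (coding == "sum") {
      contrasts(f) <- stats::contr.sum(nlevels(f))
      colnames(contrasts(f)) <- levels(f)[-nlevels(f)]
    }
    df[[nm]] <- f
  }
  df
}

tidy_mermod <- function(fit) {
  cs <- coef(summary(fit))
  cn <- colnames(cs)
  tibble(
    term = rownames(cs),
    estimate = cs[, "Estimate"],
    se = cs[, "Std. Error"],
    statistic = cs[, grep("value", cn, value = TRUE)[1]],
    df = if ("df" %in% cn) cs[, "df"] else NA_real_,
    p = cs[, grep("^Pr", cn, value = TRUE)[1]]
  )
}

# Drop the sex covariate from a fixed-effects string when it is constant
# in the data (it cannot be estimated, e.g. in small subgroups).
maybe_drop_sex <- function(base, data) {
  if (length(unique(stats::na.omit(as.character(data$sex)))) < 2) {
    sub(" \\+ sex", "", base)
  } else {
    base
  }
}

# Fit lmer/glmer down a deterministic random-effects fallback ladder,
# dropping the modality slope, then the domain slope, until non-singular
# (or return the last fit, flagged).
fit_with_ladder <- function(base, ladder, data, fitter) {
  last <- NULL
  for (re in ladder) {
    fml <- stats::as.formula(paste(base, "+", re))
    fit <- tryCatch(fitter(fml, data), error = function(e) NULL)
    if (is.null(fit)) next
    last <- list(fit = fit, re = re)
    if (!lme4::isSingular(fit, tol = 1e-4)) {
      return(c(last, list(singular = FALSE)))
    }
  }
  if (is.null(last)) stop("all candidate models failed to fit", call. = FALSE)
  c(last, list(singular = TRUE))
}

#' One-sample learning tests per group and task
#'
#' Online SL is defined by an RT slope below zero (one-tailed one-sample
#' t-test, alternative "less"); offline SL by 2-AFC accuracy above the 50%
#' chance level (one-tailed, alternative "greater"). Tests run within each
#' diagnostic group and task. A cell whose values are all exactly at the
#' null value yields t = 0 and one-tailed p = 0.5 with a `degenerate`
#' note; a constant cell away from the null is an error.
#'
#' @param measures Per participant x task measures with columns `group`,
#'   `task`, `rt_slope`, `afc_accuracy`.
#' @param on_insufficient What to do with a group x task cell holding fewer
#'   than 2 non-missing values: `"error"` (default) or `"skip"` (drop the
#'   cell from the output, as when every participant was RT-excluded in a
#'   task).
#' @return Tibble with one row per group x task x measure: `test_name`,
#'   `group`, `task`, `measure`, `n`, `mean`, `statistic`, `df`, `p`,
#'   `sided`, `alternative`, `null_value`, `note`.
#' @export
one_sample_learning_tests <- function(measures,
                                      on_insufficient = c("error", "skip")) {
  on_insufficient <- match.arg(on_insufficient)
  specs <- list(
    list(measure = "rt_slope", mu = 0, alternative = "less"),
    list(measure = "afc_accuracy", mu = 0.5, alternative = "greater")
  )
  cells <- dplyr::distinct(measures[, c("group", "task")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- measures[measures$group == cells$group[i] &
                      measures$task == cells$task[i], ]
    for (spc in specs) {
      x <- sub[[spc$measure]]
      x <- x[!is.na(x)]
      if (length(x) < 2) {
        if (on_insufficient == "skip") next
        stop("need at least 2 observations per group x task cell",
             call. = FALSE)
      }
      note <- NA_character_
      if (sd(x) == 0) {
        if (isTRUE(all.equal(mean(x), spc$mu))) {
          stat <- 0; p <- 0.5; dfree <- length(x) - 1; note <- "degenerate"
        } else {
          stop("degenerate test: zero variance away from the null value",
               call. = FALSE)
        }
      } else {
        tt <- t.test(x, mu = spc$mu, alternative = spc$alternative)
        stat <- unname(tt$statistic); p <- tt$p.value
        dfree <- unname(tt$parameter)
      }
      out[[length(out) + 1]] <- tibble(
        test_name = paste0("one_sample_", spc$measure),
        group = cells$group[i], task = cells$task[i],
        measure = spc$measure, n = length(x), mean = mean(x),
        statistic = stat, df = dfree, p = p,
        sided = "one-tailed", alternative = spc$alternative,
        null_value = spc$mu, note = note
      )
    }
  }
  bind_rows(out)
}

#' Mixed-effects model of hit-level reaction times
#'
#' Linear mixed model of z-normed RT on the full factorial of diagnostic
#' group, domain, modality, and (centered) target trial order, up to the
#' four-way interaction, with sex as a covariate; random intercepts for
#' participants and random by-participant slopes of domain and modality.
#' Factors are sum-to-zero coded by default (treatment coding available),
#' and trial order is centered within task so that the visual (1..24) and
#' auditory (1..48) scales are each centered at zero. Degrees of freedom
#' and p-values use the Satterthwaite approximation (lmerTest). Singular
#' fits are refit down a deterministic ladder (drop the modality slope,
#' then the domain slope), with the structure used recorded in the result.
#'
#' @param rt_data Hit-level tibble with columns `participant_id`, `group`,
#'   `domain`, `modality`, `sex`, `task`, `target_occurrence_index`,
#'   `z_rt`.
#' @param coding `"sum"` (default) or `"treatment"` factor coding.
#' @return An `sl_model_fit`.
#' @export
fit_rt_mixed_model <- function(rt_data, coding = c("sum", "treatment")) {
  coding <- match.arg(coding)
  need <- c("participant_id", "group", "domain", "modality", "sex", "task",
            "target_occurrence_index", "z_rt")
  check_that(
    "rt_data is missing required columns" = all(need %in% names(rt_data)),
    .prefix = "invalid RT table"
  )
  if (length(unique(rt_data$participant_id)) < 2 ||
      length(unique(rt_data$group)) < 2) {
    stop("need at least 2 participants in each diagnostic group",
         call. = FALSE)
  }
  rt_data <- code_factors(rt_data, coding)
  rt_data <- rt_data %>%
    group_by(.data$task) %>%
    mutate(order_c = .data$target_occurrence_index -
             mean(.data$target_occurrence_index)) %>%
    ungroup()
  base <- maybe_drop_sex("z_rt ~ group * domain * modality * order_c + sex",
                         rt_data)
  ladder <- c("(1 + domain + modality | participant_id)",
              "(1 + domain | participant_id)",
              "(1 | participant_id)")
  res <- fit_with_ladder(base, ladder, rt_data, function(fml, d) {
    lmerTest::lmer(fml, data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE))
  })
  new_model_fit("rt_mixed_model", stats::formula(res$fit), res$fit,
                tidy_mermod(res$fit), singular = res$singular,
                n_obs = nrow(rt_data),
                n_participants = length(unique(rt_data$participant_id)),
                re_structure = res$re)
}

#' Mixed-effects logistic model of 2-AFC accuracy
#'
#' Trial-level logistic regression of binomial accuracy on diagnostic
#' group, domain, and modality (full factorial) with sex as a covariate;
#' random intercepts for participants and test items and random
#' by-participant slopes of domain and modality, with the same singularity
#' fallback ladder as [fit_rt_mixed_model()]. Coefficients are on the
#' log-odds scale. Cells with all-identical outcomes are flagged as
#' (quasi-)complete separation; an entirely constant outcome returns a
#' flagged, coefficient-free fit.
#'
#' @param afc_trials Trial-level tibble with columns `participant_id`,
#'   `group`, `domain`, `modality`, `sex`, `item`, `correct` (0/1).
#' @param coding `"sum"` or `"treatment"`.
#' @param nAGQ Passed to [lme4::glmer()] when the model has at most one
#'   random term; use 0 for a faster, slightly less accurate fit.
#' @return An `sl_model_fit`.
#' @export
fit_accuracy_mixed_logistic <- function(afc_trials,
                                        coding = c("sum", "treatment"),
                                        nAGQ = 1) {
  coding <- match.arg(coding)
  need <- c("participant_id", "group", "domain", "modality", "sex", "item",
            "correct")
  check_that(
    "afc_trials is missing required columns" = all(need %in% names(afc_trials)),
    .prefix = "invalid 2-AFC table"
  )
  notes <- character(0)
  cell_means <- afc_trials %>%
    group_by(.data$group, .data$domain, .data$modality) %>%
    summarise(m = mean(.data$correct), .groups = "drop")
  if (any(cell_means$m %in% c(0, 1))) notes <- c(notes, "separation")
  if (length(unique(afc_trials$correct)) < 2) {
    return(new_model_fit(
      "accuracy_mixed_logistic", ~constant_outcome, NULL,
      tibble(term = character(0), estimate = numeric(0), se = numeric(0),
             statistic = numeric(0), df = numeric(0), p = numeric(0)),
      singular = TRUE, converged = FALSE, n_obs = nrow(afc_trials),
      n_participants = length(unique(afc_trials$participant_id)),
      notes = c(notes, "constant outcome; no model fitted")))
  }
  afc_trials <- code_factors(afc_trials, coding)
  base <- maybe_drop_sex("correct ~ group * domain * modality + sex",
                         afc_trials)
  ladder <- c("(1 + domain + modality | participant_id) + (1 | item)",
              "(1 + domain | participant_id) + (1 | item)",
              "(1 | participant_id) + (1 | item)")
  res <- fit_with_ladder(base, ladder, afc_trials, function(fml, d) {
    suppressMessages(lme4::glmer(fml, data = d, family = stats::binomial(),
                                 nAGQ = nAGQ))
  })
  new_model_fit("accuracy_mixed_logistic", stats::formula(res$fit), res$fit,
                tidy_mermod(res$fit), singular = res$singular,
                n_obs = nrow(afc_trials),
                n_participants = length(unique(afc_trials$participant_id)),
                re_structure = res$re, notes = notes)
}

#' Mixed-effects model of task-level scores
#'
#' Linear mixed model of a per participant x task outcome (the composite
#' SL score by default, or e.g. the raw RT slope) on diagnostic group,
#' domain, and modality with sex as a covariate and a random intercept for
#' participants. An outcome with zero variance returns a degenerate fit
#' with zero coefficients and a singularity flag.
#'
#' @param task_measures Tibble with columns `participant_id`, `group`,
#'   `domain`, `modality`, `sex`, and the outcome column.
#' @param outcome Name of the outcome column (default `"composite"`).
#' @param coding `"sum"` or `"treatment"`.
#' @return An `sl_model_fit`.
#' @export
fit_composite_model <- function(task_measures, outcome = "composite",
                                coding = c("sum", "treatment")) {
  coding <- match.arg(coding)
  need <- c("participant_id", "group", "domain", "modality", "sex", outcome)
  check_that(
    "task_measures is missing required columns" =
      all(need %in% names(task_measures)),
    .prefix = "invalid task measures"
  )
  dat <- task_measures[!is.na(task_measures[[outcome]]), ]
  y <- dat[[outcome]]
  if (sd(y) == 0) {
    terms <- c("(Intercept)", "group", "domain", "modality")
    return(new_model_fit(
      paste0(outcome, "_model"), stats::as.formula(paste(outcome, "~ ...")),
      NULL,
      tibble(term = terms, estimate = c(y[1], 0, 0, 0), se = NA_real_,
             statistic = NA_real_, df = NA_real_, p = NA_real_),
      singular = TRUE, converged = FALSE, n_obs = nrow(dat),
      n_participants = length(unique(dat$participant_id)),
      notes = "constant outcome; degenerate fit"))
  }
  dat <- code_factors(dat, coding)
  base <- maybe_drop_sex(paste(outcome, "~ group * domain * modality + sex"),
                         dat)
  res <- fit_with_ladder(base, "(1 | participant_id)", dat, function(fml, d) {
    lmerTest::lmer(fml, data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC(action = "ignore", tol = 1e-4)))
  })
  new_model_fit(paste0(outcome, "_model"), stats::formula(res$fit), res$fit,
                tidy_mermod(res$fit), singular = res$singular,
                n_obs = nrow(dat),
                n_participants = length(unique(dat$participant_id)),
                re_structure = res$re)
}

#' Developmental analysis of domain composites
#'
#' First fits the continuous-age model: domain composite on group x domain
#' x centered age (full factorial) with sex covariate and participant
#' random intercept. Then splits the pooled sample at the median age
#' (participants with age <= median go to the younger subgroup; the rule is
#' deterministic under ties) and fits the group x domain model with a
#' continuous age covariate within each subgroup.
#'
#' @param domain_scores Tibble with columns `participant_id`, `group`,
#'   `domain`, `sex`, `age_years`, `score`.
#' @param coding `"sum"` or `"treatment"`.
#' @return A list with `continuous` (`sl_model_fit`), `younger`, `older`
#'   (`sl_model_fit`s), and `split` (tibble: median age, subgroup sizes and
#'   mean ages by group).
#' @export
development_analysis <- function(domain_scores, coding = c("sum", "treatment")) {
  coding <- match.arg(coding)
  need <- c("participant_id", "group", "domain", "sex", "age_years", "score")
  check_that(
    "domain_scores is missing required columns" =
      all(need %in% names(domain_scores)),
    .prefix = "invalid domain score table"
  )
  ages <- dplyr::distinct(domain_scores[, c("participant_id", "age_years")])
  if (sd(ages$age_years) == 0) {
    stop("median split impossible: all ages identical", call. = FALSE)
  }
  dat <- code_factors(domain_scores, coding)
  dat$age_c <- dat$age_years - mean(ages$age_years)
  fit_one <- function(d, base, name) {
    d <- d[!is.na(d$score), ]
    base <- maybe_drop_sex(base, d)
    res <- fit_with_ladder(base, "(1 | participant_id)", d, function(fml, dd) {
      lmerTest::lmer(fml, data = dd,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   lme4::.makeCC(action = "ignore", tol = 1e-4)))
    })
    new_model_fit(name, stats::formula(res$fit), res$fit, tidy_mermod(res$fit),
                  singular = res$singular, n_obs = nrow(d),
                  n_participants = length(unique(d$participant_id)),
                  re_structure = res$re)
  }
  continuous <- fit_one(dat, "score ~ group * domain * age_c + sex",
                        "development_continuous")
  med <- median(ages$age_years)
  dat$age_split <- ifelse(dat$age_years <= med, "younger", "older")
  split_tab <- dat %>%
    dplyr::distinct(.data$participant_id, .data$group, .data$age_split,
                    .data$age_years) %>%
    group_by(.data$age_split, .data$group) %>%
    summarise(n = dplyr::n(), mean_age = mean(.data$age_years),
              .groups = "drop") %>%
    mutate(median_age = med)
  younger <- fit_one(dat[dat$age_split == "younger", ],
                     "score ~ group * domain + age_c + sex",
                     "development_younger")
  older <- fit_one(dat[dat$age_split == "older", ],
                   "score ~ group * domain + age_c + sex",
                   "development_older")
  list(continuous = continuous, younger = younger, older = older,
       split = split_tab)
}

#' Partial Pearson correlation via the precision matrix
#'
#' Correlation between `x` and `y` after partialling out the control
#' variables, computed from the inverse of the joint correlation matrix
#' (`r_xy.z = -p_xy / sqrt(p_xx p_yy)`). The t-test uses
#' `df = n - 2 - k` for `k` controls. With no controls this reduces to the
#' plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param controls Optional data frame / matrix of control variables.
#' @return Tibble: `r`, `n`, `statistic`, `df`, `p` (two-sided).
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  dat <- cbind(x = x, y = y,
               if (!is.null(controls)) as.matrix(controls))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- ncol(dat) - 2L
  check_that(
    "need at least k + 4 complete observations" = n >= k + 4,
    .prefix = "invalid correlation input"
  )
  if (any(apply(dat, 2, sd) == 0)) {
    stop("correlation undefined: constant column", call. = FALSE)
  }
  cm <- cor(dat)
  if (k == 0) {
    r <- cm["x", "y"]
  } else {
    pm <- solve(cm)
    r <- -pm["x", "y"] / sqrt(pm["x", "x"] * pm["y", "y"])
  }
  dfree <- n - 2 - k
  r <- min(max(r, -1), 1)
  stat <- r * sqrt(dfree / (1 - r^2))
  tibble(r = r, n = n, statistic = stat, df = dfree,
         p = 2 * pt(-abs(stat), dfree))
}

#' Pairwise (partial) correlations between SL measures
#'
#' Pearson correlations between every pair of the given columns, within
#' each level of `group` when supplied, optionally partialling out control
#' variables, with multiple-comparison adjustment of the p-values within
#' each group.
#'
#' @param data Wide tibble: one row per participant.
#' @param vars Character vector of measure columns to correlate.
#' @param group Optional grouping column name.
#' @param controls Optional character vector of control columns (e.g.
#'   `"age_years"`).
#' @param adjust Multiple-comparison method: `"holm"` (default),
#'   `"bonferroni"`, or `"BH"`.
#' @return Tibble with `group`, `var1`, `var2`, `r`, `n`, `df`,
#'   `statistic`, `p`, `p_adj`, `controls`.
#' @export
correlation_suite <- function(data, vars, group = NULL, controls = NULL,
                              adjust = c("holm", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  check_that(
    "all vars must be columns of data" = all(vars %in% names(data)),
    "need at least two vars" = length(vars) >= 2,
    .prefix = "invalid correlation request"
  )
  groups <- if (is.null(group)) list(all = data) else
    split(data, data[[group]])
  pairs <- utils::combn(vars, 2)
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      v1 <- pairs[1, j]; v2 <- pairs[2, j]
      pc <- partial_correlation(d[[v1]], d[[v2]],
                                if (!is.null(controls)) d[controls])
      tibble(group = g, var1 = v1, var2 = v2, r = pc$r, n = pc$n,
             df = pc$df, statistic = pc$statistic, p = pc$p,
             controls = paste(controls, collapse = ","))
    })
    tab <- bind_rows(rows)
    tab$p_adj <- p.adjust(tab$p, method = adjust)
    out[[g]] <- tab
  }
  bind_rows(out)
}

#' Compare two independent correlations (Fisher z)
#'
#' Tests whether two correlations from independent samples differ, using
#' the Fisher transform: `z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1 - 3) + 1/(n2 - 3))`, with a two-sided normal p-value.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @return Tibble: `z`, `p` (two-sided).
#' @examples
#' compare_correlations(0.5, 30, 0, 30) # z = 2.018
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  check_that(
    "correlations must be strictly inside (-1, 1)" =
      abs(r1) < 1 && abs(r2) < 1,
    "sample sizes must be at least 4" = n1 >= 4 && n2 >= 4,
    .prefix = "invalid correlation comparison"
  )
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Bias-corrected standardized mean difference (Hedges g*)
#'
#' Cohen's d with the pooled standard deviation, multiplied by the small-
#' sample correction `1 - 3 / (4 df - 1)` with `df = n1 + n2 - 2`.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 2).
#' @return The bias-corrected standardized mean difference (positive when
#'   `mean(x) > mean(y)`).
#' @export
effect_size_g <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  check_that(
    "each group needs at least 2 observations" = n1 >= 2 && n2 >= 2,
    .prefix = "invalid effect size input"
  )
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean(x) - mean(y)) / sp
  dfree <- n1 + n2 - 2
  d * (1 - 3 / (4 * dfree - 1))
}

#' Cousineau-Morey within-group standard errors
#'
#' Removes between-participant variability by subtracting each
#' participant's mean (over their conditions) and adding the grand mean,
#' then computes the per-condition standard error of the normalized values
#' multiplied by the `sqrt(M / (M - 1))` bias correction for `M`
#' conditions. With a single condition the correction is undefined and the
#' ordinary SE is returned with a warning. Additive between-participant
#' shifts leave the result unchanged by construction.
#'
#' @param data Long tibble with participant, condition, and value columns.
#' @param participant,condition,value Column names (strings).
#' @return Tibble: `condition`, `mean`, `se`, `n`.
#' @export
morey_within_se <- function(data, participant = "participant_id",
                            condition = "condition", value = "value") {
  check_that(
    "all columns must exist in data" =
      all(c(participant, condition, value) %in% names(data)),
    .prefix = "invalid within-SE input"
  )
  d <- tibble(
    pid = data[[participant]],
    cond = data[[condition]],
    val = data[[value]]
  )
  d <- d[!is.na(d$val), ]
  M <- length(unique(d$cond))
  if (M == 1) {
    warning("only one condition: Morey correction undefined, ",
            "returning the ordinary standard error", call. = FALSE)
    return(d %>%
             group_by(condition = .data$cond) %>%
             summarise(mean = mean(.data$val),
                       se = sd(.data$val) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop"))
  }
  corr <- sqrt(M / (M - 1))
  grand <- mean(d$val)
  d <- d %>%
    group_by(.data$pid) %>%
    mutate(norm = .data$val - mean(.data$val) + grand) %>%
    ungroup()
  d %>%
    group_by(condition = .data$cond) %>%
    summarise(
      mean = mean(.data$val),
      se = corr * sd(.data$norm) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
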