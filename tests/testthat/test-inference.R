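make_measures <- function(n_per_cell = 8, seed = 5, slope_shift = 0,
                          acc_shift = 0) {
  # balanced group x task table with mild noise; shifts apply to TD linguistic
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      group = c("TD", "ASD"),
      task = c("image", "letter", "tone", "syllable"),
      i = seq_len(n_per_cell)
    )
    grid$participant_id <- paste0(grid$group, grid$i)
    grid$domain <- ifelse(grid$task %in% c("letter", "syllable"),
                          "linguistic", "nonlinguistic")
    grid$modality <- ifelse(grid$task %in% c("image", "letter"),
                            "visual", "auditory")
    grid$sex <- rep_len(c("F", "M"), nrow(grid))
    td_ling <- grid$group == "TD" & grid$domain == "linguistic"
    grid$rt_slope <- rnorm(nrow(grid), -0.005, 0.01) + slope_shift * td_ling
    grid$afc_accuracy <- pmin(pmax(
      rnorm(nrow(grid), 0.6, 0.08) + acc_shift * td_ling, 0), 1)
    grid[, setdiff(names(grid), "i")]
  })
}

test_that("one-sample learning tests match the closed-form t-test", {
  meas <- make_measures()
  # slopes exactly zero in one cell: t = 0, one-tailed p = 0.5
  meas$rt_slope[meas$group == "TD" & meas$task == "image"] <- 0
  out <- one_sample_learning_tests(meas)
  r0 <- out[out$group == "TD" & out$task == "image" &
              out$measure == "rt_slope", ]
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 0.5)
  expect_equal(r0$note, "degenerate")
  # hand-computed accuracy test
  accs <- c(0.75, 0.8125, 0.875, 0.75)
  fix <- tibble::tibble(group = "TD", task = "letter",
                        participant_id = sprintf("P%d", 1:4),
                        rt_slope = c(-0.01, -0.02, 0.01, 0),
                        afc_accuracy = accs)
  out <- one_sample_learning_tests(fix)
  ra <- out[out$measure == "afc_accuracy", ]
  t_oracle <- (mean(accs) - 0.5) / (sd(accs) / sqrt(4))
  expect_equal(ra$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(ra$p, pt(t_oracle, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(ra$sided, "one-tailed")
  # slope side: negative mean gives p < 0.5, alternative "less"
  rs <- out[out$measure == "rt_slope", ]
  expect_equal(rs$alternative, "less")
  expect_lt(rs$p, 0.5)
  # constant values away from the null are a degenerate-test error
  bad <- fix
  bad$afc_accuracy <- 0.75
  expect_error(one_sample_learning_tests(bad), "degenerate")
})

test_that("the composite model recovers a planted group x domain gap", {
  meas <- make_measures(n_per_cell = 40, seed = 21, acc_shift = 0.12)
  cs <- composite_scores(meas)
  fit <- fit_composite_model(cs$measures)
  co <- fit$coefficients
  term <- co$term[grepl("group", co$term) & grepl("domain", co$term) &
                    !grepl("modality", co$term)]
  row <- co[co$term == term, ]
  # TD and linguistic are the positive poles of the sum coding, so a TD
  # linguistic advantage is a positive interaction
  expect_gt(row$estimate, 0)
  expect_lt(row$p, 0.05)
  expect_equal(fit$n_participants, 80)
})

test_that("degenerate composite tables give flagged zero-coefficient fits", {
  meas <- make_measures(n_per_cell = 4)
  meas$composite <- 0.7
  fit <- fit_composite_model(meas)
  expect_true(fit$singular)
  expect_false(fit$converged)
  expect_equal(fit$coefficients$estimate[-1], c(0, 0, 0))
})

test_that("the hit-level RT mixed model recovers a planted 3-way interaction", {
  # small hit-level dataset: 16 participants x 4 tasks x 12 hits
  withr::with_seed(31, {
    grid <- tidyr::expand_grid(
      group = c("TD", "ASD"), i = 1:8,
      task = c("image", "letter", "tone", "syllable"),
      target_occurrence_index = 1:12
    )
    grid$participant_id <- paste0(grid$group, grid$i)
    grid$domain <- ifelse(grid$task %in% c("letter", "syllable"),
                          "linguistic", "nonlinguistic")
    grid$modality <- ifelse(grid$task %in% c("image", "letter"),
                            "visual", "auditory")
    grid$sex <- ifelse(grid$i %% 2 == 0, "F", "M")
    slope <- ifelse(grid$group == "TD" & grid$domain == "linguistic",
                    -0.12, 0)
    grid$z_rt <- slope * grid$target_occurrence_index + rnorm(nrow(grid), 0, 0.3)
  })
  fit <- fit_rt_mixed_model(grid)
  co <- fit$coefficients
  row <- co[co$term == "groupTD:domainlinguistic:order_c", ]
  expect_equal(nrow(row), 1)
  # TD-linguistic acceleration = negative 3-way coefficient under sum coding
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.05)
  expect_true(all(c("estimate", "se", "statistic", "df", "p") %in%
                    names(co)))
  expect_true(all(co$se > 0))
  # single-group / single-participant data are rejected
  expect_error(fit_rt_mixed_model(grid[grid$participant_id == "TD1", ]),
               "2 participants")
})

test_that("the accuracy logistic model flags separation and fits otherwise", {
  withr::with_seed(41, {
    grid <- tidyr::expand_grid(
      group = c("TD", "ASD"), i = 1:10,
      task = c("image", "letter", "tone", "syllable"),
      trial = 1:16
    )
    grid$participant_id <- paste0(grid$group, grid$i)
    grid$domain <- ifelse(grid$task %in% c("letter", "syllable"),
                          "linguistic", "nonlinguistic")
    grid$modality <- ifelse(grid$task %in% c("image", "letter"),
                            "visual", "auditory")
    grid$sex <- ifelse(grid$i %% 2 == 0, "F", "M")
    grid$item <- paste0(grid$task, "_it", grid$trial %% 8)
    eta <- 0.4 + 0.5 * (grid$group == "TD")
    grid$correct <- rbinom(nrow(grid), 1, plogis(eta))
  })
  fit <- fit_accuracy_mixed_logistic(grid, nAGQ = 0)
  co <- fit$coefficients
  expect_true("groupTD" %in% co$term)
  # estimate on the log-odds scale, near the planted 0.5 advantage:
  # group coefficient is half the TD-ASD log-odds gap under sum coding
  expect_gt(co$estimate[co$term == "groupTD"], 0)
  expect_false("separation" %in% fit$notes)
  # all-correct outcome: flagged, no model
  all1 <- grid
  all1$correct <- 1
  fit1 <- fit_accuracy_mixed_logistic(all1)
  expect_true(any(grepl("constant outcome", fit1$notes)))
  expect_true(any(grepl("separation", fit1$notes)))
  expect_equal(nrow(fit1$coefficients), 0)
})

test_that("development analysis splits at the median deterministically", {
  withr::with_seed(51, {
    n <- 40
    base <- tibble::tibble(
      participant_id = sprintf("P%02d", 1:n),
      group = rep(c("TD", "ASD"), n / 2),
      sex = rep(c("F", "M"), each = n / 2),
      age_years = seq(6, 12, length.out = n)
    )
    dom <- tidyr::expand_grid(participant_id = base$participant_id,
                              domain = c("linguistic", "nonlinguistic")) %>%
      dplyr::left_join(base, by = "participant_id")
    # age-widening TD linguistic advantage
    gap <- with(dom, (group == "TD") * (domain == "linguistic") *
                  0.4 * (age_years - 6))
    dom$score <- gap + rnorm(nrow(dom), 0, 0.3)
  })
  res <- development_analysis(dom)
  co <- res$continuous$coefficients
  row <- co[co$term == "groupTD:domainlinguistic:age_c", ]
  expect_gt(row$estimate, 0)
  expect_lt(row$p, 0.05)
  # ages symmetric around the median: equal halves
  expect_equal(sum(res$split$n[res$split$age_split == "younger"]), 20)
  expect_equal(sum(res$split$n[res$split$age_split == "older"]), 20)
  expect_s3_class(res$younger, "sl_model_fit")
  expect_s3_class(res$older, "sl_model_fit")
  # tie handling: participants at the duplicated median age go to the
  # younger half (deterministic <= rule)
  tie_ages <- rep(c(6, 7, 8, 8, 8, 8, 9, 10, 11, 12), length.out = n)
  tie <- dom
  tie$age_years <- tie_ages[match(tie$participant_id,
                                  sprintf("P%02d", 1:n))]
  res_tie <- development_analysis(tie)
  med <- unique(res_tie$split$median_age)
  expect_equal(med, 8)
  expect_equal(sum(res_tie$split$n[res_tie$split$age_split == "younger"]),
               sum(tie_ages <= 8))
  # identical ages cannot be split
  flat <- dom
  flat$age_years <- 9
  expect_error(development_analysis(flat), "identical")
})

test_that("partial correlations equal the residual-method oracle", {
  withr::with_seed(61, {
    z <- rnorm(40)
    x <- 0.6 * z + rnorm(40)
    y <- -0.4 * z + rnorm(40)
  })
  pc <- partial_correlation(x, y, data.frame(z = z))
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  # df drops by one per control
  expect_equal(pc$df, 40 - 3)
  # hand-built 6-row table
  tab <- data.frame(
    x = c(1.2, 0.8, 2.5, 1.9, 3.1, 2.2),
    y = c(0.4, 1.0, 1.8, 1.1, 2.9, 2.0),
    z = c(10, 12, 15, 13, 19, 16)
  )
  pc6 <- partial_correlation(tab$x, tab$y, tab["z"])
  r_oracle <- cor(resid(lm(x ~ z, tab)), resid(lm(y ~ z, tab)))
  expect_equal(pc6$r, r_oracle, tolerance = 1e-12)
  # control uncorrelated with both -> partial ~ plain r
  withr::with_seed(62, {
    u <- rnorm(200); v <- 0.5 * u + rnorm(200); w <- rnorm(200)
  })
  expect_equal(partial_correlation(u, v, data.frame(w))$r,
               cor(u, v), tolerance = 0.02)
  # collinear pair
  expect_equal(partial_correlation(1:10, 2 * (1:10) + 3)$r, 1)
  expect_error(partial_correlation(rep(1, 8), rnorm(8)), "constant column")
})

test_that("the correlation suite adjusts p-values within group", {
  withr::with_seed(71, {
    d <- tibble::tibble(
      group = rep(c("TD", "ASD"), each = 30),
      a = rnorm(60)
    )
    d$b <- 0.7 * d$a + rnorm(60, 0, 0.5)
    d$c <- rnorm(60)
  })
  out <- correlation_suite(d, c("a", "b", "c"), group = "group")
  expect_equal(nrow(out), 6)
  expect_true(all(out$p_adj >= out$p))
  # holm within each group of 3 tests: max p unchanged
  td <- out[out$group == "TD", ]
  expect_equal(max(td$p_adj), max(td$p) * 1, tolerance = 1e-12)
  # missing data: pairwise-complete n
  d2 <- d
  d2$a[1:5] <- NA
  out2 <- correlation_suite(d2, c("a", "b"), group = "group")
  expect_equal(out2$n[out2$group == "TD"], 25)
})

test_that("Fisher-z comparison matches its closed form and is antisymmetric", {
  res <- compare_correlations(0.5, 30, 0, 30)
  expect_equal(round(res$z, 3), 2.018)
  z_oracle <- (atanh(0.5) - atanh(0)) / sqrt(1 / 27 + 1 / 27)
  expect_equal(res$z, z_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-12)
  # equal correlations: z = 0, p = 1
  expect_equal(compare_correlations(0.31, 25, 0.31, 60)$z, 0)
  # antisymmetry
  a <- compare_correlations(0.48, 40, 0.11, 49)
  b <- compare_correlations(0.11, 49, 0.48, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(compare_correlations(1, 30, 0.2, 30), "inside")
  expect_error(compare_correlations(0.5, 3, 0.2, 30), "at least 4")
})

test_that("Fisher-z comparison agrees with a permutation reference", {
  # two equal-size samples from the same bivariate normal (null is true);
  # the permutation p-value over group relabelings should match the
  # analytic Fisher p within simulation error
  withr::with_seed(91, {
    n <- 25
    z <- rnorm(2 * n)
    x <- z + rnorm(2 * n)
    y <- z + rnorm(2 * n)
    a_idx <- 1:n
    z_stat <- function(idx) {
      compare_correlations(cor(x[idx], y[idx]), n,
                           cor(x[-idx], y[-idx]), n)$z
    }
    z_obs <- z_stat(a_idx)
    z_perm <- vapply(1:1000, function(i) z_stat(sample(2 * n, n)),
                     numeric(1))
  })
  p_perm <- mean(abs(z_perm) >= abs(z_obs))
  p_fisher <- compare_correlations(cor(x[a_idx], y[a_idx]), n,
                                   cor(x[-a_idx], y[-a_idx]), n)$p
  expect_lt(abs(p_perm - p_fisher), 0.06)
})

test_that("Hedges g* applies the small-sample correction to Cohen's d", {
  expect_equal(effect_size_g(rep(c(1, 2), 10), rep(c(1, 2), 10)), 0)
  x <- c(5.1, 4.8, 6.0, 5.7, 5.3, 4.9, 5.5, 5.8, 5.2, 5.0)
  y <- c(4.2, 4.6, 4.1, 4.9, 4.4, 4.0, 4.7, 4.3, 4.8, 4.5)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  d_oracle <- (mean(x) - mean(y)) / sp
  g_oracle <- d_oracle * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  expect_equal(effect_size_g(x, y), g_oracle, tolerance = 1e-12)
  # mean difference = pooled SD at large n: g* -> 1
  withr::with_seed(81, {
    a <- rnorm(4000); b <- rnorm(4000)
    b <- (b - mean(b)) / sd(b)
    a <- (a - mean(a)) / sd(a) + 1
  })
  expect_equal(effect_size_g(a, b), 1, tolerance = 0.01)
  expect_error(effect_size_g(c(1, 1), c(1, 1)), "pooled standard deviation")
})

test_that("Cousineau-Morey within-group SEs remove participant offsets", {
  # identical condition profiles up to additive shifts: within-SE = 0
  prof <- c(a = 0.1, b = 0.5, c = 0.9)
  d <- tidyr::expand_grid(participant_id = sprintf("P%d", 1:6),
                          condition = names(prof))
  d$value <- prof[d$condition] + rep(c(0, 2, -1, 5, 3, -2), each = 3)
  out <- morey_within_se(d, value = "value")
  expect_equal(out$se, rep(0, 3))
  expect_equal(out$mean, unname(prof) + mean(rep(c(0, 2, -1, 5, 3, -2))))
  # M = 2 toy table against hand computation
  toy <- tibble::tibble(
    participant_id = rep(c("P1", "P2", "P3"), each = 2),
    condition = rep(c("a", "b"), 3),
    value = c(1, 3, 2, 2, 0, 4)
  )
  out2 <- morey_within_se(toy, value = "value")
  grand <- mean(toy$value)
  norm <- toy$value - rep(tapply(toy$value, toy$participant_id, mean),
                          each = 2) + grand
  se_a <- sqrt(2 / 1) * sd(norm[c(1, 3, 5)]) / sqrt(3)
  expect_equal(out2$se[out2$condition == "a"], se_a, tolerance = 1e-12)
  # shifting one participant wholesale changes nothing
  toy2 <- toy
  toy2$value[toy2$participant_id == "P2"] <-
    toy2$value[toy2$participant_id == "P2"] + 100
  expect_equal(morey_within_se(toy2, value = "value")$se, out2$se)
  # single condition: ordinary SE with a warning
  one <- toy[toy$condition == "a", ]
  expect_warning(out1 <- morey_within_se(one, value = "value"),
                 "one condition")
  expect_equal(out1$se, sd(one$value) / sqrt(3))
})
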