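# Shared fixtures and independent oracles used across the test files.

standard_configs <- function() {
  lapply(setNames(nm = c("image", "letter", "tone", "syllable")), task_config)
}

tiny_inventory <- function(n_triplets = 4, seed = 1) {
  build_triplet_inventory(sprintf("s%02d", seq_len(3 * n_triplets)),
                          seed = seed)
}

# Closed-form OLS slope: sum((x - xbar)(y - ybar)) / sum((x - xbar)^2).
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Grier A' through the sign/magnitude formulation (independent coding of
# the same statistic).
a_prime_oracle <- function(h, f) {
  if (h == f) return(0.5)
  s <- sign(h - f)
  0.5 + s * ((h - f)^2 + abs(h - f)) / (4 * max(h, f) - 4 * h * f)
}

# Exhaustive matching oracle: over all one-to-one keypress/target pairings
# whose latencies lie in the window, find the maximum-cardinality matchings
# and among them the minimum total |latency|; ties broken toward earlier
# targets (lexicographically smallest target index vector).
brute_force_assign <- function(target_onsets, keypresses, window) {
  nk <- length(keypresses)
  nt <- length(target_onsets)
  ok <- function(k, j) {
    lat <- keypresses[k] - target_onsets[j]
    lat >= window[1] && lat <= window[2]
  }
  best <- NULL
  # Assign each keypress to a target index or 0 (unassigned), recursively.
  rec <- function(k, used, asg) {
    if (k > nk) {
      m <- sum(asg > 0)
      tot <- sum(abs(keypresses[asg > 0] - target_onsets[asg[asg > 0]]))
      key <- list(m = m, tot = tot, asg = asg)
      if (is.null(best) || m > best$m ||
          (m == best$m && tot < best$tot - 1e-9) ||
          (m == best$m && abs(tot - best$tot) < 1e-9 &&
           paste(asg, collapse = ",") < paste(best$asg, collapse = ","))) {
        best <<- key
      }
      return(invisible())
    }
    for (j in seq_len(nt)) {
      if (!used[j] && ok(k, j)) {
        used[j] <- TRUE
        asg[k] <- j
        rec(k + 1, used, asg)
        used[j] <- FALSE
        asg[k] <- 0L
      }
    }
    rec(k + 1, used, asg)
  }
  rec(1L, logical(nt), integer(nk))
  best
}

# Quick cohort spec for pipeline-level tests: small but with every part of
# the schema exercised.
small_spec <- function(seed = 42, ...) {
  cohort_spec(n_td = 6, n_asd = 6, missing_task_prob = 0.2,
              stream_mode = "per_participant", seed = seed, ...)
}
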