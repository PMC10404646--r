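test_that("triplet inventory partitions the stimulus set", {
  ids <- sprintf("img%02d", 1:12)
  inv <- build_triplet_inventory(ids, seed = 7)
  expect_equal(nrow(inv), 4)
  elements <- c(inv$s1, inv$s2, inv$s3)
  expect_setequal(elements, ids)
  expect_false(anyDuplicated(elements) > 0)
  # single-triplet case: the three ids, permuted
  one <- build_triplet_inventory(c("a", "b", "c"), seed = 1)
  expect_setequal(c(one$s1, one$s2, one$s3), c("a", "b", "c"))
  # invalid stimulus sets
  expect_error(build_triplet_inventory(sprintf("x%d", 1:11)), "divisible")
  expect_error(build_triplet_inventory(c("a", "a", "b")), "distinct")
})

test_that("familiarization streams match the four standard designs", {
  cfgs <- standard_configs()
  for (tk in names(cfgs)) {
    cfg <- cfgs[[tk]]
    inv <- tiny_inventory(seed = 3)
    st <- generate_familiarization_stream(inv, cfg, seed = 11)
    n_pres <- cfg$n_triplets * cfg$reps_per_triplet
    expect_equal(nrow(st), 3 * n_pres)
    expect_equal(sum(st$position == 1), n_pres)
    expect_equal(sum(st$is_target), cfg$reps_per_triplet)
    expect_equal(st$onset_ms, (st$index - 1) * cfg$soa_ms)
    expect_equal(as.integer(table(st$triplet_id)),
                 rep(3L * cfg$reps_per_triplet, 4))
    # target annotation: third element of the target triplet, numbered 1..T
    tgt <- attr(st, "target_triplet_id")
    expect_true(all(st$is_target ==
                      (st$triplet_id == tgt & st$position == 3)))
    expect_equal(st$target_occurrence_index[st$is_target],
                 seq_len(cfg$reps_per_triplet))
  }
})

test_that("one-repetition stream contains each triplet exactly once", {
  cfg <- task_config("image", reps_per_triplet = 1)
  st <- generate_familiarization_stream(tiny_inventory(), cfg, seed = 5)
  expect_equal(nrow(st), 12)
  expect_equal(as.integer(table(st$triplet_id)), rep(3L, 4))
})

test_that("within-triplet transitions are deterministic, boundary transitions uniform", {
  cfg <- task_config("syllable")
  inv <- tiny_inventory(seed = 2)
  st <- generate_familiarization_stream(inv, cfg, seed = 9)
  # positions 1->2 and 2->3 always continue the same triplet
  expect_true(all(st$triplet_id[st$position %in% c(1, 2)] ==
                    st$triplet_id[which(st$position %in% c(1, 2)) + 1]))
  # no immediate repetition of a triplet by default, and the marginal
  # distribution of the following triplet is about uniform
  trip_seq <- st$triplet_id[st$position == 1]
  expect_true(all(trip_seq[-1] != trip_seq[-length(trip_seq)]))
  tab <- table(trip_seq[-1])
  n <- length(trip_seq) - 1
  # binomial tolerance: 4 SDs around n/4
  tol <- 4 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(tab - n / 4) < tol))
})

test_that("allow_immediate_repeat flag permits back-to-back triplets", {
  cfg <- task_config("syllable", allow_immediate_repeat = TRUE)
  inv <- tiny_inventory(seed = 2)
  reps <- vapply(1:20, function(s) {
    st <- generate_familiarization_stream(inv, cfg, seed = s)
    trip_seq <- st$triplet_id[st$position == 1]
    any(trip_seq[-1] == trip_seq[-length(trip_seq)])
  }, logical(1))
  expect_true(any(reps))
})

test_that("streams and test phases are reproducible from the seed", {
  cfg <- task_config("tone")
  inv <- tiny_inventory(seed = 4)
  s1 <- generate_familiarization_stream(inv, cfg, seed = 77)
  s2 <- generate_familiarization_stream(inv, cfg, seed = 77)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  f <- build_foils(inv, seed = 8)
  t1 <- generate_test_phase(inv, f, cfg, seed = 13)
  t2 <- generate_test_phase(inv, f, cfg, seed = 13)
  expect_identical(t1, t2)
  s3 <- generate_familiarization_stream(inv, cfg, seed = 78)
  expect_false(identical(s3$stimulus_id, s1$stimulus_id))
})

test_that("foils preserve positions, are novel, and never occur in the stream", {
  for (seed in 1:10) {
    inv <- tiny_inventory(seed = seed)
    foils <- build_foils(inv, seed = seed + 100)
    expect_equal(nrow(foils), 4)
    tmat <- as.matrix(inv[, c("s1", "s2", "s3")])
    fmat <- as.matrix(foils[, c("s1", "s2", "s3")])
    # position preservation: each foil element drawn from the same position
    # of some target
    for (k in 1:3) expect_true(all(fmat[, k] %in% tmat[, k]))
    # novelty: every foil differs from every target in at least one slot
    for (i in 1:4) for (j in 1:4) {
      expect_true(any(fmat[i, ] != tmat[j, ]))
    }
    # pairwise distinct foils
    expect_equal(anyDuplicated(apply(fmat, 1, paste, collapse = "|")), 0L)
    # three distinct source triplets per foil
    src <- apply(fmat, c(1, 2), function(el) which(tmat == el,
                                                   arr.ind = TRUE)[1])
    expect_true(all(apply(src, 1, function(r) length(unique(r)) == 3)))
    # foils are never contiguous subsequences of a stream built from inv
    st <- generate_familiarization_stream(inv, task_config("image"),
                                          seed = seed)
    s <- st$stimulus_id
    for (i in 1:4) {
      hits <- which(s == fmat[i, 1])
      hits <- hits[hits <= length(s) - 2]
      expect_false(any(s[hits + 1] == fmat[i, 2] & s[hits + 2] == fmat[i, 3]))
    }
  }
})

test_that("test phase is the full crossing with balanced presentation order", {
  inv <- tiny_inventory(seed = 6)
  foils <- build_foils(inv, seed = 7)
  cfg <- task_config("letter")
  tp <- generate_test_phase(inv, foils, cfg, seed = 21)
  expect_equal(nrow(tp), 32)
  # each (target, foil, rep) combination exactly once
  expect_equal(nrow(dplyr::distinct(tp[, c("target_triplet_id", "foil_id",
                                           "rep")])), 32)
  # each target appears in 8 trials (4 foils x 2 reps)
  expect_equal(as.integer(table(tp$target_triplet_id)), rep(8L, 4))
  expect_equal(as.integer(table(tp$presentation_order)), c(16L, 16L))
  # halved crossing with one repetition
  tp1 <- generate_test_phase(inv, foils, task_config("letter", test_reps = 1),
                             seed = 3)
  expect_equal(nrow(tp1), 16)
  expect_error(generate_test_phase(inv, foils[0, ], cfg, 1), "non-empty")
})
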