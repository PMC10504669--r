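spots4 <- function(df) as_spot_table(df)

test_that("find_neighbors links only cross-round spots within radius", {
  df <- spots4(data.frame(spot_id = 1:3, r = c(0, 1, 0), c = 0,
                          x = c(0, 0, 1), y = 0, z = 0, intensity = 1))
  nb0 <- find_neighbors(df, 0)
  expect_equal(nb0[["1"]], 2L)   # co-located, different round
  expect_equal(nb0[["3"]], integer(0))
  df2 <- spots4(data.frame(spot_id = 1:2, r = 0:1, c = 0,
                           x = c(0, 1), y = 0, z = 0, intensity = 1))
  expect_equal(find_neighbors(df2, 0.5)[["1"]], integer(0))
  expect_error(find_neighbors(df2, -1), ">= 0")
})

test_that("find_neighbors matches the all-pairs oracle on random spots", {
  for (s in 1:5) {
    set.seed(s)
    n <- 50
    df <- spots4(data.frame(spot_id = sample(1:200, n),
                            r = sample(0:3, n, TRUE),
                            c = sample(0:3, n, TRUE),
                            x = runif(n, 0, 10), y = runif(n, 0, 10),
                            z = runif(n, 0, 2), intensity = runif(n)))
    expect_identical(find_neighbors(df, 2), oracle_neighbors(df, 2))
  }
})

test_that("build_candidates enumerates the full cartesian product", {
  # seed in round 0 with 2 neighbors in each of rounds 1-3 -> 2^3
  df <- spots4(data.frame(spot_id = 1:7,
                          r = c(0, 1, 1, 2, 2, 3, 3), c = 0,
                          x = 0, y = 0, z = 0, intensity = 1))
  nb <- find_neighbors(df, 1)
  cands <- build_candidates(1, nb, df, 4)
  expect_length(cands, 8)
  # exactly one neighbor per round -> exactly one candidate
  df1 <- spots4(df[c(1, 2, 4, 6), ])
  cands1 <- build_candidates(1, find_neighbors(df1, 1), df1, 4)
  expect_length(cands1, 1)
  expect_equal(cands1[[1]]$spot_ids, c(1L, 2L, 4L, 6L))
  # a round with no neighbors yields zero full-length candidates
  df0 <- spots4(df[c(1, 2, 4), ])
  expect_length(build_candidates(1, find_neighbors(df0, 1), df0, 4), 0)
})

test_that("build_candidates equals the exhaustive tuple oracle", {
  for (s in 1:10) {
    inst <- random_instance(s)
    nb <- find_neighbors(inst$spots, inst$radius)
    for (seed_id in inst$spots$spot_id) {
      got <- build_candidates(seed_id, nb, inst$spots, inst$n_rounds)
      got_sets <- sort(vapply(got, function(cc)
        paste(cc$spot_ids, collapse = ";"), character(1)))
      want <- oracle_candidates(seed_id, inst$spots, inst$radius,
                                inst$n_rounds)
      want_sets <- sort(vapply(want, paste, character(1), collapse = ";"))
      expect_identical(got_sets, want_sets)
    }
  }
})

test_that("score_barcode evaluates the stated closed forms", {
  # perfect barcode: all intensities 1, co-located
  expect_equal(score_barcode(rep(1, 4), matrix(0, 4, 3), 4), 0)
  # QualSum = 3, var-sum = 1, C = 2 -> 3 ln 2
  co <- matrix(0, 4, 3)
  co[, 1] <- c(1, 1, -1, -1)  # population variance = 1
  s <- score_barcode(rep(0.75, 4), co, 4, C = 2)
  expect_equal(s, 3 * log(2), tolerance = 1e-12)
  # positional scatter strictly increases the score
  s2 <- score_barcode(rep(0.75, 4), co * 2, 4, C = 2)
  expect_gt(s2, s)
  expect_error(score_barcode(c(1.5, 1), matrix(0, 2, 3), 4), "\\[0, 1\\]")
})

test_that("select_best_per_seed honours both orders", {
  cands <- data.frame(
    seed = c(1, 1, 2, 2),
    score = c(0.1, 0.5, 0.2, 0.6),
    qualsum = c(3, 3, 3, 3),
    sidkey = c("1;2", "1;3", "2;5", "2;6"),
    target = c("g1", NA, NA, "g2"))
  ff <- select_best_per_seed(cands, "filter_first")
  df <- select_best_per_seed(cands, "decode_first")
  # seed 1: best matches -> identical under both orders
  expect_equal(ff[ff$seed == 1, ]$sidkey, "1;2")
  expect_equal(df[df$seed == 1, ]$sidkey, "1;2")
  # seed 2: best is off-codebook -> filter_first drops it, decode_first
  # falls through to the matching second-best
  expect_false(2 %in% ff$seed)
  expect_equal(df[df$seed == 2, ]$sidkey, "2;6")
})

test_that("per-seed selection matches the brute-force oracle", {
  for (s in 1:10) {
    inst <- random_instance(s + 50)
    cands <- build_scored_cands(inst$spots, inst$cb, inst$radius)
    if (is.null(cands)) next
    for (ord in c("filter_first", "decode_first")) {
      got <- select_best_per_seed(cands, ord)
      want <- oracle_best(cands, ord)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        got <- got[order(got$seed), ]
        want <- want[order(want$seed), ]
        expect_equal(got$sidkey, want$sidkey)
        expect_equal(got$score, want$score)
      }
    }
  }
})

test_that("filter_by_support counts supporting member seeds", {
  best <- data.frame(seed = c(1, 2, 3, 9),
                     score = 0.3, qualsum = 3,
                     sidkey = c("1;2;3;4", "1;2;3;4", "1;2;3;4", "9;2;5;6"),
                     target = "g1")
  expect_equal(nrow(filter_by_support(best, 1)), 2)  # all kept, deduped
  kept <- filter_by_support(best, 3, rounds_used = 4)
  expect_equal(kept$sidkey, "1;2;3;4")
  expect_equal(kept$support, 3L)
  expect_equal(nrow(filter_by_support(best, 4)), 0)  # 3 of 4 -> dropped
  expect_error(filter_by_support(best, 5, rounds_used = 4), "exceed")
})

test_that("resolve_conflicts returns a spot-disjoint set", {
  # pairwise disjoint input returned unchanged
  disj <- data.frame(sidkey = c("1;2", "3;4", "5;6"), score = c(1, 2, 3))
  expect_equal(resolve_conflicts(disj), disj)
  # two candidates sharing one spot: degree tie, worse score removed
  pair <- data.frame(sidkey = c("1;2", "2;3"), score = c(1.0, 2.0))
  expect_equal(resolve_conflicts(pair)$sidkey, "1;2")
})

test_that("greedy conflict resolution matches the independent oracle", {
  for (s in 1:25) {
    set.seed(s)
    n <- 8
    sets <- lapply(seq_len(n), function(i) sample(1:10, 3))
    scores <- round(runif(n), 3)
    cands <- data.frame(
      sidkey = vapply(sets, paste, character(1), collapse = ";"),
      score = scores)
    got <- resolve_conflicts(cands)
    want_idx <- oracle_greedy_mis(sets, scores)
    expect_equal(got$sidkey, cands$sidkey[want_idx])
    # survivors are pairwise disjoint (maximality is not guaranteed by
    # the degree-elimination rule: a removed node's neighbors may all be
    # removed after it)
    ids <- unlist(sets[want_idx])
    expect_equal(anyDuplicated(ids), 0)
    # exact MIS is an upper bound on the greedy size
    expect_lte(length(want_idx), oracle_exact_mis_size(sets))
  }
})

test_that("decode handles empty input and validates the config", {
  cb <- generate_codebook(8, 4, 4, min_hamming = 2, seed = 1)
  empty <- data.frame(spot_id = integer(0), r = integer(0),
                      c = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), intensity = numeric(0))
  out <- decode(empty, cb, decode_config(1))
  expect_equal(nrow(out), 0)
  expect_true(all(c("target", "rounds_used", "source_spot_ids") %in%
                    names(out)))
  # error correction gate
  cb1 <- generate_codebook(8, 4, 4, min_hamming = 1, seed = 99)
  expect_lt(min_pairwise_hamming(cb1), 2)
  sim <- simulate_spots(cb1, 5, seed = 1)
  expect_error(decode(sim$spots, cb1, decode_config(1, error_rounds = 1)),
               "Hamming")
  expect_error(decode_config(-1), ">= 0")
  expect_error(decode_config(2, radius_schedule = c(0.5, 2)),
               "radius_schedule")
})

test_that("decode output is spot-disjoint and deterministic", {
  cb <- generate_codebook(12, 4, 4, min_hamming = 2, seed = 2)
  sim <- simulate_spots(cb, 60, drift_sigma = 0.8, dropout_rate = 0.1,
                        noise_rate = 0.003, seed = 3)
  cfg <- decode_config(2.5, mode = "low", error_rounds = 1)
  tx <- decode(sim$spots, cb, cfg)
  ids <- unlist(lapply(strsplit(tx$source_spot_ids, ";"), as.integer))
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(tx$target %in% cb$targets))
  expect_true(all(tx$rounds_used %in% c(3L, 4L)))
  tx2 <- decode(sim$spots, cb, cfg)
  expect_identical(tx, tx2)
})

test_that("staged decode equals the oracle pipeline on tiny instances", {
  n_checked <- 0
  for (s in 1:40) {
    inst <- random_instance(s + 500)
    sched <- c(0, inst$radius / 2, inst$radius)
    for (mode in c("high", "medium", "low")) {
      cfg <- decode_config(inst$radius, mode = mode,
                           radius_schedule = sched)
      got <- decode(inst$spots, inst$cb, cfg, normalize = FALSE)
      want <- oracle_decode(inst$spots, inst$cb, sched, mode)
      got <- got[order(got$source_spot_ids), ]
      expect_equal(got$source_spot_ids, want$sidkey,
                   info = sprintf("seed %d mode %s", s, mode))
      expect_equal(got$target, want$target)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 120)
})
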