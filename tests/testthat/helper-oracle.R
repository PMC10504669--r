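# Independent brute-force reimplementations of every decoder stage, kept
# deliberately naive (plain loops, no shared code with the package
# internals) so they can serve as oracles.

oracle_neighbors <- function(spots, radius) {
  n <- nrow(spots)
  out <- setNames(vector("list", n), as.character(spots$spot_id))
  for (i in seq_len(n)) {
    ids <- integer(0)
    for (j in seq_len(n)) {
      if (i == j || spots$r[i] == spots$r[j]) next
      d <- sqrt((spots$x[i] - spots$x[j])^2 + (spots$y[i] - spots$y[j])^2 +
                  (spots$z[i] - spots$z[j])^2)
      if (d <= radius + 1e-12) ids <- c(ids, spots$spot_id[j])
    }
    out[[i]] <- sort(ids)
  }
  out
}

# All one-spot-per-round tuples that contain the seed in its own round,
# with every other member a neighbor of the seed, optionally omitting
# `drop_round`. Returns list of sorted-by-round spot_id vectors.
oracle_candidates <- function(seed_id, spots, radius, n_rounds,
                              drop_round = NULL) {
  nb <- oracle_neighbors(spots, radius)[[as.character(seed_id)]]
  seed_round <- spots$r[spots$spot_id == seed_id]
  rounds <- setdiff(0:(n_rounds - 1), drop_round)
  per_round <- lapply(rounds, function(rr) {
    if (rr == seed_round) return(seed_id)
    sort(nb[spots$r[match(nb, spots$spot_id)] == rr])
  })
  if (any(lengths(per_round) == 0)) return(list())
  grid <- expand.grid(per_round)
  lapply(seq_len(nrow(grid)), function(i) as.integer(unlist(grid[i, ])))
}

oracle_score <- function(intensity, coords, n_rounds, C = 2) {
  pv <- function(v) mean((v - mean(v))^2)
  log(1 + (n_rounds - sum(intensity))) +
    C * log(1 + pv(coords[, 1]) + pv(coords[, 2]) + pv(coords[, 3]))
}

# Per-seed best-candidate selection, plain loop over seeds.
oracle_best <- function(cands, order) {
  out <- NULL
  for (s in unique(cands$seed)) {
    sub <- cands[cands$seed == s, , drop = FALSE]
    if (order == "decode_first") sub <- sub[!is.na(sub$target), , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(sub$score, -sub$qualsum, sub$sidkey,
                     method = "radix"), , drop = FALSE]
    pick <- sub[1, , drop = FALSE]
    if (order == "filter_first" && is.na(pick$target)) next
    out <- rbind(out, pick)
  }
  out
}

oracle_support <- function(best, min_support_n) {
  if (is.null(best) || nrow(best) == 0) return(best[0, , drop = FALSE])
  keys <- unique(best$sidkey)
  kept <- NULL
  for (k in keys) {
    sup <- length(unique(best$seed[best$sidkey == k]))
    if (sup >= min_support_n) {
      row <- best[best$sidkey == k, , drop = FALSE][1, , drop = FALSE]
      row$support <- sup
      kept <- rbind(kept, row)
    }
  }
  if (is.null(kept)) return(best[0, , drop = FALSE])
  kept[order(kept$sidkey), , drop = FALSE]
}

# Greedy MIS elimination (current-degree variant), written over an
# explicit adjacency matrix. Ties: degree -> higher score -> larger index
# (the package convention).
oracle_greedy_mis <- function(sets, scores) {
  n <- length(sets)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && length(intersect(sets[[i]], sets[[j]])) > 0)
      adj[i, j] <- TRUE
  alive <- rep(TRUE, n)
  repeat {
    deg <- sapply(seq_len(n), function(i)
      if (alive[i]) sum(adj[i, ] & alive) else -1)
    if (max(deg) <= 0) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1) cand <- cand[scores[cand] == max(scores[cand])]
    victim <- cand[length(cand)]
    alive[victim] <- FALSE
  }
  which(alive)
}

# Exact maximum independent set size by subset enumeration (n <= ~15).
oracle_exact_mis_size <- function(sets) {
  n <- length(sets)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1)
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b && length(intersect(sets[[idx[a]]], sets[[idx[b]]])) > 0)
          ok <- FALSE
    if (ok) best <- max(best, length(idx))
  }
  best
}

# Full staged decode rebuilt from the oracle pieces (used for ≤12-spot
# instances). Mirrors the package's documented conventions but shares no
# code with it.
oracle_decode <- function(spots, cb, radius_schedule, mode,
                          error_rounds = 0) {
  n_rounds <- cb$n_rounds
  keyof <- function(bc) paste(bc, collapse = ",")
  exact <- setNames(seq_along(cb$targets),
                    apply(cb$barcodes, 1, keyof))
  partial <- list()
  if (error_rounds == 1) {
    for (d in 0:(n_rounds - 1))
      for (i in seq_along(cb$targets)) {
        k <- paste0(d, "|", keyof(cb$barcodes[i, -(d + 1)]))
        partial[[k]] <- c(partial[[k]], i)
      }
  }
  presets <- function(R_eff) switch(mode,
    high = list(list("filter_first", max(1, R_eff))),
    medium = list(list("filter_first", max(1, R_eff)),
                  list("decode_first", max(1, R_eff - 1))),
    low = list(list("filter_first", max(1, R_eff - 1)),
               list("decode_first", 1)))
  stages <- list()
  for (rad in radius_schedule) for (p in presets(n_rounds))
    stages[[length(stages) + 1]] <- list(rad, p[[1]], p[[2]], FALSE)
  if (error_rounds == 1)
    for (rad in radius_schedule) for (p in presets(n_rounds - 1))
      stages[[length(stages) + 1]] <- list(rad, p[[1]], p[[2]], TRUE)
  active <- spots
  calls <- NULL
  for (st in stages) {
    if (nrow(active) == 0) break
    rad <- st[[1]]; type <- st[[2]]; msup <- st[[3]]; errp <- st[[4]]
    cands <- NULL
    for (s in active$spot_id) {
      drops <- if (errp) setdiff(0:(n_rounds - 1),
                                 active$r[active$spot_id == s]) else
        list(NULL)
      for (d in drops) {
        for (ids in oracle_candidates(s, active, rad, n_rounds, d)) {
          pos <- match(ids, active$spot_id)
          ch <- active$c[pos]
          key <- if (errp) paste0(d, "|", keyof(ch)) else keyof(ch)
          tgt <- if (errp) {
            hits <- partial[[key]]
            if (length(hits) == 1) cb$targets[hits] else NA
          } else {
            hit <- exact[key]
            if (!is.na(hit)) cb$targets[hit] else NA
          }
          cands <- rbind(cands, data.frame(
            seed = s, sidkey = paste(ids, collapse = ";"),
            score = oracle_score(active$intensity[pos],
                                 cbind(active$x[pos], active$y[pos],
                                       active$z[pos]), n_rounds),
            qualsum = sum(active$intensity[pos]),
            target = if (is.na(tgt)) NA_character_ else tgt,
            rounds_used = length(ids)))
        }
      }
    }
    if (is.null(cands)) next
    best <- oracle_best(cands, type)
    kept <- oracle_support(best, msup)
    if (is.null(kept) || nrow(kept) == 0) next
    sets <- lapply(strsplit(kept$sidkey, ";"), as.integer)
    surv <- oracle_greedy_mis(sets, kept$score)
    if (length(surv) == 0) next
    kept <- kept[surv, , drop = FALSE]
    calls <- rbind(calls, kept[, c("sidkey", "target", "rounds_used",
                                   "score")])
    used <- unique(unlist(lapply(strsplit(kept$sidkey, ";"), as.integer)))
    active <- active[!active$spot_id %in% used, , drop = FALSE]
  }
  if (is.null(calls)) calls <- data.frame(sidkey = character(0),
                                          target = character(0),
                                          rounds_used = integer(0),
                                          score = numeric(0))
  calls[order(calls$sidkey), , drop = FALSE]
}

# Random tiny decode instance shared by the oracle-equivalence tests.
random_instance <- function(seed) {
  set.seed(seed)
  n_rounds <- sample(3:4, 1)
  n_channels <- sample(2:3, 1)
  n_spots <- sample(4:12, 1)
  spots <- data.frame(
    spot_id = sample(1:50, n_spots),
    r = sample(0:(n_rounds - 1), n_spots, replace = TRUE),
    c = sample(0:(n_channels - 1), n_spots, replace = TRUE),
    x = round(runif(n_spots, 0, 6), 2),
    y = round(runif(n_spots, 0, 6), 2),
    z = 0,
    intensity = round(runif(n_spots), 3))
  n_codes <- min(sample(3:6, 1), n_channels^n_rounds)
  codes <- unique(matrix(sample(0:(n_channels - 1), 60 * n_rounds,
                                replace = TRUE), ncol = n_rounds))
  cb <- codebook(sprintf("g%02d", seq_len(n_codes)),
                 codes[seq_len(n_codes), , drop = FALSE],
                 n_channels = n_channels)
  list(spots = spotcall::as_spot_table(spots), cb = cb,
       n_rounds = n_rounds, radius = round(runif(1, 0.5, 4), 2))
}

# Build the scored candidate table for an instance via exported pieces.
build_scored_cands <- function(spots, cb, radius) {
  nb <- find_neighbors(spots, radius)
  rows <- NULL
  for (s in spots$spot_id) {
    for (cand in build_candidates(s, nb, spots, cb$n_rounds)) {
      pos <- match(cand$spot_ids, spots$spot_id)
      key <- paste(cand$channels, collapse = ",")
      hit <- match(key, apply(cb$barcodes, 1, paste, collapse = ","))
      rows <- rbind(rows, data.frame(
        seed = s,
        sidkey = paste(cand$spot_ids, collapse = ";"),
        score = score_barcode(spots$intensity[pos],
                              cbind(spots$x[pos], spots$y[pos],
                                    spots$z[pos]), cb$n_rounds),
        qualsum = sum(spots$intensity[pos]),
        target = if (is.na(hit)) NA_character_ else cb$targets[hit]))
    }
  }
  rows
}
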