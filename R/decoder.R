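#' Decoder run configuration
#'
#' @param search_radius maximum spot-linking radius, in the spot table's
#'   length units. Spots farther apart than this are never combined into
#'   one barcode.
#' @param mode precision/recall preset: `"high"` (filter-first only,
#'   full support), `"medium"`, or `"low"`. Higher accuracy modes trade
#'   recall for precision. See Details.
#' @param error_rounds 0 or 1. With 1, after all exact-match passes, extra
#'   passes decode partial barcodes missing exactly one round; this
#'   requires every pair of codebook entries to differ in at least 2
#'   rounds so a partial code still identifies a unique target.
#' @param score_constant_C weight of the spatial-variance term in the
#'   barcode score (default 2).
#' @param radius_schedule increasing vector of radii, starting at 0 and
#'   ending at `search_radius`; decoding proceeds through these in order so
#'   tight, high-confidence barcodes are called first. Default: 5 evenly
#'   spaced values.
#' @param min_support named overrides for the per-mode support thresholds,
#'   e.g. `list(filter_first = 4, decode_first = 3)`.
#' @param recompute_degrees logical; during greedy conflict elimination,
#'   recompute node degrees after each removal (default) or use initial
#'   degrees.
#' @param max_candidates_per_seed safety cap on the candidate enumeration
#'   per seed spot (dense noise can make the cartesian product explode);
#'   seeds exceeding it contribute no candidates in that stage.
#' @return a `decode_config` list.
#' @details The mode presets set the minimum number of member spots that
#'   must independently select a barcode as their best ("support") and
#'   whether the lower-precision decode-first pass runs at all:
#'   `high` = filter-first only at support `n_rounds`; `medium` =
#'   filter-first at `n_rounds` then decode-first at `n_rounds - 1`;
#'   `low` = filter-first at `n_rounds - 1` then decode-first at 1.
#'   Error-correction passes use the same presets with `n_rounds - 1`
#'   playing the role of `n_rounds`.
#' @export
decode_config <- function(search_radius, mode = c("medium", "high", "low"),
                          error_rounds = 0L, score_constant_C = 2,
                          radius_schedule = NULL, min_support = NULL,
                          recompute_degrees = TRUE,
                          max_candidates_per_seed = 50000L) {
  mode <- match.arg(mode)
  if (!is.numeric(search_radius) || search_radius < 0)
    stop("search_radius must be >= 0")
  error_rounds <- as.integer(error_rounds)
  if (!error_rounds %in% c(0L, 1L)) stop("error_rounds must be 0 or 1")
  if (is.null(radius_schedule)) {
    radius_schedule <- if (search_radius == 0) 0 else
      seq(0, search_radius, length.out = 5L)
  }
  if (is.unsorted(radius_schedule, strictly = TRUE) ||
      radius_schedule[1] != 0 ||
      abs(radius_schedule[length(radius_schedule)] - search_radius) > 1e-12)
    stop("radius_schedule must strictly increase from 0 to search_radius")
  structure(list(search_radius = search_radius, mode = mode,
                 error_rounds = error_rounds, C = score_constant_C,
                 radius_schedule = radius_schedule,
                 min_support = min_support,
                 recompute_degrees = isTRUE(recompute_degrees),
                 max_candidates_per_seed = as.integer(max_candidates_per_seed)),
            class = "decode_config")
}

# Per-mode pass schedule. `R_eff` is n_rounds for exact passes and
# n_rounds - 1 for single-round error-correction passes.
mode_passes <- function(mode, R_eff, overrides = NULL) {
  ff <- function(n) list(type = "filter_first", min_support = max(1L, n))
  df <- function(n) list(type = "decode_first", min_support = max(1L, n))
  passes <- switch(mode,
    high   = list(ff(R_eff)),
    medium = list(ff(R_eff), df(R_eff - 1L)),
    low    = list(ff(R_eff - 1L), df(1L)))
  if (!is.null(overrides)) {
    for (i in seq_along(passes)) {
      ov <- overrides[[passes[[i]]$type]]
      if (!is.null(ov)) passes[[i]]$min_support <- as.integer(ov)
    }
  }
  passes
}

#' Find cross-round spot neighbors within a radius
#'
#' Two spots are neighbors when they lie in different rounds and their
#' Euclidean distance in (x, y, z) is at most `radius`. Spots in the same
#' round are never neighbors (a barcode uses one spot per round).
#'
#' @param spots a spot table.
#' @param radius search radius, >= 0.
#' @return a named list: for each `spot_id` (as name), the integer vector
#'   of neighboring spot ids, sorted.
#' @export
find_neighbors <- function(spots, radius) {
  if (radius < 0) stop("radius must be >= 0")
  spots <- as_spot_table(spots)
  adj <- neighbor_adjacency(spots, radius)
  out <- lapply(adj, function(p) sort(spots$spot_id[p]))
  names(out) <- as.character(spots$spot_id)
  out
}

# Position-indexed adjacency list (list index = row in `spots`, values =
# row positions of cross-round neighbors within `radius`).
neighbor_adjacency <- function(spots, radius) {
  n <- nrow(spots)
  adj <- rep(list(integer(0)), n)
  if (n < 2L) return(adj)
  dm <- as.matrix(stats::dist(cbind(spots$x, spots$y, spots$z)))
  ok <- dm <= radius + 1e-12
  ok[outer(spots$r, spots$r, "==")] <- FALSE
  hits <- which(ok, arr.ind = TRUE)
  if (nrow(hits)) {
    byrow <- split(hits[, 2L], hits[, 1L])
    adj[as.integer(names(byrow))] <- byrow
  }
  adj
}

#' Enumerate candidate barcodes around a seed spot
#'
#' Builds every full-length (or, with `drop_round`, every length
#' `n_rounds - 1`) combination that uses the seed spot in its own round and
#' one of the seed's neighbors in each other round -- the full cartesian
#' product over rounds.
#'
#' @param seed_spot_id the spot to build candidates around.
#' @param neighbor_map output of [find_neighbors()].
#' @param spots the spot table the map was built from.
#' @param n_rounds number of rounds in the experiment.
#' @param drop_round optional round index to omit (single-round error
#'   correction); must differ from the seed's round.
#' @return a list of candidates; each is a list with `spot_ids` (ordered by
#'   round), `rounds`, `channels`.
#' @export
build_candidates <- function(seed_spot_id, neighbor_map, spots, n_rounds,
                             drop_round = NULL) {
  spots <- as_spot_table(spots)
  pos <- match(seed_spot_id, spots$spot_id)
  if (is.na(pos)) stop("seed spot not present in spot table")
  nb_ids <- neighbor_map[[as.character(seed_spot_id)]]
  nb_pos <- match(nb_ids, spots$spot_id)
  seed_round <- spots$r[pos]
  rounds <- setdiff(0:(n_rounds - 1L), drop_round)
  if (!is.null(drop_round) && drop_round == seed_round)
    stop("cannot drop the seed spot's own round")
  lists <- lapply(rounds, function(rr) {
    if (rr == seed_round) pos else sort(nb_pos[spots$r[nb_pos] == rr])
  })
  if (any(lengths(lists) == 0L)) return(list())
  grid <- as.matrix(expand.grid(lists, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    p <- grid[i, ]
    list(spot_ids = spots$spot_id[p], rounds = rounds,
         channels = spots$c[p])
  })
}

#' Score a candidate barcode
#'
#' `Score = Q + Sv * C` with `Q = log(1 + (RoundNum - QualSum))` (QualSum =
#' summed normalized member intensities, RoundNum = rounds in the
#' experiment) and `Sv = log(1 + sum over x,y,z of var(coords))` using the
#' population variance over member spots. Lower scores are better: a
#' perfect barcode (all intensities 1, all spots co-located) scores 0.
#'
#' @param intensities normalized member intensities in `[0, 1]`.
#' @param coords numeric matrix of member coordinates, columns x, y, z.
#' @param n_rounds number of rounds in the experiment (RoundNum).
#' @param C weight of the spatial variance term (default 2).
#' @return the (lower-is-better) score.
#' @export
score_barcode <- function(intensities, coords, n_rounds, C = 2) {
  if (length(intensities) < 1L) stop("need at least one member spot")
  if (any(intensities < -1e-9) || any(intensities > 1 + 1e-9))
    stop("intensities must be normalized to [0, 1]")
  coords <- as.matrix(coords)
  q <- log1p(n_rounds - sum(intensities))
  sv <- log1p(sum(apply(coords, 2L, pop_var)))
  q + sv * C
}

#' Pick each seed spot's best candidate barcode
#'
#' Two selection orders trade precision against recall. `filter_first`
#' picks the minimum-score candidate per seed and then discards it if its
#' channel sequence matches no codebook entry (higher precision).
#' `decode_first` restricts each seed's candidates to codebook matches
#' before taking the minimum (higher recall). Score ties break toward the
#' larger summed intensity, then the lexicographically smallest spot-id
#' key, so selection is deterministic.
#'
#' @param cands data.frame with columns `seed`, `score`, `qualsum`,
#'   `sidkey` (canonical spot-set key) and either a `target` column (NA
#'   when unmatched) or a `chkey` channel-sequence key plus `codebook`.
#' @param order `"filter_first"` or `"decode_first"`.
#' @param codebook optional [codebook] used to fill `target` from `chkey`.
#' @return the selected rows, one per surviving seed.
#' @export
select_best_per_seed <- function(cands, order = c("filter_first",
                                                  "decode_first"),
                                 codebook = NULL) {
  order <- match.arg(order)
  dt <- data.table::as.data.table(cands)
  if (!"target" %in% names(dt)) {
    if (is.null(codebook)) stop("need a target column or a codebook")
    lut <- stats::setNames(codebook$targets, barcode_keys(codebook))
    dt[, target := lut[chkey]]
  }
  if (order == "decode_first") dt <- dt[!is.na(target)]
  if (nrow(dt) == 0L) return(as.data.frame(dt))
  data.table::setorder(dt, seed, score, -qualsum, sidkey)
  best <- dt[, .SD[1L], by = seed]
  if (order == "filter_first") best <- best[!is.na(target)]
  as.data.frame(best)
}

#' Keep candidates supported by enough of their own member spots
#'
#' Candidates selected as "best" by different seeds but consisting of the
#' identical spot set are the same barcode; its support is the number of
#' member spots whose per-seed selection chose it. Only barcodes with
#' support at least `min_support_n` are kept.
#'
#' @param best one row per seed, as returned by [select_best_per_seed()].
#' @param min_support_n minimum number of supporting member spots.
#' @param rounds_used barcode length, to validate `min_support_n`.
#' @return one row per surviving unique barcode, with a `support` column.
#' @export
filter_by_support <- function(best, min_support_n, rounds_used = NULL) {
  if (!is.null(rounds_used) && min_support_n > rounds_used)
    stop("min_support_n cannot exceed the number of member spots")
  dt <- data.table::as.data.table(best)
  if (nrow(dt) == 0L) return(as.data.frame(dt))
  dt[, support := data.table::uniqueN(seed), by = sidkey]
  dt <- dt[support >= min_support_n]
  uniq <- dt[, .SD[1L], by = sidkey]
  data.table::setorder(uniq, sidkey)
  as.data.frame(uniq)
}

#' Resolve spot-sharing conflicts between candidate barcodes
#'
#' Builds the conflict graph (nodes = candidate barcodes, edges between
#' candidates sharing at least one spot) and approximates a maximum
#' independent set by eliminating nodes in order of highest degree, ties
#' broken by removing the worse (higher) score, until no edges remain.
#' Survivors are pairwise spot-disjoint.
#'
#' @param cands data.frame with columns `sidkey` (semicolon-joined spot
#'   ids) and `score`.
#' @param recompute_degrees recompute degrees after each removal (default)
#'   rather than eliminating by initial degree.
#' @return the surviving rows.
#' @export
resolve_conflicts <- function(cands, recompute_degrees = TRUE) {
  n <- nrow(cands)
  if (is.null(n) || n == 0L) return(cands)
  sets <- split_spot_ids(cands$sidkey)
  keep <- resolve_conflicts_idx(sets, cands$score, recompute_degrees)
  cands[sort(keep), , drop = FALSE]
}

# Greedy MIS on index form: sets = list of integer spot-id vectors.
# Returns indices of surviving candidates. Remaining ties after
# degree/score break toward removing the later index (fixed, arbitrary).
resolve_conflicts_idx <- function(sets, scores, recompute_degrees = TRUE) {
  n <- length(sets)
  if (n == 0L) return(integer(0))
  long <- data.frame(cand = rep(seq_len(n), lengths(sets)),
                     spot = unlist(sets))
  nbr <- rep(list(integer(0)), n)
  for (grp in split(long$cand, long$spot)) {
    grp <- unique(grp)
    if (length(grp) > 1L)
      for (i in grp) nbr[[i]] <- union(nbr[[i]], setdiff(grp, i))
  }
  alive <- rep(TRUE, n)
  deg <- lengths(nbr)
  deg0 <- deg
  repeat {
    use <- if (recompute_degrees) deg else ifelse(deg > 0L, deg0, 0L)
    use[!alive] <- -1L
    if (all(use <= 0L)) break
    mx <- max(use)
    cand <- which(use == mx)
    if (length(cand) > 1L) {
      worst <- max(scores[cand])
      cand <- cand[scores[cand] == worst]
    }
    victim <- cand[length(cand)]
    alive[victim] <- FALSE
    for (j in nbr[[victim]]) {
      if (alive[j]) deg[j] <- deg[j] - 1L
      nbr[[j]] <- setdiff(nbr[[j]], victim)
    }
    deg[victim] <- 0L
    nbr[[victim]] <- integer(0)
  }
  which(alive)
}

# ---------------------------------------------------------------------------
# Full decode orchestration
# ---------------------------------------------------------------------------

# Lookup tables from channel-sequence keys to codebook entry index.
exact_lookup <- function(cb) {
  stats::setNames(seq_along(cb$targets), barcode_keys(cb))
}

# Partial-code lookup: for every (dropped round d, entry), key
# "d|channels-without-round-d". Ambiguous keys (consistent with more than
# one entry) map to NA so they are never called.
partial_lookup <- function(cb) {
  keys <- character(0); idx <- integer(0)
  for (d in 0:(cb$n_rounds - 1L)) {
    k <- apply(cb$barcodes[, -(d + 1L), drop = FALSE], 1L, paste,
               collapse = ",")
    keys <- c(keys, paste0(d, "|", k))
    idx <- c(idx, seq_along(cb$targets))
  }
  dup <- keys %in% keys[duplicated(keys)]
  idx[dup] <- NA_integer_
  first <- !duplicated(keys)
  stats::setNames(idx[first], keys[first])
}

# Enumerate all candidates for one stage over the active spot table.
# Returns NULL or list(M = position matrix (cand x rounds_used, columns in
# ascending round order), seed = seed position per candidate,
# dropped = dropped round per candidate (NA in exact passes)).
enumerate_stage <- function(active, adj, n_rounds, error_pass, cap) {
  n <- nrow(active)
  mats <- vector("list", 2L * n)
  seeds <- vector("list", 2L * n)
  drops <- vector("list", 2L * n)
  k <- 0L
  for (s in seq_len(n)) {
    nb <- adj[[s]]
    sr <- active$r[s]
    by_round <- split(nb, active$r[nb])
    drop_opts <- if (error_pass) setdiff(0:(n_rounds - 1L), sr) else NA
    for (d in drop_opts) {
      rounds <- if (is.na(d)) 0:(n_rounds - 1L) else
        setdiff(0:(n_rounds - 1L), d)
      lists <- lapply(rounds, function(rr) {
        if (rr == sr) s else {
          v <- by_round[[as.character(rr)]]
          if (is.null(v)) integer(0) else sort(v)
        }
      })
      sz <- lengths(lists)
      if (any(sz == 0L)) next
      if (prod(sz) > cap) next
      g <- as.matrix(expand.grid(lists, KEEP.OUT.ATTRS = FALSE))
      k <- k + 1L
      if (k > length(mats)) {
        mats <- c(mats, vector("list", k)); seeds <- c(seeds, vector("list", k))
        drops <- c(drops, vector("list", k))
      }
      mats[[k]] <- g
      seeds[[k]] <- rep.int(s, nrow(g))
      drops[[k]] <- rep.int(as.integer(d), nrow(g))
    }
  }
  if (k == 0L) return(NULL)
  list(M = do.call(rbind, mats[seq_len(k)]),
       seed = unlist(seeds[seq_len(k)]),
       dropped = unlist(drops[seq_len(k)]))
}

paste_rows <- function(M, sep) {
  do.call(paste, c(as.data.frame(M), list(sep = sep)))
}

# Run one (radius, pass) decoding stage. Returns list(records, used_pos).
decode_stage <- function(active, adj, pass_type, min_support, n_rounds, C,
                         lut, error_pass, cap, recompute_degrees) {
  enum <- enumerate_stage(active, adj, n_rounds, error_pass, cap)
  if (is.null(enum)) return(NULL)
  M <- enum$M
  qual <- rowSums(matrix(active$intensity[M], nrow(M)))
  varsum <- 0
  for (col in c("x", "y", "z")) {
    A <- matrix(active[[col]][M], nrow(M))
    varsum <- varsum + (rowMeans(A * A) - rowMeans(A)^2)
  }
  varsum <- pmax(varsum, 0)
  score <- log1p(n_rounds - qual) + C * log1p(varsum)
  chkey <- paste_rows(matrix(active$c[M], nrow(M)), ",")
  mkey <- if (error_pass) paste0(enum$dropped, "|", chkey) else chkey
  target_idx <- unname(lut[mkey])
  sidkey <- paste_rows(matrix(active$spot_id[M], nrow(M)), ";")
  dt <- data.table::data.table(
    seed = active$spot_id[enum$seed], row = seq_len(nrow(M)),
    score = score, qualsum = qual, sidkey = sidkey,
    target_idx = target_idx)
  if (pass_type == "decode_first") dt <- dt[!is.na(target_idx)]
  if (nrow(dt) == 0L) return(NULL)
  data.table::setorder(dt, seed, score, -qualsum, sidkey)
  best <- dt[, .SD[1L], by = seed]
  if (pass_type == "filter_first") best <- best[!is.na(target_idx)]
  if (nrow(best) == 0L) return(NULL)
  best[, support := data.table::uniqueN(seed), by = sidkey]
  best <- best[support >= min_support]
  if (nrow(best) == 0L) return(NULL)
  uniq <- best[, .SD[1L], by = sidkey]
  data.table::setorder(uniq, sidkey)
  sets <- asplit(matrix(active$spot_id[M], nrow(M))[uniq$row, , drop = FALSE],
                 1L)
  sets <- lapply(sets, as.integer)
  keep <- sort(resolve_conflicts_idx(sets, uniq$score, recompute_degrees))
  if (length(keep) == 0L) return(NULL)
  uniq <- uniq[keep]
  pos_mat <- M[uniq$row, , drop = FALSE]
  list(records = data.frame(
         target_idx = uniq$target_idx,
         x = rowMeans(matrix(active$x[pos_mat], nrow(pos_mat))),
         y = rowMeans(matrix(active$y[pos_mat], nrow(pos_mat))),
         z = rowMeans(matrix(active$z[pos_mat], nrow(pos_mat))),
         rounds_used = ncol(pos_mat),
         source_spot_ids = uniq$sidkey,
         score = uniq$score,
         cell_id = stage_cell_ids(active, pos_mat)),
       used_pos = unique(as.vector(pos_mat)))
}

# Majority cell id over member spots (NAs ignored; ties -> smallest id).
stage_cell_ids <- function(active, pos_mat) {
  if (is.null(active$cell_id)) return(rep(NA_integer_, nrow(pos_mat)))
  cid <- matrix(active$cell_id[pos_mat], nrow(pos_mat))
  apply(cid, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  })
}

#' Decode a spot table against a codebook
#'
#' Runs the staged exhaustive decoder: for each radius in the schedule,
#' a high-precision filter-first pass and (mode permitting) a
#' higher-recall decode-first pass; spots consumed by decoded barcodes are
#' removed before the next stage. With `error_rounds = 1`, a final set of
#' passes decodes partial barcodes missing exactly one round, allowed only
#' when all codebook pairs differ in at least 2 rounds. Output rows carry
#' `rounds_used` so error-corrected calls are separable from full-length
#' calls.
#'
#' @param spots a spot table (see [as_spot_table()]).
#' @param cb a [codebook].
#' @param config a [decode_config()].
#' @param normalize normalize intensities per (round, channel) first
#'   (default TRUE; see [normalize_intensities()]).
#' @param verbose emit one message per stage with spots consumed and
#'   barcodes called.
#' @return a decoded transcript data.frame with columns `target, x, y, z,
#'   rounds_used, source_spot_ids, is_off_target, cell_id, score`. No spot
#'   contributes to more than one row.
#' @export
decode <- function(spots, cb, config, normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(cb, "codebook"), inherits(config, "decode_config"))
  spots <- as_spot_table(spots)
  empty <- data.frame(target = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), rounds_used = integer(0),
                      source_spot_ids = character(0),
                      is_off_target = logical(0), cell_id = integer(0),
                      score = numeric(0))
  if (config$error_rounds == 1L && min_pairwise_hamming(cb) < 2L)
    stop("error_rounds = 1 requires minimum pairwise Hamming distance >= 2")
  if (nrow(spots) == 0L) return(empty)
  if (any(spots$r >= cb$n_rounds) || any(spots$c >= cb$n_channels))
    stop("spot round/channel indices exceed the codebook dimensions")
  if (normalize) spots <- normalize_intensities(spots)
  if (any(spots$intensity < -1e-9 | spots$intensity > 1 + 1e-9))
    stop("intensities must be in [0, 1]; set normalize = TRUE")
  n_rounds <- cb$n_rounds
  stages <- list()
  for (radius in config$radius_schedule)
    for (p in mode_passes(config$mode, n_rounds, config$min_support))
      stages[[length(stages) + 1L]] <- c(p, list(radius = radius,
                                                 error = FALSE))
  if (config$error_rounds == 1L && n_rounds >= 2L)
    for (radius in config$radius_schedule)
      for (p in mode_passes(config$mode, n_rounds - 1L, config$min_support))
        stages[[length(stages) + 1L]] <- c(p, list(radius = radius,
                                                   error = TRUE))
  lut_exact <- exact_lookup(cb)
  lut_part <- if (config$error_rounds == 1L) partial_lookup(cb)
  active <- spots
  out <- list()
  for (st in stages) {
    if (nrow(active) == 0L) break
    adj <- neighbor_adjacency(active, st$radius)
    res <- decode_stage(active, adj, st$type, st$min_support, n_rounds,
                        config$C, if (st$error) lut_part else lut_exact,
                        st$error, config$max_candidates_per_seed,
                        config$recompute_degrees)
    if (verbose)
      message(sprintf(
        "stage r=%.3g %s%s: %d barcodes, %d spots consumed, %d spots left",
        st$radius, st$type, if (st$error) " (error-corrected)" else "",
        if (is.null(res)) 0L else nrow(res$records),
        if (is.null(res)) 0L else length(res$used_pos),
        nrow(active) - if (is.null(res)) 0L else length(res$used_pos)))
    if (is.null(res)) next
    out[[length(out) + 1L]] <- res$records
    active <- active[-res$used_pos, , drop = FALSE]
  }
  if (!length(out)) return(empty)
  rec <- do.call(rbind, out)
  data.frame(target = cb$targets[rec$target_idx],
             x = rec$x, y = rec$y, z = rec$z,
             rounds_used = rec$rounds_used,
             source_spot_ids = rec$source_spot_ids,
             is_off_target = cb$is_off_target[rec$target_idx],
             cell_id = rec$cell_id, score = rec$score)
}
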