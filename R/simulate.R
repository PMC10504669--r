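#' Generate a random codebook
#'
#' Samples unique barcodes uniformly at random with rejection until
#' `n_targets` codes with pairwise Hamming distance at least `min_hamming`
#' are collected. Deterministic under the seed.
#'
#' @param n_targets number of targets.
#' @param n_rounds,n_channels barcode dimensions.
#' @param min_hamming minimum pairwise Hamming distance (2 enables
#'   single-round error correction).
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap before declaring the request
#'   infeasible.
#' @return a [codebook] with targets `gene_001`, `gene_002`, ...
#' @export
generate_codebook <- function(n_targets, n_rounds, n_channels,
                              min_hamming = 1L, seed,
                              max_tries = 20000L) {
  if (n_targets > n_channels^n_rounds)
    stop(sprintf("requested %d targets but only %d distinct codes exist",
                 n_targets, n_channels^n_rounds))
  local_rng(seed)
  kept <- matrix(integer(0), 0L, n_rounds)
  tries <- 0L
  while (nrow(kept) < n_targets && tries < max_tries) {
    tries <- tries + 1L
    cand <- sample.int(n_channels, n_rounds, replace = TRUE) - 1L
    ok <- nrow(kept) == 0L ||
      all(rowSums(kept != matrix(cand, nrow(kept), n_rounds,
                                 byrow = TRUE)) >= min_hamming)
    if (ok) kept <- rbind(kept, cand)
  }
  if (nrow(kept) < n_targets)
    stop(sprintf(paste0("could not find %d codes at min Hamming distance ",
                        "%d (got %d); request may be infeasible"),
                 n_targets, min_hamming, nrow(kept)))
  codebook(sprintf("gene_%03d", seq_len(n_targets)), kept,
           n_channels = n_channels)
}

#' Simulate a multiplexed-FISH spot dataset with known ground truth
#'
#' Places `n_transcripts` transcripts in the field of view (uniformly, or
#' in Gaussian clusters) and, for each round not lost to dropout, emits
#' one spot at the true position plus isotropic Gaussian drift, in the
#' channel dictated by the target's barcode, with intensity drawn from a
#' clamped Gaussian. Spurious background spots are added per round as a
#' Poisson count at `noise_rate` per unit area, uniform positions, random
#' channels, and (worst case for decoding) the same intensity model.
#'
#' @param cb the [codebook] to draw targets from (off-target entries are
#'   never emitted).
#' @param n_transcripts number of true transcripts.
#' @param fov_dims `c(width, height)` of the field of view.
#' @param drift_sigma per-round positional drift (Gaussian sd, length
#'   units).
#' @param dropout_rate probability that a transcript's spot in a given
#'   round is not detected, independently per (transcript, round).
#' @param noise_rate expected spurious spots per round per unit area.
#' @param intensity_mean,intensity_sd spot intensity model, clamped to
#'   `[0, 1]`.
#' @param clusters optional `list(k =, sigma =)`: place transcripts in `k`
#'   Gaussian clusters of spread `sigma` instead of uniformly.
#' @param cell_grid optional integer g: assign spots to a g-by-g grid of
#'   square "cells" via a `cell_id` column.
#' @param seed integer seed; the whole simulation is deterministic under
#'   it.
#' @return a list with `spots` (spot table), `truth` (list of
#'   `transcripts`, `emitted`, `dropped` data.frames) and the config used.
#' @export
simulate_spots <- function(cb, n_transcripts, fov_dims = c(100, 100),
                           drift_sigma = 0, dropout_rate = 0,
                           noise_rate = 0, intensity_mean = 0.8,
                           intensity_sd = 0.1, clusters = NULL,
                           cell_grid = NULL, seed) {
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  if (noise_rate < 0 || drift_sigma < 0)
    stop("rates and drift_sigma must be >= 0")
  if (any(fov_dims <= 0)) stop("fov_dims must be positive")
  local_rng(seed)
  n_rounds <- cb$n_rounds
  on_idx <- which(!cb$is_off_target)
  tid <- seq_len(n_transcripts)
  target_idx <- sample(on_idx, n_transcripts, replace = TRUE)
  if (is.null(clusters)) {
    tx <- runif(n_transcripts, 0, fov_dims[1])
    ty <- runif(n_transcripts, 0, fov_dims[2])
  } else {
    cx <- runif(clusters$k, 0, fov_dims[1])
    cy <- runif(clusters$k, 0, fov_dims[2])
    pick <- sample.int(clusters$k, n_transcripts, replace = TRUE)
    tx <- pmin(pmax(rnorm(n_transcripts, cx[pick], clusters$sigma), 0),
               fov_dims[1])
    ty <- pmin(pmax(rnorm(n_transcripts, cy[pick], clusters$sigma), 0),
               fov_dims[2])
  }
  draw_intensity <- function(n)
    pmin(pmax(rnorm(n, intensity_mean, intensity_sd), 0), 1)
  # transcript-emitted spots: one per (transcript, kept round)
  grid <- expand.grid(transcript = tid, r = 0:(n_rounds - 1L))
  keep <- runif(nrow(grid)) >= dropout_rate
  emitted <- grid[keep, , drop = FALSE]
  ne <- nrow(emitted)
  sp_tx <- data.frame(
    spot_id = seq_len(ne),
    r = emitted$r,
    c = cb$barcodes[cbind(target_idx[emitted$transcript], emitted$r + 1L)],
    x = tx[emitted$transcript] + rnorm(ne, 0, drift_sigma),
    y = ty[emitted$transcript] + rnorm(ne, 0, drift_sigma),
    z = numeric(ne), intensity = draw_intensity(ne))
  # spurious background spots, Poisson per round
  n_noise <- rpois(n_rounds, noise_rate * fov_dims[1] * fov_dims[2])
  nn <- sum(n_noise)
  sp_noise <- data.frame(
    spot_id = ne + seq_len(nn),
    r = rep(0:(n_rounds - 1L), n_noise),
    c = sample.int(cb$n_channels, nn, replace = TRUE) - 1L,
    x = runif(nn, 0, fov_dims[1]), y = runif(nn, 0, fov_dims[2]),
    z = numeric(nn), intensity = draw_intensity(nn))
  spots <- rbind(sp_tx, sp_noise)
  if (!is.null(cell_grid))
    spots$cell_id <- grid_cell_id(spots$x, spots$y, fov_dims, cell_grid)
  dropped <- grid[!keep, , drop = FALSE]
  truth <- list(
    transcripts = data.frame(transcript_id = tid,
                             target = cb$targets[target_idx],
                             x = tx, y = ty, z = 0),
    emitted = data.frame(transcript_id = emitted$transcript,
                         r = emitted$r, spot_id = sp_tx$spot_id),
    dropped = data.frame(transcript_id = dropped$transcript,
                         r = dropped$r))
  list(spots = as_spot_table(spots), truth = truth,
       config = list(n_transcripts = n_transcripts, fov_dims = fov_dims,
                     drift_sigma = drift_sigma,
                     dropout_rate = dropout_rate, noise_rate = noise_rate,
                     intensity_mean = intensity_mean,
                     intensity_sd = intensity_sd, seed = seed))
}

#' Assign points to a g-by-g grid of square cells
#'
#' A minimal stand-in for a segmentation mask: the field of view is split
#' into `g * g` equal rectangles and each point gets the 1-based id of the
#' rectangle containing it.
#'
#' @param x,y point coordinates.
#' @param fov_dims `c(width, height)`.
#' @param g cells per side.
#' @export
grid_cell_id <- function(x, y, fov_dims, g) {
  ix <- pmin(pmax(floor(x / fov_dims[1] * g), 0), g - 1)
  iy <- pmin(pmax(floor(y / fov_dims[2] * g), 0), g - 1)
  as.integer(ix + g * iy + 1)
}

#' Score decoded output against simulation ground truth
#'
#' Greedy nearest matching: a decoded call is a true positive when an
#' unmatched ground-truth transcript of the same target lies within
#' `match_radius`; candidate pairs are consumed in order of increasing
#' distance. `precision = TP / (TP + FP)`, `recall = TP / n_truth`. With
#' zero decoded calls, precision is reported as 1.0 with `zero_calls =
#' TRUE`.
#'
#' @param decoded decoded transcript table (from [decode()]).
#' @param truth ground truth (from [simulate_spots()]).
#' @param match_radius maximum decoded-to-truth distance for a match.
#' @return list with `precision`, `recall`, `tp`, `fp`, `n_truth`,
#'   `n_calls`, `zero_calls`, and the same figures restricted to
#'   non-corrected (`nc`) and error-corrected (`ec`) calls.
#' @export
evaluate_decoding <- function(decoded, truth, match_radius) {
  tt <- truth$transcripts
  n_truth <- nrow(tt)
  n_calls <- nrow(decoded)
  matched_call <- rep(FALSE, n_calls)
  if (n_calls > 0L) {
    matched_truth <- rep(FALSE, n_truth)
    for (tg in unique(decoded$target)) {
      di <- which(decoded$target == tg)
      ti <- which(tt$target == tg)
      if (!length(ti)) next
      dmat <- outer(decoded$x[di], tt$x[ti], "-")^2 +
        outer(decoded$y[di], tt$y[ti], "-")^2
      pairs <- which(dmat <= match_radius^2, arr.ind = TRUE)
      if (!nrow(pairs)) next
      pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
      for (k in seq_len(nrow(pairs))) {
        a <- di[pairs[k, 1L]]; b <- ti[pairs[k, 2L]]
        if (!matched_call[a] && !matched_truth[b]) {
          matched_call[a] <- TRUE; matched_truth[b] <- TRUE
        }
      }
    }
  }
  summarize <- function(sel) {
    tp <- sum(matched_call[sel]); fp <- sum(sel) - tp
    list(tp = tp, fp = fp, n_calls = sum(sel),
         precision = if (sum(sel) == 0L) 1.0 else tp / (tp + fp))
  }
  all_s <- summarize(rep(TRUE, n_calls))
  nr <- if (n_calls > 0L) max(decoded$rounds_used) else 0L
  full <- if (n_calls > 0L) decoded$rounds_used == nr else logical(0)
  c(all_s,
    list(recall = if (n_truth == 0L) 1.0 else all_s$tp / n_truth,
         n_truth = n_truth, zero_calls = n_calls == 0L,
         nc = summarize(full), ec = summarize(!full)))
}

#' Multiplicative Gaussian noise model
#'
#' `output = input + n * input` with `n ~ Normal(mean, sqrt(variance))`
#' drawn independently per value -- the model used to emulate images
#' acquired with a shorter exposure time. Negative results are clamped at
#' 0, since the values being degraded (intensities/counts) are
#' non-negative.
#'
#' @param values finite numeric vector.
#' @param mean,variance parameters of the Gaussian factor (defaults 1.5
#'   and 3.0).
#' @param seed integer seed.
#' @param clamp clamp negative outputs at 0 (default TRUE); disable to
#'   study the raw noise model.
#' @export
add_multiplicative_gaussian_noise <- function(values, mean = 1.5,
                                              variance = 3.0, seed,
                                              clamp = TRUE) {
  if (variance < 0) stop("variance must be >= 0")
  if (!all(is.finite(values))) stop("values must be finite")
  local_rng(seed)
  n <- rnorm(length(values), mean, sqrt(variance))
  out <- values + n * values
  if (clamp) out <- pmax(out, 0)
  out
}
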