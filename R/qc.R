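# Upper end of a two-tailed 95% normal confidence interval.
Z95 <- 1.959964

#' Off-target count threshold for on-target calls
#'
#' Tallies decoded calls per codebook target (targets with zero calls
#' included), then models the off-target (blank) counts as normal and
#' proposes `mean + 1.959964 * sd` -- the upper end of a two-tailed 95%
#' confidence interval -- as the cutoff below which an on-target barcode
#' is indistinguishable from noise. Computed once on the non-corrected
#' calls (full-length barcodes only) and once on the combination of
#' corrected and non-corrected calls.
#'
#' @param transcripts decoded transcript table (needs `target` and
#'   `rounds_used`).
#' @param cb the [codebook] used for decoding; at least 2 off-target
#'   entries required.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a list with `threshold_nc`, `threshold_nc_ec`, the per-target
#'   tallies for both scopes, and per-target above/below classification.
#' @export
offtarget_count_threshold <- function(transcripts, cb,
                                      sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (sum(cb$is_off_target) < 2L)
    stop("need at least 2 off-target codebook entries")
  n_rounds <- cb$n_rounds
  tally <- function(tx) {
    tb <- table(factor(tx$target, levels = cb$targets))
    as.numeric(tb)
  }
  counts_nc <- tally(transcripts[transcripts$rounds_used == n_rounds, ,
                                 drop = FALSE])
  counts_all <- tally(transcripts)
  thr <- function(counts) {
    off <- counts[cb$is_off_target]
    s <- if (sd_type == "sample") stats::sd(off) else
      sqrt(pop_var(off))
    mean(off) + Z95 * s
  }
  t_nc <- thr(counts_nc); t_all <- thr(counts_all)
  list(threshold_nc = t_nc, threshold_nc_ec = t_all,
       counts_nc = setNames(counts_nc, cb$targets),
       counts_nc_ec = setNames(counts_all, cb$targets),
       above_cutoff_nc = setNames(counts_nc > t_nc, cb$targets),
       above_cutoff_nc_ec = setNames(counts_all > t_all, cb$targets))
}

#' Off-target threshold from a raw count vector
#'
#' The bare confidence-interval computation: `mean + 1.959964 * sd` of the
#' supplied off-target counts.
#'
#' @param counts numeric vector of off-target call counts (length >= 2).
#' @param sd_type `"sample"` or `"population"` standard deviation.
#' @export
offtarget_threshold_from_counts <- function(counts,
                                            sd_type = c("sample",
                                                        "population")) {
  sd_type <- match.arg(sd_type)
  if (length(counts) < 2L) stop("need at least 2 off-target counts")
  s <- if (sd_type == "sample") stats::sd(counts) else sqrt(pop_var(counts))
  mean(counts) + Z95 * s
}

#' Per-cell false-positive rate
#'
#' For each cell, `FPR = off_targets / (off_targets + on_targets)` over the
#' decoded calls assigned to it. Calls without a cell assignment are
#' excluded; cells appear only if they have at least one decoded call.
#'
#' @param transcripts decoded transcript table with `cell_id` and
#'   `is_off_target`.
#' @return a list with `per_cell` (data.frame cell_id, n_off, n_on, fpr)
#'   and `mean_fpr`, `median_fpr`.
#' @export
false_positive_rate_per_cell <- function(transcripts) {
  tx <- transcripts[!is.na(transcripts$cell_id), , drop = FALSE]
  if (nrow(tx) == 0L) stop("no cell assignments present")
  off <- tapply(tx$is_off_target, tx$cell_id, sum)
  tot <- tapply(tx$is_off_target, tx$cell_id, length)
  per <- data.frame(cell_id = as.integer(names(off)),
                    n_off = as.integer(off),
                    n_on = as.integer(tot - off),
                    fpr = as.numeric(off / tot))
  list(per_cell = per[order(per$cell_id), ],
       mean_fpr = mean(per$fpr), median_fpr = stats::median(per$fpr))
}

tally_stats <- function(counts) {
  list(counts = counts, std = stats::sd(counts),
       skew = sample_skewness(counts))
}

#' Spot tallies per round / per channel
#'
#' The number of spots in each round (channel) with the standard deviation
#' and adjusted sample skewness of the tally vector. A trend across rounds
#' suggests degradation between hybridizations; an outlying channel
#' suggests fluorophore or normalization problems.
#'
#' @param spots a spot table.
#' @param n_rounds,n_channels number of rounds/channels (so empty levels
#'   tally as zero); defaults to `max + 1` over the table.
#' @return a list with `counts` (named vector), `std`, `skew`.
#' @name tally-stats
#' @export
spots_per_round_stats <- function(spots, n_rounds = NULL) {
  spots <- as_spot_table(spots)
  if (nrow(spots) == 0L) stop("empty spot table")
  if (is.null(n_rounds)) n_rounds <- max(spots$r) + 1L
  tb <- table(factor(spots$r, levels = 0:(n_rounds - 1L)))
  tally_stats(setNames(as.numeric(tb), names(tb)))
}

#' @rdname tally-stats
#' @export
spots_per_channel_stats <- function(spots, n_channels = NULL) {
  spots <- as_spot_table(spots)
  if (nrow(spots) == 0L) stop("empty spot table")
  if (is.null(n_channels)) n_channels <- max(spots$c) + 1L
  tb <- table(factor(spots$c, levels = 0:(n_channels - 1L)))
  tally_stats(setNames(as.numeric(tb), names(tb)))
}

resolve_source_spots <- function(transcripts, spots) {
  ids <- unlist(split_spot_ids(transcripts$source_spot_ids))
  pos <- match(ids, spots$spot_id)
  if (anyNA(pos))
    stop("dangling source spot ids: ",
         paste(utils::head(ids[is.na(pos)], 5L), collapse = ", "))
  pos
}

#' Tallies of the spots used to decode transcripts
#'
#' Resolves each decoded transcript's member spots and tallies the rounds
#' (channels) they came from, with the same moment statistics as the raw
#' spot tallies. A deficit in one round relative to the raw spot tallies
#' points at rounds consistently omitted by error correction.
#'
#' @param transcripts decoded transcript table.
#' @param spots the spot table decoding ran on.
#' @param n_rounds,n_channels level counts, as in [spots_per_round_stats()].
#' @name source-tally-stats
#' @export
source_spot_round_stats <- function(transcripts, spots, n_rounds = NULL) {
  spots <- as_spot_table(spots)
  pos <- resolve_source_spots(transcripts, spots)
  if (is.null(n_rounds)) n_rounds <- max(spots$r) + 1L
  tb <- table(factor(spots$r[pos], levels = 0:(n_rounds - 1L)))
  tally_stats(setNames(as.numeric(tb), names(tb)))
}

#' @rdname source-tally-stats
#' @export
source_spot_channel_stats <- function(transcripts, spots,
                                      n_channels = NULL) {
  spots <- as_spot_table(spots)
  pos <- resolve_source_spots(transcripts, spots)
  if (is.null(n_channels)) n_channels <- max(spots$c) + 1L
  tb <- table(factor(spots$c[pos], levels = 0:(n_channels - 1L)))
  tally_stats(setNames(as.numeric(tb), names(tb)))
}

#' Low-count cell cutoff from transcripts per cell
#'
#' Tallies decoded transcripts per cell and suggests removing cells with a
#' count below `median - 1.5 * (Q3 - Q1)` (linear-interpolation
#' quantiles).
#'
#' @param transcripts decoded transcript table with `cell_id`.
#' @return a list with `per_cell` counts, `cutoff`, and `flagged` cell
#'   ids (count strictly below the cutoff).
#' @export
transcripts_per_cell_cutoff <- function(transcripts) {
  tx <- transcripts[!is.na(transcripts$cell_id), , drop = FALSE]
  if (nrow(tx) == 0L) stop("no cell assignments present")
  counts <- tapply(tx$cell_id, tx$cell_id, length)
  counts <- setNames(as.numeric(counts), names(counts))
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cutoff <- q[2] - 1.5 * (q[3] - q[1])
  list(per_cell = counts, cutoff = cutoff,
       flagged = as.integer(names(counts)[counts < cutoff]))
}

#' Ripley's K function (raw estimator)
#'
#' `K(r) = area * n_pairs(d <= r) / (n * (n - 1))` over ordered pairs, with
#' no edge correction -- matching the plain estimator evaluated on the
#' image window.
#'
#' @param x,y point coordinates.
#' @param radii radii at which to evaluate.
#' @param area window area.
#' @return numeric vector of K values, one per radius.
#' @export
ripley_k <- function(x, y, radii, area) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 points")
  d <- stats::dist(cbind(x, y))
  vapply(radii, function(r) area * 2 * sum(d <= r) / (n * (n - 1)),
         numeric(1))
}

#' Monte-Carlo test of complete spatial randomness via Ripley's K
#'
#' Evaluates K for the observed 2D pattern at `n_radii` radii spanning 0 to
#' `sqrt(area) / 2`, and builds a pointwise 95% (or `1 - alpha`) envelope
#' from uniform-random patterns with the same number of points in the same
#' window. Clustered data exceed the upper envelope at small radii.
#'
#' @param x,y observed point coordinates (>= 10 points).
#' @param fov_dims `c(width, height)` of the field of view.
#' @param n_radii number of radii (default 10).
#' @param n_mc number of Monte-Carlo simulations (default 100).
#' @param alpha envelope tail mass (default 0.05, i.e. 2.5/97.5
#'   percentiles).
#' @param seed integer seed for the simulations.
#' @return data.frame with columns `radius, k_obs, k_lo, k_hi, outside,
#'   above`.
#' @export
ripley_k_csr_test <- function(x, y, fov_dims, n_radii = 10L, n_mc = 100L,
                              alpha = 0.05, seed) {
  if (length(x) < 10L) stop("need at least 10 points")
  if (any(fov_dims <= 0)) stop("fov_dims must be positive")
  local_rng(seed)
  area <- fov_dims[1] * fov_dims[2]
  radii <- seq(0, sqrt(area) / 2, length.out = n_radii)
  k_obs <- ripley_k(x, y, radii, area)
  n <- length(x)
  sims <- matrix(0, n_mc, n_radii)
  for (i in seq_len(n_mc)) {
    sims[i, ] <- ripley_k(runif(n, 0, fov_dims[1]),
                          runif(n, 0, fov_dims[2]), radii, area)
  }
  lo <- apply(sims, 2L, quantile, probs = alpha / 2, names = FALSE)
  hi <- apply(sims, 2L, quantile, probs = 1 - alpha / 2, names = FALSE)
  data.frame(radius = radii, k_obs = k_obs, k_lo = lo, k_hi = hi,
             outside = k_obs < lo | k_obs > hi, above = k_obs > hi)
}

#' Spots per codebook entry
#'
#' Total spot count divided by codebook length; a crude sanity check of
#' detection density against barcode capacity.
#'
#' @param spots a spot table.
#' @param cb a [codebook].
#' @export
spots_per_barcode <- function(spots, cb) {
  if (length(cb) == 0L) stop("empty codebook")
  nrow(as_spot_table(spots)) / length(cb)
}

#' Fraction of detected spots used in decoded transcripts
#'
#' `|union of source spot ids| / n_spots`. Low values indicate many
#' detected spots never assembled into a barcode.
#'
#' @param transcripts decoded transcript table.
#' @param spots the spot table decoding ran on.
#' @export
fraction_spots_used <- function(transcripts, spots) {
  spots <- as_spot_table(spots)
  if (nrow(spots) == 0L) return(0)
  if (nrow(transcripts) == 0L) return(0)
  used <- unique(unlist(split_spot_ids(transcripts$source_spot_ids)))
  length(used) / nrow(spots)
}

#' Compute the full QC metric suite for one field of view
#'
#' Aggregates every metric into one structured report. When the spot table
#' carries a `cell_id` column, spots with no cell assignment are filtered
#' out before the spot-based tallies, matching the convention that QC runs
#' on segmented spots. Cell-scoped metrics (per-cell FPR, transcripts per
#' cell) are skipped with a note when no cell assignments exist; the
#' off-target threshold is skipped when the codebook has fewer than two
#' blank entries.
#'
#' @param spots spot table for the FOV.
#' @param transcripts decoded transcript table for the FOV.
#' @param cb the [codebook].
#' @param fov_dims `c(width, height)`.
#' @param seed seed for the Ripley Monte-Carlo envelope.
#' @param ripley_n_mc,ripley_n_radii,alpha Ripley test settings.
#' @return a list of class `qc_report`.
#' @export
compute_qc <- function(spots, transcripts, cb, fov_dims, seed = 1L,
                       ripley_n_mc = 100L, ripley_n_radii = 10L,
                       alpha = 0.05) {
  spots <- as_spot_table(spots)
  spot_scope <- spots
  if (!is.null(spots$cell_id))
    spot_scope <- spots[!is.na(spots$cell_id), , drop = FALSE]
  if (nrow(spot_scope) == 0L) spot_scope <- spots
  rep <- list()
  rep$n_spots <- nrow(spots)
  rep$n_transcripts <- nrow(transcripts)
  rep$barcode_tallies <- list(
    noncorrected_on = sum(transcripts$rounds_used == cb$n_rounds &
                            !transcripts$is_off_target),
    noncorrected_off = sum(transcripts$rounds_used == cb$n_rounds &
                             transcripts$is_off_target),
    corrected_on = sum(transcripts$rounds_used < cb$n_rounds &
                         !transcripts$is_off_target),
    corrected_off = sum(transcripts$rounds_used < cb$n_rounds &
                          transcripts$is_off_target))
  rep$offtarget_threshold <- if (sum(cb$is_off_target) >= 2L)
    offtarget_count_threshold(transcripts, cb) else
      "skipped: fewer than 2 off-target codebook entries"
  has_cells <- !is.null(transcripts$cell_id) &&
    any(!is.na(transcripts$cell_id))
  rep$fpr_per_cell <- if (has_cells)
    false_positive_rate_per_cell(transcripts) else
      "skipped: no cell assignments"
  rep$spots_per_round <- spots_per_round_stats(spot_scope, cb$n_rounds)
  rep$spots_per_channel <- spots_per_channel_stats(spot_scope,
                                                   cb$n_channels)
  if (nrow(transcripts) > 0L) {
    rep$source_spots_per_round <-
      source_spot_round_stats(transcripts, spots, cb$n_rounds)
    rep$source_spots_per_channel <-
      source_spot_channel_stats(transcripts, spots, cb$n_channels)
  } else {
    rep$source_spots_per_round <- rep$source_spots_per_channel <-
      "skipped: no decoded transcripts"
  }
  rep$transcripts_per_cell <- if (has_cells)
    transcripts_per_cell_cutoff(transcripts) else
      "skipped: no cell assignments"
  rep$ripley <- if (nrow(transcripts) >= 10L)
    ripley_k_csr_test(transcripts$x, transcripts$y, fov_dims,
                      n_radii = ripley_n_radii, n_mc = ripley_n_mc,
                      alpha = alpha, seed = seed) else
      "skipped: fewer than 10 transcripts"
  rep$spots_per_barcode <- spots_per_barcode(spots, cb)
  rep$fraction_spots_used <- fraction_spots_used(transcripts, spots)
  class(rep) <- "qc_report"
  rep
}

#' Serialize / read a QC report
#'
#' Human-readable YAML; data.frame sections round-trip as column lists.
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @name qc-io
#' @export
write_qc_report <- function(report, path) {
  ser <- rapply(unclass(report), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, classes = "data.frame", how = "replace")
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname qc-io
#' @export
read_qc_report <- function(path) {
  obj <- yaml::read_yaml(path)
  class(obj) <- "qc_report"
  obj
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_spots, "spots,", x$n_transcripts, "transcripts\n")
  cat("  fraction of spots used:", format(x$fraction_spots_used), "\n")
  cat("  spots per barcode:", format(x$spots_per_barcode), "\n")
  invisible(x)
}

#' Plot QC summaries to a multi-page PDF
#'
#' One page each for barcode tallies with the off-target threshold,
#' per-round/channel spot tallies, transcripts per cell with the low-count
#' cutoff, and the Ripley K curve with its CSR envelope. Sections that
#' were skipped in the report are skipped here too.
#'
#' @param report a `qc_report` (from [compute_qc()], not a deserialized
#'   one).
#' @param path output PDF path.
#' @export
plot_qc_report <- function(report, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  ot <- report$offtarget_threshold
  if (is.list(ot)) {
    cn <- sort(ot$counts_nc_ec, decreasing = TRUE)
    graphics::barplot(cn, las = 2, cex.names = 0.5,
                      main = "calls per target (NC+EC)")
    graphics::abline(h = ot$threshold_nc_ec, col = "red", lty = 2)
  }
  sr <- report$spots_per_round
  if (is.list(sr))
    graphics::barplot(sr$counts, main = "spots per round", xlab = "round")
  sc <- report$spots_per_channel
  if (is.list(sc))
    graphics::barplot(sc$counts, main = "spots per channel",
                      xlab = "channel")
  tc <- report$transcripts_per_cell
  if (is.list(tc)) {
    graphics::hist(tc$per_cell, main = "transcripts per cell",
                   xlab = "count", breaks = 20)
    graphics::abline(v = tc$cutoff, col = "red", lty = 2)
  }
  rk <- report$ripley
  if (is.data.frame(rk)) {
    graphics::plot(rk$radius, rk$k_obs, type = "l",
                   ylim = range(rk[, c("k_obs", "k_lo", "k_hi")]),
                   xlab = "radius", ylab = "K(r)",
                   main = "Ripley's K vs CSR envelope")
    graphics::lines(rk$radius, rk$k_lo, lty = 2)
    graphics::lines(rk$radius, rk$k_hi, lty = 2)
  }
  invisible(path)
}
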