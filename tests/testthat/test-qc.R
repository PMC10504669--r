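test_that("off-target threshold is mean + 1.959964 sd of blank counts", {
  expect_equal(offtarget_threshold_from_counts(c(0, 0, 0)), 0)
  # frozen: 10 + 1.959964 * sd(c(8, 10, 10, 12))
  expect_equal(offtarget_threshold_from_counts(c(8, 10, 10, 12)),
               13.2006078095, tolerance = 1e-9)
  expect_error(offtarget_threshold_from_counts(5), "at least 2")
})

test_that("offtarget_count_threshold tallies NC and NC+EC scopes", {
  cb <- codebook(c("g1", "g2", "b1", "b2"),
                 rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
                 is_off_target = c(FALSE, FALSE, TRUE, TRUE))
  tx <- data.frame(
    target = c("g1", "g1", "g1", "g2", "b1", "b1", "b2"),
    rounds_used = c(2, 2, 1, 2, 2, 1, 2),
    is_off_target = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  res <- offtarget_count_threshold(tx, cb)
  expect_equal(unname(res$counts_nc[c("b1", "b2")]), c(1, 1))
  expect_equal(unname(res$counts_nc_ec[c("b1", "b2")]), c(2, 1))
  expect_equal(res$threshold_nc, 1)  # sd = 0
  expect_equal(res$threshold_nc_ec, 1.5 + 1.959964 * sd(c(2, 1)))
  expect_true(res$above_cutoff_nc[["g1"]])   # 2 > 1
  expect_false(res$above_cutoff_nc[["g2"]])  # 1 below-or-equal
  cb_no_blanks <- codebook(c("g1", "g2"), rbind(c(0, 0), c(1, 1)))
  expect_error(offtarget_count_threshold(tx, cb_no_blanks), "at least 2")
})

test_that("per-cell FPR matches the definitional tallies", {
  tx <- data.frame(cell_id = c(rep(1, 10), rep(2, 4)),
                   is_off_target = c(rep(TRUE, 2), rep(FALSE, 8),
                                     rep(FALSE, 4)))
  res <- false_positive_rate_per_cell(tx)
  expect_equal(res$per_cell$fpr, c(0.2, 0))
  expect_error(false_positive_rate_per_cell(
    data.frame(cell_id = NA, is_off_target = FALSE)), "no cell")
  # recount oracle on randomized tables
  for (s in 1:10) {
    tx <- random_transcripts(80, c("a", "b", "blankA"),
                             c(FALSE, FALSE, TRUE), seed = s)
    res <- false_positive_rate_per_cell(tx)
    for (k in seq_len(nrow(res$per_cell))) {
      cid <- res$per_cell$cell_id[k]
      sub <- tx[tx$cell_id == cid, ]
      expect_equal(res$per_cell$fpr[k],
                   sum(sub$is_off_target) / nrow(sub))
    }
    expect_true(all(res$per_cell$fpr >= 0 & res$per_cell$fpr <= 1))
  }
})

test_that("per-round/channel tallies and moments behave", {
  df <- as_spot_table(data.frame(
    spot_id = 1:60, r = rep(0:2, each = 20), c = rep(0:3, 15),
    x = 0, y = 0, z = 0, intensity = 1))
  res <- spots_per_round_stats(df)
  expect_equal(unname(res$counts), c(20, 20, 20))
  expect_equal(res$std, 0)
  expect_equal(res$skew, 0)
  # counts (10, 10, 40): frozen moments (sd = sqrt(300), skew = sqrt(3))
  df2 <- as_spot_table(data.frame(
    spot_id = 1:60, r = rep(0:2, c(10, 10, 40)), c = 0,
    x = 0, y = 0, z = 0, intensity = 1))
  res2 <- spots_per_round_stats(df2)
  expect_equal(res2$std, sqrt(300))
  expect_equal(res2$skew, sqrt(3), tolerance = 1e-12)
  # permuting labels permutes tallies but preserves the moments
  df3 <- df2; df3$r <- c(2L, 0L, 1L)[df3$r + 1L]
  res3 <- spots_per_round_stats(df3)
  expect_equal(sort(res3$counts), sort(res2$counts), ignore_attr = TRUE)
  expect_equal(res3$std, res2$std)
  expect_equal(res3$skew, res2$skew)
  expect_error(spots_per_round_stats(df[0, ]), "empty")
  res4 <- spots_per_channel_stats(df)
  expect_equal(unname(res4$counts), rep(15, 4))
})

test_that("source-spot tallies resolve member spots of transcripts", {
  cb <- generate_codebook(10, 4, 4, min_hamming = 2, seed = 5)
  sim <- simulate_spots(cb, 40, seed = 6)
  tx <- decode(sim$spots, cb, decode_config(1))
  res <- source_spot_round_stats(tx, sim$spots)
  # all transcripts full length -> tally = n_transcripts in every round
  expect_equal(unname(res$counts), rep(nrow(tx), 4))
  # dangling ids error
  bad <- tx; bad$source_spot_ids[1] <- "999999;1;2;3"
  expect_error(source_spot_round_stats(bad, sim$spots), "dangling")
  # channel tallies match a naive recount
  resc <- source_spot_channel_stats(tx, sim$spots)
  ids <- unlist(lapply(strsplit(tx$source_spot_ids, ";"), as.integer))
  want <- table(factor(sim$spots$c[match(ids, sim$spots$spot_id)],
                       levels = 0:3))
  expect_equal(unname(resc$counts), as.numeric(want))
})

test_that("transcripts-per-cell cutoff follows median - 1.5 IQR", {
  # per-cell counts 3x100: IQR 0 -> cutoff = median, nothing flagged
  tx <- data.frame(cell_id = rep(1:3, each = 100))
  res <- transcripts_per_cell_cutoff(tx)
  expect_equal(res$cutoff, 100)
  expect_length(res$flagged, 0)
  # quantile oracle on random counts
  for (s in 1:10) {
    set.seed(s)
    counts <- rpois(30, 50)
    tx <- data.frame(cell_id = rep(seq_along(counts), counts))
    res <- transcripts_per_cell_cutoff(tx)
    q <- quantile(counts[counts > 0], c(0.25, 0.5, 0.75), type = 7)
    cut <- unname(q[2] - 1.5 * (q[3] - q[1]))
    expect_equal(res$cutoff, cut)
    expect_setequal(res$flagged, which(counts > 0)[
      counts[counts > 0] < cut])
  }
})

test_that("ripley K basics: zero at r = 0, CSR inside, clusters above", {
  set.seed(9)
  expect_equal(ripley_k(runif(50), runif(50), 0, 1)[1], 0)
  # uniform pattern stays inside the envelope at most radii
  res <- ripley_k_csr_test(runif(80, 0, 50), runif(80, 0, 50),
                           c(50, 50), seed = 10)
  expect_equal(nrow(res), 10)
  expect_gte(sum(!res$outside), 8)
  # tight Gaussian clusters exceed the upper envelope at small radii
  cx <- rep(runif(4, 10, 40), each = 20)
  cy <- rep(runif(4, 10, 40), each = 20)
  resc <- ripley_k_csr_test(cx + rnorm(80, 0, 0.8),
                            cy + rnorm(80, 0, 0.8),
                            c(50, 50), seed = 11)
  expect_true(any(resc$above[2:4]))
  expect_error(ripley_k_csr_test(1:5, 1:5, c(10, 10), seed = 1),
               "at least 10")
})

test_that("spots_per_barcode and fraction_spots_used match recounts", {
  cb <- generate_codebook(10, 4, 4, seed = 12)
  sim <- simulate_spots(cb, 25, seed = 13)
  expect_equal(spots_per_barcode(sim$spots, cb), nrow(sim$spots) / 10)
  tx <- decode(sim$spots, cb, decode_config(1))
  fr <- fraction_spots_used(tx, sim$spots)
  ids <- unique(unlist(strsplit(tx$source_spot_ids, ";")))
  expect_equal(fr, length(ids) / nrow(sim$spots))
  expect_gte(fr, 0); expect_lte(fr, 1)
  expect_equal(fraction_spots_used(tx[0, ], sim$spots), 0)
})

test_that("compute_qc aggregates all metric families and round-trips", {
  cb <- generate_codebook(15, 4, 4, min_hamming = 2, seed = 14)
  cb <- insert_off_target_barcodes(cb, 3, min_distance = 2, seed = 15)
  sim <- simulate_spots(cb, 120, drift_sigma = 0.5, dropout_rate = 0.05,
                        noise_rate = 0.002, cell_grid = 4, seed = 16)
  tx <- decode(sim$spots, cb, decode_config(2, error_rounds = 1))
  rep <- compute_qc(sim$spots, tx, cb, c(100, 100), seed = 17)
  fams <- c("barcode_tallies", "offtarget_threshold", "fpr_per_cell",
            "spots_per_round", "spots_per_channel",
            "source_spots_per_round", "source_spots_per_channel",
            "transcripts_per_cell", "ripley", "spots_per_barcode",
            "fraction_spots_used")
  expect_true(all(fams %in% names(rep)))
  tallies <- unlist(rep$barcode_tallies)
  expect_equal(sum(tallies), nrow(tx))
  p <- withr::local_tempfile(fileext = ".yml")
  write_qc_report(rep, p)
  back <- read_qc_report(p)
  expect_s3_class(back, "qc_report")
  expect_equal(back$fraction_spots_used, rep$fraction_spots_used,
               tolerance = 1e-12)
  expect_equal(back$spots_per_barcode, rep$spots_per_barcode,
               tolerance = 1e-12)
  expect_equal(unlist(back$barcode_tallies), tallies)
})
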