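#' Construct a codebook
#'
#' A codebook maps target (gene) names to barcodes: for each imaging round,
#' the fluorescence channel in which the target emits a spot. Barcodes have
#' no "off" rounds -- every round carries a channel assignment. Channel and
#' round indices are 0-based throughout the package, matching the SpaceTx
#' JSON convention.
#'
#' @param targets character vector of unique target names.
#' @param barcodes integer matrix, one row per target, one column per round;
#'   entries are 0-based channel indices in `[0, n_channels)`.
#' @param n_channels number of channels in the experiment. Defaults to
#'   `max(barcodes) + 1`.
#' @param is_off_target logical vector flagging entries with no real probe
#'   (blank/off-target barcodes); any call to such a target is a false
#'   positive by construction. Defaults to all `FALSE`.
#' @return an object of class `codebook`: a list with elements `targets`,
#'   `barcodes`, `is_off_target`, `n_rounds`, `n_channels`.
#' @export
codebook <- function(targets, barcodes, n_channels = NULL,
                     is_off_target = NULL) {
  if (is.vector(barcodes)) barcodes <- matrix(barcodes, nrow = 1L)
  barcodes <- as.matrix(barcodes)
  storage.mode(barcodes) <- "integer"
  dimnames(barcodes) <- NULL
  targets <- as.character(targets)
  if (length(targets) != nrow(barcodes))
    stop("length(targets) must equal nrow(barcodes)")
  if (anyNA(barcodes)) stop("barcodes may not contain NA (no off rounds)")
  if (any(barcodes < 0L)) stop("channel indices must be >= 0")
  if (is.null(n_channels)) n_channels <- max(barcodes) + 1L
  n_channels <- as.integer(n_channels)
  if (any(barcodes >= n_channels))
    stop("channel index out of range [0, n_channels)")
  if (anyDuplicated(targets)) stop("target names must be unique")
  keys <- apply(barcodes, 1L, paste, collapse = ",")
  if (anyDuplicated(keys)) stop("barcodes must be unique across entries")
  if (is.null(is_off_target)) is_off_target <- rep(FALSE, length(targets))
  if (length(is_off_target) != length(targets))
    stop("is_off_target must have one flag per target")
  structure(
    list(targets = targets, barcodes = barcodes,
         is_off_target = as.logical(is_off_target),
         n_rounds = ncol(barcodes), n_channels = n_channels),
    class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d targets (%d off-target), %d rounds x %d channels\n",
              length(x$targets), sum(x$is_off_target),
              x$n_rounds, x$n_channels))
  invisible(x)
}

#' @export
length.codebook <- function(x) length(x$targets)

barcode_keys <- function(cb) apply(cb$barcodes, 1L, paste, collapse = ",")

#' Hamming distance between two barcodes
#'
#' The number of rounds at which two channel sequences differ.
#'
#' @param a,b integer vectors of equal length (per-round channel indices).
#' @return non-negative integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("barcodes must have equal length")
  sum(a != b)
}

#' Minimum pairwise Hamming distance of a codebook
#'
#' Single-round error correction requires every pair of codes to differ in
#' at least 2 rounds; this gate is checked with the minimum over all
#' unordered pairs.
#'
#' @param cb a [codebook].
#' @return the minimum Hamming distance over all unordered pairs of entries.
#' @export
min_pairwise_hamming <- function(cb) {
  bc <- cb$barcodes
  n <- nrow(bc)
  if (n < 2L) stop("need at least 2 codebook entries")
  best <- ncol(bc)
  for (i in seq_len(n - 1L)) {
    # vectorized row-vs-rows mismatch count
    d <- rowSums(bc[(i + 1L):n, , drop = FALSE] !=
                   matrix(bc[i, ], n - i, ncol(bc), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

#' Insert off-target (blank) barcodes into a codebook
#'
#' Samples unused barcodes uniformly at random (with rejection) and appends
#' them flagged `is_off_target = TRUE`. Every inserted code is at Hamming
#' distance >= `min_distance` from every existing code and from every other
#' inserted code, so calls to them estimate the decoder's false-positive
#' behaviour.
#'
#' @param cb a [codebook].
#' @param count number of off-target codes to insert.
#' @param min_distance minimum Hamming distance to all other codes.
#' @param seed integer seed; insertion is deterministic given the seed.
#' @param prefix name prefix for inserted targets.
#' @param max_tries rejection-sampling attempt cap before an exhaustive
#'   enumeration fallback decides feasibility.
#' @return a new [codebook] with `count` additional off-target entries.
#' @export
insert_off_target_barcodes <- function(cb, count, min_distance = 1L,
                                       seed, prefix = "blank",
                                       max_tries = 10000L) {
  count <- as.integer(count)
  if (count < 0L) stop("count must be >= 0")
  if (count == 0L) return(cb)
  if (missing(seed)) stop("seed is required")
  rng <- local_rng(seed)
  existing <- cb$barcodes
  added <- matrix(integer(0), 0L, cb$n_rounds)
  tries <- 0L
  while (nrow(added) < count && tries < max_tries) {
    tries <- tries + 1L
    cand <- sample.int(cb$n_channels, cb$n_rounds, replace = TRUE) - 1L
    pool <- rbind(existing, added)
    d <- rowSums(pool != matrix(cand, nrow(pool), cb$n_rounds, byrow = TRUE))
    if (all(d >= min_distance)) added <- rbind(added, cand)
  }
  if (nrow(added) < count) {
    achievable <- count_feasible_codes(rbind(existing, added), cb$n_rounds,
                                       cb$n_channels, min_distance)
    stop(sprintf(paste0("could not insert %d off-target codes at min ",
                        "Hamming distance %d; at most %d more are feasible"),
                 count, min_distance, nrow(added) + achievable))
  }
  codebook(c(cb$targets, sprintf("%s_%03d", prefix, seq_len(count))),
           rbind(cb$barcodes, added), n_channels = cb$n_channels,
           is_off_target = c(cb$is_off_target, rep(TRUE, count)))
}

# Exhaustive count of remaining codes at >= min_distance from `pool`
# (greedy, used only for error messages; feasible when barcode space small).
count_feasible_codes <- function(pool, n_rounds, n_channels, min_distance) {
  total <- n_channels^n_rounds
  if (total > 2e5) return(NA_integer_)
  all_codes <- as.matrix(expand.grid(rep(list(0:(n_channels - 1L)), n_rounds)))
  kept <- 0L
  for (i in seq_len(nrow(all_codes))) {
    d <- rowSums(pool != matrix(all_codes[i, ], nrow(pool), n_rounds,
                                byrow = TRUE))
    if (all(d >= min_distance)) {
      pool <- rbind(pool, all_codes[i, ])
      kept <- kept + 1L
    }
  }
  kept
}

#' Read / write codebooks
#'
#' Two dialects are supported. The SpaceTx-style JSON carries a version
#' string and, per target, a list of `{r, c, v}` entries (round, channel,
#' value); a target is off-target when its name is listed under
#' `off_target_names` or carries a `"blank"` prefix. The TSV dialect has
#' columns `target`, `barcode` (comma-separated channel sequence) and
#' `off_target` (0/1).
#'
#' @param path file path.
#' @param cb a [codebook].
#' @return `read_codebook_*` return a [codebook]; writers return `path`
#'   invisibly.
#' @name codebook-io
NULL

#' @rdname codebook-io
#' @export
write_codebook_json <- function(cb, path) {
  mappings <- lapply(seq_along(cb$targets), function(i) {
    list(codeword = lapply(seq_len(cb$n_rounds), function(r)
      list(r = r - 1L, c = cb$barcodes[i, r], v = 1)),
      target = cb$targets[i])
  })
  obj <- list(version = "0.0.0",
              n_rounds = cb$n_rounds, n_channels = cb$n_channels,
              off_target_names = cb$targets[cb$is_off_target],
              mappings = mappings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname codebook-io
#' @export
read_codebook_json <- function(path) {
  obj <- jsonlite::read_json(path)
  n_rounds <- if (!is.null(obj$n_rounds)) as.integer(obj$n_rounds) else
    length(obj$mappings[[1]]$codeword)
  targets <- vapply(obj$mappings, function(m) m$target, character(1))
  barcodes <- t(vapply(obj$mappings, function(m) {
    bc <- rep(NA_integer_, n_rounds)
    for (e in m$codeword) bc[as.integer(e$r) + 1L] <- as.integer(e$c)
    bc
  }, integer(n_rounds)))
  off_names <- unlist(obj$off_target_names)
  off <- targets %in% off_names | startsWith(targets, "blank")
  n_channels <- if (!is.null(obj$n_channels)) as.integer(obj$n_channels)
  codebook(targets, barcodes, n_channels = n_channels, is_off_target = off)
}

#' @rdname codebook-io
#' @export
write_codebook_tsv <- function(cb, path) {
  df <- data.frame(target = cb$targets,
                   barcode = barcode_keys(cb),
                   off_target = as.integer(cb$is_off_target))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname codebook-io
#' @export
read_codebook_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  barcodes <- t(vapply(strsplit(df$barcode, ","),
                       function(v) as.integer(v),
                       integer(length(strsplit(df$barcode[1], ",")[[1]]))))
  codebook(df$target, barcodes, is_off_target = df$off_target == 1L)
}
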