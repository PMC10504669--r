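#' Validate / construct a spot table
#'
#' A spot table holds one record per detected fluorescent spot: a unique
#' integer `spot_id`, the hybridization round `r` and channel `c` (0-based),
#' continuous coordinates `x`, `y`, `z` in physical length units (origin at
#' the field-of-view corner; `z` is 0 for 2D experiments), and `intensity`.
#' An optional `cell_id` column carries segmentation assignments (NA =
#' unassigned).
#'
#' @param df a data.frame with columns `spot_id`, `r`, `c`, `x`, `y`, `z`,
#'   `intensity` (`z` optional, defaults to 0).
#' @return the validated data.frame (ordered by `spot_id`).
#' @export
as_spot_table <- function(df) {
  need <- c("spot_id", "r", "c", "x", "y", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spot table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$z)) df$z <- 0
  df$spot_id <- as.integer(df$spot_id)
  df$r <- as.integer(df$r); df$c <- as.integer(df$c)
  if (anyDuplicated(df$spot_id)) stop("spot_id must be unique")
  if (any(df$r < 0L) || any(df$c < 0L)) stop("r and c must be >= 0")
  coords <- c(df$x, df$y, df$z)
  if (!all(is.finite(coords))) stop("spot coordinates must be finite")
  df[order(df$spot_id), , drop = FALSE]
}

#' Normalize spot intensities per (round, channel)
#'
#' Divides each spot's intensity by the maximum intensity observed in its
#' (round, channel) group and clamps to `[0, 1]`. This bounds the summed
#' intensity of any full barcode by the number of rounds, as the decoder's
#' quality score requires.
#'
#' @param spots a spot table.
#' @return the spot table with `intensity` replaced by normalized values.
#' @export
normalize_intensities <- function(spots) {
  spots <- as_spot_table(spots)
  grp <- interaction(spots$r, spots$c, drop = TRUE)
  mx <- stats::ave(spots$intensity, grp, FUN = max)
  spots$intensity <- pmin(pmax(ifelse(mx > 0, spots$intensity / mx, 0), 0), 1)
  spots
}

#' Read / write spot tables
#'
#' Delimited text with header columns `spot_id, r, c, x, y, z, intensity`
#' (plus `cell_id` when present).
#'
#' @param path file path.
#' @param spots a spot table.
#' @name spots-io
NULL

#' @rdname spots-io
#' @export
read_spots <- function(path) {
  as_spot_table(utils::read.csv(path))
}

#' @rdname spots-io
#' @export
write_spots <- function(spots, path) {
  utils::write.csv(as_spot_table(spots), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct a pseudoround/pseudochannel map
#'
#' Experiments that pack barcodes into "pseudocolors" index each physical
#' (round, channel) pair by a logical (pseudoround, pseudochannel) pair.
#' The map must be injective and cover every physical pair used.
#'
#' @param r,c physical round and channel indices (0-based, recycled
#'   together).
#' @param pr,pc pseudoround and pseudochannel indices.
#' @return a data.frame of class `pseudomap`.
#' @export
pseudomap <- function(r, c, pr, pc) {
  df <- data.frame(r = as.integer(r), c = as.integer(c),
                   pr = as.integer(pr), pc = as.integer(pc))
  if (anyDuplicated(df[, c("r", "c")]))
    stop("duplicate physical (round, channel) pair in map")
  if (anyDuplicated(df[, c("pr", "pc")]))
    stop("pseudomap must be injective: duplicate (pr, pc) target")
  class(df) <- c("pseudomap", "data.frame")
  df
}

#' Relabel spots with pseudoround/pseudochannel indices
#'
#' Spot ids, coordinates and intensities are unchanged; only the `r` and
#' `c` labels are rewritten through the map.
#'
#' @param spots a spot table.
#' @param map a [pseudomap].
#' @return the relabeled spot table.
#' @export
apply_pseudomap <- function(spots, map) {
  spots <- as_spot_table(spots)
  key <- paste(spots$r, spots$c)
  mkey <- paste(map$r, map$c)
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("unmapped (round, channel) pairs: ", paste(bad, collapse = "; "))
  }
  spots$r <- map$pr[idx]
  spots$c <- map$pc[idx]
  spots
}

#' Read / write decoded transcript tables
#'
#' Delimited text with header columns `target, x, y, z, rounds_used,
#' source_spot_ids` (semicolon-joined spot ids), `is_off_target, cell_id`.
#'
#' @param path file path.
#' @param transcripts a decoded transcript table as returned by [decode()].
#' @name transcripts-io
NULL

#' @rdname transcripts-io
#' @export
write_transcripts <- function(transcripts, path) {
  utils::write.csv(transcripts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname transcripts-io
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, colClasses = list(source_spot_ids = "character",
                                                target = "character"))
  df$is_off_target <- as.logical(df$is_off_target)
  df
}

# Split semicolon-joined source spot ids into an integer vector list.
split_spot_ids <- function(x) lapply(strsplit(as.character(x), ";"),
                                     as.integer)
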