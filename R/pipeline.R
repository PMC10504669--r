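#' Read a run configuration from JSON or YAML
#'
#' @param path config file, `.json` or `.yml`/`.yaml`.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
}

fov_name <- function(fov, i) {
  if (!is.null(fov$name)) fov$name else sprintf("fov_%03d", i)
}

#' Run the decode + QC pipeline over one or more fields of view
#'
#' Per FOV: optionally insert off-target barcodes into the codebook, run
#' the decoder, then the QC suite; finally compute a combined-FOV QC
#' report over all transcripts and spots (spot ids are offset per FOV so
#' they stay unique in the combined scope). Each stage writes its outputs
#' under `out_dir` so later stages can be rerun from saved output:
#' `stages = "qc"` reloads `<fov>_transcripts.csv` instead of decoding.
#' FOVs are processed sequentially.
#'
#' @param config a list (or path readable by [read_run_config()]) with
#'   elements: `fovs` (list of `list(name =, spots = path)`), `codebook`
#'   (path), `out_dir`, `fov_dims` (width, height), `seed`, `decode` (args
#'   for [decode_config()]), and optional `qc` (`offtarget_count`,
#'   `offtarget_min_distance`, `ripley_n_mc`, `alpha`), `write_plots`.
#' @param stages subset of `c("decode", "qc")` to execute.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with per-FOV transcript tables and QC
#'   reports plus the combined report.
#' @export
run_pipeline <- function(config, stages = c("decode", "qc"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  req <- c("fovs", "codebook", "out_dir", "fov_dims", "seed", "decode")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing fields: ",
                         paste(miss, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cb <- if (grepl("\\.json$", config$codebook))
    read_codebook_json(config$codebook) else
      read_codebook_tsv(config$codebook)
  qc_opts <- config$qc
  if (!is.null(qc_opts$offtarget_count) && qc_opts$offtarget_count > 0) {
    cb <- insert_off_target_barcodes(
      cb, qc_opts$offtarget_count,
      min_distance = qc_opts$offtarget_min_distance %||% 1L,
      seed = config$seed)
    write_codebook_json(cb, file.path(config$out_dir,
                                      "codebook_with_blanks.json"))
  }
  dcfg <- do.call(decode_config, config$decode)
  say <- function(...) if (!quiet) message(sprintf(...))
  fovs <- config$fovs
  per_fov <- list()
  for (i in seq_along(fovs)) {
    nm <- fov_name(fovs[[i]], i)
    spots <- read_spots(fovs[[i]]$spots)
    tx_path <- file.path(config$out_dir, paste0(nm, "_transcripts.csv"))
    if ("decode" %in% stages) {
      t0 <- Sys.time()
      tx <- decode(spots, cb, dcfg)
      write_transcripts(tx, tx_path)
      say("[%s] decode: %d spots -> %d transcripts (%.1fs)", nm,
          nrow(spots), nrow(tx),
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
    } else {
      if (!file.exists(tx_path))
        stop("stage qc: missing decode output ", tx_path)
      tx <- read_transcripts(tx_path)
    }
    rep <- NULL
    if ("qc" %in% stages) {
      t0 <- Sys.time()
      rep <- compute_qc(spots, tx, cb, unlist(config$fov_dims),
                        seed = config$seed + i,
                        ripley_n_mc = qc_opts$ripley_n_mc %||% 100L,
                        alpha = qc_opts$alpha %||% 0.05)
      write_qc_report(rep, file.path(config$out_dir, paste0(nm, "_qc.yml")))
      if (isTRUE(config$write_plots))
        plot_qc_report(rep, file.path(config$out_dir, paste0(nm, "_qc.pdf")))
      say("[%s] qc written (%.1fs)", nm,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
    per_fov[[nm]] <- list(spots = spots, transcripts = tx, qc = rep)
  }
  combined <- NULL
  if ("qc" %in% stages) {
    offset <- 0L
    all_spots <- list(); all_tx <- list()
    for (nm in names(per_fov)) {
      sp <- per_fov[[nm]]$spots
      tx <- per_fov[[nm]]$transcripts
      sp$spot_id <- sp$spot_id + offset
      if (nrow(tx))
        tx$source_spot_ids <- vapply(split_spot_ids(tx$source_spot_ids),
                                     function(v)
                                       paste(v + offset, collapse = ";"),
                                     character(1))
      offset <- offset + max(sp$spot_id, 0L) + 1L
      all_spots[[nm]] <- sp; all_tx[[nm]] <- tx
    }
    combined <- compute_qc(do.call(rbind, all_spots),
                           do.call(rbind, all_tx), cb,
                           unlist(config$fov_dims), seed = config$seed,
                           ripley_n_mc = qc_opts$ripley_n_mc %||% 100L,
                           alpha = qc_opts$alpha %||% 0.05)
    write_qc_report(combined, file.path(config$out_dir, "combined_qc.yml"))
  }
  invisible(list(per_fov = per_fov, combined_qc = combined,
                 codebook = cb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate` (synthetic dataset), `decode` (spot decoding),
#' `qc` (QC report), `threshold` (elbow + normalized AUC of a spot-count
#' curve), `run` (full pipeline from a config file). Invoke with
#' `Rscript -e 'spotcall::spotcall_cli()' <subcommand> [options]` or via
#' the wrapper script in `inst/cli/`.
#'
#' @param args character vector of arguments (defaults to the command
#'   line).
#' @return exit status 0 invisibly on success; errors propagate.
#' @export
spotcall_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: spotcall <simulate|decode|qc|threshold|run> [options]")
  sub <- args[1L]; rest <- args[-1L]
  switch(sub,
         simulate = cli_simulate(rest),
         decode = cli_decode(rest),
         qc = cli_qc(rest),
         threshold = cli_threshold(rest),
         run = cli_run(rest),
         stop("unknown subcommand: ", sub))
  invisible(0L)
}

opt <- optparse::make_option

cli_simulate <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    opt("--n-targets", type = "integer", default = 20L),
    opt("--n-rounds", type = "integer", default = 4L),
    opt("--n-channels", type = "integer", default = 4L),
    opt("--min-hamming", type = "integer", default = 2L),
    opt("--n-transcripts", type = "integer", default = 200L),
    opt("--fov", type = "character", default = "100,100"),
    opt("--drift-sigma", type = "double", default = 0),
    opt("--dropout", type = "double", default = 0),
    opt("--noise-rate", type = "double", default = 0),
    opt("--cell-grid", type = "integer", default = NULL),
    opt("--seed", type = "integer", default = 1L),
    opt("--out-prefix", type = "character", default = "sim")))
  o <- optparse::parse_args(parser, args)
  fov <- as.numeric(strsplit(o$fov, ",")[[1]])
  cb <- generate_codebook(o$`n-targets`, o$`n-rounds`, o$`n-channels`,
                          o$`min-hamming`, seed = o$seed)
  sim <- simulate_spots(cb, o$`n-transcripts`, fov_dims = fov,
                        drift_sigma = o$`drift-sigma`,
                        dropout_rate = o$dropout,
                        noise_rate = o$`noise-rate`,
                        cell_grid = o$`cell-grid`, seed = o$seed + 1L)
  write_codebook_json(cb, paste0(o$`out-prefix`, "_codebook.json"))
  write_spots(sim$spots, paste0(o$`out-prefix`, "_spots.csv"))
  write.csv(sim$truth$transcripts, paste0(o$`out-prefix`, "_truth.csv"),
            row.names = FALSE)
  message("wrote ", o$`out-prefix`, "_{codebook.json,spots.csv,truth.csv}")
}

cli_decode <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    opt("--spots", type = "character"),
    opt("--codebook", type = "character"),
    opt("--radius", type = "double"),
    opt("--mode", type = "character", default = "medium"),
    opt("--error-rounds", type = "integer", default = 0L),
    opt("--seed", type = "integer", default = 1L),
    opt("--out", type = "character", default = "transcripts.csv")))
  o <- optparse::parse_args(parser, args)
  cb <- if (grepl("\\.json$", o$codebook)) read_codebook_json(o$codebook)
  else read_codebook_tsv(o$codebook)
  spots <- read_spots(o$spots)
  cfg <- decode_config(o$radius, mode = o$mode,
                       error_rounds = o$`error-rounds`)
  tx <- decode(spots, cb, cfg, verbose = TRUE)
  write_transcripts(tx, o$out)
  message(nrow(tx), " transcripts -> ", o$out)
}

cli_qc <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    opt("--spots", type = "character"),
    opt("--transcripts", type = "character"),
    opt("--codebook", type = "character"),
    opt("--fov", type = "character", default = "100,100"),
    opt("--seed", type = "integer", default = 1L),
    opt("--pdf", type = "character", default = NULL),
    opt("--out", type = "character", default = "qc.yml")))
  o <- optparse::parse_args(parser, args)
  cb <- if (grepl("\\.json$", o$codebook)) read_codebook_json(o$codebook)
  else read_codebook_tsv(o$codebook)
  rep <- compute_qc(read_spots(o$spots), read_transcripts(o$transcripts),
                    cb, as.numeric(strsplit(o$fov, ",")[[1]]),
                    seed = o$seed)
  write_qc_report(rep, o$out)
  if (!is.null(o$pdf)) plot_qc_report(rep, o$pdf)
  message("QC report -> ", o$out)
}

cli_threshold <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    opt("--curve", type = "character"),
    opt("--out", type = "character", default = "threshold.json")))
  o <- optparse::parse_args(parser, args)
  curve <- read_threshold_curve(o$curve)
  res <- list(elbow_threshold = elbow_threshold(curve),
              normalized_auc = normalized_auc(curve))
  jsonlite::write_json(res, o$out, auto_unbox = TRUE, digits = NA)
  message("elbow = ", res$elbow_threshold,
          ", normalized AUC = ", signif(res$normalized_auc, 4))
}

cli_run <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    opt("--config", type = "character"),
    opt("--stages", type = "character", default = "decode,qc")))
  o <- optparse::parse_args(parser, args)
  run_pipeline(o$config, stages = strsplit(o$stages, ",")[[1]])
}
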