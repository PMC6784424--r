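#' Read and validate a pipeline configuration
#'
#' A pipeline configuration is a YAML (or JSON) file with:
#' \describe{
#'   \item{seed}{Integer master seed; per-analyte stream seeds are derived
#'     from it.}
#'   \item{n_days}{Number of generated days per stream.}
#'   \item{block}{Bias-simulation block length (default 400).}
#'   \item{profiles}{List of analyte profiles (the [analyte_profile()] fields,
#'     plus optional `tea_percent`).}
#'   \item{candidates}{List of candidate procedures, each with `analyte`,
#'     `algorithm`, `batch_size` or `weighting_factor`, and an optional
#'     `truncation: {lower, upper}` block.}
#' }
#' Every analyte referenced by a candidate must have a profile.
#'
#' @param path Path to the configuration file.
#' @return A list of class `pipeline_config` with elements `seed`, `n_days`,
#'   `block`, `profiles` (named list of profiles), `candidates` (named list of
#'   per-analyte [ma_config()] lists) and `hash`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (f in c("seed", "n_days", "profiles", "candidates"))
    if (is.null(raw[[f]])) stop_validation("missing config field '", f, "'")

  profiles <- lapply(raw$profiles, profile_from_list)
  names(profiles) <- vapply(profiles, function(p) p$name, character(1))

  candidates <- lapply(raw$candidates, function(cd) {
    if (is.null(cd$analyte))
      stop_validation("missing candidate field 'analyte'")
    if (!cd$analyte %in% names(profiles))
      stop_validation("candidate references analyte '", cd$analyte,
                      "' with no profile")
    tr <- truncation_limits(lower = cd$truncation$lower,
                            upper = cd$truncation$upper)
    cfg <- ma_config(cd$algorithm %||% stop_validation("missing candidate field 'algorithm'"),
                     batch_size = cd$batch_size,
                     weighting_factor = cd$weighting_factor,
                     truncation = tr,
                     init_value = cd$init_value %||% "population_mean",
                     id = cd$id)
    list(analyte = cd$analyte, config = cfg)
  })

  by_analyte <- split(candidates,
                      vapply(candidates, function(x) x$analyte, character(1)))
  structure(list(seed = as.integer(raw$seed), n_days = as.integer(raw$n_days),
                 block = as.integer(raw$block %||% 400L),
                 profiles = profiles,
                 candidates = lapply(by_analyte, function(g)
                   lapply(g, function(x) x$config)),
                 hash = config_hash(raw)),
            class = "pipeline_config")
}

stream_path <- function(dir, analyte) file.path(dir, paste0(analyte, ".csv"))

#' Generate the configured synthetic streams
#'
#' Writes one stream CSV per configured analyte profile into `out_dir`, each
#' stamped with its seed and the configuration hash. Existing files are kept
#' (reruns are idempotent) unless `overwrite = TRUE`.
#'
#' @param config A [read_pipeline_config()] result.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Regenerate files that already exist. Default `FALSE`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the named vector of written (or reused) file paths.
#' @export
pipeline_generate <- function(config, out_dir, overwrite = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(config$profiles)) {
    prof <- config$profiles[[i]]
    path <- stream_path(out_dir, prof$name)
    if (file.exists(path) && !overwrite) {
      if (!quiet) message("keeping existing stream: ", path)
    } else {
      seed_i <- config$seed + i - 1L
      stream <- generate_stream(prof, config$n_days, seed_i)
      write_stream(stream, path, extra_comments = c(config_hash = config$hash))
      if (!quiet) message("wrote ", path, " (seed ", seed_i, ", ",
                          nrow(stream), " results)")
    }
    paths[prof$name] <- path
  }
  write_manifest(out_dir, config, stage = "generate", files = paths)
  invisible(paths)
}

#' Run the bias-injection simulations for all candidates
#'
#' For every candidate procedure: computes the MA series of its analyte's
#' stream, derives min/max control limits, simulates the full bias grid
#' (the analyte's TEa, when profiled, is added to the grid), and writes
#' per-run and per-bias summary CSVs. Candidates whose outputs already exist
#' are skipped, so an interrupted run resumes where it stopped.
#'
#' @param config A [read_pipeline_config()] result.
#' @param streams_dir Directory holding the stream CSVs (from
#'   [pipeline_generate()]).
#' @param out_dir Output directory.
#' @param overwrite Recompute existing outputs. Default `FALSE`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a data frame listing analyte, config_id and the written
#'   summary files.
#' @export
pipeline_simulate <- function(config, streams_dir, out_dir,
                              overwrite = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- list()
  for (analyte in names(config$candidates)) {
    spath <- stream_path(streams_dir, analyte)
    if (!file.exists(spath)) stop_validation("stream file not found: ", spath)
    stream <- read_stream(spath)
    if (nrow(stream) == 0L) stop_validation("empty stream: ", spath)
    prof <- config$profiles[[analyte]]
    grid <- bias_grid(tea_percent = prof$tea_percent)
    for (cfg in config$candidates[[analyte]]) {
      sum_path <- file.path(out_dir, sprintf("summary_%s_%s.csv", analyte, cfg$id))
      runs_path <- file.path(out_dir, sprintf("runs_%s_%s.csv", analyte, cfg$id))
      if (file.exists(sum_path) && !overwrite) {
        if (!quiet) message("keeping existing summary: ", sum_path)
      } else {
        sim <- simulate_bias_grid(stream, cfg, grid = grid, block = config$block)
        runs <- cbind(analyte = analyte, config_id = cfg$id, sim$runs)
        runs$censored <- as.logical(runs$censored)
        sums <- cbind(analyte = analyte, config_id = cfg$id, sim$summaries)
        write_csv_commented(runs, runs_path, config)
        write_csv_commented(sums, sum_path, config)
        if (!quiet) message("simulated ", analyte, " / ", cfg$id,
                            " (limits [", format(sim$limits$lower), ", ",
                            format(sim$limits$upper), "])")
      }
      index[[length(index) + 1L]] <- data.frame(analyte = analyte,
                                                config_id = cfg$id,
                                                summary_file = sum_path)
    }
  }
  out <- do.call(rbind, index)
  write_manifest(out_dir, config, stage = "simulate", files = out$summary_file)
  invisible(out)
}

#' Rank the simulated candidates per analyte
#'
#' Reads the per-candidate summaries written by [pipeline_simulate()], builds
#' validation charts, applies the optimization criteria (TEa and daily volume
#' from each analyte's profile) and writes one ranking CSV per analyte with
#' `rank`, `feasible` and `reason` columns.
#'
#' @param config A [read_pipeline_config()] result.
#' @param summaries_dir Directory holding the summary CSVs.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of ranking data frames, one per analyte.
#' @export
pipeline_rank <- function(config, summaries_dir, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rankings <- list()
  for (analyte in names(config$candidates)) {
    cands <- config$candidates[[analyte]]
    if (!length(cands)) stop_validation("no candidates configured for ", analyte)
    prof <- config$profiles[[analyte]]
    if (is.null(prof$tea_percent))
      stop_validation("profile '", analyte, "' has no tea_percent; cannot rank")
    charts <- lapply(cands, function(cfg) {
      sum_path <- file.path(summaries_dir,
                            sprintf("summary_%s_%s.csv", analyte, cfg$id))
      if (!file.exists(sum_path))
        stop_validation("summary file not found: ", sum_path)
      sums <- read_csv_commented(sum_path)
      build_validation_chart(sums, cfg$id, config = cfg)
    })
    criteria <- optimization_criteria(prof$tea_percent, prof$daily_volume)
    ranking <- rank_candidates(charts, criteria)
    path <- file.path(out_dir, sprintf("ranking_%s.csv", analyte))
    write_csv_commented(ranking, path, config)
    if (!quiet) message("ranked ", length(charts), " candidate(s) for ",
                        analyte, " -> ", path)
    rankings[[analyte]] <- ranking
  }
  write_manifest(out_dir, config, stage = "rank",
                 files = file.path(out_dir, sprintf("ranking_%s.csv",
                                                    names(rankings))))
  invisible(rankings)
}

write_csv_commented <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", config$hash), con)
  writeLines(sprintf("# seed=%d", config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_manifest <- function(dir, config, stage, files) {
  manifest <- list(stage = stage, config_hash = config$hash, seed = config$seed,
                   n_days = config$n_days, block = config$block,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   files = unname(files))
  jsonlite::write_json(manifest,
                       file.path(dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
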