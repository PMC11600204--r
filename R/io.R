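# Recording CSV format, JSON run configuration, and the end-to-end
# simulate -> analyze -> screen pipeline.

RECORDING_COLS <- c("time_s", "Lm_um", "x_px", "x_um", "Fs_uN", "stim",
                    "medium")

#' Write a recording to CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal; units encoded in the
#' column names (`time_s, Lm_um, x_px, x_um, Fs_uN`; `Fcmd_uN` for
#' controlled runs). Full double precision is preserved.
#'
#' @param recording A `recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  cols <- intersect(c(RECORDING_COLS, "Fcmd_uN"), names(recording))
  df <- as.data.frame(recording)[, cols]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Validates the column set and the uniform time grid (errors name the
#' offending rows). A legacy file lacking `x_um` is reconstructed from
#' `x_px` and the probe's pixel size. Rows with non-finite force are kept
#' but flagged (attribute `bad_rows`); analysis excludes them.
#'
#' @param path CSV file path.
#' @param probe Optional [probe_spec()]; enables `x_um` reconstruction and
#'   consistency validation of the unit columns (1e-9 relative).
#' @return A `recording`.
#' @export
read_recording <- function(path, probe = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(RECORDING_COLS, "x_um"), names(df))
  if (length(miss))
    stop("recording format error in ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(RECORDING_COLS, "Fcmd_uN"))
  if (length(extra))
    stop("recording format error in ", path, ": unexpected columns ",
         paste(extra, collapse = ", "))
  if (!"x_um" %in% names(df)) {
    if (is.null(probe))
      stop("file lacks x_um and no probe was given to reconstruct it")
    df$x_um <- df$x_px * probe$pixel_size * 1e6
    df <- df[, c(RECORDING_COLS, intersect("Fcmd_uN", names(df)))]
  }
  dt <- diff(df$time_s)
  bad_dt <- which(abs(dt - stats::median(dt)) > 1e-6 * max(stats::median(dt), 1e-12))
  if (length(bad_dt))
    stop("recording format error in ", path, ": non-uniform time at rows ",
         paste(utils::head(bad_dt + 2, 5), collapse = ", "),
         " (1-based, counting the header)")
  if (!is.null(probe)) {
    rel <- abs(df$x_um - df$x_px * probe$pixel_size * 1e6) /
      pmax(abs(df$x_um), 1e-12)
    ok <- is.finite(rel)
    if (any(rel[ok] > 1e-6))
      stop("recording format error in ", path,
           ": x_um inconsistent with x_px * pixel_size")
    attr(df, "probe") <- probe
  }
  bad <- which(!is.finite(df$Fs_uN))
  if (length(bad)) attr(df, "bad_rows") <- bad
  class(df) <- c("recording", "data.frame")
  df
}

#' Read and resolve a JSON run configuration
#'
#' A run is reproducible from its configuration alone. Recognized keys:
#' `probe` (preset name or full field set), `grid` (preset name),
#' `stage`, `culture_period`, `n_replicates`, `protocol`
#' (`"oscillation"`, `"cf"`, `"both"`), `f_m`, `noise_px`, `seed`,
#' `criteria` (thresholds for [criteria_config()]), `mpc` (fields for
#' [mpc_config()]), `out_dir`. Presets are resolved here so that the
#' logged configuration is self-contained.
#'
#' @param path JSON file path, or a list already parsed.
#' @return A resolved configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::fromJSON(path) else path
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_replicates <- as.integer(cfg$n_replicates %||% 4L)
  cfg$protocol <- cfg$protocol %||% "oscillation"
  cfg$f_m <- cfg$f_m %||% 0.1
  cfg$noise_px <- cfg$noise_px %||% 0.3
  cfg$probe <- if (is.character(cfg$probe %||% "short"))
    probe_preset(cfg$probe %||% "short")
  else do.call(probe_spec, cfg$probe)
  if (is.character(cfg$grid %||% "gelma12"))
    cfg$grid <- condition_grid(cfg$grid %||% "gelma12")
  cfg$criteria <- if (is.null(cfg$criteria)) criteria_config()
    else do.call(criteria_config, cfg$criteria)
  cfg$mpc <- if (is.null(cfg$mpc)) mpc_config() else do.call(mpc_config, cfg$mpc)
  if (!is.null(cfg$out_dir)) cfg$out_dir <- as.character(cfg$out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulate / analyze / screen pipeline
#'
#' Generates the seeded population over the configured condition grid (the
#' measured end state, plus the paired reference state when the protocol
#' includes viscoelasticity, so the modulus-increase criterion is
#' evaluable), analyzes every recording, evaluates the three criteria and
#' the funnel, and writes `manifest.csv`, `summary.csv`,
#' `screening_results.csv`, `funnel.txt`, the resolved `config.json` and
#' per-sample recording CSVs under `recordings/` in the output directory.
#' Re-running the same configuration reproduces identical tables.
#'
#' @param config A `run_config` (or path to one, or a list).
#' @param out_dir Output directory (overrides the config's).
#' @param write_recordings Write per-sample CSVs (default TRUE).
#' @return Invisibly, a list with `summary`, `results`, `funnel`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, write_recordings = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message(sprintf("[simulate] grid=%d conditions, n=%d, seed=%d, protocol=%s",
                  nrow(cfg$grid), cfg$n_replicates, cfg$seed, cfg$protocol))
  pop <- generate_population(cfg$grid, cfg$n_replicates,
                             protocol = cfg$protocol, seed = cfg$seed,
                             stage = cfg$stage,
                             culture_period = cfg$culture_period %||% "optimized",
                             probe = cfg$probe, noise_px = cfg$noise_px)
  with_estar <- cfg$protocol %in% c("oscillation", "both")
  before <- NULL
  if (with_estar) {
    message("[simulate] paired reference state for the modulus criterion")
    grid_name <- cfg$grid$grid[1]
    before_stage <- if (grid_name == "gelma12") {
      if (identical(cfg$stage, "differentiated")) "cultured" else "pre_culture"
    } else "before"
    pop_before <- generate_population(cfg$grid, cfg$n_replicates,
                                      protocol = "oscillation",
                                      seed = cfg$seed + 1,
                                      stage = before_stage,
                                      probe = cfg$probe,
                                      noise_px = cfg$noise_px)
    before <- analyze_population(pop_before, f_m = cfg$f_m)
  }
  if (write_recordings) {
    rdir <- file.path(out_dir, "recordings")
    dir.create(rdir, showWarnings = FALSE)
    for (id in names(pop$recordings)) {
      rec <- pop$recordings[[id]]
      if (inherits(rec, "recording"))
        write_recording(rec, file.path(rdir, paste0(id, ".csv")))
      else for (nm in names(rec))
        write_recording(rec[[nm]], file.path(rdir, paste0(id, "_", nm, ".csv")))
    }
  }
  utils::write.csv(pop$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  message(sprintf("[analyze] %d recordings at f_m=%g Hz",
                  length(pop$recordings), cfg$f_m))
  summary <- analyze_population(pop, f_m = cfg$f_m,
                                cf_threshold = cfg$criteria$cf_min_difference)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  message("[screen] evaluating criteria and funnel")
  results <- evaluate_criteria(summary, cfg$criteria, before = before)
  fun <- screening_funnel(results)
  results$stage <- fun$stage
  utils::write.csv(results, file.path(out_dir, "screening_results.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("conditions entering: %d", fun$counts[["entering"]]),
               sprintf("after CF criterion: %d", fun$counts[["after_cf"]]),
               sprintf("after tan-delta criterion: %d", fun$counts[["after_tan"]]),
               sprintf("after modulus-increase criterion: %d",
                       fun$counts[["after_estar"]]),
               "selected conditions:",
               utils::capture.output(print(
                 results[fun$selected, , drop = FALSE]))),
             file.path(out_dir, "funnel.txt"))
  cfg_out <- cfg
  cfg_out$grid <- NULL
  jsonlite::write_json(
    list(seed = cfg$seed, n_replicates = cfg$n_replicates,
         protocol = cfg$protocol, f_m = cfg$f_m, noise_px = cfg$noise_px),
    file.path(out_dir, "config.json"), auto_unbox = TRUE)
  invisible(list(summary = summary, results = results, funnel = fun,
                 out_dir = out_dir))
}
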