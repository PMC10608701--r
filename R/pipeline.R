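#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one flat list, suitable for
#' YAML round-tripping. Unknown keys are rejected at load time so config
#' typos fail fast rather than silently using defaults.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    min_snr = 5, mz_range_lo = 70, mz_range_hi = 1000,
    mz_tol_ppm = 5, rt_tol_min = 0.5,
    intensity_ratio_lo = 0.2, intensity_ratio_hi = 5,
    c_max = 40L, n_max = 10L,
    formula_tol_ppm = 5,
    h_max = 80L, o_max = 20L, p_max = 4L, s_max = 4L,
    rdbe_lo = 0, rdbe_hi = 25, hc_lo = 0.1, hc_hi = 4,
    mass_tol_ppm = 5, ms2_threshold = 0.7, frag_tol_mz = 0.01,
    merge_rt_tol_min = 0.5,
    sim_n_compounds = 1000L, sim_ppm_noise_sd = 2, sim_rt_jitter_sd = 0.05,
    sim_dropout = 0.1, sim_decoy_density = 1,
    sim_esi_only = 0.4, sim_apci_only = 0.25, sim_prob_negative = 0.6,
    seed = 1L
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of configuration overrides and merges it onto
#' [default_config()]. Unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A complete configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  cfg
}

.cfg_match <- function(cfg)
  match_config(cfg$mz_tol_ppm, cfg$rt_tol_min,
               c(cfg$intensity_ratio_lo, cfg$intensity_ratio_hi),
               cfg$c_max, cfg$n_max)

.cfg_bounds <- function(cfg)
  element_bounds(C = c(0L, cfg$c_max), H = c(0L, cfg$h_max),
                 N = c(0L, cfg$n_max), O = c(0L, cfg$o_max),
                 P = c(0L, cfg$p_max), S = c(0L, cfg$s_max),
                 rdbe_range = c(cfg$rdbe_lo, cfg$rdbe_hi),
                 hc_ratio_range = c(cfg$hc_lo, cfg$hc_hi))

.cfg_ann <- function(cfg)
  annotation_config(cfg$mass_tol_ppm, cfg$rt_tol_min, cfg$ms2_threshold,
                    cfg$frag_tol_mz)

.cfg_sim <- function(cfg)
  sim_config(cfg$sim_n_compounds, cfg$sim_ppm_noise_sd, cfg$sim_rt_jitter_sd,
             cfg$sim_dropout, cfg$sim_decoy_density, cfg$sim_esi_only,
             cfg$sim_apci_only, cfg$sim_prob_negative, cfg$seed)

#' Run the full credentialing-to-database pipeline
#'
#' Discovers per-channel four-condition peak tables in `input_dir` (layout
#' of [write_simulation()]: `peaks_<SRC>_<neg|pos>_<COND>.csv` plus
#' `library.tsv`/`library.msp`), then for each channel runs
#' filter -> quartet matching -> credentialing -> formula decomposition ->
#' library annotation, merges the channels into one metabolite database and
#' writes all intermediate and final tables to `out_dir`. Stage counts are
#' logged via `message()`.
#'
#' @param input_dir Directory of input tables.
#' @param out_dir Output directory (created if needed).
#' @param cfg Configuration list, see [load_config()].
#' @return Invisibly, a list: `db`, `counts`, `annotations` (per channel),
#'   `quartets` (per channel, credentialed).
#' @export
run_pipeline <- function(input_dir, out_dir, cfg = default_config()) {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir,
                                   call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib_path <- file.path(input_dir, "library.tsv")
  msp_path <- file.path(input_dir, "library.msp")
  if (!file.exists(lib_path)) stop("library.tsv not found in ", input_dir,
                                   call. = FALSE)
  lib <- read_library(lib_path, if (file.exists(msp_path)) msp_path else NULL)

  files <- list.files(input_dir, "^peaks_[A-Z]+_(neg|pos)_[A-Z0-9]+\\.csv$")
  keys <- unique(sub("^peaks_([A-Z]+_(neg|pos))_.*$", "\\1", files))
  mcfg <- .cfg_match(cfg); bounds <- .cfg_bounds(cfg); acfg <- .cfg_ann(cfg)

  anns <- list(); creds <- list()
  for (key in sort(keys)) {
    src <- sub("_.*$", "", key)
    pol <- if (endsWith(key, "pos")) "positive" else "negative"
    ch <- .channel(src, pol)
    sets <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond) {
      f <- file.path(input_dir, sprintf("peaks_%s_%s.csv", key, cond))
      if (!file.exists(f)) stop("missing peak table: ", f, call. = FALSE)
      filter_peaks(read_peak_table(f, cond, pol, src),
                   cfg$min_snr, c(cfg$mz_range_lo, cfg$mz_range_hi))
    })
    qt <- match_quartets(sets$U, sets$C13, sets$N15, sets$C13N15, mcfg)
    cred <- credential(qt)
    ann <- annotate_quartets(cred, lib, acfg, bounds, cfg$formula_tol_ppm)
    message(sprintf("[%s] peaks U=%d, quartets=%d, credentialed=%d, annotated=%d",
                    ch, nrow(sets$U), nrow(qt), nrow(cred),
                    sum(ann$tier != "unannotated")))
    utils::write.table(as.data.frame(qt),
                       file.path(out_dir, paste0("quartets_", key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(ann),
                       file.path(out_dir, paste0("annotations_", key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    anns[[ch]] <- ann; creds[[ch]] <- cred
  }
  if (!length(anns)) {
    warning("no peak tables found in ", input_dir, call. = FALSE)
    db <- .empty_db()
  } else {
    db <- merge_annotations(anns, cfg$merge_rt_tol_min)
  }
  counts <- count_by_source(db)
  utils::write.table(as.data.frame(db), file.path(out_dir, "database.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(channel = c(names(counts$by_channel), "total"),
               count = c(unname(counts$by_channel), counts$total)),
    file.path(out_dir, "source_counts.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("database: %d distinct entries (%s)", counts$total,
                  paste(names(counts$by_channel), counts$by_channel,
                        sep = "=", collapse = ", ")))
  invisible(list(db = db, counts = counts, annotations = anns,
                 quartets = creds))
}

#' Simulate a labeled study and write its pipeline inputs
#'
#' Convenience wrapper: [sample_library()] + [simulate_quartets()] +
#' [write_simulation()] driven by one configuration list.
#'
#' @param out_dir Output directory.
#' @param cfg Configuration list, see [load_config()].
#' @return Invisibly, the `sim_result`.
#' @export
simulate_to_dir <- function(out_dir, cfg = default_config()) {
  lib <- sample_library(cfg$sim_n_compounds, cfg$seed)
  sim <- simulate_quartets(lib, .cfg_sim(cfg))
  write_simulation(sim, lib, out_dir)
  message(sprintf("simulated %d compounds into %d channels -> %s",
                  nrow(sim$truth), length(sim$channels), out_dir))
  invisible(sim)
}
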