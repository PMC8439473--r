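# End-to-end pipeline: simulate -> features -> maps -> stats, with a
# reproducibility manifest.

RUN_CONFIG_KEYS <- c("seed", "out_dir", "environment", "nx", "ny",
                     "noise_sd", "tear_fraction", "groups",
                     "calibration_percents", "calibration_feature",
                     "probe_freq", "pump_freq")

#' Validate a pipeline run configuration
#'
#' @param config Named list. Recognised keys: \code{seed}, \code{out_dir},
#'   \code{environment}, \code{nx}, \code{ny}, \code{noise_sd},
#'   \code{tear_fraction}, \code{groups} (named list mapping group label to
#'   \code{list(preset=, n_lenses=)}), \code{calibration_percents},
#'   \code{calibration_feature}, \code{probe_freq}, \code{pump_freq}.
#'   Unknown keys are rejected before any compute.
#' @return The config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$environment <- config$environment %||% "ffpe"
  config$nx <- config$nx %||% 16L
  config$ny <- config$ny %||% 16L
  config$noise_sd <- config$noise_sd %||% 0.005
  config$tear_fraction <- config$tear_fraction %||% 0
  config$groups <- config$groups %||%
    list(wt = list(preset = "wt_mouse", n_lenses = 2L),
         r120g = list(preset = "r120g_mouse", n_lenses = 2L))
  config$calibration_percents <- config$calibration_percents %||% 0:6
  config$calibration_feature <- config$calibration_feature %||% "diag_ratio"
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  config
}

#' Build calibration standards from noiseless generator mixtures
#'
#' Renders uniform FFPE-library mixtures at known amyloid percents and
#' measures the calibration feature on each, yielding a same-generator
#' standards table.
#'
#' @param percents Known amyloid percents (0-100 scale).
#' @param environment,host Component library selectors.
#' @param feature \code{"diag_ratio"} or \code{"xpeak_intensity"}.
#' @param helix_weight Fixed helix/coil weight of the standards.
#' @param sample_class Normalization class (default from environment).
#' @return Data frame with columns \code{percent}, \code{feature}.
#' @export
calibration_standards <- function(percents = 0:6, environment = "ffpe",
                                  host = "mouse", feature = "diag_ratio",
                                  helix_weight = 0,
                                  sample_class = NULL) {
  lib <- component_library(environment, host)
  sample_class <- sample_class %||%
    sample_class_for(if (host == "mouse") "wt_mouse" else "juvenile_human",
                     environment)
  xp <- HOST_XPEAK[[host]]
  vals <- vapply(percents, function(p) {
    f <- p / 100
    w <- c(native_beta = 1 - helix_weight - f, amyloid_beta = f,
           helix_coil = helix_weight)
    s <- compose_spectrum(w, lib, noise_sd = 0, oversample = 5L)
    pf <- pixel_features(s, sample_class, probe_freq = xp[["probe"]],
                         pump_freq = xp[["pump"]])
    pf[[feature]]
  }, numeric(1))
  data.frame(percent = percents, feature = vals)
}

#' Run the full analysis pipeline
#'
#' Simulates every lens of every group, writes cube containers, per-pixel
#' feature TSVs, ratio/cross-peak map TSVs and peak-frequency histograms,
#' computes group statistics and calibration-based percent-amyloid
#' estimates, and records a manifest with content hashes. Re-running with
#' the same config and seed reproduces all data files bit-for-bit.
#'
#' @param config Run configuration (see \code{\link{validate_run_config}}).
#' @return Invisibly, a list with \code{manifest}, \code{summaries},
#'   \code{comparisons}, \code{estimates}.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  summaries <- list()
  lens_seed <- config$seed
  for (g in names(config$groups)) {
    spec <- config$groups[[g]]
    for (k in seq_len(spec$n_lenses %||% 1L)) {
      lens_id <- sprintf("%s_lens%d", g, k)
      lens_seed <- lens_seed + 1L
      cube <- simulate_cube(spec$preset, nx = config$nx, ny = config$ny,
                            environment = config$environment,
                            tear_params = list(fraction =
                                                 config$tear_fraction),
                            noise_sd = config$noise_sd, seed = lens_seed)
      write_cube(cube, emit(out(paste0(lens_id, ".rds"))))
      tab <- feature_table(cube)
      write_tsv(tab, emit(out(paste0(lens_id, "_features.tsv"))))
      for (feat in c("diag_ratio", "xpeak_intensity")) {
        map <- build_feature_map(cube, feat)
        write_map_tsv(map, emit(out(sprintf("%s_%s_map.tsv", lens_id,
                                            feat))))
      }
      pk <- build_feature_map(cube, "peak_freq")
      hist <- frequency_histogram(pk)
      write_tsv(data.frame(bin_lo = utils::head(hist$bin_edges, -1),
                           bin_hi = hist$bin_edges[-1],
                           percent = hist$percent_of_locations),
                emit(out(paste0(lens_id, "_peakfreq_hist.tsv"))))
      summaries[[lens_id]] <- summarize_lens(tab, lens_id = lens_id,
                                             group = g)
    }
  }

  # group comparisons on pooled pixels and on per-lens means
  groups <- names(config$groups)
  comparisons <- list()
  if (length(groups) >= 2L) {
    for (feat in c("diag_ratio", "xpeak_intensity")) {
      a <- unlist(lapply(summaries, function(s)
        if (s$group == groups[2]) s$pixels[[feat]]))
      b <- unlist(lapply(summaries, function(s)
        if (s$group == groups[1]) s$pixels[[feat]]))
      comparisons[[paste0(feat, "_pixels")]] <-
        compare_groups(a, b, feature = feat, group_a = groups[2],
                       group_b = groups[1])
    }
  }

  host <- GENOTYPE_PRESETS[[config$groups[[1]]$preset]]$host
  stds <- calibration_standards(config$calibration_percents,
                                config$environment, host,
                                config$calibration_feature)
  curve <- fit_calibration(stds)
  estimates <- lapply(summaries, estimate_percent_amyloid, curve = curve,
                      feature = config$calibration_feature)
  write_tsv(stds, emit(out("calibration_standards.tsv")))

  stats_obj <- list(
    seed = config$seed,
    lens_summaries = lapply(summaries, function(s)
      s[c("lens_id", "group", "mean_diag_ratio", "mean_xpeak_intensity",
          "n_pixels", "ci95")]),
    comparisons = lapply(comparisons, unclass),
    percent_amyloid = estimates)
  jsonlite::write_json(stats_obj, emit(out("stats.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write_tsv(manifest, out("manifest.tsv"))
  invisible(list(manifest = manifest, summaries = summaries,
                 comparisons = comparisons, estimates = estimates))
}
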