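#' Study configuration
#'
#' Assembles the parameter blocks driving [run_study()]: the generative
#' ground truth (or paths to measured profiles), per-module settings and the
#' master seed. Can also be loaded from a JSON file whose top-level fields
#' mirror the arguments (`truth` overrides are applied over the defaults).
#'
#' @param truth A [ground_truth()].
#' @param mode One of `"simulate"`, `"waxs"`, `"sans"`, `"wans"`, `"all"`.
#' @param seed Master seed; defaults to `truth$seed`.
#' @param sans_fractions D2O fractions of the simulated hydration series.
#' @param sans_noise Noise fraction for the SANS profiles (the SANS
#'   instrument noise differs from WAXS; default 0.02).
#' @param anchor_windows Background anchors for the WAXS stage.
#' @param envelope_height,envelope_width Microfibril envelope dimensions for
#'   the geometry stage; `NA` means take them from the recovered L and the
#'   dry-state SANS spacing.
#' @return A `study_config` list.
#' @export
study_config <- function(truth = ground_truth(),
                         mode = c("all", "simulate", "waxs", "sans", "wans"),
                         seed = truth$seed,
                         sans_fractions = c(0, 0.1, 0.25),
                         sans_noise = 0.02,
                         anchor_windows = list(c(5, 6.5), c(33.5, 35)),
                         envelope_height = NA_real_,
                         envelope_width = NA_real_) {
  mode <- match.arg(mode)
  structure(list(truth = truth, mode = mode, seed = as.integer(seed),
                 sans_fractions = sans_fractions, sans_noise = sans_noise,
                 anchor_windows = anchor_windows,
                 envelope_height = envelope_height,
                 envelope_width = envelope_width),
            class = "study_config")
}

#' Load a study configuration from JSON
#'
#' @param path JSON file whose fields mirror [study_config()] arguments;
#'   a `truth` object holds [ground_truth()] overrides (`cell` as
#'   `{a, b, gamma}`).
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- cfg$truth %||% list()
  if (!is.null(tr$cell)) {
    tr$cell <- monoclinic_cell(tr$cell$a, tr$cell$b, tr$cell$gamma)
  }
  for (nm in c("peak_heights", "sans_spacing", "deuteration_scale",
               "background", "sans_background")) {
    if (!is.null(tr[[nm]])) tr[[nm]] <- unlist(tr[[nm]])
  }
  truth <- do.call(ground_truth, tr)
  args <- cfg[setdiff(names(cfg), "truth")]
  if (!is.null(args$anchor_windows)) {
    args$anchor_windows <- purrr::map(args$anchor_windows, as.numeric)
  }
  do.call(study_config, c(list(truth = truth), args))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates, per the configured mode: simulation of the WAXS, SANS and
#' WANS data from the ground truth, the WAXS size/disorder and lattice
#' analysis, the SANS hydration-series and contrast-match analysis, the WANS
#' difference and consistency analysis, and the chain-count geometry.
#' Deterministic given the config seed. When `out_dir` is given, writes
#' `report.json`, the simulated profiles and CSV tables there.
#'
#' @param config A [study_config()] or path to a JSON config file.
#' @param out_dir Optional output directory.
#' @return A `study_report` list with elements `waxs`, `sans`, `wans`,
#'   `geometry` and `provenance`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  truth <- config$truth
  seed <- config$seed
  mode <- config$mode
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("fibrilscatter")),
    seed = seed, mode = mode, config_hash = rlang::hash(config)))

  waxs_profile <- generate_equatorial_waxs(truth, seed = seed)
  azim <- generate_azimuthal(truth, seed = seed + 10L)
  sans_truth <- truth
  sans_truth$noise_fraction <- config$sans_noise
  sans_profiles <- setNames(
    purrr::imap(config$sans_fractions,
                ~ generate_sans(sans_truth, .x, seed = seed + 100L + .y)),
    as.character(config$sans_fractions))
  wans <- generate_wans_pair(truth, seed = seed + 200L)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "profiles"), recursive = TRUE,
               showWarnings = FALSE)
    write_profile(waxs_profile, file.path(out_dir, "profiles", "waxs_equatorial.txt"))
    purrr::iwalk(sans_profiles, function(p, f) {
      write_profile(p, file.path(out_dir, "profiles",
                                 sprintf("sans_d2o_%s.txt", f)))
    })
    purrr::iwalk(wans, function(p, nm) {
      write_profile(p, file.path(out_dir, "profiles",
                                 sprintf("wans_%s.txt", nm)))
    })
  }
  if (mode == "simulate") {
    report$simulated <- list(n_profiles = 2 + length(sans_profiles) +
                               length(wans))
    return(finish_report(report, out_dir))
  }

  if (mode %in% c("waxs", "all")) {
    wx <- analyze_equatorial_waxs(waxs_profile,
                                  anchor_windows = config$anchor_windows)
    az_fit <- fit_azimuthal(azim)
    report$waxs <- list(
      d_spacings = dplyr::select(wx$equatorial$components, "hkl", "d"),
      monoclinic_angle = wx$cell$gamma,
      cell = list(a = wx$cell$a, b = wx$cell$b, gamma = wx$cell$gamma),
      L = wx$broadening$L, g = wx$broadening$g,
      delta_q0 = wx$broadening$delta_q0,
      azimuthal = list(narrow_fwhm = az_fit$narrow$fwhm,
                       wide_fwhm = az_fit$wide$fwhm,
                       narrow_fraction = az_fit$narrow_fraction))
  }

  if (mode %in% c("sans", "all")) {
    series <- analyze_hydration_series(sans_profiles)
    report$sans <- list(
      spacing_trend = spacing_trend(series),
      match_fraction = contrast_match_fraction(cellulose_spec()))
  }

  if (mode %in% c("wans", "all")) {
    h_fit <- fit_equatorial(wans$h, overlap_width_ratio = 1.5,
                            background = "power-law")
    ch <- h_fit$components
    d_init <- c(q1m10 = ch$q0[ch$hkl == "1-10"],
                dq110 = ch$q0[ch$hkl == "110"] - ch$q0[ch$hkl == "1-10"],
                q200 = ch$q0[ch$hkl == "200"],
                s200 = ch$sigma[ch$hkl == "200"])
    d_fit <- fit_equatorial(wans$d, init = d_init,
                            overlap_width_ratio = 1.5,
                            background = "power-law")
    consistency <- check_equatorial_consistency(
      h_fit, d_fit, reflections = c("200", "400"))
    eq_diff <- difference_profile(wans$d, wans$h)
    lobe <- locate_difference_lobe(eq_diff)
    pair <- fit_equatorial_pair(wans$h, wans$d)
    mer_diff <- difference_profile(wans$d_meridional, wans$h_meridional,
                                   normalisation = "none")
    detections <- suppressWarnings(
      detect_meridional(mer_diff, truth$fibre_repeat_c, orders = 1:2))
    report$wans <- list(
      consistency = as_tibble(consistency),
      consistency_pass = attr(consistency, "pass"),
      q_1m10_from_difference = lobe$q0,
      monoclinic_angle = pair$cell$gamma,
      deuteration_scales = dplyr::select(pair$components, "hkl",
                                         "deuteration_scale"),
      meridional = detections)
  }

  if (mode == "all") {
    d200 <- report$waxs$d_spacings$d[report$waxs$d_spacings$hkl == "200"]
    packing <- scale_chain_area(cellulose_ibeta_cell(), d200)
    height <- config$envelope_height
    width <- config$envelope_width
    if (is.na(height)) height <- report$waxs$L
    if (is.na(width)) {
      tr <- report$sans$spacing_trend
      width <- tr$d[which.min(tr$fraction)]
    }
    report$geometry <- list(
      area_per_chain = packing$area_per_chain,
      envelope = list(height = height, width = width),
      chains_rectangle = count_chains(
        microfibril_envelope(height, width, "rectangle"), packing),
      chains_ellipse = count_chains(
        microfibril_envelope(height, width, "ellipse"), packing))
  }
  finish_report(report, out_dir)
}

finish_report <- function(report, out_dir) {
  report <- structure(report, class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    tabs <- list(waxs_d_spacings = report$waxs$d_spacings,
                 sans_spacing_trend = report$sans$spacing_trend,
                 wans_consistency = report$wans$consistency,
                 wans_meridional = report$wans$meridional)
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    purrr::iwalk(purrr::compact(tabs), function(tab, nm) {
      utils::write.csv(tab, file.path(out_dir, "tables",
                                      paste0(nm, ".csv")),
                       row.names = FALSE)
    })
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$waxs)) {
    cat(sprintf("  WAXS: d200 = %.4f nm, gamma = %.1f deg, L = %.2f nm, g = %.4f\n",
                x$waxs$d_spacings$d[x$waxs$d_spacings$hkl == "200"],
                x$waxs$monoclinic_angle, x$waxs$L, x$waxs$g))
  }
  if (!is.null(x$sans)) {
    tr <- x$sans$spacing_trend
    cat(sprintf("  SANS: spacing %s nm at fractions %s; match at %.0f%% D2O\n",
                paste(sprintf("%.2f", tr$d), collapse = "/"),
                paste(tr$fraction, collapse = "/"),
                100 * x$sans$match_fraction))
  }
  if (!is.null(x$wans)) {
    cat(sprintf("  WANS: lattice consistency %s; 00l detected: %s\n",
                if (isTRUE(x$wans$consistency_pass)) "pass" else "FAIL",
                paste(x$wans$meridional$l[x$wans$meridional$detected],
                      collapse = ", ")))
  }
  if (!is.null(x$geometry)) {
    cat(sprintf("  Geometry: %.3f nm^2 per chain; %d chains (rectangle), %d (ellipse)\n",
                x$geometry$area_per_chain, x$geometry$chains_rectangle,
                x$geometry$chains_ellipse))
  }
  invisible(x)
}
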