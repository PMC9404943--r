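#' Pipeline configuration
#'
#' Builds and validates the parameter set driving [run_pipeline()]. Values
#' can come from a YAML file and/or overrides; every parameter is
#' type-checked on load with a typed error naming the offending field.
#'
#' @param file optional YAML file of parameter blocks.
#' @param ... name = value overrides (highest precedence).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  defaults <- list(
    median_window = 3L,          # impulse-noise median window (px, odd)
    tophat_radius = 20,          # background disk radius (px)
    symmetry_scales = c(4, 8),   # symmetry-map scales (px)
    log_sigma = 4,               # LoG scale for curvature filter (px)
    classifier_path = NULL,      # JSON weights; NULL = train on the fly
    classifier_n = 200L,         # patches/class when training on the fly
    classifier_seed = 1L,
    landmark_ratio = 0.85,       # descriptor ratio-test threshold
    tps_lambda = 0,              # TPS regularization
    pairing_gate = 6,            # spot-pairing residual gate (px)
    fc_threshold = 2,            # fold-change rule
    straighten = FALSE,          # warp gels before detection
    seed = 1L,
    verbosity = 1L)
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    y <- yaml::read_yaml(file)
    unknown <- setdiff(names(y), names(defaults))
    if (length(unknown) > 0)
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(y)] <- y
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  chk <- function(name, test, msg) {
    if (!isTRUE(test)) stop("config field '", name, "' ", msg)
  }
  chk("median_window", cfg$median_window %% 2 == 1 && cfg$median_window >= 3,
      "must be odd and >= 3")
  chk("tophat_radius", is.numeric(cfg$tophat_radius) && cfg$tophat_radius > 0,
      "must be positive")
  chk("symmetry_scales", is.numeric(cfg$symmetry_scales) &&
        all(cfg$symmetry_scales >= 1), "must be numeric >= 1")
  chk("log_sigma", is.numeric(cfg$log_sigma) && cfg$log_sigma > 0,
      "must be positive")
  chk("landmark_ratio", cfg$landmark_ratio > 0 && cfg$landmark_ratio < 1,
      "must lie in (0, 1)")
  chk("tps_lambda", is.numeric(cfg$tps_lambda) && cfg$tps_lambda >= 0,
      "must be >= 0")
  chk("pairing_gate", is.numeric(cfg$pairing_gate) && cfg$pairing_gate > 0,
      "must be positive")
  chk("fc_threshold", is.numeric(cfg$fc_threshold) && cfg$fc_threshold >= 1,
      "must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Run the full two-gel analysis pipeline
#'
#' Executes the stages in order — preprocessing (median smoothing,
#' optional straightening, background removal), master-gel selection,
#' spot detection and classification on both gels, landmark alignment
#' (rigid + thin-plate spline), spot pairing, quantification and
#' comparison — writing every intermediate artifact plus a manifest
#' (package version, configuration and its hash, seeds) into `out_dir`.
#' Re-running with identical inputs and configuration reproduces the
#' comparison table exactly.
#'
#' @param config a [pipeline_config()].
#' @param gels list of two [gel_image()]s, or paths readable by
#'   [read_gel()]. With `single = TRUE` a single gel is allowed and the
#'   run stops after detection/quantification.
#' @param out_dir artifact directory (created).
#' @param classifier optional pre-trained `region_classifier` (overrides
#'   the config's path).
#' @param single detection-only mode for one gel.
#' @return invisibly, a list with the key results (`spots`, `comparison`,
#'   `matches`, `master`, paths).
#' @export
run_pipeline <- function(config, gels, out_dir, classifier = NULL,
                         single = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.list(gels)) gels <- as.list(gels)
  gels <- lapply(gels, function(g)
    if (inherits(g, "gel_image")) g else read_gel(g))
  if (!single && length(gels) < 2)
    stop("stage preparation: need >= 2 gels (or set single = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbosity > 0) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  # -- preprocessing ---------------------------------------------------
  say("preprocessing ", length(gels), " gel(s)")
  pp <- stage("preprocess", lapply(gels, function(g) {
    sm <- median_smooth(g, config$median_window)
    if (isTRUE(config$straighten)) {
      prof <- distortion_profile(sm)
      sm <- straighten(sm, prof)
    }
    sig <- subtract_background(sm, config$tophat_radius)
    list(smooth = sm, signal = sig)
  }))
  for (i in seq_along(pp))
    write_gel(pp[[i]]$smooth, file.path(out_dir,
                                        sprintf("gel%d_preprocessed.tiff", i)))
  # -- master selection ------------------------------------------------
  # gels without enough horizontal row structure cannot be scored; fall
  # back to input order rather than aborting the run
  master <- if (length(gels) >= 2)
    tryCatch(select_master(lapply(pp, `[[`, "smooth")),
             error = function(e) {
               warning("master selection fell back to gel 1: ",
                       conditionMessage(e))
               1L
             }) else 1L
  say("master gel: ", master)
  # -- detection -------------------------------------------------------
  if (is.null(classifier)) {
    classifier <- if (!is.null(config$classifier_path))
      load_classifier(config$classifier_path)
    else stage("classifier_training",
               train_region_classifier(config$classifier_n,
                                       seed = config$classifier_seed))
  }
  # detection runs on the smoothed dark-polarity scan (the distribution
  # the classifier is trained on); the background-subtracted signal is
  # used for quantification only
  det <- stage("detection", lapply(pp, function(p)
    detect_spots(p$smooth, classifier,
                 scales = config$symmetry_scales,
                 log_sigma = config$log_sigma, polarity = "dark")))
  for (i in seq_along(det)) {
    utils::write.csv(det[[i]]$spots,
                     file.path(out_dir, sprintf("gel%d_spots.csv", i)),
                     row.names = FALSE)
  }
  quants <- stage("quantification", lapply(seq_along(det), function(i) {
    sp <- det[[i]]$spots
    vols <- region_volumes(pp[[i]]$signal, det[[i]]$regions,
                           ids = sp$id)
    data.frame(spot_id = sp$spot_id, row = sp$row, col = sp$col,
               volume = vols$volume,
               quantity = normalize_quantities(vols$volume))
  }))
  for (i in seq_along(quants))
    utils::write.csv(quants[[i]],
                     file.path(out_dir, sprintf("gel%d_quant.csv", i)),
                     row.names = FALSE)
  result <- list(master = master, spots = lapply(det, `[[`, "spots"),
                 out_dir = out_dir)
  # -- alignment + comparison -----------------------------------------
  if (!single && length(gels) >= 2) {
    other <- setdiff(seq_along(gels), master)[1]
    gA <- pp[[other]]$smooth; gB <- pp[[master]]$smooth
    lm <- stage("alignment", initial_landmarks(gA, gB,
                                               ratio = config$landmark_ratio))
    model <- stage("alignment", fit_tps(lm, lambda = config$tps_lambda))
    jsonlite::write_json(list(landmarks = lm,
                              affine = model$a, weights = model$W,
                              centers = model$src,
                              lambda = model$lambda,
                              bending_energy = model$bending_energy),
                         file.path(out_dir, "alignment.json"),
                         digits = NA, auto_unbox = TRUE)
    matching <- stage("pairing",
                      pair_spots(det[[other]]$spots, det[[master]]$spots,
                                 model, gate = config$pairing_gate))
    utils::write.csv(matching$matches,
                     file.path(out_dir, "matches.csv"), row.names = FALSE)
    # report the comparison in input order (first gel = G1), whichever
    # gel served as the registration master
    cmp_matching <- matching
    lo <- other; hi <- master
    if (other > master) {
      cmp_matching <- list(
        matches = data.frame(spot_id_A = matching$matches$spot_id_B,
                             spot_id_B = matching$matches$spot_id_A,
                             residual = matching$matches$residual),
        unmatched_A = matching$unmatched_B,
        unmatched_B = matching$unmatched_A)
      lo <- master; hi <- other
    }
    comparison <- stage("comparison",
                        compare_gels(quants[[lo]], quants[[hi]],
                                     cmp_matching,
                                     threshold = config$fc_threshold))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    render_overlay(gA, gB, model, file.path(out_dir, "overlay.png"))
    result$matches <- matching
    result$comparison <- comparison
  }
  # -- manifest --------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "gelmap2d",
    version = as.character(utils::packageVersion("gelmap2d")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    n_gels = length(gels),
    master = master,
    artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}
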