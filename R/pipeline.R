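# End-to-end driver: simulate a cohort of phantoms, run the proton and gas
# ventilation analyses per subject, compare the modalities regionally, and
# produce the cohort tables and run report.

#' Build a validated run configuration
#'
#' Collects the pipeline's tunable parameters with their pinned defaults:
#' the RVent defect threshold is 0.4 times the in-mask 90th percentile, the
#' FVL-CM defect threshold is 0.9, gas-grid slab thickness 15 mm, slab
#' defect vote 0.5.
#'
#' @param phantom A [phantom_config()] used as the template for simulated
#'   subjects.
#' @param n_subjects Cohort size.
#' @param n_diseased Number of obstructed ("COPD-like") subjects; the rest
#'   are healthy-like.
#' @param preful Proton-analysis options: `n_phases`, `smoothing_kernel`,
#'   `rvent_factor`, `rvent_percentile`, `fvlcm_threshold`, `register`.
#' @param xe Gas-analysis options: `edges`, `normalization_percentile`,
#'   `bias_order`.
#' @param compare Comparison options: `slab_thickness_mm`, `majority`.
#' @param seed Base seed for the cohort.
#' @param output_dir Optional directory for per-subject NIfTI and CSV
#'   outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       n_subjects = 20,
                       n_diseased = 14,
                       preful = list(),
                       xe = list(),
                       compare = list(),
                       seed = 1L,
                       output_dir = NULL) {
  preful_def <- list(n_phases = 8, smoothing_kernel = 3, rvent_factor = 0.4,
                     rvent_percentile = 0.9, fvlcm_threshold = 0.9,
                     register = TRUE)
  xe_def <- list(edges = c(0.16, 0.34, 0.52, 0.7, 0.88, 1),
                 normalization_percentile = 0.99, bias_order = 2)
  cmp_def <- list(slab_thickness_mm = 15, majority = 0.5)
  preful <- utils::modifyList(preful_def, preful)
  xe <- utils::modifyList(xe_def, xe)
  compare <- utils::modifyList(cmp_def, compare)
  if (preful$rvent_factor <= 0 || preful$rvent_factor >= 1) {
    stop_lungvent("rvent_factor must lie in (0, 1)",
                  class = "lungvent_config_error")
  }
  if (preful$fvlcm_threshold <= -1 || preful$fvlcm_threshold >= 1) {
    stop_lungvent("fvlcm_threshold must lie in (-1, 1)",
                  class = "lungvent_config_error")
  }
  if (n_diseased > n_subjects) {
    stop_lungvent("n_diseased cannot exceed n_subjects",
                  class = "lungvent_config_error")
  }
  structure(list(phantom = phantom, n_subjects = as.integer(n_subjects),
                 n_diseased = as.integer(n_diseased), preful = preful,
                 xe = xe, compare = compare, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Simulate and analyse a single subject
#'
#' Generates a phantom subject, runs the proton phase-resolved analysis and
#' the gas analysis, brings the proton defect maps onto the gas slab grid,
#' and measures regional agreement per marker.
#'
#' @param phantom_cfg The subject's [phantom_config()].
#' @param config A [run_config()] carrying the analysis options.
#' @return List with `record` (one-row data frame of VDPs and agreement
#'   metrics), `preful`, `xe`, `agreement` (per-marker
#'   [agreement_overlay()] results) and `truth`.
#' @export
simulate_subject <- function(phantom_cfg, config = run_config()) {
  sim <- generate_breathing_series(phantom_cfg)
  gaspair <- generate_gas_image(sim$truth, phantom_cfg)

  pf <- preful_analysis(sim$series,
                        n_phases = config$preful$n_phases,
                        register = config$preful$register,
                        smooth_kernel = config$preful$smoothing_kernel,
                        rvent_factor = config$preful$rvent_factor,
                        rvent_percentile = config$preful$rvent_percentile,
                        fvlcm_threshold = config$preful$fvlcm_threshold)
  xa <- xe_analysis(gaspair$gas, gaspair$anatomical, gaspair$seeds,
                    edges = config$xe$edges,
                    bias_order = config$xe$bias_order)

  agreement <- lapply(pf$defects, function(dm) {
    slab <- resample_to_slabs(dm,
                              target_thickness_mm = config$compare$slab_thickness_mm,
                              majority = config$compare$majority)
    reg <- coregister(slab, gaspair$gas)
    agreement_overlay(reg, xa$defect)
  })

  comb <- agreement$combined
  record <- data.frame(
    vdp_rvent = pf$vdp[["rvent"]],
    vdp_fvlcm = pf$vdp[["fvlcm"]],
    vdp_combined = pf$vdp[["combined"]],
    vdp_xe = xa$vdp,
    spatial_overlap_pct = comb$spatial_overlap_pct,
    dice_healthy = comb$dice_healthy,
    dice_defect = comb$dice_defect,
    true_defect_pct = 100 * mean(sim$truth$defect_labels[sim$truth$lung_mask] > 1L))
  list(record = record, preful = pf, xe = xa, agreement = agreement,
       truth = sim$truth, gas = gaspair)
}

subject_phantom_config <- function(template, group, subject_seed) {
  with_seed(subject_seed, {
    f <- if (group == "COPD") stats::runif(1, 0.12, 0.45) else
      stats::runif(1, 0, 0.02)
    cfg <- unclass(template)
    cfg$defect_fraction <- f
    cfg$seed <- subject_seed
    do.call(phantom_config, cfg)
  })
}

simulate_spirometry <- function(defect_fraction, subject_seed) {
  with_seed(subject_seed + 13L, {
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    data.frame(
      fev1_pct = clamp(98 - 130 * defect_fraction + stats::rnorm(1, 0, 7),
                       15, 130),
      fvc_pct = clamp(97 - 45 * defect_fraction + stats::rnorm(1, 0, 7),
                      30, 130),
      fev1_fvc_pct = clamp(97 - 100 * defect_fraction + stats::rnorm(1, 0, 6),
                           20, 130))
  })
}

#' Run the full simulated-cohort pipeline
#'
#' Simulates `n_subjects` phantom subjects (a diseased stratum with
#' substantial defect burden and a healthy stratum with near-zero burden),
#' analyses each with both modalities, and assembles the cohort outputs:
#' the per-subject record table, the median/IQR group summary, the VDP and
#' spirometry correlation table, and Bland-Altman comparisons of each
#' proton VDP against the gas VDP.
#'
#' @param config A [run_config()].
#' @param progress Print per-subject progress lines.
#' @return List of class `run_report` with `records`, `summary`,
#'   `correlations`, `bland_altman`, `thresholds` and `config`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  groups <- c(rep("COPD", config$n_diseased),
              rep("healthy", config$n_subjects - config$n_diseased))
  records <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subject_seed <- (config$seed + i * 101L) %% 2147483647L
    pcfg <- subject_phantom_config(config$phantom, groups[i], subject_seed)
    t0 <- Sys.time()
    sub <- simulate_subject(pcfg, config)
    rec <- cbind(data.frame(subject_id = sprintf("S%02d", i),
                            group = groups[i]),
                 sub$record,
                 simulate_spirometry(pcfg$defect_fraction, subject_seed))
    records[[i]] <- rec
    if (progress) {
      message(sprintf("%s (%s): VDP RVent %.1f / FVL-CM %.1f / Comb %.1f / Xe %.1f [%.1fs]",
                      rec$subject_id, rec$group, rec$vdp_rvent,
                      rec$vdp_fvlcm, rec$vdp_combined, rec$vdp_xe,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      sid <- sprintf("S%02d", i)
      write_defect_map(sub$preful$defects$combined,
                       file.path(config$output_dir,
                                 paste0(sid, "_vd_combined.nii.gz")))
      write_defect_map(sub$xe$defect,
                       file.path(config$output_dir,
                                 paste0(sid, "_vd_xe.nii.gz")))
    }
  }
  records <- do.call(rbind, records)

  ba <- list(
    rvent = bland_altman(records$vdp_xe, records$vdp_rvent),
    fvlcm = bland_altman(records$vdp_xe, records$vdp_fvlcm),
    combined = bland_altman(records$vdp_xe, records$vdp_combined))

  report <- structure(list(
    records = records,
    summary = cohort_summary(records),
    correlations = vdp_correlation_table(records),
    bland_altman = ba,
    thresholds = list(
      rvent = sprintf("%.2g x P%.0f of in-mask RVent",
                      config$preful$rvent_factor,
                      100 * config$preful$rvent_percentile),
      rvent_factor = config$preful$rvent_factor,
      rvent_percentile = 100 * config$preful$rvent_percentile,
      fvlcm_threshold = config$preful$fvlcm_threshold),
    config = config), class = "run_report")

  if (!is.null(config$output_dir)) {
    write_records(records, file.path(config$output_dir, "cohort.csv"))
    write_sidecar(unclass_deep(config),
                  file.path(config$output_dir, "run.json"))
  }
  report
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$records), " subjects (",
      sum(x$records$group == "COPD"), " diseased)\n", sep = "")
  med <- vapply(c("vdp_rvent", "vdp_fvlcm", "vdp_combined", "vdp_xe"),
                function(col) stats::median(x$records[[col]]), numeric(1))
  cat("  median VDP: RVent ", sprintf("%.1f", med[1]), "%, FVL-CM ",
      sprintf("%.1f", med[2]), "%, Combined ", sprintf("%.1f", med[3]),
      "%, Xe ", sprintf("%.1f", med[4]), "%\n", sep = "")
  invisible(x)
}
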