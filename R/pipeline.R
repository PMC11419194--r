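# Study configuration, end-to-end orchestration, and reporting.  Binds the
# simulator, prescan, reconstruction, quantification and relaxometry stages
# into one reproducible run driven by a config + seed.

#' Study configuration
#'
#' Builds the fully-specified, serializable configuration a pipeline run is
#' reproducible from.  Any field may be overridden; unknown fields are
#' rejected (typo guard).
#'
#' @param subject_id identifier written into the report.
#' @param seed master seed for every stochastic stage.
#' @param phantom list: `grid_shape`, `fov_cm`.
#' @param kinetics list of [kinetic_params()] arguments.
#' @param acquisition list of [acq_params()] arguments.
#' @param coils list: `n_channels`, `noise_sigma`, `rho`.
#' @param processing list: `noise_frames`, `fermi_cutoff`, `fermi_width`,
#'   `mask_threshold_k`, `zero_fill_factor`, `bolus_threshold`,
#'   `mean_time_reference` (NULL = study's own mean time, i.e. no trim),
#'   `candidates`, `tolerance_s`, `sample_sd`.
#' @param output_dir directory for artifacts (NULL = in-memory run).
#' @return nested list of class `study_config`.
#' @export
study_config <- function(subject_id = "phantom-01", seed = 1L,
                         phantom = list(), kinetics = list(),
                         acquisition = list(), coils = list(),
                         processing = list(), output_dir = NULL) {
  defaults <- list(
    subject_id = subject_id,
    seed = as.integer(seed),
    phantom = list(grid_shape = c(64L, 64L), fov_cm = 50),
    kinetics = list(kpl = c(0.13, 0.091, 0), kpb = c(0.013, 0.0095, 0),
                    t1_pyr = 30, t1_lac = 25, t1_bic = 25,
                    aif_t0 = 18, aif_alpha = 2.5, aif_beta = 4.5,
                    aif_amplitude = 100),
    acquisition = list(temporal_resolution_s = 3.5, n_timepoints = 30L,
                       inplane_res_cm = c(pyruvate = 1, lactate = 1,
                                          bicarbonate = 2)),
    coils = list(n_channels = 8L, noise_sigma = 11, rho = 0.2),
    processing = list(noise_frames = 5L, fermi_cutoff = 0.85,
                      fermi_width = 0.05, mask_threshold_k = 3,
                      zero_fill_factor = 2L, bolus_threshold = 2,
                      mean_time_reference = NULL, candidates = c(3L, 4L),
                      tolerance_s = NULL, sample_sd = FALSE),
    output_dir = output_dir
  )
  user <- list(phantom = phantom, kinetics = kinetics,
               acquisition = acquisition, coils = coils,
               processing = processing)
  for (sec in names(user)) {
    extra <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(extra)) {
      stop(sprintf("unknown %s option(s): %s", sec, paste(extra, collapse = ", ")))
    }
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(defaults, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Unknown keys at any validated level are an error.
#'
#' @param path YAML file.
#' @return `study_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("subject_id", "seed", "phantom", "kinetics", "acquisition",
                 "coils", "processing", "output_dir")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  args <- raw[intersect(names(raw), known_top)]
  for (sec in c("phantom", "kinetics", "acquisition", "coils", "processing")) {
    if (is.null(args[[sec]])) args[[sec]] <- list()
    args[[sec]] <- lapply(args[[sec]], function(v) if (is.list(v)) unlist(v) else v)
  }
  if (!is.null(args$acquisition$inplane_res_cm)) {
    v <- args$acquisition$inplane_res_cm
    if (is.null(names(v)) || !all(c("pyruvate", "lactate", "bicarbonate") %in% names(v))) {
      stop("acquisition$inplane_res_cm must be named pyruvate/lactate/bicarbonate")
    }
  }
  do.call(study_config, args)
}

#' Serialize a study configuration to YAML
#'
#' @param cfg a `study_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(named_vectors_to_lists(unclass(cfg)), path)
  invisible(path)
}

# named atomic vectors serialize as YAML/JSON maps so names survive the trip
#' @noRd
named_vectors_to_lists <- function(x) {
  if (is.list(x)) return(lapply(x, named_vectors_to_lists))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Run the full pipeline on one (simulated) study
#'
#' simulate -> bolus detection -> noise covariance / pre-whitening ->
#' sensitivity estimation -> matched-filter combination -> mean-time
#' correction -> AUC maps (voxel-size normalized, Fermi-zero-filled) ->
#' ratio maps and ROI statistics -> ADC / R2* fits -> report row.  When
#' `cfg$output_dir` is set, maps are written as NIfTI and the report as
#' CSV + JSON with a hash manifest.
#'
#' @param cfg a [study_config()].
#' @return list of class `pipeline_result`: `report_row` (one-row
#'   data.frame), `ratio_maps`, `auc_maps`, `auc_snr`, `bolus`, `recon`,
#'   `study`, `frames_removed`, `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  spec <- phantom_spec(grid_shape = cfg$phantom$grid_shape,
                       fov_cm = cfg$phantom$fov_cm, seed = cfg$seed)
  kp <- do.call(kinetic_params, cfg$kinetics)
  acq <- do.call(acq_params, cfg$acquisition)
  coil <- coil_model(spec, n_channels = cfg$coils$n_channels,
                     noise_sigma = cfg$coils$noise_sigma, rho = cfg$coils$rho)
  study <- simulate_study(spec, kp, acq, coil, seed = cfg$seed)

  # prescan: noise floor from the first (pre-injection) frame, coil-RSS
  pyr_rss <- sqrt(apply(Mod(study$channels$pyruvate$data)^2, c(1, 2, 3), sum))
  noise_level <- prescan_noise_level(pyr_rss[, , 1, drop = FALSE])
  bolus <- detect_bolus(pyr_rss, noise_level = noise_level,
                        threshold_factor = cfg$processing$bolus_threshold,
                        times = study$channels$pyruvate$times)

  recon <- reconstruct_study(study, n_noise_frames = cfg$processing$noise_frames,
                             mask_threshold_k = cfg$processing$mask_threshold_k)

  kmask <- kidney_mask(spec)
  ref_mt <- cfg$processing$mean_time_reference
  if (is.null(ref_mt)) {
    mtc <- mean_time_correct(recon$combined$pyruvate, reference_mean_time = Inf,
                             roi = kmask, candidates = cfg$processing$candidates,
                             tolerance_s = Inf)           # no-trim path
    mtc$frames_removed <- 0L
  } else {
    mtc <- mean_time_correct(recon$combined$pyruvate, reference_mean_time = ref_mt,
                             roi = kmask, candidates = cfg$processing$candidates,
                             tolerance_s = cfg$processing$tolerance_s)
  }
  nrem <- mtc$frames_removed

  ref_area <- acq$inplane_res_cm[["pyruvate"]]^2
  auc_maps <- lapply(recon$combined, compute_auc_map, frames_removed = nrem)

  # AUC SNR on the acquired scale (noise-level normalization, reported
  # separately from the ratios), before any voxel-size normalization
  snr_maps <- lapply(names(auc_maps), function(m) {
    sig <- estimate_auc_noise(recon$combined[[m]],
                              n_frames_used = auc_maps[[m]]$n_frames_used,
                              n_last_frames = cfg$processing$noise_frames,
                              mask = !recon$sensitivity$support_mask)
    auc_snr(auc_maps[[m]], sig)
  })
  names(snr_maps) <- names(auc_maps)

  auc_maps$bicarbonate <- normalize_voxel_size(auc_maps$bicarbonate, ref_area)

  # Fermi-filtered zero-fill to the reporting grid
  zf <- cfg$processing$zero_fill_factor
  target <- spec$grid_shape * zf
  auc_zf <- lapply(auc_maps, function(a) {
    a$values <- pmax(fermi_zero_fill(a$values, target,
                                     cutoff_frac = cfg$processing$fermi_cutoff,
                                     width_frac = cfg$processing$fermi_width), 0)
    a
  })
  kmask_zf <- upsample_nearest(kmask, target)
  cortex_zf <- upsample_nearest(spec$labels == 1L, target)

  ratio <- list(
    lactate = metabolite_ratio_map(auc_zf$lactate, auc_zf$pyruvate, kmask_zf),
    bicarbonate = metabolite_ratio_map(auc_zf$bicarbonate, auc_zf$pyruvate, kmask_zf)
  )
  ssd <- isTRUE(cfg$processing$sample_sd)
  lp <- roi_stats(ratio$lactate, cortex_zf, sample_sd = ssd)
  bp <- roi_stats(ratio$bicarbonate, cortex_zf, sample_sd = ssd)

  adc_fit <- fit_adc(study$dwi, mask = kmask)
  r2_fit <- fit_r2star(study$multiecho, mask = kmask)
  cortex <- spec$labels == 1L
  adc_cortex <- mean(adc_fit$adc[cortex & adc_fit$valid])
  r2_cortex <- mean(r2_fit$r2star[cortex & r2_fit$valid])

  report_row <- data.frame(
    subject_id = cfg$subject_id,
    roi = "cortex",
    lac_pyr_mean = lp$mean, lac_pyr_sd = lp$sd,
    bic_pyr_mean = bp$mean, bic_pyr_sd = bp$sd,
    adc_mm2_s = adc_cortex,
    r2star_s1 = r2_cortex,
    bolus_time_s = bolus$trigger_time_s,
    frames_removed = nrem,
    pyr_auc_snr = roi_stats(snr_maps$pyruvate, kmask)$mean,
    lac_auc_snr = roi_stats(snr_maps$lactate, kmask)$mean,
    bic_auc_snr = roi_stats(snr_maps$bicarbonate, kmask)$mean,
    stringsAsFactors = FALSE
  )

  result <- structure(
    list(report_row = report_row, ratio_maps = ratio, auc_maps = auc_zf,
         auc_snr = snr_maps, bolus = bolus, recon = recon, study = study,
         frames_removed = nrem, config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(cfg$output_dir)) write_pipeline_artifacts(result, cfg$output_dir)
  result
}

#' @noRd
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wn <- function(img, name) {
    p <- file.path(out_dir, name)
    RNifti::writeNifti(RNifti::asNifti(img), p)
    files <<- c(files, p)
  }
  for (m in names(result$auc_maps)) {
    wn(result$auc_maps[[m]]$values, sprintf("auc_%s.nii.gz", m))
  }
  for (m in names(result$ratio_maps)) {
    v <- result$ratio_maps[[m]]$values
    v[is.na(v)] <- -1   # NIfTI has no NA; sentinel documented in sidecar
    wn(v, sprintf("ratio_%s_to_pyruvate.nii.gz", m))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(result$config, cfg_path)
  files <- c(files, cfg_path)
  report <- quant_report(list(result))
  files <- c(files, write_report(report, file.path(out_dir, "report")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(files)
}

#' Assemble a quantification report over one or more pipeline runs
#'
#' @param results list of `pipeline_result` objects.
#' @return object of class `quant_report`: `subjects` (data.frame, one row
#'   per run) and `groups` (data.frame of mean / min / max per measure).
#' @export
quant_report <- function(results) {
  stopifnot(length(results) >= 0)
  rows <- do.call(rbind, lapply(results, function(r) r$report_row))
  if (is.null(rows)) {
    rows <- run_pipeline_empty_rows()
  }
  measures <- c("lac_pyr_mean", "bic_pyr_mean", "adc_mm2_s", "r2star_s1",
                "bolus_time_s")
  groups <- do.call(rbind, lapply(measures, function(m) {
    v <- rows[[m]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      data.frame(measure = m, mean = NA_real_, min = NA_real_, max = NA_real_,
                 n_subjects = 0L, stringsAsFactors = FALSE)
    } else {
      g <- group_summary(v)
      data.frame(measure = m, mean = g$mean, min = g$min, max = g$max,
                 n_subjects = g$n_subjects, stringsAsFactors = FALSE)
    }
  }))
  structure(list(subjects = rows, groups = groups), class = "quant_report")
}

#' @noRd
run_pipeline_empty_rows <- function() {
  data.frame(subject_id = character(0), roi = character(0),
             lac_pyr_mean = numeric(0), lac_pyr_sd = numeric(0),
             bic_pyr_mean = numeric(0), bic_pyr_sd = numeric(0),
             adc_mm2_s = numeric(0), r2star_s1 = numeric(0),
             bolus_time_s = numeric(0), frames_removed = integer(0),
             pyr_auc_snr = numeric(0), lac_auc_snr = numeric(0),
             bic_auc_snr = numeric(0), stringsAsFactors = FALSE)
}

#' Format a mean +/- SD cell to two decimals
#'
#' `0.4233, 0.0351` becomes `"0.42±0.04"`.
#'
#' @param mean,sd numeric scalars.
#' @param digits decimals (default 2).
#' @return character scalar.
#' @export
format_mean_sd <- function(mean, sd, digits = 2) {
  if (!is.finite(mean) || !is.finite(sd)) return("N/A")
  sprintf(paste0("%.", digits, "f±%.", digits, "f"), mean, sd)
}

#' Write a quantification report as CSV and JSON
#'
#' The CSV mirrors a clinical summary table: one row per subject with
#' `mean +/- SD` ratio cells to two decimals; group means are written to
#' three decimals.  The JSON carries full precision for round-tripping.
#'
#' @param report a [quant_report()].
#' @param path base path (without extension); `.csv` and `.json` are added.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "quant_report"))
  s <- report$subjects
  fmt <- function(m, sd) {
    if (length(m) == 0L) character(0) else
      mapply(format_mean_sd, m, sd, USE.NAMES = FALSE)
  }
  tab <- data.frame(
    subject_id = s$subject_id,
    roi = s$roi,
    lactate_to_pyruvate = fmt(s$lac_pyr_mean, s$lac_pyr_sd),
    bicarbonate_to_pyruvate = fmt(s$bic_pyr_mean, s$bic_pyr_sd),
    adc_mm2_s = s$adc_mm2_s,
    r2star_s1 = s$r2star_s1,
    bolus_time_s = s$bolus_time_s,
    frames_removed = s$frames_removed,
    stringsAsFactors = FALSE
  )
  csv <- paste0(path, ".csv")
  con <- file(csv, open = "w", encoding = "UTF-8")
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  g <- report$groups
  g$mean <- round(g$mean, 3); g$min <- round(g$min, 3); g$max <- round(g$max, 3)
  json <- paste0(path, ".json")
  jsonlite::write_json(
    list(subjects = report$subjects, groups = g),
    json, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(c(csv, json))
}

#' Read back a JSON quantification report
#'
#' @param path the `.json` file written by [write_report()].
#' @return `quant_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(subjects = as.data.frame(raw$subjects),
                 groups = as.data.frame(raw$groups)),
            class = "quant_report")
}
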