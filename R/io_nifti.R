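# Persistence of dynamic studies: 4D NIfTI volumes per metabolite (complex
# data as a real/imaginary pair) plus a JSON sidecar with acquisition
# parameters, ground truth (when simulated) and the seed.

#' Write a dynamic study to NIfTI + JSON sidecar
#'
#' Each metabolite's (y, x, time, channel) complex series is stored as a
#' pair of 4D NIfTI volumes `<met>_real.nii.gz` / `<met>_imag.nii.gz`; the
#' sidecar `study.json` records timing, acquisition parameters, seed and —
#' for simulated studies — the kinetic ground truth.
#'
#' @param study an `hp_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (m in names(study$channels)) {
    d <- study$channels[[m]]$data
    re <- file.path(dir, sprintf("%s_real.nii.gz", m))
    im <- file.path(dir, sprintf("%s_imag.nii.gz", m))
    RNifti::writeNifti(RNifti::asNifti(Re(d)), re)
    RNifti::writeNifti(RNifti::asNifti(Im(d)), im)
    files <- c(files, re, im)
  }
  side <- list(
    seed = study$seed,
    times_s = study$channels$pyruvate$times,
    acquisition = named_vectors_to_lists(unclass(study$acq)),
    kinetics_ground_truth = unclass(study$kp),
    grid_shape = study$spec$grid_shape,
    fov_cm = study$spec$fov_cm
  )
  sp <- file.path(dir, "study.json")
  jsonlite::write_json(side, sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, sp)
  invisible(files)
}

#' Read a dynamic study written by [write_study()]
#'
#' @param dir directory holding the NIfTI pairs and `study.json`.
#' @return list with `channels` (named `multichannel_dynamic`s), `acq`,
#'   `seed` — the subset of an `hp_study` the reconstruction consumes.
#' @export
read_study <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  acq_args <- lapply(side$acquisition[
    intersect(names(side$acquisition), names(formals(acq_params)))],
    function(v) if (is.list(v)) unlist(v) else v)
  acq <- do.call(acq_params, acq_args)
  channels <- list()
  for (m in c("pyruvate", "lactate", "bicarbonate")) {
    re <- file.path(dir, sprintf("%s_real.nii.gz", m))
    if (!file.exists(re)) next
    strip <- function(p) {
      v <- RNifti::readNifti(p)
      array(as.numeric(v), dim = dim(v))
    }
    re_a <- strip(re)
    im_p <- file.path(dir, sprintf("%s_imag.nii.gz", m))
    im_a <- if (file.exists(im_p)) strip(im_p) else 0
    channels[[m]] <- multichannel_dynamic(
      re_a + 1i * im_a, metabolite = m, times = side$times_s, acq = acq
    )
  }
  list(channels = channels, acq = acq, seed = side$seed)
}
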