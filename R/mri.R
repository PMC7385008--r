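#' In-plane voxel size of an MR acquisition
#'
#' `voxel = FOV / matrix` for a square acquisition matrix with no
#' interpolation.
#'
#' @param fov_mm field of view, mm.
#' @param matrix_px acquisition matrix size, pixels.
#' @return voxel size in mm.
#' @export
mri_voxel_size <- function(fov_mm, matrix_px) {
  if (any(fov_mm <= 0) || any(matrix_px <= 0)) {
    stop("fov_mm and matrix_px must be > 0")
  }
  fov_mm / matrix_px
}

#' Acquisition parameters of the two study sequences
#'
#' The time-of-flight (ToF) and multi-echo data image combination (MEDIC)
#' protocols used to image the phantoms and patients: field of view,
#' acquisition matrix (square, no interpolation) and slice thickness.
#'
#' @return data.frame with one row per sequence and columns `sequence`,
#'   `fov_mm`, `matrix_px`, `slice_thickness_mm`.
#' @export
mri_sequence_params <- function() {
  data.frame(
    sequence = c("tof", "medic"),
    fov_mm = c(140, 136),
    matrix_px = c(512L, 512L),
    slice_thickness_mm = c(1.5, 1.06),
    stringsAsFactors = FALSE
  )
}
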