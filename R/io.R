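# NIfTI / sidecar I/O for pipeline artifacts.

voxdim_affine <- function(voxel_size) {
  a <- diag(4)
  a[1, 1] <- voxel_size[1]; a[2, 2] <- voxel_size[2]; a[3, 3] <- voxel_size[3]
  a
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param x numeric array; NA is written as `na` (default 0, the
#'   displayed-map convention for flagged voxels).
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size mm per axis.
#' @param na value substituted for NA.
#' @export
write_nifti_map <- function(x, path, voxel_size = c(1, 1, 1), na = 0) {
  x[is.na(x)] <- na
  img <- RNifti::asNifti(x, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path .nii/.nii.gz path.
#' @export
read_nifti_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write an ASE series with its JSON sidecar
#'
#' The sidecar records `taus_ms` and `TE_ms`, the acquisition metadata the
#' fit needs.
#' @param series an [ase_series()].
#' @param path .nii/.nii.gz path; the sidecar replaces the extension with
#'   .json.
#' @param voxel_size mm per axis.
#' @export
write_ase_series <- function(series, path, voxel_size = c(1, 1, 1)) {
  write_nifti_map(series$data, path, voxel_size)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(taus_ms = series$taus_ms, TE_ms = series$TE_ms,
                            TI_ms = series$TI_ms),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ASE series written by [write_ase_series()]
#' @param path the .nii/.nii.gz path.
#' @export
read_ase_series <- function(path) {
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  ase_series(read_nifti_map(path), taus_ms = side$taus_ms,
             TE_ms = side$TE_ms, TI_ms = side$TI_ms)
}

#' Write sqBOLD maps as NIfTI volumes
#'
#' Flagged (NA) voxels are zero-filled, matching the convention that error
#' voxels are zeroed out in displayed maps; the error mask itself is
#' written alongside.
#' @param maps a `qbold_maps`.
#' @param dir output directory.
#' @param voxel_size mm per axis.
#' @export
write_qbold_maps <- function(maps, dir, voxel_size = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("R2prime", "DBV", "OEF", "fit_residual")) {
    write_nifti_map(maps[[f]], file.path(dir, paste0(f, ".nii.gz")),
                    voxel_size)
  }
  write_nifti_map(maps$error_mask, file.path(dir, "error_mask.nii.gz"),
                  voxel_size)
  invisible(dir)
}

#' Example brain-tumor cohort table
#'
#' Characteristics of a ten-patient glioma / brain-metastasis cohort used
#' as the worked aggregation example: per patient, age, sex, diagnosis,
#' diagnostic group and the number of targeted biopsies per tumor
#' compartment.
#'
#' @return data frame with one row per patient.
#' @export
patient_characteristics <- function() {
  path <- system.file("extdata", "patient_characteristics.csv",
                      package = "hypoxmap")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate a cohort table into sample counts and group mean ages
#'
#' @param patients data frame as returned by [patient_characteristics()].
#' @return list with `n_total` biopsies, per-compartment counts, and the
#'   rounded mean age per diagnostic group.
#' @export
cohort_summary <- function(patients = patient_characteristics()) {
  list(
    n_total = sum(patients$n_necrosis + patients$n_enhancing +
                    patients$n_nonenhancing),
    n_necrosis = sum(patients$n_necrosis),
    n_enhancing = sum(patients$n_enhancing),
    n_nonenhancing = sum(patients$n_nonenhancing),
    mean_age_glioma = round(mean(patients$age[patients$group == "glioma"])),
    mean_age_metastasis = round(mean(patients$age[patients$group == "metastasis"])))
}
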