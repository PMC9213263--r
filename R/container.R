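# Raw-data container I/O and NIfTI export.

CONTAINER_SCHEMA <- 1L
CONTAINER_FIELDS <- c("kspace", "lines", "inav", "trajectory", "coils",
                      "params", "truth")

#' Save a simulated raw-data container
#'
#' Serializes the full raw-data bundle (dual-echo multi-coil k-space lines,
#' line table, navigator stack, trajectory, coil maps, acquisition
#' parameters and simulation truth) as a single versioned file.
#'
#' @param scan output of [simulate_scan()]
#' @param path file path
#' @export
save_container <- function(scan, path) {
  missing <- setdiff(CONTAINER_FIELDS, names(scan))
  if (length(missing))
    stop("container is missing fields: ", paste(missing, collapse = ", "))
  obj <- scan[CONTAINER_FIELDS]
  obj$schema_version <- CONTAINER_SCHEMA
  saveRDS(obj, path)
  invisible(path)
}

#' Load a raw-data container
#'
#' @param path file path written by [save_container()]
#' @return the raw-data bundle (same structure as [simulate_scan()] output)
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stop("container file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable container: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) || obj$schema_version != CONTAINER_SCHEMA)
    stop("container schema_version mismatch (expected ", CONTAINER_SCHEMA,
         ")")
  missing <- setdiff(CONTAINER_FIELDS, names(obj))
  if (length(missing))
    stop("container is missing fields: ", paste(missing, collapse = ", "))
  obj[CONTAINER_FIELDS]
}

#' Write a volume as NIfTI
#'
#' Magnitude is written for complex input; the affine encodes the voxel
#' size.
#'
#' @param vol 3D array (real or complex)
#' @param path output path (`.nii` / `.nii.gz`)
#' @param voxel_mm length-3 voxel size (mm)
#' @export
write_volume <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  if (is.complex(vol)) vol <- Mod(vol)
  img <- RNifti::asNifti(array(as.double(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
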