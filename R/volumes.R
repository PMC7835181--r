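#' Dynamic image volumes
#'
#' Minimal container for a 4D dynamic PET dataset: a voxel array
#' `(x, y, z, frame)` in kBq/mL plus its [frame_schedule()] and voxel size.
#' Together with an integer label volume it supports regional TAC extraction
#' and voxel-wise Logan mapping; it deliberately knows nothing about
#' reconstruction, registration or atlases.
#'
#' @param data 4D numeric array `(x, y, z, frame)`.
#' @param schedule A [frame_schedule()]; its length must equal `dim(data)[4]`.
#' @param voxel_size_mm Numeric length-3 voxel size, mm.
#' @return An object of class `dynamic_volume`.
#' @export
dynamic_volume <- function(data, schedule, voxel_size_mm = c(2, 2, 2)) {
  schedule <- as_schedule(schedule)
  if (length(dim(data)) != 4L) abort("data must be a 4D array (x, y, z, frame)")
  if (dim(data)[4] != nrow(schedule)) {
    abort("frame axis length must equal the schedule length")
  }
  structure(
    list(data = data, schedule = schedule, voxel_size_mm = voxel_size_mm),
    class = "dynamic_volume"
  )
}

#' Read / write dynamic and label volumes (NIfTI-1)
#'
#' Thin wrappers around RNifti. The frame schedule is not stored in NIfTI
#' headers, so it must be supplied on read.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param schedule A [frame_schedule()] for the 4D data.
#' @param volume A [dynamic_volume()] (or 3D array for labels/maps).
#' @return `read_dynamic_volume()` returns a [dynamic_volume()];
#'   `read_label_volume()` an integer 3D array.
#' @export
read_dynamic_volume <- function(path, schedule) {
  img <- RNifti::readNifti(path)
  dynamic_volume(array(as.numeric(img), dim = dim(img)), schedule,
    voxel_size_mm = RNifti::pixdim(img)[1:3]
  )
}

#' @rdname read_dynamic_volume
#' @export
write_volume <- function(volume, path) {
  data <- if (inherits(volume, "dynamic_volume")) volume$data else volume
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

#' @rdname read_dynamic_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.integer(img), dim = dim(img))
}

#' Extract regional mean TACs from a dynamic volume
#'
#' Averages voxel TACs within each labelled region of an integer label volume
#' congruent with the dynamic grid. This is deliberate plumbing that stands in
#' for atlas-based parcellation: any labelling scheme that produces an integer
#' volume can feed it.
#'
#' @param volume A [dynamic_volume()].
#' @param labels Integer 3D array, same grid as `volume`; 0 = background.
#' @param region_map Named integer vector mapping region names to label
#'   values, e.g. `c(hippocampus = 1, brainstem = 2)`.
#' @param decay_corrected Flag recorded on the extracted curves.
#' @return A TAC table (see [tac_table()]) with one column per region, with a
#'   `voxel_counts` attribute (named integer vector). Labels present in the
#'   volume but missing from `region_map` trigger a warning and are skipped.
#' @export
extract_regional_tacs <- function(volume, labels, region_map,
                                  decay_corrected = TRUE) {
  stopifnot(inherits(volume, "dynamic_volume"))
  if (!identical(dim(labels), dim(volume$data)[1:3])) {
    abort("label volume grid must match the dynamic volume grid")
  }
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  unmapped <- setdiff(present, as.integer(region_map))
  if (length(unmapped)) {
    warn(paste0(
      "labels without region name skipped: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  nf <- nrow(volume$schedule)
  flat <- matrix(volume$data, ncol = nf) # voxels x frames
  lab <- as.integer(labels)
  counts <- integer(0)
  tacs <- list()
  for (nm in names(region_map)) {
    lv <- as.integer(region_map[[nm]])
    idx <- which(lab == lv)
    if (!length(idx)) next
    tacs[[nm]] <- tac(volume$schedule, colMeans(flat[idx, , drop = FALSE]),
      label = nm, decay_corrected = decay_corrected
    )
    counts[nm] <- length(idx)
  }
  if (!length(tacs)) abort("no mapped region present in the label volume")
  out <- tac_table(tacs)
  attr(out, "voxel_counts") <- counts
  out
}
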