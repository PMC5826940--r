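# NIfTI and YAML interchange.

#' Write a tissue label volume (or any 3D array) as NIfTI-1
#'
#' Integer arrays are written with an integer datatype; the grid-centered
#' RAS affine is recorded in the sform.
#'
#' @param x A `tissue_volume`, a `roi_set` mask, or a bare 3D array.
#' @param path Output `.nii` path.
#' @param voxel_size Required for bare arrays.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, voxel_size = NULL) {
  if (inherits(x, "tissue_volume")) {
    arr <- x$labels
    vs <- x$voxel_size
    aff <- x$affine
  } else {
    arr <- x
    if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
    vs <- voxel_size
    aff <- grid_affine(dim(arr), vs)
  }
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr, pixdim = rep(vs, 3))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tissue label volume from NIfTI-1
#'
#' @param path `.nii`/`.nii.gz` file with integer labels following the
#'   package label scheme (see [tissue_labels()]).
#' @return A `tissue_volume` (the file's affine is preserved).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(img[]), dim(img))
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  vs <- sqrt(sum(aff[1:3, 1]^2))  # voxel edge from the recorded affine
  vol <- new_tissue_volume(labels, vs)
  vol$affine <- aff
  vol
}

#' Export the scalar maps of a field solution as NIfTI volumes
#'
#' Writes `phi.nii`, `E_mag.nii` and, when present, `E_n.nii` aligned to the
#' solution grid.
#'
#' @param solution A `field_solution`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_field_nifti <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- solution$voxel_size
  paths <- character(0)
  maps <- list(phi = solution$phi, E_mag = solution$E_mag, E_n = solution$E_n)
  for (nm in names(maps)) {
    if (is.null(maps[[nm]])) next
    arr <- maps[[nm]]
    arr[is.na(arr)] <- 0
    p <- file.path(dir, paste0(nm, ".nii"))
    write_volume_nifti(arr, p, voxel_size = vs)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a phantom specification as YAML
#' @param spec A [phantom_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_yaml <- function(spec, path) {
  yaml::write_yaml(list(
    grid_shape = as.integer(spec$grid_shape),
    voxel_size = spec$voxel_size,
    shell_radii = as.list(spec$shell_radii),
    air_cavity = spec$air_cavity,
    scale = spec$scale,
    perturbation = spec$perturbation,
    seed = spec$seed), path)
  invisible(path)
}

#' Read a phantom specification from YAML
#' @param path YAML path written by [write_phantom_yaml()].
#' @return A [phantom_spec()].
#' @export
read_phantom_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(
    grid_shape = unlist(y$grid_shape),
    voxel_size = y$voxel_size,
    shell_radii = unlist(y$shell_radii),
    air_cavity = y$air_cavity,
    scale = unlist(y$scale) %||% c(1, 1, 1),
    perturbation = y$perturbation %||% list(),
    seed = y$seed %||% 1L)
}
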