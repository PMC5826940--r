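# Prescribing target ROIs from external sources: affine transforms between
# coordinate spaces, mapping point coordinates onto a label atlas, and
# extracting ROI masks from an atlas into a target grid.

#' Coordinate table constructor
#'
#' Rows of reported activation/morphometry coordinates: source tag, space
#' tag (e.g. `"MNI"`, `"TAL"`), world coordinates in mm (RAS) and a modality
#' tag.
#'
#' @param source,space,x,y,z,modality Column vectors (recycled as usual).
#' @return Data frame of class `coordinate_table`.
#' @export
coordinate_table <- function(source, space, x, y, z, modality = NA_character_) {
  if (!all(is.finite(c(x, y, z)))) stop("coordinates must be finite")
  structure(
    data.frame(source = source, space = space, x = x, y = y, z = z,
               modality = modality, stringsAsFactors = FALSE),
    class = c("coordinate_table", "data.frame"))
}

#' Read a coordinate table from CSV
#'
#' Expects a header `source, space, x, y, z, modality` (modality optional).
#'
#' @param path CSV file path.
#' @return A `coordinate_table`.
#' @export
read_coordinate_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "space", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("coordinate CSV needs columns ", paste(need, collapse = ", "))
  coordinate_table(d$source, d$space, d$x, d$y, d$z,
                   if ("modality" %in% names(d)) d$modality else NA_character_)
}

#' Apply a 4x4 affine transform to a coordinate table
#'
#' Homogeneous-coordinate mapping of every row, e.g. a Talairach-to-MNI
#' transform supplied via configuration. The space tag is updated.
#'
#' @param coords A `coordinate_table`.
#' @param transform Invertible 4x4 matrix.
#' @param new_space Space tag for the output (default appends `"*"`).
#' @return Transformed `coordinate_table`.
#' @export
apply_affine <- function(coords, transform, new_space = NULL) {
  stopifnot(is.matrix(transform), all(dim(transform) == c(4, 4)))
  if (abs(det(transform)) < 1e-12)
    stop("transform is singular (determinant ~ 0)")
  xyz1 <- t(cbind(coords$x, coords$y, coords$z, 1))
  out <- t(transform %*% xyz1)
  res <- coords
  res$x <- out[, 1]; res$y <- out[, 2]; res$z <- out[, 3]
  res$space <- new_space %||% paste0(unique(coords$space)[1], "*")
  res
}

#' Map coordinates to named atlas regions
#'
#' World-to-voxel lookup through the atlas affine (nearest voxel); rows
#' falling outside the atlas or on the background label are flagged
#' `"unassigned"` rather than dropped.
#'
#' @param coords A `coordinate_table` in the atlas's space.
#' @param atlas List with `labels` (integer 3D array) and `affine`
#'   (voxel-to-world, 0-based voxel indices), e.g. from [read_atlas()].
#' @param name_table Data frame with columns `label`, `name` (and optionally
#'   `laterality`) covering the atlas labels.
#' @return The coordinate table with a `region` column appended.
#' @export
map_to_atlas <- function(coords, atlas, name_table) {
  stopifnot(!is.null(atlas$labels), !is.null(atlas$affine))
  if (abs(det(atlas$affine)) < 1e-12) stop("atlas affine is singular")
  inv <- solve(atlas$affine)
  dm <- dim(atlas$labels)
  vox <- t(inv %*% t(cbind(coords$x, coords$y, coords$z, 1)))[, 1:3,
                                                              drop = FALSE]
  ijk <- round(vox) + 1  # to 1-based indices
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
  region <- rep("unassigned", nrow(coords))
  if (any(inside)) {
    lab <- atlas$labels[ijk[inside, , drop = FALSE]]
    hit <- match(lab, name_table$label)
    nm <- ifelse(lab == 0 | is.na(hit), "unassigned", name_table$name[hit])
    region[inside] <- nm
  }
  res <- coords
  res$region <- region
  res
}

#' Extract an ROI set from a label atlas into a target volume grid
#'
#' Nearest-neighbor resampling through both affines: each target voxel
#' center is mapped to world space and then into the atlas; its mask value
#' is that of the nearest atlas voxel, so no new labels are created.
#' Laterality is inferred from the `name_table` `laterality` column when
#' present, else from a `_L`/`_R` name suffix.
#'
#' @param atlas List with `labels` and `affine` (see [map_to_atlas()]).
#' @param name_table Data frame `label`, `name` (+ optional `laterality`).
#' @param regions Character vector of region names to extract.
#' @param target_volume A `tissue_volume` defining the output grid.
#' @return A `roi_set`.
#' @export
roiset_from_atlas <- function(atlas, name_table, regions, target_volume) {
  stopifnot(inherits(target_volume, "tissue_volume"))
  missing <- setdiff(regions, name_table$name)
  if (length(missing) > 0)
    stop("region(s) absent from the atlas name table: ",
         paste(missing, collapse = ", "))
  inv <- solve(atlas$affine)
  dm <- target_volume$dim
  adm <- dim(atlas$labels)
  # target voxel centers -> world -> atlas voxel (nearest neighbor)
  ijk <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  world <- t(target_volume$affine %*% t(cbind(ijk, 1)))[, 1:3, drop = FALSE]
  avox <- round(t(inv %*% t(cbind(world, 1)))[, 1:3, drop = FALSE]) + 1
  inside <- avox[, 1] >= 1 & avox[, 1] <= adm[1] &
    avox[, 2] >= 1 & avox[, 2] <= adm[2] &
    avox[, 3] >= 1 & avox[, 3] <= adm[3]
  lab <- rep(0L, nrow(avox))
  lab[inside] <- atlas$labels[avox[inside, , drop = FALSE]]
  masks <- list()
  info <- list()
  for (rn in regions) {
    codes <- name_table$label[name_table$name == rn]
    mask <- array(lab %in% codes, dm)
    if (!any(mask))
      stop("region '", rn, "' resamples to an empty mask in the target grid")
    lat <- if ("laterality" %in% names(name_table))
      name_table$laterality[match(rn, name_table$name)]
    else if (grepl("_L$", rn)) "left"
    else if (grepl("_R$", rn)) "right"
    else "midline"
    masks[[rn]] <- mask
    ctr <- colMeans(world[as.vector(mask), , drop = FALSE])
    info[[length(info) + 1]] <- data.frame(
      name = rn, base = sub("_[LR]$", "", rn), laterality = lat,
      center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
      radius_mm = NA_real_, stringsAsFactors = FALSE)
  }
  structure(list(masks = masks, info = do.call(rbind, info)),
            class = "roi_set")
}

#' Read a label atlas from NIfTI + TSV name table
#'
#' @param nifti_path Integer label NIfTI volume.
#' @param names_path Tab-separated table with columns `label`, `name` and
#'   optionally `laterality`.
#' @return List with `labels`, `affine`, `name_table`.
#' @export
read_atlas <- function(nifti_path, names_path) {
  img <- RNifti::readNifti(nifti_path)
  labels <- array(as.integer(img[]), dim(img))
  affine <- unclass(RNifti::xform(img))
  attr(affine, "imagedim") <- NULL
  attr(affine, "code") <- NULL
  nt <- read.delim(names_path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(nt)))
    stop("name table needs columns 'label' and 'name'")
  list(labels = labels, affine = affine, name_table = nt)
}
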