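#' Specification of a multi-shell spherical head phantom
#'
#' Describes a concentric-shell stand-in for a segmented human head: five
#' tissue boundaries (skin, skull, CSF, gray matter, white matter, outermost
#' to innermost), an optional air cavity, and the perturbation magnitudes used
#' when generating a cohort of distinct heads. Spheres keep every downstream
#' quantity checkable against closed forms while exercising the same
#' heterogeneous-conductivity physics as anatomical segmentations.
#'
#' @param grid_shape Voxels per axis (scalar or length 3).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param shell_radii Named numeric, outer boundary radius in mm for
#'   `skin`, `skull`, `csf`, `gray`, `white`; must be strictly decreasing in
#'   that order and leave at least one background voxel on every grid face.
#' @param air_cavity Optional `list(center = c(x, y, z), radius)` in mm,
#'   carving an air pocket (label 6) out of the skull/interior.
#' @param scale Per-axis multiplicative scale applied to voxel coordinates
#'   before the radius comparison; values other than 1 give ellipsoidal heads.
#' @param perturbation `list(radius_frac, roi_jitter_mm)`: fractional jitter
#'   applied to shell thicknesses and uniform jitter (mm) applied to ROI
#'   centers when generating a cohort.
#' @param seed Integer seed; together with the spec it fully determines every
#'   generated volume.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = 40, voxel_size = 4)
#' head <- make_spherical_head(spec)
#' table(head$labels)
phantom_spec <- function(grid_shape = 64,
                         voxel_size = 3,
                         shell_radii = c(skin = 88, skull = 82, csf = 78,
                                         gray = 75, white = 60),
                         air_cavity = NULL,
                         scale = c(1, 1, 1),
                         perturbation = list(radius_frac = 0.05,
                                             roi_jitter_mm = 3),
                         seed = 1L) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            is.numeric(voxel_size), length(voxel_size) == 1, voxel_size > 0,
            length(scale) == 3, all(scale > 0))
  shell_names <- c("skin", "skull", "csf", "gray", "white")
  if (is.null(names(shell_radii))) names(shell_radii) <- shell_names
  shell_radii <- shell_radii[shell_names]
  if (anyNA(shell_radii))
    stop("shell_radii must provide skin, skull, csf, gray and white radii")
  if (any(shell_radii <= 0) || any(diff(shell_radii) >= 0))
    stop("shell radii must be strictly decreasing: skin > skull > csf > gray > white > 0")
  # >= 1 background voxel margin: the outermost voxel layer on each face must
  # stay outside the skin boundary.
  half_extent <- (grid_shape - 1) / 2 * voxel_size
  margin_limit <- half_extent - voxel_size
  if (any(shell_radii["skin"] * scale > margin_limit))
    stop(sprintf(
      "skin radius %.1f mm exceeds the grid: shells must leave >= 1 background voxel on every face (limit %.2f mm)",
      shell_radii["skin"], min(margin_limit / scale)))
  if (!is.null(air_cavity)) {
    stopifnot(is.list(air_cavity), length(air_cavity$center) == 3,
              is.numeric(air_cavity$radius))
    if (air_cavity$radius <= 0) stop("air cavity radius must be positive")
  }
  perturbation <- utils::modifyList(
    list(radius_frac = 0.05, roi_jitter_mm = 3), as.list(perturbation))
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         shell_radii = shell_radii, air_cavity = air_cavity,
         scale = as.numeric(scale), perturbation = perturbation,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

new_tissue_volume <- function(labels, voxel_size) {
  structure(
    list(labels = labels, voxel_size = voxel_size,
         dim = dim(labels), affine = grid_affine(dim(labels), voxel_size)),
    class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  cat(sprintf("<tissue_volume> %s voxels @ %.3g mm\n",
              paste(x$dim, collapse = " x "), x$voxel_size))
  tab <- table(factor(x$labels, levels = TISSUE_LABELS,
                      labels = names(TISSUE_LABELS)))
  print(tab)
  invisible(x)
}

#' Build a multi-shell spherical head phantom
#'
#' Rasterizes the concentric shells of a [phantom_spec()] onto the voxel
#' grid: each voxel takes the label of the innermost shell containing its
#' center, walking outward white -> gray -> CSF -> skull -> skin ->
#' background, with an optional air cavity overriding interior labels.
#'
#' @param spec A [phantom_spec()].
#' @return A `tissue_volume`: integer label array plus voxel size and
#'   voxel-to-world affine (RAS mm, grid-centered).
#' @export
make_spherical_head <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  g <- coord_grids(dm, spec$voxel_size)
  r <- sqrt((g$x / spec$scale[1])^2 + (g$y / spec$scale[2])^2 +
              (g$z / spec$scale[3])^2)
  labels <- array(TISSUE_LABELS[["background"]], dm)
  labels[r <= spec$shell_radii["skin"]] <- TISSUE_LABELS[["skin"]]
  labels[r <= spec$shell_radii["skull"]] <- TISSUE_LABELS[["skull"]]
  labels[r <= spec$shell_radii["csf"]] <- TISSUE_LABELS[["csf"]]
  labels[r <= spec$shell_radii["gray"]] <- TISSUE_LABELS[["gray"]]
  labels[r <= spec$shell_radii["white"]] <- TISSUE_LABELS[["white"]]
  if (!is.null(spec$air_cavity)) {
    cc <- spec$air_cavity$center
    ra <- sqrt((g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2)
    inside <- ra <= spec$air_cavity$radius
    if (!any(inside & labels != TISSUE_LABELS[["background"]]))
      stop("air cavity lies entirely outside the head")
    labels[inside & labels != TISSUE_LABELS[["background"]]] <-
      TISSUE_LABELS[["air"]]
  }
  storage.mode(labels) <- "integer"
  new_tissue_volume(labels, spec$voxel_size)
}

#' Default bilateral target ROI specification
#'
#' Ten bilateral regions named after the cortical and subcortical areas
#' recurrently implicated in auditory verbal hallucinations (inferior frontal
#' gyrus pars opercularis/triangularis, anterior cingulate, pre-/postcentral
#' gyri, Heschl's gyrus, superior temporal gyrus, hippocampus, insula,
#' thalamus), placed at plausible angular positions and depths on the
#' spherical phantom. Angles are configuration, not anatomy: `polar_deg` is
#' measured from the vertex (+z), `azim_deg` from the anterior axis (+y)
#' toward lateral, `depth_mm` is the distance of the ROI center from the head
#' center, and `radius_mm` the ROI sphere radius.
#'
#' @return A data frame with columns `name`, `laterality`, `polar_deg`,
#'   `azim_deg`, `depth_mm`, `radius_mm`.
#' @export
default_roi_spec <- function() {
  data.frame(
    name = c("IFGo", "IFGt", "ACG", "PreCG", "PoCG",
             "HES", "STG", "HIP", "INS", "THA"),
    laterality = "bilateral",
    polar_deg = c(75, 78, 55, 35, 38, 85, 88, 95, 80, 90),
    azim_deg = c(55, 65, 15, 60, 110, 100, 105, 115, 85, 120),
    depth_mm = c(67, 67, 58, 68, 68, 63, 68, 45, 53, 18),
    radius_mm = c(7, 7, 6, 8, 8, 5, 8, 6, 6, 6),
    stringsAsFactors = FALSE)
}

roi_direction <- function(polar_deg, azim_deg, side) {
  th <- polar_deg * pi / 180
  ph <- azim_deg * pi / 180
  lat <- sin(th) * sin(ph)   # lateral (+x = right)
  ant <- sin(th) * cos(ph)   # anterior (+y)
  sup <- cos(th)             # superior (+z)
  if (side == "left") lat <- -lat
  c(lat, ant, sup)
}

#' Construct a set of spherical target ROIs on a head volume
#'
#' Each row of `roi_spec` yields one spherical mask clipped to brain tissue
#' (gray or white matter). Rows with `laterality = "bilateral"` expand into a
#' name-matched left/right pair mirrored across the midsagittal plane
#' (suffixes `_L`/`_R`); `"left"`, `"right"` and `"midline"` yield single
#' masks.
#'
#' @param volume A `tissue_volume`.
#' @param roi_spec Data frame as returned by [default_roi_spec()], optionally
#'   with a `jitter` attribute applied by [make_cohort()].
#' @param centers_mm Optional list of explicit world-space centers (mm), one
#'   per output mask, overriding the angular placement (used internally for
#'   cohort jitter).
#' @return An object of class `roi_set`: named list of logical masks plus an
#'   `info` data frame (`name`, `base`, `laterality`, `center_*`).
#' @export
make_roiset <- function(volume, roi_spec = default_roi_spec(),
                        centers_mm = NULL) {
  stopifnot(inherits(volume, "tissue_volume"), is.data.frame(roi_spec))
  needed <- c("name", "laterality", "polar_deg", "azim_deg",
              "depth_mm", "radius_mm")
  if (!all(needed %in% names(roi_spec)))
    stop("roi_spec must have columns ", paste(needed, collapse = ", "))
  if (any(roi_spec$radius_mm <= 0))
    stop("ROI radius must be positive (offending: ",
         paste(roi_spec$name[roi_spec$radius_mm <= 0], collapse = ", "), ")")

  g <- coord_grids(volume$dim, volume$voxel_size)
  brain <- array(volume$labels %in% BRAIN_LABELS, volume$dim)
  masks <- list()
  info <- list()
  k <- 0
  for (i in seq_len(nrow(roi_spec))) {
    row <- roi_spec[i, ]
    sides <- switch(row$laterality,
                    bilateral = c("left", "right"),
                    left = "left", right = "right", midline = "midline",
                    stop("unknown laterality: ", row$laterality))
    for (side in sides) {
      k <- k + 1
      nm <- if (row$laterality == "bilateral")
        paste0(row$name, "_", toupper(substr(side, 1, 1))) else row$name
      ctr <- if (!is.null(centers_mm)) centers_mm[[k]]
      else roi_direction(row$polar_deg, row$azim_deg,
                         if (side == "midline") "right" else side) * row$depth_mm
      d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
      mask <- d2 <= row$radius_mm^2 & brain
      if (!any(mask))
        stop("ROI '", nm, "' is empty after clipping to brain tissue")
      masks[[nm]] <- mask
      info[[k]] <- data.frame(
        name = nm, base = row$name,
        laterality = if (row$laterality == "bilateral") side else row$laterality,
        center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
        radius_mm = row$radius_mm, stringsAsFactors = FALSE)
    }
  }
  structure(list(masks = masks, info = do.call(rbind, info)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d masks: %s\n", length(x$masks),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Union mask of one side of an ROI network
#'
#' @param rois A `roi_set`.
#' @param side `"left"` or `"right"`.
#' @return Logical array, the union of that side's masks (overlaps counted
#'   once).
#' @export
side_union <- function(rois, side = c("left", "right")) {
  side <- match.arg(side)
  nm <- rois$info$name[rois$info$laterality == side]
  if (length(nm) == 0) stop("no ROIs with laterality '", side, "'")
  Reduce(`|`, rois$masks[nm])
}

#' Generate a cohort of perturbed head phantoms
#'
#' Emulates anatomical variability across individuals: each head gets its own
#' shell geometry (every shell thickness jittered by a uniform
#' `+/- radius_frac` multiplicative factor, which preserves the strict shell
#' ordering by construction) and its own ROI centers (uniform
#' `+/- roi_jitter_mm` per axis). Seeds are derived from the master seed so
#' the cohort is bit-reproducible.
#'
#' @param n Number of heads (>= 1).
#' @param spec A [phantom_spec()]; its `perturbation` entry sets the jitter
#'   magnitudes (zero jitter gives `n` identical heads).
#' @param roi_spec ROI specification passed to [make_roiset()].
#' @return List of `n` elements, each `list(volume, rois, shell_radii)`.
#' @export
make_cohort <- function(n, spec, roi_spec = default_roi_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("cohort size n must be >= 1")
  pf <- spec$perturbation$radius_frac
  jit <- spec$perturbation$roi_jitter_mm
  lapply(seq_len(n), function(h) {
    with_seed(spec$seed + h, {
      # jitter thicknesses, not radii, so ordering can never invert
      radii <- spec$shell_radii
      thick <- c(-diff(radii), radii[length(radii)])
      thick <- thick * (1 + runif(length(thick), -pf, pf))
      radii_h <- rev(cumsum(rev(thick)))
      names(radii_h) <- names(radii)
      spec_h <- phantom_spec(
        grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
        shell_radii = radii_h, air_cavity = spec$air_cavity,
        scale = spec$scale, perturbation = spec$perturbation,
        seed = spec$seed + h)
      vol <- make_spherical_head(spec_h)
      # expand bilateral rows the same way make_roiset will, jitter each center
      centers <- list()
      k <- 0
      for (i in seq_len(nrow(roi_spec))) {
        row <- roi_spec[i, ]
        sides <- if (row$laterality == "bilateral") c("left", "right")
        else if (row$laterality == "midline") "midline" else row$laterality
        for (side in sides) {
          k <- k + 1
          ctr <- roi_direction(row$polar_deg, row$azim_deg,
                               if (side == "midline") "right" else side) *
            row$depth_mm
          centers[[k]] <- ctr + runif(3, -jit, jit)
        }
      }
      rois <- make_roiset(vol, roi_spec, centers_mm = centers)
      list(volume = vol, rois = rois, shell_radii = radii_h)
    })
  })
}
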