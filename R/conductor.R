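#' Default tissue conductivities
#'
#' Literature-standard isotropic conductivities (S/m) for the six tissue
#' compartments of a segmented head plus saline-soaked sponge electrodes:
#' gray matter 0.33, white matter 0.14, CSF 1.79, skin 0.43, skull 0.0132,
#' air 0, electrode (saline) 1.4. Exterior background is 0 S/m; zero-
#' conductivity voxels are excluded from the computational domain rather than
#' regularized, so air cavities are genuine insulators.
#'
#' @param overrides Optional named numeric vector (names from
#'   [tissue_labels()]) replacing individual entries.
#' @return A `conductivity_table`: named numeric vector indexed by tissue
#'   name, with the integer label codes in attribute `labels`.
#' @export
#' @examples
#' default_conductivities()[["gray"]]   # 0.33 S/m
default_conductivities <- function(overrides = NULL) {
  sigma <- c(background = 0, skin = 0.43, skull = 0.0132, csf = 1.79,
             gray = 0.33, white = 0.14, air = 0, electrode = 1.4)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% names(sigma)))
      stop("overrides must be named with tissue names: ",
           paste(names(sigma), collapse = ", "))
    sigma[names(overrides)] <- overrides
  }
  if (any(sigma < 0)) stop("conductivities must be non-negative")
  if (!any(sigma > 0)) stop("at least one conductivity must be positive")
  structure(sigma, labels = TISSUE_LABELS[names(sigma)],
            class = "conductivity_table")
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat("<conductivity_table> (S/m)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Assign a conductivity to every voxel of a labeled volume
#'
#' Pure relabeling: each voxel's integer tissue label is replaced by its
#' conductivity, so the histogram of the output equals the label histogram
#' mapped through the table.
#'
#' @param volume A `tissue_volume` (or bare integer array).
#' @param table A [default_conductivities()] table covering every label
#'   present in the volume.
#' @return Numeric 3D array of conductivities (S/m), same shape as the input.
#' @export
assign_conductivity <- function(volume, table = default_conductivities()) {
  labels <- if (inherits(volume, "tissue_volume")) volume$labels else volume
  stopifnot(inherits(table, "conductivity_table"))
  codes <- attr(table, "labels")
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, codes)
  if (length(unknown) > 0)
    stop("volume contains labels with no conductivity entry: ",
         paste(unknown, collapse = ", "))
  lut <- numeric(max(codes) + 1)
  lut[codes + 1] <- as.numeric(table)
  sigma <- array(lut[as.vector(labels) + 1], dim(labels))
  sigma
}
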