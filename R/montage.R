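# 10-20 scalp coordinate frame: unit directions from the head center.
# Nasion = +y, left ear = -x, vertex Cz = +z. Ring electrodes (Fp1/2, F7/8,
# T3/4, T5/6, O1/2) sit on the equatorial circumference at 10/20% arc steps
# from the nasion; midline sites step along the nasion-inion arc; lateral
# parasagittal sites (F3/4, C3/4, P3/4) are geodesic midpoints of their
# neighbors, following the standard 10-20 construction.
slerp <- function(a, b, t = 0.5) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

ring_dir <- function(deg_from_nasion, side) {
  # along the z = 0 circumference; side "left" bends toward -x
  s <- if (side == "left") -1 else 1
  th <- deg_from_nasion * pi / 180
  c(s * sin(th), cos(th), 0)
}

midline_dir <- function(deg_from_nasion) {
  th <- deg_from_nasion * pi / 180
  c(0, cos(th), sin(th))  # 90 deg = Cz
}

ten_twenty_table <- function() {
  tab <- list(
    FPZ = midline_dir(18), FZ = midline_dir(54), CZ = midline_dir(90),
    PZ = midline_dir(126), OZ = midline_dir(162),
    FP1 = ring_dir(18, "left"), FP2 = ring_dir(18, "right"),
    F7 = ring_dir(54, "left"), F8 = ring_dir(54, "right"),
    T3 = ring_dir(90, "left"), T4 = ring_dir(90, "right"),
    T5 = ring_dir(126, "left"), T6 = ring_dir(126, "right"),
    O1 = ring_dir(162, "left"), O2 = ring_dir(162, "right"))
  tab$F3 <- slerp(tab$FZ, tab$F7); tab$F4 <- slerp(tab$FZ, tab$F8)
  tab$C3 <- slerp(tab$CZ, tab$T3); tab$C4 <- slerp(tab$CZ, tab$T4)
  tab$P3 <- slerp(tab$PZ, tab$T5); tab$P4 <- slerp(tab$PZ, tab$T6)
  tab
}

#' Unit direction of a 10-20 scalp site
#'
#' Resolves a 10-20 label (or hyphenated compound such as `"F3-FP1"`, the
#' geodesic midpoint of the two sites) to a unit direction from the head
#' center in the package's RAS frame.
#'
#' @param label Character 10-20 label, case-insensitive.
#' @return Unit numeric vector of length 3.
#' @export
ten_twenty_direction <- function(label) {
  tab <- ten_twenty_table()
  parts <- toupper(strsplit(label, "-", fixed = TRUE)[[1]])
  unknown <- setdiff(parts, names(tab))
  if (length(unknown) > 0)
    stop("unsupported 10-20 label(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(sort(names(tab)), collapse = ", "))
  if (length(parts) == 1) return(tab[[parts]])
  if (length(parts) == 2) return(slerp(tab[[parts[1]]], tab[[parts[2]]]))
  stop("at most one hyphen is supported in a compound label: ", label)
}

#' Locate a 10-20 site on the scalp surface of a head volume
#'
#' Casts a ray from the head center along the site's direction and returns
#' the outermost skin voxel it crosses, i.e. a point on the outer scalp
#' surface.
#'
#' @param label 10-20 label or hyphenated compound (geodesic midpoint).
#' @param volume A `tissue_volume`.
#' @return List with `point` (world mm), `direction` (unit vector) and
#'   `radius` (mm from center).
#' @export
scalp_position <- function(label, volume) {
  stopifnot(inherits(volume, "tissue_volume"))
  dir <- ten_twenty_direction(label)
  vs <- volume$voxel_size
  dm <- volume$dim
  tmax <- max(dm) / 2 * vs
  ts <- seq(0, tmax, by = vs / 4)
  pts <- outer(ts, dir)                      # n x 3 world coords
  ijk <- nearest_voxel(pts, dm, vs)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] & ijk[, 2] >= 1 &
    ijk[, 2] <= dm[2] & ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
  lab <- rep(NA_integer_, length(ts))
  lab[ok] <- volume$labels[ijk[ok, , drop = FALSE]]
  hit <- which(lab == TISSUE_LABELS[["skin"]])
  if (length(hit) == 0)
    stop("no skin surface found along direction of '", label, "'")
  t_surf <- ts[max(hit)]
  list(point = dir * t_surf, direction = dir, radius = t_surf)
}

#' Build a tDCS montage from a named preset
#'
#' The three montages studied for auditory-hallucination targets:
#' * `LUL` — left unilateral 1x1: anode F3-FP1 (left prefrontal), cathode
#'   over the left temporoparietal junction (default `T3-P3`; set
#'   `lul_cathode = "P3"` for the alternative placement).
#' * `BL` — bilateral prefrontal 1x1: anode F3-FP1, cathode FP2.
#' * `TWO_BY_ONE` — anode F3-FP1 at the full amplitude, two cathodes T3-P3
#'   and T4-P4 each carrying half the return current.
#'
#' @param name Preset name (`"LUL"`, `"BL"`, `"TWO_BY_ONE"`; `"2x1"` is
#'   accepted as an alias).
#' @param amplitude_mA Anode current in mA (> 0); cathode currents are set so
#'   the montage sums to zero.
#' @param lul_cathode Cathode anchor for the LUL preset.
#' @param size_cm Pad surface dimensions in cm (default 5 x 7 sponge).
#' @param thickness_mm Sponge thickness in mm.
#' @return A `montage`: list with `name` and `pads`, each pad a list
#'   `(name, anchor, current_mA, size_cm, thickness_mm)`.
#' @export
#' @examples
#' preset_montage("TWO_BY_ONE", 2)  # currents +2, -1, -1 mA
preset_montage <- function(name, amplitude_mA = 2, lul_cathode = "T3-P3",
                           size_cm = c(5, 7), thickness_mm = 5) {
  if (!is.numeric(amplitude_mA) || amplitude_mA <= 0)
    stop("amplitude_mA must be > 0")
  key <- toupper(gsub("[^A-Za-z0-9]", "", name))
  key <- switch(key, "2X1" = "TWO_BY_ONE", "TWOBYONE" = "TWO_BY_ONE",
                "LUL" = "LUL", "BL" = "BL",
                stop("unknown montage preset '", name,
                     "'; valid presets: LUL, BL, TWO_BY_ONE (2x1)"))
  pad <- function(anchor, current)
    list(name = anchor, anchor = anchor, current_mA = current,
         size_cm = size_cm, thickness_mm = thickness_mm)
  pads <- switch(key,
    LUL = list(pad("F3-FP1", amplitude_mA), pad(lul_cathode, -amplitude_mA)),
    BL = list(pad("F3-FP1", amplitude_mA), pad("FP2", -amplitude_mA)),
    TWO_BY_ONE = list(pad("F3-FP1", amplitude_mA),
                      pad("T3-P3", -amplitude_mA / 2),
                      pad("T4-P4", -amplitude_mA / 2)))
  new_montage(key, pads)
}

new_montage <- function(name, pads) {
  currents <- vapply(pads, function(p) p$current_mA, numeric(1))
  if (abs(sum(currents)) > 1e-9)
    stop("montage currents must sum to zero (got ",
         format(sum(currents)), " mA)")
  if (!any(currents > 0) || !any(currents < 0))
    stop("montage needs at least one anode (+) and one cathode (-)")
  structure(list(name = name, pads = pads), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %s\n", x$name))
  for (p in x$pads)
    cat(sprintf("  %-8s %+.2f mA  (%g x %g cm, %g mm)\n", p$anchor,
                p$current_mA, p$size_cm[1], p$size_cm[2], p$thickness_mm))
  invisible(x)
}

#' Read a montage from a YAML description
#'
#' Accepts either `preset: <name>` (+ optional `amplitude_mA`,
#' `lul_cathode`) or an explicit `pads:` list with `anchor`, `current_mA`
#' and optional `size_cm`, `thickness_mm` per pad.
#'
#' @param path YAML file path.
#' @return A `montage`.
#' @export
read_montage_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset))
    return(preset_montage(cfg$preset, cfg$amplitude_mA %||% 2,
                          lul_cathode = cfg$lul_cathode %||% "T3-P3"))
  if (is.null(cfg$pads)) stop("montage YAML needs 'preset' or 'pads'")
  pads <- lapply(cfg$pads, function(p) {
    list(name = p$name %||% p$anchor, anchor = p$anchor,
         current_mA = p$current_mA,
         size_cm = unlist(p$size_cm %||% c(5, 7)),
         thickness_mm = p$thickness_mm %||% 5)
  })
  new_montage(cfg$name %||% "custom", pads)
}

#' Voxelize the sponge pads of a montage into a head volume
#'
#' Each pad becomes a conformal patch of electrode voxels (label 7) hugging
#' the scalp: background voxels within `thickness_mm` outward of the head
#' surface whose geodesic tangent-plane coordinates at the anchor fall inside
#' the pad rectangle (long axis along the projected superior direction). The
#' exposed outer face of each pad — its voxels with a free background
#' neighbor, the surface "away from the head" — is recorded for current
#' injection.
#'
#' @param volume A `tissue_volume` without electrodes.
#' @param montage A `montage`.
#' @return The volume with electrode voxels labeled 7 and attribute `pads`:
#'   per pad, `name`, `current_mA`, `voxels` and `face` (linear indices).
#' @export
voxelize_pads <- function(volume, montage) {
  stopifnot(inherits(volume, "tissue_volume"), inherits(montage, "montage"))
  dm <- volume$dim
  vs <- volume$voxel_size
  labels <- volume$labels
  head_mask <- array(labels != TISSUE_LABELS[["background"]] &
                       labels != TISSUE_LABELS[["air"]], dm)
  g <- coord_grids(dm, vs)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  bg <- array(labels == TISSUE_LABELS[["background"]], dm)

  pad_info <- list()
  all_pad <- array(FALSE, dm)
  for (p in montage$pads) {
    n_lay <- max(1L, as.integer(round(p$thickness_mm / vs)))
    shell <- dilate6(head_mask, n_lay) & bg
    sp <- scalp_position(p$anchor, volume)
    a_hat <- sp$direction
    # local tangent frame: long axis (u) along projected +z, short axis (v)
    ref <- if (abs(a_hat[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
    u <- ref - sum(ref * a_hat) * a_hat
    u <- u / sqrt(sum(u^2))
    v <- c(a_hat[2] * u[3] - a_hat[3] * u[2],
           a_hat[3] * u[1] - a_hat[1] * u[3],
           a_hat[1] * u[2] - a_hat[2] * u[1])
    hu <- p$size_cm[2] * 10 / 2   # long half-extent, mm
    hv <- p$size_cm[1] * 10 / 2
    # geodesic tangent coordinates of candidate voxels
    cand <- which(shell)
    if (length(cand) == 0) stop("pad '", p$anchor, "' finds no scalp shell")
    wx <- g$x[cand]; wy <- g$y[cand]; wz <- g$z[cand]
    rr <- r[cand]
    dx <- wx / rr; dy <- wy / rr; dz <- wz / rr
    cosg <- pmin(1, pmax(-1, dx * a_hat[1] + dy * a_hat[2] + dz * a_hat[3]))
    gamma <- acos(cosg)
    tx <- dx - cosg * a_hat[1]; ty <- dy - cosg * a_hat[2]
    tz <- dz - cosg * a_hat[3]
    tn <- sqrt(tx^2 + ty^2 + tz^2)
    tn[tn < 1e-12] <- 1
    arc <- gamma * sp$radius
    su <- arc * (tx * u[1] + ty * u[2] + tz * u[3]) / tn
    sv <- arc * (tx * v[1] + ty * v[2] + tz * v[3]) / tn
    sel <- cand[abs(su) <= hu & abs(sv) <= hv]
    if (length(sel) == 0)
      stop("pad '", p$anchor, "' voxelizes to an empty set")
    pm <- array(FALSE, dm)
    pm[sel] <- TRUE
    if (!touches6(pm, array(labels == TISSUE_LABELS[["skin"]], dm)))
      stop("pad '", p$anchor, "' does not touch the scalp")
    overlap <- all_pad & pm
    if (any(overlap)) {
      prev <- vapply(pad_info, function(q) any(q$mask & pm), logical(1))
      stop("pads overlap: '", p$anchor, "' and '",
           pad_info[[which(prev)[1]]]$name, "'")
    }
    all_pad <- all_pad | pm
    pad_info[[length(pad_info) + 1]] <-
      list(name = p$anchor, current_mA = p$current_mA, mask = pm,
           voxels = sel)
  }

  new_labels <- labels
  new_labels[all_pad] <- TISSUE_LABELS[["electrode"]]
  storage.mode(new_labels) <- "integer"
  free_bg <- array(new_labels == TISSUE_LABELS[["background"]], dm)
  # treat off-grid as free space so pads flush with the grid edge still expose
  near_free <- dilate6(free_bg, 1) | edge_mask(dm)
  pads <- lapply(pad_info, function(p) {
    face <- p$voxels[near_free[p$voxels]]
    if (length(face) == 0) face <- p$voxels  # fully enclosed: inject everywhere
    list(name = p$name, current_mA = p$current_mA, voxels = p$voxels,
         face = face)
  })
  out <- new_tissue_volume(new_labels, vs)
  attr(out, "pads") <- pads
  out
}

edge_mask <- function(dm) {
  m <- array(FALSE, dm)
  m[c(1, dm[1]), , ] <- TRUE
  m[, c(1, dm[2]), ] <- TRUE
  m[, , c(1, dm[3])] <- TRUE
  m
}
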