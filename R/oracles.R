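# Closed-form references used to verify the numerical solver.

#' Uniform-slab field reference
#'
#' A homogeneous conductor of cross-sectional area `A` carrying a total
#' current `I` supports the uniform field `E = I / (sigma * A)` — the
#' elementary check for the finite-volume solver with full-face electrodes.
#'
#' @param sigma Conductivity, S/m (> 0).
#' @param area_m2 Cross-sectional area, m^2 (> 0).
#' @param current_A Total current, A.
#' @return Field magnitude in V/m.
#' @export
#' @examples
#' slab_reference(0.33, 0.01, 2e-3)  # 0.606 V/m
slab_reference <- function(sigma, area_m2, current_A) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.numeric(area_m2) || area_m2 <= 0) stop("area must be > 0")
  current_A / (sigma * area_m2)
}

#' Legendre-series potential of two point electrodes on a homogeneous sphere
#'
#' Analytic interior solution of the Neumann problem for a uniform sphere of
#' radius `R` and conductivity `sigma` with current `I` injected at one
#' surface point and withdrawn at another:
#' `phi(r) = I / (4 pi sigma R) * sum_{n>=1} (2n+1)/n (r/R)^n
#' [P_n(cos g_A) - P_n(cos g_C)]`,
#' where `g_A`, `g_C` are the angles between the evaluation point and the
#' two electrode directions. The series converges for `r < R` and (slowly)
#' on the surface away from the singular electrode points, which must be
#' excluded from any comparison.
#'
#' @param points Numeric matrix (n x 3) of evaluation points, same length
#'   unit as `radius`; points must satisfy `|p| <= radius`.
#' @param radius Sphere radius.
#' @param sigma Conductivity, S/m.
#' @param anode_dir,cathode_dir Unit direction vectors of the two surface
#'   electrodes.
#' @param current_A Injected current, A (positive at the anode).
#' @param order Series truncation order (>= 10).
#' @return Numeric vector of potentials (V), zero-mean gauge not applied.
#' @export
sphere_series_reference <- function(points, radius, sigma,
                                    anode_dir, cathode_dir,
                                    current_A, order = 200L) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (order < 10) stop("truncation order must be >= 10")
  if (sigma <= 0 || radius <= 0) stop("sigma and radius must be > 0")
  a <- anode_dir / sqrt(sum(anode_dir^2))
  c_ <- cathode_dir / sqrt(sum(cathode_dir^2))
  r <- sqrt(rowSums(points^2))
  if (any(r > radius * (1 + 1e-9)))
    stop("all evaluation points must lie inside (or on) the sphere")
  rn <- pmin(r / radius, 1)
  dir <- points / pmax(r, .Machine$double.eps)
  dir[r == 0, ] <- 0
  ca <- pmin(1, pmax(-1, as.vector(dir %*% a)))
  cc <- pmin(1, pmax(-1, as.vector(dir %*% c_)))
  # Legendre recurrence: P_0 = 1, P_1 = x,
  # (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
  phi <- numeric(nrow(points))
  Pa_prev <- rep(1, length(ca)); Pa <- ca
  Pc_prev <- rep(1, length(cc)); Pc <- cc
  rpow <- rn
  for (n in seq_len(order)) {
    phi <- phi + (2 * n + 1) / n * rpow * (Pa - Pc)
    rpow <- rpow * rn
    Pa_next <- ((2 * n + 1) * ca * Pa - n * Pa_prev) / (n + 1)
    Pc_next <- ((2 * n + 1) * cc * Pc - n * Pc_prev) / (n + 1)
    Pa_prev <- Pa; Pa <- Pa_next
    Pc_prev <- Pc; Pc <- Pc_next
  }
  current_A / (4 * pi * sigma * radius) * phi
}

#' Homogeneous-sphere solver benchmark
#'
#' Builds a uniform sphere on the voxel grid, injects current through two
#' single-voxel surface electrodes, solves with [solve_potential()], and
#' compares the potential against [sphere_series_reference()] in relative L2
#' norm over conductive voxels, excluding a ball of `exclude_vox` voxels
#' around each electrode where both the discrete delta source and the series
#' are singular. Both potentials are referenced to zero mean over the
#' comparison set.
#'
#' @param n_vox Grid size per axis.
#' @param voxel_size Voxel edge, mm.
#' @param radius_mm Sphere radius, mm.
#' @param sigma Conductivity, S/m.
#' @param anode_dir,cathode_dir Unit electrode directions.
#' @param current_mA Injected current, mA.
#' @param exclude_vox Exclusion radius around each electrode, in voxels.
#' @param order Series truncation order.
#' @param tol,maxit Solver controls.
#' @return List with `rel_l2` (relative L2 error), `solution`, `n_compared`.
#' @export
sphere_benchmark <- function(n_vox = 64, voxel_size = 2.5, radius_mm = 70,
                             sigma = 0.33,
                             anode_dir = c(sin(pi / 3), 0, cos(pi / 3)),
                             cathode_dir = c(-sin(pi / 3), 0, cos(pi / 3)),
                             current_mA = 2, exclude_vox = 2,
                             order = 200L, tol = 1e-8, maxit = 50000L) {
  dm <- rep(as.integer(n_vox), 3)
  g <- coord_grids(dm, voxel_size)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  sig <- array(0, dm)
  sig[r <= radius_mm] <- sigma
  pick_surface <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    # outermost conductive voxel along the ray
    ts <- seq(0, radius_mm + voxel_size, by = voxel_size / 4)
    ijk <- round(sweep(outer(ts, dir) / voxel_size, 2, (dm - 1) / 2, `+`)) + 1
    ok <- apply(ijk >= 1 & sweep(ijk, 2, dm, `<=`), 1, all)
    lin <- ijk[ok, 1] + (ijk[ok, 2] - 1) * dm[1] +
      (ijk[ok, 3] - 1) * dm[1] * dm[2]
    lin <- lin[sig[lin] > 0]
    lin[length(lin)]
  }
  ia <- pick_surface(anode_dir)
  ic <- pick_surface(cathode_dir)
  pads <- list(list(name = "anode", current_mA = current_mA, face = ia),
               list(name = "cathode", current_mA = -current_mA, face = ic))
  sol <- solve_potential(sig, pads, voxel_size, tol = tol, maxit = maxit)
  cond <- which(sig > 0)
  pa <- c(g$x[ia], g$y[ia], g$z[ia])
  pc <- c(g$x[ic], g$y[ic], g$z[ic])
  d2a <- (g$x - pa[1])^2 + (g$y - pa[2])^2 + (g$z - pa[3])^2
  d2c <- (g$x - pc[1])^2 + (g$y - pc[2])^2 + (g$z - pc[3])^2
  excl <- (exclude_vox * voxel_size)^2
  keep <- cond[d2a[cond] > excl & d2c[cond] > excl]
  # series evaluated in meters so that sigma in S/m gives volts; electrodes
  # placed at the actual discrete electrode directions
  pts <- cbind(g$x[keep], g$y[keep], g$z[keep]) / 1000
  ref <- sphere_series_reference(pts, radius_mm / 1000, sigma,
                                 pa / sqrt(sum(pa^2)), pc / sqrt(sum(pc^2)),
                                 current_mA / 1000, order = order)
  num <- sol$phi[keep]
  ref <- ref - mean(ref)
  num <- num - mean(num)
  list(rel_l2 = sqrt(sum((num - ref)^2) / sum(ref^2)),
       solution = sol, n_compared = length(keep))
}

#' Uniform-slab solver benchmark
#'
#' Builds a homogeneous cuboid conductor inside the grid with full-face
#' electrodes on two opposite ends, solves, and compares the interior field
#' magnitude with the closed form `I / (sigma A)`.
#'
#' @param n_vox Grid size per axis (the cuboid cross-section is sized to
#'   `area_m2` within it).
#' @param voxel_size Voxel edge, mm.
#' @param sigma Conductivity, S/m.
#' @param area_m2 Cross-sectional area, m^2; must voxelize exactly.
#' @param current_mA Injected current, mA.
#' @param tol,maxit Solver controls.
#' @return List with `expected` (V/m), `max_rel_err` over the interior,
#'   `solution`.
#' @export
slab_benchmark <- function(n_vox = 64, voxel_size = 2.5, sigma = 0.33,
                           area_m2 = 0.01, current_mA = 2,
                           tol = 1e-8, maxit = 50000L) {
  dm <- rep(as.integer(n_vox), 3)
  side_mm <- sqrt(area_m2) * 1000
  nside <- as.integer(round(side_mm / voxel_size))
  if (abs(nside * voxel_size - side_mm) > 1e-9)
    stop("cross-section side ", side_mm, " mm must be a multiple of the voxel size")
  if (nside > dm[1] || nside > dm[2]) stop("cross-section exceeds the grid")
  i0 <- (dm[1] - nside) %/% 2 + 1
  j0 <- (dm[2] - nside) %/% 2 + 1
  sig <- array(0, dm)
  sig[i0:(i0 + nside - 1), j0:(j0 + nside - 1), ] <- sigma
  lin <- array(seq_len(prod(dm)), dm)
  top <- as.vector(lin[i0:(i0 + nside - 1), j0:(j0 + nside - 1), dm[3]])
  bot <- as.vector(lin[i0:(i0 + nside - 1), j0:(j0 + nside - 1), 1])
  pads <- list(list(name = "top", current_mA = current_mA, face = top),
               list(name = "bottom", current_mA = -current_mA, face = bot))
  sol <- solve_potential(sig, pads, voxel_size, tol = tol, maxit = maxit)
  sol <- compute_field(sol)
  interior <- array(FALSE, dm)
  interior[i0:(i0 + nside - 1), j0:(j0 + nside - 1), 3:(dm[3] - 2)] <- TRUE
  expected <- slab_reference(sigma, area_m2, current_mA / 1000)
  err <- abs(sol$E_mag[interior] - expected) / expected
  list(expected = expected, max_rel_err = max(err), solution = sol)
}
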