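# Cell-centered finite-volume discretization of div(sigma grad phi) = 0 on
# the voxel grid. Unknowns are the conductive voxels (sigma > 0); the face
# conductance between 6-neighbors i,j is the harmonic mean of their
# conductivities times h (face area h^2 over distance h), which preserves
# flux continuity across tissue interfaces. Faces to sigma = 0 voxels and to
# the grid boundary carry zero flux (Neumann), making the operator singular
# with a constant null space; the potential is referenced to zero mean.

build_fv_system <- function(sigma, voxel_size) {
  dm <- dim(sigma)
  cond <- sigma > 0
  N <- sum(cond)
  if (N == 0) stop("no conductive voxels (all sigma = 0)")
  idx <- array(0L, dm)
  idx[cond] <- seq_len(N)
  h_m <- voxel_size / 1000  # mm -> m; conductance sigma_face * h (S)
  lin <- array(seq_len(prod(dm)), dm)
  ii <- jj <- vector("list", 3)
  gg <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]
    sl <- function(rng) {
      args <- list(lin, TRUE, TRUE, TRUE)
      args[[ax + 1]] <- rng
      do.call(`[`, args)
    }
    A <- as.vector(sl(1:(n - 1)))
    B <- as.vector(sl(2:n))
    sA <- sigma[A]; sB <- sigma[B]
    keep <- sA > 0 & sB > 0
    A <- A[keep]; B <- B[keep]; sA <- sA[keep]; sB <- sB[keep]
    ii[[ax]] <- idx[A]
    jj[[ax]] <- idx[B]
    gg[[ax]] <- 2 * sA * sB / (sA + sB) * h_m
  }
  i <- unlist(ii); j <- unlist(jj); g <- unlist(gg)
  K <- Matrix::sparseMatrix(
    i = c(i, j, i, j), j = c(j, i, i, j), x = c(-g, -g, g, g),
    dims = c(N, N))
  list(K = K, index = idx, cond = cond, n = N, h_m = h_m)
}

#' Solve for the electric potential induced by injected pad currents
#'
#' Solves the current-conservation (Laplace) equation
#' `div(sigma grad phi) = 0` on the conductive voxels of a heterogeneous
#' volume with Neumann (zero-flux) boundaries, each pad's total current
#' distributed uniformly over its exposed outer-face voxels (constant current
#' density on the surface away from the head). The linear system is solved
#' with Jacobi-preconditioned conjugate gradients; the potential is
#' referenced to zero mean over the conductive domain.
#'
#' @param sigma Numeric 3D conductivity array (S/m), e.g. from
#'   [assign_conductivity()] after [voxelize_pads()].
#' @param pads List of pads, each `list(name, current_mA, face)` with `face`
#'   linear voxel indices of the injection surface (as produced by
#'   [voxelize_pads()]; `voxels` may also be present and is ignored here).
#'   Currents must sum to zero.
#' @param voxel_size Voxel edge length in mm.
#' @param tol Relative residual tolerance of the conjugate gradient solver.
#' @param maxit Maximum iterations.
#' @return A `field_solution` with `phi` (V; `NA` outside the conductive
#'   domain), the pad list, grid metadata and solver `diagnostics`
#'   (`iterations`, `relres`, `converged`).
#' @export
solve_potential <- function(sigma, pads, voxel_size,
                            tol = 1e-8, maxit = 50000L) {
  stopifnot(is.array(sigma), length(dim(sigma)) == 3)
  currents <- vapply(pads, function(p) p$current_mA, numeric(1))
  if (abs(sum(currents)) > 1e-9)
    stop("pad currents must sum to zero (got ", format(sum(currents)), " mA)")
  for (p in pads) {
    if (length(p$face) == 0) stop("pad '", p$name, "' has an empty face set")
    if (any(sigma[p$face] <= 0))
      stop("pad '", p$name, "' has injection voxels with sigma <= 0")
  }
  sys <- build_fv_system(sigma, voxel_size)
  # single conductive component containing all pads
  comp <- flood_component(as.vector(sys$cond), dim(sigma), pads[[1]]$face[1])
  if (sum(comp) != sys$n)
    stop("conductive domain is disconnected (",
         sys$n - sum(comp), " voxels unreachable from pad '",
         pads[[1]]$name, "')")
  b <- numeric(sys$n)
  for (p in pads) {
    rows <- sys$index[p$face]
    b[rows] <- b[rows] + (p$current_mA / 1000) / length(p$face)
  }
  b <- b - sum(b) / sys$n  # exact consistency for the singular Neumann system
  if (max(abs(b)) == 0) {
    phi <- array(NA_real_, dim(sigma))
    phi[sys$cond] <- 0
    return(new_field_solution(phi, sigma, pads, voxel_size,
                              list(iterations = 0L, relres = 0,
                                   converged = TRUE)))
  }
  res <- pcg_csc(sys$K@p, sys$K@i, sys$K@x, b, tol, as.integer(maxit))
  if (!res$converged)
    stop(sprintf(
      "conjugate gradient did not converge in %d iterations (relative residual %.3e, tolerance %.1e)",
      res$iterations, res$relres, tol))
  x <- res$x - mean(res$x)
  phi <- array(NA_real_, dim(sigma))
  phi[sys$cond] <- x
  new_field_solution(phi, sigma, pads, voxel_size,
                     list(iterations = res$iterations, relres = res$relres,
                          converged = res$converged))
}

new_field_solution <- function(phi, sigma, pads, voxel_size, diagnostics) {
  structure(
    list(phi = phi, sigma = sigma, pads = pads, voxel_size = voxel_size,
         dim = dim(phi), E = NULL, E_mag = NULL, E_n = NULL,
         diagnostics = diagnostics),
    class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> %s voxels @ %g mm; %d CG iterations, relres %.2e\n",
    paste(x$dim, collapse = " x "), x$voxel_size,
    x$diagnostics$iterations, x$diagnostics$relres))
  if (!is.null(x$E_mag))
    cat(sprintf("  |E| range: %.4g - %.4g V/m\n",
                min(x$E_mag, na.rm = TRUE), max(x$E_mag, na.rm = TRUE)))
  invisible(x)
}

#' Derive the electric field from a solved potential
#'
#' `E = -grad(phi)` by central differences on interior conductive voxels,
#' falling back to one-sided differences at conductive-domain boundaries;
#' `|E|` is the Euclidean norm. Fields are in V/m (grid spacing converted
#' from mm to m).
#'
#' @param solution A `field_solution` with `phi` present, or a bare numeric
#'   potential array (then `voxel_size` must be given).
#' @param voxel_size Voxel edge length in mm (taken from the solution when
#'   omitted).
#' @return The `field_solution` with `E` (4D array, last dim x/y/z) and
#'   `E_mag` filled (a new `field_solution` is synthesized for array input).
#' @export
compute_field <- function(solution, voxel_size = NULL) {
  if (is.array(solution) && !inherits(solution, "field_solution")) {
    if (is.null(voxel_size)) stop("voxel_size required for bare phi arrays")
    solution <- new_field_solution(solution, NULL, list(), voxel_size,
                                   list(iterations = NA, relres = NA,
                                        converged = NA))
  }
  phi <- solution$phi
  if (is.null(phi)) stop("solution has no potential phi")
  h_m <- (voxel_size %||% solution$voxel_size) / 1000
  dm <- dim(phi)
  E <- array(0, c(dm, 3))
  inside <- !is.na(phi)
  for (ax in 1:3) {
    fwd <- shift_array(phi, ax, 1L)
    bwd <- shift_array(phi, ax, -1L)
    hf <- !is.na(fwd)
    hb <- !is.na(bwd)
    grad <- array(0, dm)
    both <- inside & hf & hb
    fonly <- inside & hf & !hb
    bonly <- inside & !hf & hb
    grad[both] <- (fwd[both] - bwd[both]) / (2 * h_m)
    grad[fonly] <- (fwd[fonly] - phi[fonly]) / h_m
    grad[bonly] <- (phi[bonly] - bwd[bonly]) / h_m
    comp <- array(NA_real_, dm)
    comp[inside] <- -grad[inside]
    E[, , , ax] <- comp
  }
  solution$E <- E
  solution$E_mag <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  solution
}

# Separable Gaussian smoothing of a numeric array (zero-padded edges).
gaussian_smooth3 <- function(a, sd_vox = 1, radius = max(1L, ceiling(3 * sd_vox))) {
  w <- dnorm(seq(-radius, radius), sd = sd_vox)
  w <- w / sum(w)
  out <- a
  for (ax in 1:3) {
    acc <- array(0, dim(a))
    for (k in seq(-radius, radius))
      acc <- acc + w[k + radius + 1] * shift_array(out, ax, k, fill = 0)
    out <- acc
  }
  out
}

#' Cortical-normal (radial) component of the electric field
#'
#' Estimates surface normals as the normalized gradient of a Gaussian-
#' smoothed brain indicator (gray + white matter), pointing inward, and
#' projects the field onto them: `E_n = E . n_hat`, positive for inward
#' current flow. Values are reported on gray-matter surface voxels (gray
#' voxels with a non-brain 6-neighbor).
#'
#' @param solution A `field_solution` with `E` present.
#' @param gray_mask Logical array of gray-matter voxels.
#' @param brain_mask Logical array used for normal estimation; defaults to
#'   `gray_mask` (supply gray + white for anatomical volumes).
#' @param smooth_sd Gaussian smoothing width for the indicator, in voxels.
#' @return The `field_solution` with `E_n` filled (`NA` off-surface).
#' @export
radial_component <- function(solution, gray_mask, brain_mask = gray_mask,
                             smooth_sd = 1) {
  if (is.null(solution$E)) stop("solution has no field E; run compute_field()")
  if (!any(gray_mask)) stop("gray-matter mask is empty")
  dm <- dim(gray_mask)
  ind <- gaussian_smooth3(array(as.numeric(brain_mask), dm), smooth_sd)
  h <- 1  # normals only need direction; voxel units suffice
  nx <- (shift_array(ind, 1, 1L, 0) - shift_array(ind, 1, -1L, 0)) / (2 * h)
  ny <- (shift_array(ind, 2, 1L, 0) - shift_array(ind, 2, -1L, 0)) / (2 * h)
  nz <- (shift_array(ind, 3, 1L, 0) - shift_array(ind, 3, -1L, 0)) / (2 * h)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nn[nn < 1e-12] <- 1
  # gradient of the indicator points toward the interior: inward-positive
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  surf <- gray_mask & !(
    shift_array(brain_mask, 1, 1L, FALSE) & shift_array(brain_mask, 1, -1L, FALSE) &
    shift_array(brain_mask, 2, 1L, FALSE) & shift_array(brain_mask, 2, -1L, FALSE) &
    shift_array(brain_mask, 3, 1L, FALSE) & shift_array(brain_mask, 3, -1L, FALSE))
  En <- array(NA_real_, dm)
  En[surf] <- solution$E[, , , 1][surf] * nx[surf] +
    solution$E[, , , 2][surf] * ny[surf] +
    solution$E[, , , 3][surf] * nz[surf]
  solution$E_n <- En
  solution
}

#' Net discrete current delivered by each pad
#'
#' Sums the finite-volume face fluxes from each pad's electrode voxels into
#' the rest of the conductive domain; at convergence this recovers the
#' configured injected current (a discrete conservation check).
#'
#' @param solution A `field_solution` from [solve_potential()] whose pads
#'   carry `voxels` index sets (as from [voxelize_pads()]); pads given only
#'   by `face` are treated as having `voxels = face`.
#' @return Data frame with `pad`, `configured_mA`, `measured_mA`,
#'   `rel_error`.
#' @export
pad_currents <- function(solution) {
  sigma <- solution$sigma
  if (is.null(sigma)) stop("solution carries no conductivity grid")
  phi <- solution$phi
  dm <- dim(phi)
  h_m <- solution$voxel_size / 1000
  lin <- array(seq_len(prod(dm)), dm)
  rows <- lapply(solution$pads, function(p) {
    vox <- p$voxels %||% p$face
    inpad <- array(FALSE, dm)
    inpad[vox] <- TRUE
    flux <- 0
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_array(lin, ax, s)  # neighbor index at offset s
      ok <- inpad & !is.na(nb)
      nbv <- nb[ok]
      outside <- !inpad[nbv] & sigma[nbv] > 0
      a <- lin[ok][outside]
      bvox <- nbv[outside]
      if (length(a) == 0) next
      gcond <- 2 * sigma[a] * sigma[bvox] / (sigma[a] + sigma[bvox]) * h_m
      flux <- flux + sum(gcond * (phi[a] - phi[bvox]))
    }
    measured <- flux * 1000  # A -> mA
    data.frame(pad = p$name, configured_mA = p$current_mA,
               measured_mA = measured,
               rel_error = abs(measured - p$current_mA) /
                 max(abs(p$current_mA), .Machine$double.eps),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interior divergence residual of a solved potential
#'
#' Maximum absolute discrete divergence (net current imbalance, A) over
#' conductive voxels that are not injection-face voxels, normalized by the
#' total injected positive current. Zero up to solver tolerance for a
#' converged solution.
#'
#' @param solution A `field_solution` from [solve_potential()].
#' @return Scalar relative residual.
#' @export
divergence_residual <- function(solution) {
  sigma <- solution$sigma
  sys <- build_fv_system(sigma, solution$voxel_size)
  x <- solution$phi[sys$cond]
  r <- as.numeric(sys$K %*% x)
  face_rows <- unlist(lapply(solution$pads, function(p) sys$index[p$face]))
  inj <- sum(vapply(solution$pads, function(p) max(p$current_mA, 0),
                    numeric(1))) / 1000
  max(abs(r[-face_rows])) / inj
}
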