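test_that("null sources give a zero potential and field", {
  s <- small_sphere_setup(n_vox = 24, voxel_size = 6.5, radius_mm = 70,
                          current_mA = 0)
  s$pads[[2]]$current_mA <- 0
  sol <- solve_potential(s$sigma, s$pads, s$voxel_size)
  expect_true(all(sol$phi[!is.na(sol$phi)] == 0))
  sol <- compute_field(sol)
  expect_true(all(sol$E_mag[!is.na(sol$E_mag)] == 0))
})

test_that("a linear potential yields a uniform field", {
  dm <- c(12, 10, 8)
  ax <- (seq_len(dm[1]) - 1) * 2  # mm
  phi <- array(rep(-2 * ax / 1000, times = prod(dm[2:3])), dm)  # -2x, x in m
  sol <- compute_field(phi, voxel_size = 2)
  expect_equal(as.vector(sol$E[, , , 1]), rep(2, prod(dm)), tolerance = 1e-12)
  expect_equal(max(abs(sol$E[, , , 2:3])), 0)
  expect_equal(as.vector(sol$E_mag), rep(2, prod(dm)), tolerance = 1e-12)
  # doubling phi doubles E exactly
  sol2 <- compute_field(2 * phi, voxel_size = 2)
  expect_identical(sol2$E_mag, 2 * sol$E_mag)
})

test_that("slab solution reproduces E = I/(sigma A) and the closed form itself", {
  expect_equal(slab_reference(0.33, 0.01, 2e-3), 0.60606, tolerance = 1e-4)
  expect_equal(slab_reference(1, 1, 1), 1)
  expect_equal(slab_reference(0.66, 0.01, 2e-3),
               slab_reference(0.33, 0.01, 2e-3) / 2)
  expect_error(slab_reference(0, 1, 1), "> 0")

  sb <- slab_benchmark(n_vox = 32, voxel_size = 5)
  expect_equal(sb$expected, 0.6060606, tolerance = 1e-6)
  expect_lt(sb$max_rel_err, 0.01)
})

test_that("homogeneous-sphere potential matches the Legendre series", {
  sp <- sphere_benchmark(n_vox = 32, voxel_size = 5, radius_mm = 70)
  expect_lt(sp$rel_l2, 0.10)
  expect_true(sp$solution$diagnostics$converged)
  # zero-mean gauge over the conductive domain
  expect_lt(abs(mean(sp$solution$phi, na.rm = TRUE)),
            1e-10 * max(abs(sp$solution$phi), na.rm = TRUE))
})

test_that("the Legendre series oracle is self-consistent", {
  pts <- rbind(c(0.02, 0.01, 0.03), c(-0.03, 0.02, 0.01),
               c(0, 0, 0.05), c(0.04, -0.02, -0.01))
  a <- c(0, 0, 1); ct <- c(1, 0, 0)
  lo <- sphere_series_reference(pts, 0.07, 0.33, a, ct, 2e-3, order = 40)
  hi <- sphere_series_reference(pts, 0.07, 0.33, a, ct, 2e-3, order = 80)
  expect_lt(max(abs(lo - hi)) / max(abs(hi)), 1e-3)
  # linearity in the injected current
  expect_equal(sphere_series_reference(pts, 0.07, 0.33, a, ct, 4e-3,
                                       order = 40), 2 * lo)
  # antipodal electrodes: phi is antisymmetric under point reflection
  anti <- sphere_series_reference(-pts, 0.07, 0.33, a, -a, 2e-3, order = 60)
  direct <- sphere_series_reference(pts, 0.07, 0.33, a, -a, 2e-3, order = 60)
  expect_equal(anti, -direct, tolerance = 1e-10)
  expect_error(sphere_series_reference(pts, 0.07, 0.33, a, ct, 1, order = 5),
               ">= 10")
})

test_that("solutions scale linearly and flip sign with polarity", {
  s1 <- small_sphere_setup(current_mA = 1)
  s2 <- small_sphere_setup(current_mA = 2)
  sol1 <- solve_potential(s1$sigma, s1$pads, s1$voxel_size)
  sol2 <- solve_potential(s2$sigma, s2$pads, s2$voxel_size)
  d <- max(abs(sol2$phi - 2 * sol1$phi), na.rm = TRUE) /
    max(abs(sol2$phi), na.rm = TRUE)
  expect_lt(d, 1e-12)

  sneg <- small_sphere_setup(current_mA = 2)
  sneg$pads[[1]]$current_mA <- -2
  sneg$pads[[2]]$current_mA <- 2
  solneg <- solve_potential(sneg$sigma, sneg$pads, sneg$voxel_size)
  expect_identical(solneg$phi, -sol2$phi)
})

test_that("discrete current is conserved at the pads and in the interior", {
  s <- small_sphere_setup()
  sol <- solve_potential(s$sigma, s$pads, s$voxel_size)
  sol$pads <- lapply(sol$pads, function(p) { p$voxels <- p$face; p })
  pc <- pad_currents(sol)
  expect_equal(pc$measured_mA, pc$configured_mA, tolerance = 5e-3)
  expect_lt(divergence_residual(sol), 1e-6)
})

test_that("disconnected conductors and bad pad sets are rejected", {
  s <- small_sphere_setup()
  sig <- s$sigma
  # detached conductive blob in a corner
  sig[1:2, 1:2, 1:2] <- 0.33
  expect_error(solve_potential(sig, s$pads, s$voxel_size), "disconnected")
  unbalanced <- s$pads
  unbalanced[[1]]$current_mA <- 1
  expect_error(solve_potential(s$sigma, unbalanced, s$voxel_size),
               "sum to zero")
  onair <- s$pads
  onair[[1]]$face <- which(s$sigma == 0)[1]
  expect_error(solve_potential(s$sigma, onair, s$voxel_size), "sigma <= 0")
})

test_that("radial component recovers radial and rejects tangential fields", {
  s <- small_sphere_setup()
  dm <- dim(s$sigma)
  vs <- s$voxel_size
  ax <- (seq_len(dm[1]) - 1 - (dm[1] - 1) / 2) * vs
  X <- array(ax, dm); Y <- array(rep(ax, each = dm[1]), dm)
  Z <- array(rep(ax, each = dm[1]^2), dm)
  r <- sqrt(X^2 + Y^2 + Z^2)
  inside <- s$sigma > 0
  mask <- inside & r >= 40  # outer shell standing in for cortex
  # phi = |x|^2 (m^2): E = -grad phi = -2 r, purely radial, pointing inward
  phi <- array(NA_real_, dm)
  phi[inside] <- ((X^2 + Y^2 + Z^2) / 1e6)[inside]
  sol <- compute_field(phi, voxel_size = vs)
  sol <- radial_component(sol, gray_mask = mask, brain_mask = inside)
  on_surf <- which(!is.na(sol$E_n))
  expect_gt(length(on_surf), 50)
  ratio <- sol$E_n[on_surf] / sol$E_mag[on_surf]
  expect_true(all(ratio <= 1 + 1e-9))
  expect_gt(stats::median(ratio), 0.97)  # inward-positive, nearly parallel

  # purely tangential field: E = z_hat x r_hat has no radial component
  sol$E[, , , 1] <- -Y; sol$E[, , , 2] <- X; sol$E[, , , 3] <- 0
  sol$E_mag <- sqrt(sol$E[, , , 1]^2 + sol$E[, , , 2]^2)
  sol <- radial_component(sol, gray_mask = mask, brain_mask = inside)
  on_surf <- which(!is.na(sol$E_n) & sol$E_mag > 1)
  expect_lt(stats::median(abs(sol$E_n[on_surf]) / sol$E_mag[on_surf]), 0.1)

  expect_error(radial_component(sol, gray_mask = array(FALSE, dm)), "empty")
})
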