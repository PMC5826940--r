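# Coarse fixtures shared across tests: anatomy-scaled phantoms on small
# grids so each solve stays in the seconds range.

test_spec <- function(grid = 40, vs = 5, seed = 42L,
                      perturbation = list(radius_frac = 0.05,
                                          roi_jitter_mm = 3)) {
  phantom_spec(grid_shape = grid, voxel_size = vs, seed = seed,
               perturbation = perturbation)
}

test_head <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_spherical_head(test_spec())
    cache
  }
})

# homogeneous sphere conductor with two single-voxel surface electrodes
small_sphere_setup <- function(n_vox = 32, voxel_size = 5, radius_mm = 70,
                               sigma = 0.33, current_mA = 2) {
  dm <- rep(n_vox, 3)
  ax <- (seq_len(n_vox) - 1 - (n_vox - 1) / 2) * voxel_size
  X <- array(ax, dm)
  Y <- array(rep(ax, each = n_vox), dm)
  Z <- array(rep(ax, each = n_vox^2), dm)
  r <- sqrt(X^2 + Y^2 + Z^2)
  sig <- array(0, dm)
  sig[r <= radius_mm] <- sigma
  pick <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    ts <- seq(0, radius_mm + voxel_size, by = voxel_size / 4)
    ijk <- round(sweep(outer(ts, dir) / voxel_size, 2, (dm - 1) / 2, `+`)) + 1
    ok <- apply(ijk >= 1 & sweep(ijk, 2, dm, `<=`), 1, all)
    lin <- ijk[ok, 1] + (ijk[ok, 2] - 1) * dm[1] + (ijk[ok, 3] - 1) * dm[1]^2
    lin <- lin[sig[lin] > 0]
    lin[length(lin)]
  }
  ia <- pick(c(0, 0, 1))
  ic <- pick(c(1, 0, 0))
  list(sigma = sig, voxel_size = voxel_size, radius_mm = radius_mm,
       pads = list(list(name = "A", current_mA = current_mA, face = ia),
                   list(name = "C", current_mA = -current_mA, face = ic)))
}
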