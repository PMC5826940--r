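test_that("spherical head contains every shell, in radial order, deterministically", {
  spec <- test_spec()
  vol <- make_spherical_head(spec)
  expect_setequal(unique(as.vector(vol$labels)), 0:5)

  # same spec, same seed -> identical grids
  expect_identical(vol$labels, make_spherical_head(test_spec())$labels)

  # along rays from the center outward, first appearances follow
  # white -> gray -> csf -> skull -> skin -> background
  mid <- (vol$dim + 1) %/% 2
  rays <- list(vol$labels[mid[1]:vol$dim[1], mid[2], mid[3]],
               vol$labels[mid[1], mid[2]:vol$dim[2], mid[3]],
               vol$labels[mid[1], mid[2], mid[3]:vol$dim[3]],
               rev(vol$labels[1:mid[1], mid[2], mid[3]]))
  for (ray in rays) {
    first <- vapply(c(5L, 4L, 3L, 2L, 1L, 0L), function(l)
      which(ray == l)[1], numeric(1))
    first <- first[!is.na(first)]
    expect_true(!is.unsorted(first, strictly = TRUE))
  }
})

test_that("shells exceeding the grid margin are rejected", {
  expect_error(
    phantom_spec(grid_shape = 64, voxel_size = 2.5,
                 shell_radii = c(skin = 80, skull = 75, csf = 71,
                                 gray = 68, white = 55)),
    "margin|exceeds")
  expect_error(phantom_spec(shell_radii = c(skin = 60, skull = 66, csf = 62,
                                            gray = 59, white = 47)),
               "decreasing")
})

test_that("air cavity voxel count matches the analytic sphere volume", {
  ra <- 15
  spec <- test_spec()
  spec$air_cavity <- list(center = c(0, 30, 20), radius = ra)
  vol <- make_spherical_head(spec)
  n_air <- sum(vol$labels == 6L)
  vox_vol <- spec$voxel_size^3
  expected <- 4 / 3 * pi * ra^3 / vox_vol
  # within one voxel layer of the cavity surface
  layer <- 4 * pi * ra^2 * spec$voxel_size / vox_vol
  expect_lt(abs(n_air - expected), layer)
})

test_that("bilateral ROI sets come in mirrored name-matched pairs", {
  vol <- test_head()
  rois <- make_roiset(vol)
  expect_length(rois$masks, 20)
  expect_equal(sum(rois$info$laterality == "left"), 10)
  expect_equal(sum(rois$info$laterality == "right"), 10)
  # symmetry of the unperturbed phantom: mirrored pairs have equal volume
  for (base in unique(rois$info$base)) {
    expect_equal(sum(rois$masks[[paste0(base, "_L")]]),
                 sum(rois$masks[[paste0(base, "_R")]]),
                 info = base)
  }
  # every mask lies inside brain tissue
  brain <- vol$labels %in% c(4L, 5L)
  for (m in rois$masks) expect_true(all(brain[m]))
})

test_that("degenerate ROI specs are rejected by name", {
  vol <- test_head()
  bad <- default_roi_spec()
  bad$radius_mm[3] <- 0
  expect_error(make_roiset(vol, bad), "ACG")
  outside <- data.frame(name = "X", laterality = "bilateral",
                        polar_deg = 90, azim_deg = 0, depth_mm = 85,
                        radius_mm = 2)
  expect_error(make_roiset(vol, outside), "empty")
})

test_that("cohorts are seed-reproducible, distinct under jitter, identical without", {
  spec <- test_spec()
  ch1 <- make_cohort(3, spec)
  ch2 <- make_cohort(3, spec)
  for (h in 1:3) {
    expect_identical(ch1[[h]]$volume$labels, ch2[[h]]$volume$labels)
    expect_identical(ch1[[h]]$rois$masks, ch2[[h]]$rois$masks)
  }
  labs <- lapply(ch1, function(x) x$volume$labels)
  expect_false(identical(labs[[1]], labs[[2]]))
  expect_false(identical(labs[[2]], labs[[3]]))

  frozen <- test_spec(perturbation = list(radius_frac = 0, roi_jitter_mm = 0))
  chz <- make_cohort(3, frozen)
  expect_identical(chz[[1]]$volume$labels, chz[[2]]$volume$labels)
  expect_identical(chz[[1]]$volume$labels, chz[[3]]$volume$labels)

  expect_error(make_cohort(0, spec), ">= 1")
})

test_that("label volumes survive a NIfTI round trip", {
  vol <- test_head()
  f <- tempfile(fileext = ".nii")
  write_volume_nifti(vol, f)
  back <- read_volume_nifti(f)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$voxel_size, vol$voxel_size)
  expect_equal(back$affine, vol$affine, tolerance = 1e-5)
  unlink(f)
})

test_that("phantom specs survive a YAML round trip", {
  spec <- test_spec()
  f <- tempfile(fileext = ".yaml")
  write_phantom_yaml(spec, f)
  back <- read_phantom_yaml(f)
  expect_equal(back$shell_radii, spec$shell_radii)
  expect_equal(back$grid_shape, spec$grid_shape)
  expect_identical(make_spherical_head(back)$labels,
                   make_spherical_head(spec)$labels)
  unlink(f)
})
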