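make_test_atlas <- function(n_regions = 4, vs = 4) {
  dm <- c(24, 4 + 5 * ceiling(n_regions / 4), 24)
  labels <- array(0L, dm)
  # one cubic region per label, laid out on a grid, alternating sides
  nt <- list()
  for (k in seq_len(n_regions)) {
    i0 <- 2 + 5 * ((k - 1) %% 4)
    j0 <- 2 + 5 * ((k - 1) %/% 4)
    labels[i0:(i0 + 3), j0:(j0 + 3), 10:13] <- k
    nt[[k]] <- data.frame(
      label = k,
      name = paste0("R", (k + 1) %/% 2, "_", if (k %% 2) "L" else "R"),
      laterality = if (k %% 2) "left" else "right",
      stringsAsFactors = FALSE)
  }
  list(labels = labels, affine = tdcsim:::grid_affine(dm, vs),
       name_table = do.call(rbind, nt), voxel_size = vs)
}

test_that("affine transforms map, invert and reject singular matrices", {
  ct <- coordinate_table("s1", "TAL", c(10, -5), c(0, 20), c(30, 7), "fMRI")
  id <- apply_affine(ct, diag(4), new_space = "TAL")
  expect_equal(id$x, ct$x)
  tr <- diag(4); tr[1, 4] <- 10
  shifted <- apply_affine(ct, tr)
  expect_equal(shifted$x, ct$x + 10)
  expect_equal(shifted$y, ct$y)
  M <- diag(4); M[1:3, 1:3] <- matrix(c(0.99, 0.05, 0, -0.04, 1.02, 0.03,
                                        0, -0.02, 0.97), 3)
  M[1:3, 4] <- c(1.2, -0.7, 3)
  round_trip <- apply_affine(apply_affine(ct, M), solve(M))
  expect_equal(round_trip$x, ct$x, tolerance = 1e-9)
  expect_equal(round_trip$z, ct$z, tolerance = 1e-9)
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(apply_affine(ct, sing), "singular")
  expect_error(coordinate_table("a", "MNI", Inf, 0, 0), "finite")
})

test_that("coordinates map to atlas regions with unassigned fallbacks", {
  atl <- make_test_atlas()
  # center of region 1 in world coordinates
  w <- atl$affine %*% c(3.5, 3.5, 11.5, 1)
  ct <- coordinate_table("s", "MNI",
                         x = c(w[1], -900, 44),
                         y = c(w[2], 0, 44),
                         z = c(w[3], 0, 44))
  res <- map_to_atlas(ct, atl, atl$name_table)
  expect_equal(res$region[1], "R1_L")
  expect_equal(res$region[2], "unassigned")  # outside the grid
  expect_equal(res$region[3], "unassigned")  # background label
  # two coordinates in the same region agree
  w2 <- atl$affine %*% c(4.5, 3.5, 11.5, 1)
  ct2 <- coordinate_table("s", "MNI", c(w[1], w2[1]), c(w[2], w2[2]),
                          c(w[3], w2[3]))
  expect_equal(unique(map_to_atlas(ct2, atl, atl$name_table)$region), "R1_L")
})

test_that("atlas ROIs resample into a target grid without new labels", {
  atl <- make_test_atlas(n_regions = 20)
  target <- tdcsim:::new_tissue_volume(
    array(4L, dim(atl$labels)), atl$voxel_size)
  regions <- atl$name_table$name
  rs <- roiset_from_atlas(atl, atl$name_table, regions, target)
  expect_length(rs$masks, 20)
  expect_equal(sum(rs$info$laterality == "left"), 10)
  # identity resample equals direct label extraction
  for (k in seq_len(20)) {
    direct <- array(atl$labels == k, dim(atl$labels))
    expect_identical(rs$masks[[atl$name_table$name[k]]], direct)
  }
  expect_error(roiset_from_atlas(atl, atl$name_table, "missing_region",
                                 target), "absent")
  # a coarser target grid still yields non-empty nearest-neighbor masks
  coarse <- tdcsim:::new_tissue_volume(array(4L, c(12, 12, 12)),
                                       atl$voxel_size * 2)
  rs2 <- roiset_from_atlas(atl, atl$name_table, regions[1], coarse)
  expect_gt(sum(rs2$masks[[1]]), 0)
})

test_that("atlas NIfTI + TSV round trip feeds the same pipeline", {
  atl <- make_test_atlas()
  nii <- tempfile(fileext = ".nii")
  tsv <- tempfile(fileext = ".tsv")
  write_volume_nifti(atl$labels, nii, voxel_size = atl$voxel_size)
  utils::write.table(atl$name_table, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_atlas(nii, tsv)
  expect_identical(back$labels, atl$labels)
  expect_equal(back$name_table$name, atl$name_table$name)
  expect_equal(back$affine, atl$affine, tolerance = 1e-5)
  unlink(c(nii, tsv))
})
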