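# A fake flattened stack whose ROI region is addressable by construction:
# plates at rows (top_row, bottom_row), upsample 4, lateral pixel 1.5 um.
blank_flat <- function(n_z, n_x, n_frames, top_row, bottom_row) {
  fake_flat(array(0, c(n_z, n_x, n_frames)), top_row, bottom_row)
}

test_that("ROI height follows the plate-separation rule", {
  # measured H ~292 um (>200): 12-px ROIs
  d_ax <- distortion_factors(1.45, 0)$axial
  bot <- 20 + round(292 / (2 * d_ax))
  fl <- blank_flat(bot + 20, 800, 2, 20, bot)
  g <- partition_grid(fl)
  expect_equal(g$roi_height, 12L)
  expect_equal(g$roi_width, 400L)
  # measured H ~154 um (<200): 18-px ROIs
  bot2 <- 20 + round(154 / (2 * d_ax))
  fl2 <- blank_flat(bot2 + 20, 800, 2, 20, bot2)
  g2 <- partition_grid(fl2)
  expect_equal(g2$roi_height, 18L)
  # depths are strictly increasing and inside (0, H)
  expect_true(all(diff(g$depth_um) > 0))
  expect_true(all(g$depth_um > 0 & g$depth_um < fl$measured_H))
  # region only one ROI tall: error
  fl3 <- blank_flat(60, 800, 2, 20, 20 + 18)
  expect_error(partition_grid(fl3), class = "octflow_error_invalid_stack")
})

test_that("row thresholds are mean + 1.5 SD with affine equivariance", {
  fl <- blank_flat(100, 800, 3, 10, 80)
  fl$frames[] <- 0.2  # constant image: threshold = mean, all pixels zeroed
  g <- partition_grid(fl)
  thr <- threshold_rows(fl, g)
  expect_equal(thr, rep(0.2, g$n_row))
  roi <- roi_pixels(fl, g, 1, 1, 1)
  expect_true(all(apply_threshold(roi, thr[1]) == 0))
  # one bright blob on a flat background survives alone
  fl$frames[] <- 0.05
  rs <- g$row_start[2]
  fl$frames[rs + 3:4, 101:102, ] <- 0.9
  thr2 <- threshold_rows(fl, g)
  t_roi <- apply_threshold(roi_pixels(fl, g, 2, 1, 1), thr2[2])
  expect_true(all(t_roi[t_roi > 0] >= 0.9 - 1e-12))
  expect_equal(sum(t_roi > 0), 4)
  # scaling intensities by c scales the threshold by c
  fl2 <- fl
  fl2$frames <- fl$frames * 3
  expect_equal(threshold_rows(fl2, g), 3 * thr2)
})

test_that("cluster check demands more than one diagonally adjacent pixel", {
  expect_false(cluster_check(matrix(0, 12, 40)))
  one <- matrix(0, 12, 40); one[5, 7] <- 1
  expect_false(cluster_check(one))
  block <- matrix(0, 12, 40); block[5:6, 7:8] <- 1
  expect_true(cluster_check(block))
  # two isolated pixels without diagonal adjacency fail
  iso <- matrix(0, 12, 40); iso[3, 5] <- 1; iso[9, 30] <- 1
  expect_false(cluster_check(iso))
  # a horizontal single-row streak has no diagonal overlap
  streak <- matrix(0, 12, 40); streak[6, 5:35] <- 1
  expect_false(cluster_check(streak))
})

test_that("validity mask requires every row to keep a clustered ROI", {
  fl <- blank_flat(74, 800, 4, 10, 64)  # 2 rows of 18 after margins
  g <- partition_grid(fl)
  # put a 2x2 particle in every (i, j) in all frames
  for (i in seq_len(g$n_row)) for (j in seq_len(g$n_col)) {
    fl$frames[g$row_start[i] + 5:6, g$col_start[j] + 10:11, ] <- 1
  }
  thr <- threshold_rows(fl, g)
  v <- build_validity(fl, g, thr)
  expect_true(all(v))
  # a particle leaving one ROI mid-sequence invalidates only that ROI
  fl2 <- fl
  fl2$frames[g$row_start[1] + 5:6, g$col_start[1] + 10:11, 3:4] <- 0
  v2 <- build_validity(fl2, g, threshold_rows(fl2, g))
  expect_false(v2[1, 1])
  expect_true(v2[1, 2])
  # an empty middle row invalidates the whole stack, naming the row
  fl3 <- fl
  fl3$frames[g$row_start[2] + 0:11, , ] <- 0
  err <- expect_error(build_validity(fl3, g, threshold_rows(fl3, g)),
                      class = "octflow_error_invalid_stack")
  expect_match(conditionMessage(err), "row 2")
})
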