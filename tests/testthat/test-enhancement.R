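test_that("stalk reference is the ROI maximum", {
  fx <- awe_fixture()
  expect_equal(stalk_reference(fx$vol), 1000)
  one <- fx$vol
  one$stalk_mask <- array(FALSE, dim(one$voxels))
  one$stalk_mask[3, 3, 3] <- TRUE
  one$voxels[3, 3, 3] <- 123
  expect_equal(stalk_reference(one), 123)
  none <- fx$vol
  none$stalk_mask <- array(FALSE, dim(none$voxels))
  expect_error(stalk_reference(none), "empty")
})

test_that("AWE segmentation matches the exhaustive voxel oracle", {
  fx <- awe_fixture()
  mask <- segment_awe(fx$vol, fx$mesh, wall_band_mm = 1.5)
  expect_equal(sum(mask), 6L)
  expect_true(all(mask[fx$wall6 + 1L]))
  oracle <- awe_oracle(fx$vol, fx$mesh, 0.6 * 1000, 1.5)
  expect_identical(mask, oracle)

  # threshold factor 0 selects every wall-band voxel outside lumen/stalk
  m0 <- segment_awe(fx$vol, fx$mesh, threshold_factor = 0)
  o0 <- awe_oracle(fx$vol, fx$mesh, 0, 1.5)
  expect_identical(m0, o0)
  expect_gt(sum(m0), sum(mask))

  # nothing above threshold -> empty mask and zero downstream area
  dark <- fx$vol
  dark$voxels[dark$voxels == 700] <- 100
  md <- segment_awe(dark, fx$mesh)
  expect_equal(sum(md), 0L)
  proj <- project_to_surface(dark, md, fx$mesh)
  s <- fx$mesh$point_data$s
  met <- enhancement_metrics(fx$mesh, proj$enhanced,
                             er_map(proj$intensity, 1000), s > 2 & s < 10)
  expect_equal(met$enhancement_area, 0)
  expect_equal(met$proportion_enhanced, 0)
  expect_equal(met$cr_max, 0)
})

test_that("surface projection flags exactly the in-radius vertices", {
  fx <- awe_fixture()
  vol <- fx$vol
  vol$voxels[] <- 0
  awe <- array(FALSE, dim(vol$voxels))
  awe[6, 12, 9] <- TRUE          # world (5, 11, 8)
  vol$voxels[6, 12, 9] <- 800
  proj <- project_to_surface(vol, awe, fx$mesh, search_radius_mm = 1.0)
  d <- sqrt((fx$mesh$vertices[, 1] - 5)^2 + (fx$mesh$vertices[, 2] - 11)^2 +
              (fx$mesh$vertices[, 3] - 8)^2)
  expect_identical(proj$enhanced, d <= 1.0)
  expect_true(all(proj$intensity[proj$enhanced] == 800))
  expect_true(all(proj$intensity[!proj$enhanced] == 0))

  none <- project_to_surface(vol, array(FALSE, dim(vol$voxels)), fx$mesh)
  expect_false(any(none$enhanced))
  zero <- project_to_surface(vol, awe, fx$mesh, search_radius_mm = 0)
  expect_false(any(zero$enhanced))
})

test_that("ER is the stalk-normalized intensity", {
  expect_equal(er_map(600, 1000), 0.6)
  expect_equal(er_map(0, 1000), 0)
  expect_error(er_map(600, 0), "> 0")

  # noise-free generator round-trip: surface ER recovers a + b * rank(RRT)/n
  bc <- bulge_case(r0 = 2, A = 1, s0 = 20, sigma = 4, spacing = 0.7,
                   angular_res = 32)
  nv <- n_vertices(bc$mesh)
  # spatially smooth pathology field (as real RRT is), so the voxel
  # round-trip error is voxelization, not neighbor-rank shuffling
  rrt_truth <- bc$mesh$point_data$s + 0.2 * sin(bc$mesh$point_data$theta)
  vol <- make_enhancement_volume(bc$mesh, rrt_truth,
                                 coupling_params(a = 0.2, b = 0.6,
                                                 noise_sd = 0, I_stalk = 1000),
                                 voxel_spacing = 0.7)
  awe <- segment_awe(vol, bc$mesh, threshold_factor = 0.05)
  proj <- project_to_surface(vol, awe, bc$mesh)
  er <- er_map(proj$intensity, stalk_reference(vol))
  truth <- 0.2 + 0.6 * rank(rrt_truth, ties.method = "average") / nv
  hit <- proj$enhanced
  expect_gt(mean(hit), 0.9)
  expect_lt(mean(abs(er[hit] - truth[hit])), 0.05)
})

test_that("enhanced and non-enhanced areas partition the segment exactly", {
  cs <- cylinder_case(r0 = 2, L = 20, spacing = 0.5, angular_res = 64)
  nv <- n_vertices(cs$mesh)
  seg_mask <- cs$mesh$point_data$s >= 4 & cs$mesh$point_data$s <= 16
  # azimuthal half-painting
  enhanced <- cs$mesh$point_data$theta < pi
  er <- ifelse(enhanced, 0.8, 0)
  met <- enhancement_metrics(cs$mesh, enhanced, er, seg_mask)
  expect_equal(met$proportion_enhanced, 0.5, tolerance = 0.02)
  expect_identical(met$enhancement_area + met$nonenhanced_area,
                   met$segment_area)
  expect_equal(met$cr_max, 0.8)

  all_on <- enhancement_metrics(cs$mesh, rep(TRUE, nv), er, seg_mask)
  expect_equal(all_on$proportion_enhanced, 1)
  expect_error(enhancement_metrics(cs$mesh, enhanced, er, rep(FALSE, nv)),
               "empty")
})

test_that("lowering the threshold never shrinks the enhanced set", {
  bc <- bulge_case(r0 = 2, A = 1, s0 = 20, sigma = 4, spacing = 0.7,
                   angular_res = 32)
  nv <- n_vertices(bc$mesh)
  set.seed(9)
  vol <- make_enhancement_volume(bc$mesh, runif(nv),
                                 coupling_params(a = 0.1, b = 0.8,
                                                 noise_sd = 0.15,
                                                 I_stalk = 1000),
                                 voxel_spacing = 0.7)
  sets <- lapply(c(0.8, 0.6, 0.4), function(tf) {
    awe <- segment_awe(vol, bc$mesh, threshold_factor = tf)
    project_to_surface(vol, awe, bc$mesh)$enhanced
  })
  expect_true(all(sets[[2]][sets[[1]]]))   # 0.8 -> 0.6 grows
  expect_true(all(sets[[3]][sets[[2]]]))   # 0.6 -> 0.4 grows
})

test_that("CR_max respects the threshold and rigid motions", {
  bc <- bulge_case(r0 = 2, A = 1, s0 = 20, sigma = 4, spacing = 0.7,
                   angular_res = 32)
  nv <- n_vertices(bc$mesh)
  set.seed(2)
  vol <- make_enhancement_volume(bc$mesh, runif(nv),
                                 coupling_params(a = 0.1, b = 0.8,
                                                 noise_sd = 0.1,
                                                 I_stalk = 1000),
                                 voxel_spacing = 0.7)
  seg <- c(12, 28)
  e1 <- enhancement_map(vol, bc$mesh, bc$cl, seg)
  expect_true(any(e1$enhanced))
  expect_gte(e1$cr_max, 0.6)

  # joint rigid motion of mesh, centerline and volume
  ang <- 0.6
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  Tm <- rbind(cbind(R, shift), c(0, 0, 0, 1))
  mesh2 <- bc$mesh
  mesh2$vertices <- bc$mesh$vertices %*% t(R) +
    matrix(shift, nv, 3, byrow = TRUE)
  cl2 <- centerline(bc$cl$points %*% t(R) +
                      matrix(shift, nrow(bc$cl$points), 3, byrow = TRUE))
  vol2 <- vol
  vol2$affine <- Tm %*% vol$affine
  e2 <- enhancement_map(vol2, mesh2, cl2, seg)
  expect_equal(e2$cr_max, e1$cr_max, tolerance = 1e-9)
  expect_equal(e2$enhancement_area, e1$enhancement_area, tolerance = 1e-6)
})
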