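test_that("segmentation finds the spheroid disk and its centroid", {
  cfg <- small_stack_cfg(disk_gain = 0.5)
  st <- simulate_zstack(cfg)
  seg <- segment_spheroid(st)
  ctr <- (cfg$image_side + 1) / 2
  expect_true(seg$found)
  expect_lt(max(abs(seg$centroid - ctr)), 2)
  expect_lt(abs(seg$area - pi * cfg$disk_radius^2) / (pi * cfg$disk_radius^2),
            0.10)
})

test_that("uniform images fall back to the image centre", {
  st <- zstack(array(500, dim = c(3L, 64L, 64L)), z_positions = 1:3)
  seg <- segment_spheroid(st)
  expect_false(seg$found)
  expect_equal(unname(seg$centroid), c(32.5, 32.5))
})

test_that("with two objects the larger one wins", {
  img <- matrix(100, 128L, 128L)
  rows <- matrix(seq_len(128L), 128L, 128L); cols <- t(rows)
  img[(rows - 40)^2 + (cols - 40)^2 <= 24^2] <- 400   # large disk, r = 24
  img[(rows - 95)^2 + (cols - 95)^2 <= 12^2] <- 400   # small disk, r = 12
  st <- zstack(array(img, dim = c(1L, 128L, 128L)), z_positions = 0)
  seg <- segment_spheroid(st, reference_slice = 1L)
  expect_lt(max(abs(seg$centroid - c(40, 40))), 2)
})

test_that("uniform stacks give a flat ratio of exactly 1", {
  st <- zstack(array(500, dim = c(5L, 64L, 64L)), z_positions = 1:5)
  rois <- roi_pair(c(32, 32), 3L, {
    m <- matrix(FALSE, 64L, 64L); m[1:5, ] <- TRUE; m
  })
  cv <- focal_ratio_curve(st, rois)
  expect_equal(cv$ratio, rep(1, 5L))
  sm <- focus_summary(cv)
  expect_equal(sm$peak_ratio, 1)
  expect_false(sm$focuses_light)
})

test_that("the focal curve matches the generator's closed form", {
  cfg <- small_stack_cfg()
  st <- simulate_zstack(cfg)
  cv <- focal_ratio_curve(st)
  # peak exactly at the planted focal plane
  sm <- focus_summary(cv)
  expect_equal(sm$peak_z, cfg$z_f)
  expect_true(sm$focuses_light)
  # R(z_f) = (b + A(z_f)) / b within quantization error
  a_f <- spot_amplitude(cfg, cfg$z_f)
  expect_equal(sm$peak_ratio, (cfg$background_b + a_f) / cfg$background_b,
               tolerance = 1e-3)
  # strictly decreasing with |z - z_f|
  expect_true(all(diff(by_distance(cv$ratio, cv$z, cfg$z_f)) < 0))
})

test_that("errors: zero background, out-of-bounds ROI, overlap", {
  st <- zstack(array(0, dim = c(2L, 64L, 64L)), z_positions = 1:2)
  bg <- matrix(FALSE, 64L, 64L); bg[1:4, ] <- TRUE
  expect_error(focal_ratio_curve(st, roi_pair(c(32, 32), 3L, bg)),
               "zero background")
  st2 <- zstack(array(500, dim = c(2L, 64L, 64L)), z_positions = 1:2)
  bg2 <- matrix(FALSE, 64L, 64L); bg2[60:64, ] <- TRUE
  expect_error(focal_ratio_curve(st2, roi_pair(c(5, 5), 10L, bg2)),
               "bounds")
  full <- matrix(TRUE, 64L, 64L)
  expect_error(roi_pair(c(32, 32), 3L, full), "overlap")
})

test_that("the ratio is scale invariant and offsets shrink it toward 1", {
  cfg <- small_stack_cfg(spot_flux_F = 2e4)
  st <- simulate_zstack(cfg)
  rois <- auto_roi(st)
  cv <- focal_ratio_curve(st, rois)
  st2 <- zstack(st$intensities * 2, st$z_positions)
  expect_equal(focal_ratio_curve(st2, rois)$ratio, cv$ratio)
  st3 <- zstack(st$intensities + 300, st$z_positions)
  cv3 <- focal_ratio_curve(st3, rois)
  expect_true(all(cv3$ratio <= cv$ratio))
  expect_true(all(cv3$ratio >= 1))
})

test_that("ties in the peak resolve to the z closest to focus", {
  cv <- structure(data.frame(z = c(-30, -10, 10), ratio = c(2, 2, 1.5),
                             max_center = 1, mean_background = 1),
                  class = c("focal_curve", "data.frame"))
  expect_equal(focus_summary(cv)$peak_z, -10)
})

test_that("condition comparison is consistent and needs valid groups", {
  cfg <- small_stack_cfg()
  cv <- focal_ratio_curve(simulate_zstack(cfg))
  cmp <- compare_conditions(list(a = list(cv, cv), b = list(cv, cv)))
  expect_equal(cmp$summary$mean_peak_ratio[1L], cmp$summary$mean_peak_ratio[2L])
  expect_equal(cmp$summary$sd_peak_ratio, c(0, 0))
  expect_error(compare_conditions(list(list(cv))), "named")
  expect_error(compare_conditions(list(a = list())), ">= 1 curve")
})

test_that("Poisson noise rarely displaces the focal peak", {
  n_runs <- 200L
  step <- 30 / 12  # z-step of the small stack
  hits <- vapply(seq_len(n_runs), function(k) {
    cfg <- small_stack_cfg(noise_model = "poisson", seed = 1000L + k)
    sm <- focus_summary(focal_ratio_curve(simulate_zstack(cfg)))
    abs(sm$peak_z - cfg$z_f) <= step + 1e-9
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})
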