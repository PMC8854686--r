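make_moving_blob_movie <- function(n_frames = 20, step = c(0, 0),
                                   start = c(30, 30), H = 80, W = 80,
                                   amp = 100, sigma = 3, noise = 0,
                                   seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(t) {
    f <- gauss_frame(H, W, rbind(start + (t - 1) * step), amp = amp,
                     sigma = sigma, bg = 10)
    if (noise > 0) f <- pmax(f + matrix(rnorm(H * W, sd = noise), H, W), 0)
    f
  })
  frame_stack(frames)
}

seed_roi_at <- function(p, frame = 1L, half = 4) {
  roi(1L, frame, centroid = p,
      bbox = c(p[1] - half, p[2] - half, p[1] + half, p[2] + half))
}

test_that("tracker initialization centers the cloud on the roi", {
  st <- make_moving_blob_movie()
  cl <- init_tracker(st, seed_roi_at(c(30, 30)), seqtrack_params(rng_seed = 7))
  expect_equal(cl$estimate, c(30, 30))
  expect_equal(sum(cl$weights), 1)
  expect_true(all(cl$positions[, 1] == 30))
  # corner roi: replicate padding, no failure
  cl2 <- init_tracker(st, seed_roi_at(c(1, 1)), seqtrack_params())
  expect_equal(dim(cl2$template), dim(cl$template))
  expect_error(init_tracker(st, seed_roi_at(c(500, 500)),
                            seqtrack_params()), "outside")
})

test_that("identical seeds give bit-identical tracks", {
  st <- make_moving_blob_movie(10, step = c(1, 0.5), noise = 3)
  p <- seqtrack_params(n_particles = 100, rng_seed = 5)
  a <- track_sequential(st, seed_roi_at(c(30, 30)), 1, 10, p)
  b <- track_sequential(st, seed_roi_at(c(30, 30)), 1, 10, p)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$confidence, b$confidence)
})

test_that("normalized cross-correlation has its closed-form anchors", {
  set.seed(2)
  a <- matrix(rnorm(49), 7)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a), -1)
  expect_equal(ncc(a, matrix(5, 7, 7)), 0)  # zero-variance contract
})

test_that("a uniform next frame yields uniform weights", {
  st0 <- frame_stack(list(gauss_frame(40, 40, rbind(c(20, 20)), 50, 3),
                          matrix(3, 40, 40)))
  cl <- init_tracker(st0, seed_roi_at(c(20, 20)), seqtrack_params(rng_seed = 1))
  cl2 <- step_tracker(cl, get_frame(st0, 2))
  expect_false(cl2$lost)
  expect_true(max(abs(cl2$weights - 1 / length(cl2$weights))) < 1e-12)
})

test_that("a static noiseless blob is held within a pixel for 20 steps", {
  st <- make_moving_blob_movie(21)
  res <- track_sequential(st, seed_roi_at(c(30, 30)), 1, 21,
                          seqtrack_params(rng_seed = 0, motion_sigma = 3))
  expect_length(res$frames, 21)
  errs <- sqrt(rowSums((res$estimates -
                          matrix(c(30, 30), 21, 2, byrow = TRUE))^2))
  expect_lt(max(errs[-1]), 1)
})

test_that("a drifting noisy blob is followed to within 2 px on average", {
  step <- c(2, 1)
  st <- make_moving_blob_movie(30, step = step, start = c(15, 15),
                               H = 100, W = 80, amp = 100, noise = 5,
                               seed = 3)
  res <- track_sequential(st, seed_roi_at(c(15, 15)), 1, 30,
                          seqtrack_params(rng_seed = 1))
  truth <- cbind(15 + (res$frames - 1) * step[1],
                 15 + (res$frames - 1) * step[2])
  expect_length(res$frames, 30)
  expect_lt(mean(sqrt(rowSums((res$estimates - truth)^2))), 2)
})

test_that("backward tracking mirrors forward tracking on a reversed movie", {
  step <- c(2, 1)
  fwd <- make_moving_blob_movie(15, step = step, start = c(20, 20),
                                H = 80, W = 60, noise = 5, seed = 4)
  bwd <- frame_stack(rev(fwd$frames))
  endpt <- c(20, 20) + 14 * step
  a <- track_sequential(fwd, seed_roi_at(endpt, 15), 15, 1,
                        seqtrack_params(rng_seed = 2))
  b <- track_sequential(bwd, seed_roi_at(endpt, 1), 1, 15,
                        seqtrack_params(rng_seed = 2))
  expect_identical(a$frames, 15:1)
  # same physical trajectory, visited in mirrored frame order
  expect_lt(max(sqrt(rowSums((a$estimates - b$estimates)^2))), 2)
})

test_that("a single-frame range returns the seed as a one-node track", {
  st <- make_moving_blob_movie(5)
  res <- track_sequential(st, seed_roi_at(c(30, 30)), 3, 3,
                          seqtrack_params())
  expect_equal(res$frames, 3L)
  expect_equal(res$track$frames, 3L)
  expect_equal(res$estimates[1, ], c(30, 30))
})

test_that("resume_from truncates, re-seeds and completes the range", {
  st <- make_moving_blob_movie(20, step = c(1.5, 0), start = c(20, 30),
                               H = 90, W = 60, noise = 5, seed = 6)
  res <- track_sequential(st, seed_roi_at(c(20, 30)), 1, 20,
                          seqtrack_params(rng_seed = 3))
  # resume at frame 1 re-runs everything
  full <- resume_from(res, 1, c(20, 30))
  expect_length(full$frames, 20)
  # resume mid-way from the true position: nodes before stay unchanged
  mid <- resume_from(res, 10, c(20 + 9 * 1.5, 30))
  expect_length(mid$frames, 20)
  expect_equal(mid$estimates[1:9, ], res$estimates[1:9, ])
  truth10 <- cbind(20 + (10:20 - 1) * 1.5, 30)
  errs <- sqrt(rowSums((mid$estimates[10:20, ] - truth10)^2))
  expect_lt(mean(errs), 2)
  expect_error(resume_from(res, 25, c(0, 0)), "range")
})

test_that("a corrected restart beats an uncorrected run after an occlusion", {
  # blank out some frames mid-movie so the tracker walks off target
  step <- c(2, 0)
  st <- make_moving_blob_movie(20, step = step, start = c(20, 30),
                               H = 90, W = 60, noise = 4, seed = 9)
  frames <- st$frames
  for (t in 8:10) frames[[t]][] <- 10
  occluded <- frame_stack(frames)
  res <- track_sequential(occluded, seed_roi_at(c(20, 30)), 1, 20,
                          seqtrack_params(rng_seed = 11))
  truth <- cbind(20 + (0:19) * step[1], 30)
  err_pre <- sqrt(rowSums((res$estimates[res$frames %in% 11:20, ,
                                         drop = FALSE] -
                             truth[11:20, ])^2))
  fixed <- resume_from(res, 11, truth[11, ])
  err_post <- sqrt(rowSums((fixed$estimates[fixed$frames %in% 11:20, ,
                                            drop = FALSE] -
                              truth[11:20, ])^2))
  expect_lt(mean(err_post), mean(err_pre) + 1e-9)
})

test_that("weights stay normalized and the estimate stays in bounds", {
  st <- make_moving_blob_movie(10, step = c(3, 3), start = c(70, 70),
                               H = 80, W = 80, noise = 5, seed = 12)
  res <- track_sequential(st, seed_roi_at(c(70, 70)), 1, 10,
                          seqtrack_params(rng_seed = 4, motion_sigma = 4))
  expect_true(all(res$estimates[, 1] >= 1 & res$estimates[, 1] <= 80))
  expect_true(all(res$estimates[, 2] >= 1 & res$estimates[, 2] <= 80))
})
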