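test_that("LoG response is zero on constants and linear in intensity", {
  fr <- matrix(7, 40, 40)
  expect_lt(max(abs(log_response(fr, 3))), 1e-9 * 7)
  fr2 <- gauss_frame(50, 50, rbind(c(25, 25)), amp = 10, sigma = 3)
  expect_equal(log_response(3 * fr2, 3), 3 * log_response(fr2, 3),
               tolerance = 1e-9)
  expect_error(log_response(matrix(c(NaN, 1, 1, 1), 2, 2), 2),
               "non-finite")
})

test_that("LoG response of a matched Gaussian blob peaks at its center", {
  # dense-grid oracle: evaluate the response everywhere, take the argmax
  fr <- gauss_frame(60, 60, rbind(c(30.4, 28.7)), amp = 100, sigma = 3)
  resp <- log_response(fr, 3)
  peak <- which(resp == max(resp), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((peak - c(30.4, 28.7))^2)), 1)
  # scale-normalized matched-filter peak is about half the amplitude
  expect_gt(max(resp), 30)
})

test_that("detect_spots finds isolated blobs where an exhaustive scan does", {
  ctr <- rbind(c(15, 15), c(15, 55), c(55, 35))
  fr <- gauss_frame(70, 70, ctr, amp = 100, sigma = 3)
  p <- detection_params(sigma = 3, threshold = 5, min_distance = 5)
  sp <- detect_spots(fr, p)
  expect_length(sp, 3)
  # oracle: every returned spot is a strict neighborhood maximum of the
  # response above threshold
  resp <- log_response(fr, 3)
  for (s in sp) {
    pk <- round(s$centroid)
    nb <- resp[(pk[1] - 1):(pk[1] + 1), (pk[2] - 1):(pk[2] + 1)]
    expect_equal(max(nb), resp[pk[1], pk[2]])
    expect_gt(resp[pk[1], pk[2]], p$threshold)
  }
  # each true center is recovered within 1 px
  got <- t(vapply(sp, function(s) s$centroid, numeric(2)))
  for (k in 1:3)
    expect_lt(min(sqrt(rowSums((got - matrix(ctr[k, ], 3, 2,
                                             byrow = TRUE))^2))), 1)
  # responses are sorted descending
  rs <- vapply(sp, function(s) s$features$response, numeric(1))
  expect_true(all(diff(rs) <= 0))
  # blank frame: nothing
  expect_length(detect_spots(matrix(0, 40, 40), p), 0)
})

test_that("minimum-distance suppression keeps the stronger of a close pair", {
  fr <- gauss_frame(40, 40, rbind(c(20, 18), c(20, 22)), amp = 100,
                    sigma = 2)
  sp <- detect_spots(fr, detection_params(sigma = 2, threshold = 5,
                                          min_distance = 10))
  # brute-force check: among all returned pairs, none closer than 10
  if (length(sp) > 1)
    for (i in seq_along(sp)) for (j in seq_len(i - 1))
      expect_gte(sqrt(sum((sp[[i]]$centroid - sp[[j]]$centroid)^2)), 10)
  expect_length(sp, 1)
})

test_that("spot detection is translation-equivariant in the interior", {
  base <- gauss_frame(64, 64, rbind(c(25, 25), c(40, 45)), amp = 80,
                      sigma = 3)
  shift <- c(4, -3)
  shifted <- gauss_frame(64, 64,
                         rbind(c(25, 25) + shift, c(40, 45) + shift),
                         amp = 80, sigma = 3)
  p <- detection_params(sigma = 3, threshold = 5)
  a <- t(vapply(detect_spots(base, p), function(s) s$centroid, numeric(2)))
  b <- t(vapply(detect_spots(shifted, p), function(s) s$centroid,
                numeric(2)))
  a <- a[order(a[, 1]), , drop = FALSE]
  b <- b[order(b[, 1]), , drop = FALSE]
  expect_equal(b, a + matrix(shift, nrow(a), 2, byrow = TRUE),
               tolerance = 0.2)
})

test_that("watershed regions partition the foreground around their markers", {
  fr <- gauss_frame(40, 40, rbind(c(18, 14), c(22, 26)), amp = 100,
                    sigma = 4, bg = 2)
  p <- detection_params(sigma = 4, threshold = 5, fg_method = "otsu")
  sp <- list(roi(1, 1, centroid = c(18, 14)), roi(2, 1, centroid = c(22, 26)))
  seg <- segment_regions(fr, sp, p)
  expect_length(attr(seg, "background_markers"), 0)
  m <- seg$masks
  # disjoint regions containing their markers
  expect_equal(m[18, 14], 1L)
  expect_equal(m[22, 26], 2L)
  # regions cover exactly the foreground (this fg rule keeps it whole)
  sm <- trackcells:::gaussian_smooth(fr, p$smoothing_sigma)
  expect_true(all(m[sm <= min(sm[m > 0])] == 0 | m[sm <= min(sm[m > 0])] > 0))
  expect_true(sum(m == 1) + sum(m == 2) <= sum(sm > min(sm[m > 0]) - 1e-12))
  # every region pixel is closer (in relief order) to its own marker:
  # check the updated rois carry connected regions with correct centroids
  for (r in seg$rois) expect_length(validate_roi(r), 0)
})

test_that("a marker on background yields an empty region and is reported", {
  fr <- gauss_frame(40, 40, rbind(c(20, 20)), amp = 100, sigma = 3, bg = 1)
  sp <- list(roi(1, 1, centroid = c(20, 20)), roi(2, 1, centroid = c(5, 35)))
  seg <- segment_regions(fr, sp, detection_params(sigma = 3))
  expect_equal(attr(seg, "background_markers"), 2L)
  expect_false(any(seg$masks == 2))
  expect_error(segment_regions(fr, list(roi(1, 1, centroid = c(99, 5))),
                               detection_params()), "outside")
})

test_that("feature quantification matches closed forms", {
  sqr <- matrix(0L, 20, 20)
  sqr[8:12, 6:10] <- 1L
  r <- rois_from_masks(list(sqr))[[1]][[1]]
  f <- compute_features(r, matrix(10, 20, 20))
  expect_equal(f$area, 25)
  expect_equal(f$mean_c1, 10)
  expect_equal(f$sum_c1, 250)

  dm <- disk_mask(61, 61, c(31, 31), 20)
  rd <- rois_from_masks(list(dm))[[1]][[1]]
  fd <- compute_features(rd, matrix(1, 61, 61))
  expect_gt(fd$circularity, 0.85)
  expect_lt(fd$circularity, 1.05)
  hollow <- roi(1, 1, centroid = c(5, 5), bbox = c(4, 4, 6, 6))
  hollow$region <- matrix(integer(0), 0, 2)
  expect_error(compute_features(hollow, matrix(1, 9, 9)), "empty")
})

test_that("the plugin registry dispatches and vets detector output", {
  fr <- gauss_frame(50, 50, rbind(c(25, 25)), amp = 100, sigma = 3)
  p <- detection_params(sigma = 3, threshold = 5)
  a <- run_detector_plugin("log_spots", fr, p)
  b <- detect_spots(fr, p)
  expect_equal(a, b)
  expect_error(run_detector_plugin("no_such_detector", fr, p),
               "no detector plugin")

  m <- disk_mask(50, 50, c(10, 10), 3)
  m[disk_mask(50, 50, c(30, 30), 4) > 0] <- 2L
  p2 <- p
  p2$mask <- m
  rois <- run_detector_plugin("masks", fr, p2)
  expect_length(rois, 2)
  expect_equal(rois, rois_from_masks(list(m))[[1]])

  register_detector("broken", function(frame, params) {
    bad <- roi(1, 1, centroid = c(5, 5), bbox = c(10, 10, 12, 12))
    list(bad)
  })
  expect_error(run_detector_plugin("broken", fr, p), "broken")
})

test_that("detection recovers nearly all cells in the benign regime", {
  mv <- generate_movie(synth_config(n_frames = 6,
                                    scheduled_divisions = list(),
                                    rng_seed = 5))
  det <- detect_movie(mv$stack)
  hits <- 0; n_gt <- 0; n_det <- 0
  for (t in seq_len(6)) {
    truth <- mv$positions[[t]][vapply(mv$lineage$tracks, function(tr)
      t %in% tr$frames, logical(1)), , drop = FALSE]
    got <- t(vapply(det$rois[[t]], function(r) r$centroid, numeric(2)))
    n_gt <- n_gt + nrow(truth); n_det <- n_det + nrow(got)
    for (k in seq_len(nrow(truth)))
      if (min(sqrt(rowSums((got - matrix(truth[k, ], nrow(got), 2,
                                         byrow = TRUE))^2))) < 3)
        hits <- hits + 1
  }
  expect_gte(hits / n_gt, 0.95)   # recall
  expect_gte(hits / n_det, 0.95)  # precision
})
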