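test_that("frame cost matrices follow the augmented LAP construction", {
  expect_equal(dim(frame_cost_matrix(list(), list())), c(0L, 0L))

  a <- list(roi(1, 1, centroid = c(0, 0)))
  b <- list(roi(1, 2, centroid = c(3, 4)))
  cm <- frame_cost_matrix(a, b, link_params(max_link_dist = 10))
  expect_equal(cm[1, 1], 25)           # 3^2 + 4^2
  expect_equal(cm[1, 2], 1.05 * 25)    # death alternative
  expect_equal(cm[2, 1], 1.05 * 25)    # birth alternative
  expect_equal(cm[2, 2], 0)            # mirrored feasibility

  # an out-of-range pair is forbidden and routed to birth + death
  a2 <- list(roi(1, 1, centroid = c(0, 0)), roi(2, 1, centroid = c(50, 50)))
  b2 <- list(roi(1, 2, centroid = c(1, 0)), roi(2, 2, centroid = c(90, 90)))
  cm2 <- frame_cost_matrix(a2, b2, link_params(max_link_dist = 10))
  expect_true(is.infinite(cm2[2, 2]))
  asg <- solve_lap(cm2)
  bf <- brute_lap(ifelse(is.infinite(cm2), 1e9, unclass(cm2)))
  expect_equal(asg$total_cost,
               sum(cm2[cbind(seq_len(4), bf$perm)]))
  expect_equal(asg$deaths, 2L)
  expect_equal(asg$births, 2L)
})

test_that("the LAP solver is exact against exhaustive search", {
  expect_equal(solve_lap(matrix(c(1, 2, 2, 1), 2))$total_cost, 2)
  idm <- matrix(1, 4, 4) - diag(4)
  sid <- solve_lap(idm)
  expect_equal(sid$total_cost, 0)
  expect_equal(sid$col4row, 1:4)

  set.seed(99)
  for (k in 1:100) {
    n <- sample(2:5, 1)
    M <- matrix(sample(1:50, n * n, replace = TRUE), n)
    expect_equal(solve_lap(M)$total_cost, brute_lap(M)$cost)
  }
  expect_error(solve_lap(matrix(Inf, 2, 2)), "infeasible")
})

test_that("adjacent-frame linking chains identical detections", {
  rois <- drifting_rois(5, 2, c(10, 10), c(0, 0))
  segs <- link_all_frames(rois)
  expect_length(segs, 5)
  expect_true(all(vapply(segs, function(s) length(s$frames) == 2L,
                         logical(1))))
})

test_that("stage 1 leaves gaps unbridged", {
  # one cell absent in frame 2, present in frames 1 and 3
  rois <- list(
    list(roi(1, 1, centroid = c(10, 10))),
    list(),
    list(roi(1, 3, centroid = c(10, 10))))
  segs <- link_all_frames(rois)
  expect_length(segs, 2)
})

test_that("stage-1 chains agree with per-pair exhaustive assignment", {
  set.seed(4)
  n <- 3; TT <- 6
  pos <- lapply(seq_len(TT), function(t)
    matrix(c(10 + 2 * t + rnorm(n, 0, 0.3),
             seq(10, 70, length.out = n) + rnorm(n, 0, 0.3)), n))
  rois <- lapply(seq_len(TT), function(t)
    lapply(seq_len(n), function(i) roi(i, t, centroid = pos[[t]][i, ])))
  segs <- link_all_frames(rois, link_params(max_link_dist = 10))
  expect_length(segs, n)
  # oracle: per frame pair, exhaustive assignment over the augmented matrix
  for (t in seq_len(TT - 1)) {
    cm <- frame_cost_matrix(rois[[t]], rois[[t + 1]],
                            link_params(max_link_dist = 10))
    bf <- brute_lap(ifelse(is.infinite(cm), 1e9, unclass(cm)))
    expect_equal(solve_lap(cm)$total_cost,
                 sum(cm[cbind(seq_len(2 * n), bf$perm)]))
  }
  # appearance mid-movie becomes its own segment
  rois2 <- rois
  rois2[[4]] <- c(rois2[[4]], list(roi(n + 1, 4, centroid = c(60, 60))))
  rois2[[5]] <- c(rois2[[5]], list(roi(n + 1, 5, centroid = c(60, 60))))
  rois2[[6]] <- c(rois2[[6]], list(roi(n + 1, 6, centroid = c(60, 60))))
  segs2 <- link_all_frames(rois2, link_params(max_link_dist = 10))
  expect_length(segs2, n + 1)
})

test_that("stage 2 closes a two-frame gap for a stationary cell", {
  rois <- list(
    list(roi(1, 1, centroid = c(20, 20))),
    list(),
    list(),
    list(roi(1, 4, centroid = c(20.5, 20)))
  )
  segs <- link_all_frames(rois)
  expect_length(segs, 2)
  lin <- close_gaps_and_split(segs, rois, link_params(max_gap_frames = 2))
  expect_length(lin$tracks, 1)
  expect_equal(lin$tracks[[1]]$frames, c(1L, 4L))
  # and refuses when the gap exceeds the cap
  lin0 <- close_gaps_and_split(segs, rois, link_params(max_gap_frames = 1))
  expect_length(lin0$tracks, 2)
})

test_that("stage 2 turns an ending mother plus two starters into a division", {
  # both daughters are beyond the stage-1 radius, so the mother segment
  # genuinely ends at frame 2 and stage 2 must adopt both starters
  rois <- list(
    list(roi(1, 1, centroid = c(20, 20))),
    list(roi(1, 2, centroid = c(20, 20))),
    list(roi(1, 3, centroid = c(14, 20)), roi(2, 3, centroid = c(26, 20))),
    list(roi(1, 4, centroid = c(12, 20)), roi(2, 4, centroid = c(28, 20))))
  segs <- link_all_frames(rois, link_params(max_link_dist = 5))
  expect_length(segs, 3)
  lin <- close_gaps_and_split(segs, rois,
                              link_params(max_link_dist = 5,
                                          max_split_dist = 8))
  expect_length(validate_lineage(lin), 0)
  par <- vapply(lin$tracks, function(t)
    if (is.null(t$parent_id)) NA_integer_ else t$parent_id, integer(1))
  mother <- which(vapply(lin$tracks, function(t)
    identical(t$frames, 1:2), logical(1)))
  expect_length(mother, 1)
  expect_equal(sum(par == lin$tracks[[mother]]$track_id, na.rm = TRUE), 2)
})

test_that("stage 2 cuts a through-linked mother at an interior division", {
  # one daughter close enough for stage 1 to chain through the division;
  # stage 2 must cut the chain and re-hang both daughters off the mother
  rois <- list(
    list(roi(1, 1, centroid = c(20, 20))),
    list(roi(1, 2, centroid = c(20, 20))),
    list(roi(1, 3, centroid = c(16, 20)), roi(2, 3, centroid = c(24, 20))),
    list(roi(1, 4, centroid = c(14, 20)), roi(2, 4, centroid = c(26, 20))))
  segs <- link_all_frames(rois, link_params(max_link_dist = 5))
  expect_length(segs, 2)
  lin <- close_gaps_and_split(segs, rois,
                              link_params(max_link_dist = 5,
                                          max_split_dist = 8))
  expect_length(validate_lineage(lin), 0)
  expect_length(lin$tracks, 3)
  mother <- which(vapply(lin$tracks, function(t)
    identical(t$frames, 1:2), logical(1)))
  expect_length(mother, 1)
  par <- vapply(lin$tracks, function(t)
    if (is.null(t$parent_id)) NA_integer_ else t$parent_id, integer(1))
  expect_equal(sum(par == lin$tracks[[mother]]$track_id, na.rm = TRUE), 2)
})

test_that("disabling stage 2 is the identity on segments", {
  rois <- drifting_rois(3, 4, c(10, 10), c(2, 1))
  segs <- link_all_frames(rois)
  lin <- close_gaps_and_split(segs, rois,
                              link_params(allow_splits = FALSE,
                                          max_gap_frames = 0))
  expect_length(lin$tracks, length(segs))
  expect_true(all(vapply(lin$tracks, function(t) is.null(t$parent_id),
                         logical(1))))
})

test_that("every roi ends up in exactly one track of the lineage", {
  mv <- generate_movie(synth_config(n_frames = 10, n_cells = 8,
                                    scheduled_divisions = list(c(2L, 5L)),
                                    rng_seed = 3))
  res <- track_movie(mv$stack)
  want <- sort(unlist(lapply(seq_along(res$rois), function(t)
    vapply(res$rois[[t]], function(r) paste(t, r$roi_id), character(1)))))
  got <- sort(unname(unlist(lapply(res$lineage$tracks, function(tr)
    paste(tr$frames, tr$roi_ids)))))
  expect_identical(got, want)
  expect_length(validate_lineage(res$lineage), 0)
})

test_that("raising the alternative cost never adds birth/death events", {
  set.seed(8)
  a <- lapply(1:6, function(i) roi(i, 1, centroid = runif(2, 10, 90)))
  b <- lapply(1:6, function(i)
    roi(i, 2, centroid = a[[i]]$centroid + rnorm(2, 0, 4)))
  n_events <- vapply(c(1.01, 1.05, 1.2, 1.5, 2), function(f) {
    asg <- solve_lap(frame_cost_matrix(a, b,
                                       link_params(max_link_dist = 30,
                                                   alt_cost_factor = f)))
    length(asg$births) + length(asg$deaths)
  }, numeric(1))
  expect_true(all(diff(n_events) <= 0))
})
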