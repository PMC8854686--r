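ten_node_lineage <- function() {
  lineage(list(track(1, 1:10, rep(1, 10)),
               track(2, 11:13, rep(2, 3), parent_id = 1)))
}

test_that("cutting a track splits its nodes and re-points daughters", {
  lin <- cut_track(ten_node_lineage(), 1, 5)
  expect_length(validate_lineage(lin), 0)
  expect_equal(get_track(lin, 1)$frames, 1:5)
  b <- get_track(lin, 3)
  expect_equal(b$frames, 6:10)
  expect_null(b$parent_id)
  # the daughter must follow the segment holding the old last frame:
  # of the two possible re-pointings only that one keeps parent < child
  expect_equal(get_track(lin, 2)$parent_id, 3L)
  expect_error(cut_track(ten_node_lineage(), 1, 0), "inside")
  expect_error(cut_track(ten_node_lineage(), 1, 10), "inside")
})

test_that("cut then concatenate at the same frame is the identity", {
  lin0 <- ten_node_lineage()
  lin <- cut_track(lin0, 1, 4)
  lin <- link_tracks(lin, 1, 3)
  expect_equal(get_track(lin, 1)$frames, 1:10)
  expect_equal(get_track(lin, 1)$roi_ids, rep(1L, 10))
  expect_equal(get_track(lin, 2)$parent_id, 1L)
  expect_length(validate_lineage(lin), 0)
})

test_that("link_tracks enforces temporal order and the children cap", {
  lin <- lineage(list(track(1, 1:5, rep(1, 5)),
                      track(2, 6:9, rep(2, 4))))
  merged <- link_tracks(lin, 1, 2)
  expect_length(merged$tracks, 1)
  expect_equal(get_track(merged, 1)$frames, 1:9)

  overlap <- lineage(list(track(1, 1:5, rep(1, 5)),
                          track(2, 4:9, rep(2, 6))))
  expect_error(link_tracks(overlap, 1, 2), "overlap")

  full <- lineage(list(
    track(1, 1:2, rep(1, 2)),
    track(2, 3:4, rep(2, 2), parent_id = 1),
    track(3, 3:4, rep(3, 2), parent_id = 1),
    track(4, 5:6, rep(4, 2))))
  expect_error(link_tracks(full, 1, 4, as_division = TRUE), "cap")
})

test_that("deleting rois splits interior holes like a cut would", {
  lin1 <- lineage(list(track(1, 4, 9)))
  expect_length(delete_roi_node(lin1, 4, 9)$tracks, 0)

  lin5 <- lineage(list(track(1, 1:5, rep(1, 5))))
  lin <- delete_roi_node(lin5, 3, 1)
  expect_length(lin$tracks, 2)
  expect_equal(get_track(lin, 1)$frames, 1:2)
  expect_equal(get_track(lin, 2)$frames, 4:5)
  # oracle: cut at the hole, then drop the hole node from segment A
  alt <- cut_track(lin5, 1, 3)
  a <- get_track(alt, 1)
  alt$tracks[["1"]] <- track(1, a$frames[-3], a$roi_ids[-3])
  expect_equal(summary(lin), summary(alt))

  # endpoint deletion shortens without splitting
  lin_end <- delete_roi_node(lin5, 5, 1)
  expect_equal(get_track(lin_end, 1)$frames, 1:4)
})

test_that("deleting a parent orphans its daughters (or cascades)", {
  lin <- ten_node_lineage()
  orphaned <- delete_track(lin, 1)
  expect_length(orphaned$tracks, 1)
  expect_null(get_track(orphaned, 2)$parent_id)
  gone <- delete_track(lin, 1, cascade = TRUE)
  expect_length(gone$tracks, 0)
  expect_error(delete_track(lin, 99), "no track")
})

test_that("edit scripts apply atomically", {
  lin <- ten_node_lineage()
  rois <- lapply(1:13, function(t) {
    rs <- list()
    if (t <= 10) rs <- c(rs, list(roi(1, t, centroid = c(10, 10))))
    if (t >= 11) rs <- c(rs, list(roi(2, t, centroid = c(12, 12))))
    rs
  })
  out <- apply_script(lin, rois, character(0))
  expect_equal(out$lineage, lin)

  # a failure at command 3 leaves everything untouched
  bad <- c("cut 1 5", "add_roi 2 50 50", "delete_track 42")
  err <- tryCatch(apply_script(lin, rois, bad), error = identity)
  expect_match(conditionMessage(err), "command 3")
  expect_length(lin$tracks, 2)  # inputs unchanged by reference semantics

  # the delete-and-redraw division fix: remove an over-segmented roi,
  # draw a replacement, and re-hang both daughters off the mother
  lin2 <- lineage(list(track(1, 1:4, rep(1, 4)),
                       track(2, 5:8, rep(2, 4)),
                       track(3, 5:8, rep(3, 4))))
  rois2 <- lapply(1:8, function(t) {
    rs <- list(roi(9, t, centroid = c(40, 40)))
    if (t <= 4) rs <- c(rs, list(roi(1, t, centroid = c(10, 10))))
    if (t >= 5) rs <- c(rs, list(roi(2, t, centroid = c(8, 8)),
                                 roi(3, t, centroid = c(12, 12))))
    rs
  })
  fix <- apply_script(lin2, rois2, c(
    "delete_roi 5 2",
    "add_roi 5 8 8 2",
    "divide 1 2",
    "divide 1 3"))
  expect_length(validate_lineage(fix$lineage), 0)
  kids <- sort(vapply(fix$lineage$tracks, function(t)
    if (is.null(t$parent_id)) NA_integer_ else t$parent_id, integer(1)))
  expect_equal(unname(kids[!is.na(kids)]), c(1L, 1L))
})

test_that("random edit sequences preserve lineage validity", {
  set.seed(21)
  lin <- lineage(list(
    track(1, 1:12, rep(1, 12)),
    track(2, 1:12, rep(2, 12)),
    track(3, 13:20, rep(3, 8), parent_id = 1),
    track(4, 13:20, rep(4, 8), parent_id = 1),
    track(5, 5:15, rep(5, 11))))
  applied <- 0
  for (k in 1:50) {
    ids <- vapply(lin$tracks, function(t) t$track_id, integer(1))
    op <- sample(c("cut", "link", "divide", "delete_roi",
                   "delete_track", "clear_parent"), 1)
    lin2 <- tryCatch(switch(op,
      cut = {
        id <- sample(ids, 1)
        tr <- get_track(lin, id)
        cut_track(lin, id, sample(tr$frames, 1))
      },
      link = {
        ab <- sample(ids, 2)
        link_tracks(lin, ab[1], ab[2])
      },
      divide = {
        ab <- sample(ids, 2)
        link_tracks(lin, ab[1], ab[2], as_division = TRUE)
      },
      delete_roi = {
        id <- sample(ids, 1)
        tr <- get_track(lin, id)
        k2 <- sample(length(tr$frames), 1)
        delete_roi_node(lin, tr$frames[k2], tr$roi_ids[k2])
      },
      delete_track = delete_track(lin, sample(ids, 1)),
      clear_parent = set_parent(lin, sample(ids, 1), NULL)),
      error = function(e) NULL)
    if (!is.null(lin2)) {
      expect_length(validate_lineage(lin2), 0)
      applied <- applied + 1
      if (length(lin2$tracks) > 1) lin <- lin2
    }
  }
  expect_gt(applied, 10)
})

test_that("relinking consumes edited and detected rois identically", {
  rois <- drifting_rois(2, 5, c(10, 10), c(1, 0))
  base <- relink_movie(rois)
  edited <- add_roi(rois, 3, centroid = c(50, 50))
  again <- relink_movie(edited)
  # the original chains are unchanged; the manual roi is a new singleton
  expect_length(again$lineage$tracks, length(base$lineage$tracks) + 1)
  expect_length(validate_lineage(again$lineage), 0)
})
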