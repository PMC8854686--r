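#' Re-track and separate two cells travelling in close contact
#'
#' The programmatic counterpart of the interactive repair for the
#' "two cells moving in close contact" failure: the detector sees one
#' object, so its track carries both identities. Given one user-supplied
#' seed position per cell (the stand-in for a mouse click), the
#' sequential tracker follows each cell through the movie; in every frame
#' where both estimates land in the same detected roi, that roi's region
#' is split between the two cells by nearest tracked position and
#' replaced by two rois.
#'
#' The roi lists are edited in place; relink the movie afterwards
#' (see [relink_movie()]) to rebuild the lineage over the repaired rois,
#' mirroring the recreate-rois-then-relink-all workflow.
#'
#' @param stack the `frame_stack` the result came from.
#' @param rois_by_frame per-frame roi lists of the tracking result.
#' @param seed_positions 2 x 2 matrix: one `(row, col)` per cell, in
#'   `seed_frame`.
#' @param seed_frame frame of the seed positions (default 1).
#' @param params a [seqtrack_params()] object for the re-tracking.
#' @param channel channel to track on.
#' @return the edited roi lists, with attribute `repaired_frames`.
#' @export
repair_contact_pair <- function(stack, rois_by_frame, seed_positions,
                                seed_frame = 1L,
                                params = seqtrack_params(motion_sigma = 2),
                                channel = 1L) {
  stopifnot(nrow(seed_positions) == 2L)
  runs <- lapply(1:2, function(k) {
    p <- seed_positions[k, ]
    sr <- roi(k, seed_frame, centroid = p,
              bbox = c(p[1] - 5, p[2] - 5, p[1] + 5, p[2] + 5))
    prm <- params
    prm$rng_seed <- params$rng_seed + k
    track_sequential(stack, sr, seed_frame, stack$n_frames, prm, channel)
  })

  # a contact pair travels (nearly) rigidly, so the frame-to-frame offset
  # between the two trackers is regularized to its componentwise median:
  # per-frame jitter of either tracker then moves the split line by only
  # half of the midpoint error
  common <- intersect(runs[[1]]$frames, runs[[2]]$frames)
  e1_all <- runs[[1]]$estimates[match(common, runs[[1]]$frames), ,
                                drop = FALSE]
  e2_all <- runs[[2]]$estimates[match(common, runs[[2]]$frames), ,
                                drop = FALSE]
  off <- apply(e2_all - e1_all, 2, stats::median)

  repaired <- integer(0)
  for (t in common) {
    k <- match(t, common)
    mid <- (e1_all[k, ] + e2_all[k, ]) / 2
    c1 <- mid - off / 2
    c2 <- mid + off / 2
    r1 <- nearest_roi(rois_by_frame[[t]], c1)
    r2 <- nearest_roi(rois_by_frame[[t]], c2)
    if (is.null(r1) || is.null(r2) || r1$roi_id != r2$roi_id) next
    if (is.null(r1$region)) next
    px <- r1$region
    d1 <- (px[, 1] - c1[1])^2 + (px[, 2] - c1[2])^2
    d2 <- (px[, 1] - c2[1])^2 + (px[, 2] - c2[2])^2
    toA <- d1 <= d2
    if (!any(toA) || all(toA)) next
    ids <- vapply(rois_by_frame[[t]], function(r) r$roi_id, integer(1))
    base <- max(ids) + 1L
    rois_by_frame[[t]] <- c(
      Filter(function(r) r$roi_id != r1$roi_id, rois_by_frame[[t]]),
      list(roi(base, t, region = px[toA, , drop = FALSE]),
           roi(base + 1L, t, region = px[!toA, , drop = FALSE])))
    repaired <- c(repaired, t)
  }
  structure(rois_by_frame, repaired_frames = repaired)
}

nearest_roi <- function(rois, pos) {
  if (!length(rois)) return(NULL)
  d <- vapply(rois, function(r)
    sum((r$centroid - pos)^2), numeric(1))
  rois[[which.min(d)]]
}

#' Merge over-segmented rois back into one object
#'
#' The repair for division-time over-segmentation: the late mitotic
#' figure is recognized as several rois, so they are deleted and one roi
#' spanning their union is created in their place (the delete-and-redraw
#' workflow, with the union region standing in for the redrawn shape).
#'
#' @param rois_by_frame per-frame roi lists.
#' @param frame frame to repair.
#' @param center `(row, col)` of the over-segmented object.
#' @param radius rois with centroids within `radius` of `center` are
#'   merged.
#' @return the edited roi lists; unchanged if fewer than two rois fall
#'   within the radius.
#' @export
repair_oversegmentation <- function(rois_by_frame, frame, center,
                                    radius = 10) {
  rs <- rois_by_frame[[frame]]
  d <- vapply(rs, function(r) sqrt(sum((r$centroid - center)^2)),
              numeric(1))
  hit <- which(d <= radius)
  if (length(hit) < 2L) return(rois_by_frame)
  regions <- lapply(rs[hit], function(r) {
    if (is.null(r$region))
      stop("over-segmentation repair needs rois with regions")
    r$region
  })
  px <- unique(do.call(rbind, regions))
  keep_id <- min(vapply(rs[hit], function(r) r$roi_id, integer(1)))
  rois_by_frame[[frame]] <- c(rs[-hit],
                              list(roi(keep_id, frame, region = px)))
  rois_by_frame
}

#' Relink a movie's rois from scratch
#'
#' Reapplies the link-type tracking (stage 1 and 2) to the current roi
#' lists - the relink-all step after roi repairs. Detected, imported and
#' repaired rois are treated identically.
#'
#' @param rois_by_frame per-frame roi lists.
#' @param params a [link_params()] object.
#' @param dim `c(height, width)` for the rebuilt masks (optional).
#' @return a list with `lineage`, `rois` and `masks` (`NULL` when `dim`
#'   is missing).
#' @export
relink_movie <- function(rois_by_frame, params = link_params(),
                         dim = NULL) {
  segments <- link_all_frames(rois_by_frame, params)
  lin <- close_gaps_and_split(segments, rois_by_frame, params)
  masks <- if (!is.null(dim)) masks_from_rois(rois_by_frame, dim)
  list(lineage = lin, rois = rois_by_frame, masks = masks)
}
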