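#' Create a time-lapse frame stack
#'
#' The container for a 2D+time movie. Frames are stored as a list of
#' `H x W x C` arrays (single-channel input is promoted to `C = 1`), all
#' sharing the same dimensions. Intensities must be finite and non-negative:
#' the detection path interprets them as (background-offset) photon counts.
#'
#' @param frames a list of matrices or `H x W x C` arrays, a 3D array
#'   (`H x W x T`), or a 4D array (`H x W x C x T`).
#' @param pixel_size physical length per pixel (optional metadata).
#' @param frame_interval time between frames (optional metadata).
#' @param channel_names optional character vector, one name per channel.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size = NULL, frame_interval = NULL,
                        channel_names = NULL) {
  if (is.array(frames) && !is.list(frames)) {
    d <- dim(frames)
    if (length(d) == 2L) {
      frames <- list(frames)
    } else if (length(d) == 3L) {
      frames <- lapply(seq_len(d[3]), function(t) frames[, , t, drop = FALSE])
    } else if (length(d) == 4L) {
      frames <- lapply(seq_len(d[4]), function(t) {
        array(frames[, , , t], dim = d[1:3])
      })
    } else stop("frames array must be 2D, 3D or 4D")
  }
  if (!is.list(frames) || length(frames) < 1L)
    stop("need at least one frame")
  frames <- lapply(frames, function(f) {
    if (is.matrix(f)) f <- array(f, dim = c(dim(f), 1L))
    if (length(dim(f)) != 3L) stop("each frame must be H x W or H x W x C")
    f
  })
  d0 <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d0), logical(1))
  if (!all(ok)) stop("all frames must share height, width and channel count")
  for (f in frames) {
    if (!all(is.finite(f))) stop("frame intensities must be finite")
    if (any(f < 0)) stop("frame intensities must be non-negative")
  }
  structure(list(frames = frames, n_frames = length(frames),
                 height = d0[1], width = d0[2], n_channels = d0[3],
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 channel_names = channel_names),
            class = "frame_stack")
}

#' Extract one channel of one frame as a matrix
#' @param stack a `frame_stack`.
#' @param t frame index (1-based).
#' @param channel channel index (1-based).
#' @export
get_frame <- function(stack, t, channel = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (t < 1L || t > stack$n_frames) stop("frame index out of range")
  if (channel < 1L || channel > stack$n_channels) stop("channel out of range")
  stack$frames[[t]][, , channel]
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %d channel(s)\n",
              x$n_frames, x$height, x$width, x$n_channels))
  invisible(x)
}

#' Create a region of interest (one object in one frame)
#'
#' A `roi` records one detected or user-supplied object: a sub-pixel
#' centroid, an inclusive bounding box `(rmin, cmin, rmax, cmax)`, an
#' optional pixel region (an `n x 2` matrix of `(row, col)` coordinates,
#' required to be one 8-connected component), and a named feature list.
#' When a region is supplied, the centroid and bounding box are derived
#' from it so the stored geometry is always self-consistent. `roi_id` is
#' unique within a frame; the `(frame, roi_id)` pair is the global key.
#'
#' @param roi_id integer id, unique within `frame`.
#' @param frame 1-based frame index.
#' @param centroid numeric `(row, col)`; ignored when `region` is given.
#' @param bbox integer `(rmin, cmin, rmax, cmax)`, inclusive; ignored when
#'   `region` is given.
#' @param region optional `n x 2` integer matrix of pixel coordinates.
#' @param features named list of feature values.
#' @return an object of class `roi`.
#' @export
roi <- function(roi_id, frame, centroid = NULL, bbox = NULL, region = NULL,
                features = list()) {
  if (!is.null(region)) {
    region <- matrix(as.integer(region), ncol = 2L)
    if (nrow(region) == 0L) stop("region must contain at least one pixel")
    centroid <- c(mean(region[, 1]), mean(region[, 2]))
    bbox <- c(min(region[, 1]), min(region[, 2]),
              max(region[, 1]), max(region[, 2]))
  }
  if (is.null(centroid)) stop("need a centroid or a region")
  if (is.null(bbox))
    bbox <- c(floor(centroid[1]), floor(centroid[2]),
              ceiling(centroid[1]), ceiling(centroid[2]))
  structure(list(roi_id = as.integer(roi_id), frame = as.integer(frame),
                 centroid = as.numeric(centroid), bbox = as.numeric(bbox),
                 region = region, features = features),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %d @ frame %d> centroid (%.2f, %.2f)%s\n",
              x$roi_id, x$frame, x$centroid[1], x$centroid[2],
              if (is.null(x$region)) "" else
                sprintf(", region %d px", nrow(x$region))))
  invisible(x)
}

# Structural checks used by the plugin contract: centroid inside bbox,
# region consistent with centroid/bbox and a single 8-connected component.
validate_roi <- function(x) {
  msgs <- character(0)
  if (!inherits(x, "roi")) return("not a roi object")
  if (x$centroid[1] < x$bbox[1] - 1e-9 || x$centroid[1] > x$bbox[3] + 1e-9 ||
      x$centroid[2] < x$bbox[2] - 1e-9 || x$centroid[2] > x$bbox[4] + 1e-9)
    msgs <- c(msgs, "centroid outside bounding box")
  if (!is.null(x$region)) {
    ctr <- c(mean(x$region[, 1]), mean(x$region[, 2]))
    if (max(abs(ctr - x$centroid)) > 1e-6)
      msgs <- c(msgs, "centroid does not match region centroid")
    bb <- c(min(x$region[, 1]), min(x$region[, 2]),
            max(x$region[, 1]), max(x$region[, 2]))
    if (max(abs(bb - x$bbox)) > 1e-9)
      msgs <- c(msgs, "bbox is not the tight region bounding box")
    if (!region_connected(x$region))
      msgs <- c(msgs, "region is not a single 8-connected component")
  }
  msgs
}

region_connected <- function(px) {
  n <- nrow(px)
  if (n <= 1L) return(TRUE)
  key <- function(r, c) paste(r, c, sep = ",")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) assign(key(px[i, 1], px[i, 2]), i, envir = idx)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      k <- key(px[i, 1] + dr, px[i, 2] + dc)
      j <- idx[[k]]
      if (!is.null(j) && !seen[j]) {
        seen[j] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  all(seen)
}

#' Create a track (one identity followed through time)
#'
#' @param track_id positive integer.
#' @param frames strictly increasing integer vector of frame indices.
#' @param roi_ids integer vector, parallel to `frames`.
#' @param parent_id id of the mother track, or `NULL`.
#' @export
track <- function(track_id, frames, roi_ids, parent_id = NULL) {
  if (length(frames) != length(roi_ids))
    stop("frames and roi_ids must have equal length")
  structure(list(track_id = as.integer(track_id),
                 frames = as.integer(frames),
                 roi_ids = as.integer(roi_ids),
                 parent_id = if (is.null(parent_id)) NULL
                             else as.integer(parent_id)),
            class = "track")
}

#' Create a lineage (a set of tracks plus mother-daughter relations)
#'
#' @param tracks a list of `track` objects.
#' @return an object of class `lineage`; tracks are indexed by id.
#' @export
lineage <- function(tracks = list()) {
  ids <- vapply(tracks, function(t) t$track_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate track ids")
  names(tracks) <- as.character(ids)
  structure(list(tracks = tracks), class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  nt <- length(x$tracks)
  nd <- sum(vapply(x$tracks, function(t) !is.null(t$parent_id), logical(1)))
  nn <- sum(vapply(x$tracks, function(t) length(t$frames), integer(1)))
  cat(sprintf("<lineage> %d tracks, %d nodes, %d parent links\n", nt, nn, nd))
  invisible(x)
}

#' @export
summary.lineage <- function(object, ...) {
  tr <- object$tracks
  df <- data.frame(
    track_id = vapply(tr, function(t) t$track_id, integer(1)),
    parent_id = vapply(tr, function(t)
      if (is.null(t$parent_id)) NA_integer_ else t$parent_id, integer(1)),
    begin = vapply(tr, function(t) min(t$frames), integer(1)),
    end = vapply(tr, function(t) max(t$frames), integer(1)),
    n_nodes = vapply(tr, function(t) length(t$frames), integer(1)),
    row.names = NULL)
  df[order(df$track_id), , drop = FALSE]
}

next_track_id <- function(lin) {
  if (!length(lin$tracks)) return(1L)
  max(vapply(lin$tracks, function(t) t$track_id, integer(1))) + 1L
}

get_track <- function(lin, id) {
  t <- lin$tracks[[as.character(id)]]
  if (is.null(t)) stop(sprintf("no track with id %d", id))
  t
}

children_of <- function(lin, id) {
  kid <- vapply(lin$tracks, function(t)
    !is.null(t$parent_id) && t$parent_id == id, logical(1))
  unname(vapply(lin$tracks[kid], function(t) t$track_id, integer(1)))
}

#' Validate a lineage
#'
#' Diagnostic check of the lineage invariants: strictly increasing frames
#' within each track, existing parents, parent ending strictly before the
#' child begins, no cycles in the parent relation, no `(frame, roi_id)`
#' claimed by two tracks, and at most `max_children` daughters per track.
#' Broken trajectories surface in a lineage display as exactly these
#' defects, so the same checks guard every operation that rewrites tracks.
#'
#' @param lin a `lineage`.
#' @param max_children division cap (default 2: mother into two daughters).
#' @return a list of violations, empty when the lineage is valid. Each
#'   violation is a list with elements `type`, `track_id` and `detail`.
#' @export
validate_lineage <- function(lin, max_children = 2L) {
  stopifnot(inherits(lin, "lineage"))
  v <- list()
  add <- function(type, id, detail)
    v[[length(v) + 1L]] <<- list(type = type, track_id = id, detail = detail)
  ids <- vapply(lin$tracks, function(t) t$track_id, integer(1))

  for (t in lin$tracks) {
    if (length(t$frames) == 0L) {
      add("empty-track", t$track_id, "track has no nodes")
      next
    }
    if (any(diff(t$frames) <= 0L))
      add("frame-order", t$track_id, "frames are not strictly increasing")
    if (!is.null(t$parent_id)) {
      if (t$parent_id == t$track_id) {
        add("cycle", t$track_id, "track is its own parent")
      } else if (!t$parent_id %in% ids) {
        add("parent-missing", t$track_id,
            sprintf("parent %d does not exist", t$parent_id))
      } else {
        p <- get_track(lin, t$parent_id)
        if (length(p$frames) && max(p$frames) >= min(t$frames))
          add("frame-order", t$track_id,
              sprintf("parent %d ends at frame %d, child starts at frame %d",
                      p$track_id, max(p$frames), min(t$frames)))
      }
    }
  }

  # cycles longer than a self-loop
  for (t in lin$tracks) {
    seen <- integer(0)
    cur <- t$track_id
    repeat {
      tr <- lin$tracks[[as.character(cur)]]
      if (is.null(tr) || is.null(tr$parent_id)) break
      if (tr$parent_id %in% c(seen, t$track_id)) {
        if (tr$parent_id == t$track_id && cur != t$track_id)
          add("cycle", t$track_id, "parent relation contains a cycle")
        break
      }
      seen <- c(seen, cur)
      cur <- tr$parent_id
      if (!cur %in% ids) break
    }
  }

  keys <- unlist(lapply(lin$tracks, function(t)
    paste(t$frames, t$roi_ids, sep = ":")))
  dup <- unique(keys[duplicated(keys)])
  for (k in dup)
    add("duplicate-roi", NA_integer_,
        sprintf("(frame, roi_id) = (%s) used by more than one track",
                sub(":", ", ", k)))

  for (t in lin$tracks) {
    kids <- children_of(lin, t$track_id)
    if (length(kids) > max_children)
      add("children-cap", t$track_id,
          sprintf("%d children exceed the cap of %d",
                  length(kids), max_children))
  }
  v
}

#' Convert labeled masks into per-frame ROI lists
#'
#' Bridges externally produced label images (e.g. a deep-learning detector's
#' output, or Cell Tracking Challenge ground truth) into the `roi` model.
#' One `roi` is made per nonzero label per frame, in ascending label order,
#' with `roi_id` equal to the label. When the image stack is supplied,
#' intensity features are computed over each region.
#'
#' @param masks a list of integer label matrices, one per frame
#'   (0 = background).
#' @param stack optional `frame_stack` matching the masks.
#' @return a list (one element per frame) of lists of `roi` objects.
#' @export
rois_from_masks <- function(masks, stack = NULL) {
  if (is.matrix(masks)) masks <- list(masks)
  if (!is.null(stack)) {
    stopifnot(inherits(stack, "frame_stack"))
    if (length(masks) != stack$n_frames ||
        any(vapply(masks, nrow, integer(1)) != stack$height) ||
        any(vapply(masks, ncol, integer(1)) != stack$width))
      stop("mask dimensions do not match the stack")
  }
  lapply(seq_along(masks), function(t) {
    m <- masks[[t]]
    labs <- sort(unique(m[m > 0]))
    out <- vector("list", length(labs))
    for (i in seq_along(labs)) {
      px <- which(m == labs[i], arr.ind = TRUE)
      r <- roi(roi_id = labs[i], frame = t, region = px)
      if (!is.null(stack))
        r$features <- compute_features(r, stack$frames[[t]])
      else
        r$features <- list(area = nrow(px))
      out[[i]] <- r
    }
    out
  })
}

#' Rasterize per-frame ROI lists back into labeled masks
#'
#' The inverse of [rois_from_masks()] on label geometry: each roi with a
#' region paints its pixels with its `roi_id`. ROIs without regions are
#' skipped.
#'
#' @param rois_by_frame list of per-frame roi lists.
#' @param dim `c(height, width)` of the output masks.
#' @export
masks_from_rois <- function(rois_by_frame, dim) {
  lapply(rois_by_frame, function(rs) {
    m <- matrix(0L, dim[1], dim[2])
    for (r in rs) {
      if (is.null(r$region)) next
      m[r$region] <- r$roi_id
    }
    m
  })
}

# Fast lookup table (frame:roi_id -> roi) over per-frame roi lists.
roi_index <- function(rois_by_frame) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_along(rois_by_frame))
    for (r in rois_by_frame[[t]])
      assign(paste(t, r$roi_id, sep = ":"), r, envir = env)
  env
}

lookup_roi <- function(index, frame, roi_id) {
  r <- index[[paste(frame, roi_id, sep = ":")]]
  if (is.null(r)) stop(sprintf("no roi %d in frame %d", roi_id, frame))
  r
}
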