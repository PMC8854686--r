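#' Cut a track after a frame
#'
#' Splits a track into segment A (nodes at frames `<= frame`, keeping the
#' original id and parent) and segment B (the remaining nodes, a fresh id,
#' no parent). Daughters of the original track re-point to B, the segment
#' that contains the old last frame, so parent-before-child ordering is
#' preserved.
#'
#' @param lin a `lineage`.
#' @param track_id id of the track to cut.
#' @param frame cut position: the last frame kept in segment A.
#' @return the edited lineage.
#' @export
cut_track <- function(lin, track_id, frame) {
  tr <- get_track(lin, track_id)
  before <- tr$frames <= frame
  if (!any(before) || all(before))
    stop("cut position must fall strictly inside the track's span")
  new_id <- next_track_id(lin)
  a <- track(tr$track_id, tr$frames[before], tr$roi_ids[before],
             parent_id = tr$parent_id)
  b <- track(new_id, tr$frames[!before], tr$roi_ids[!before])
  for (k in children_of(lin, track_id))
    lin$tracks[[as.character(k)]]$parent_id <- new_id
  lin$tracks[[as.character(track_id)]] <- a
  lin$tracks[[as.character(new_id)]] <- b
  lin
}

#' Join two tracks
#'
#' With `as_division = FALSE` the tracks are concatenated: `b`'s nodes are
#' absorbed into `a`, `b` disappears and `b`'s daughters re-point to `a`.
#' With `as_division = TRUE`, `b` becomes a daughter of `a` (the
#' mother-daughter link reconfiguration). Both forms refuse edits that
#' would leave the lineage invalid (temporal overlap, a second parent,
#' more daughters than the cap).
#'
#' @param lin a `lineage`.
#' @param a_id,b_id track ids; `a` must end before `b` begins.
#' @param as_division link as mother-daughter instead of concatenating.
#' @param max_children division cap.
#' @return the edited lineage.
#' @export
link_tracks <- function(lin, a_id, b_id, as_division = FALSE,
                        max_children = 2L) {
  a <- get_track(lin, a_id)
  b <- get_track(lin, b_id)
  if (a_id == b_id) stop("cannot link a track to itself")
  if (max(a$frames) >= min(b$frames))
    stop(sprintf(
      "temporal overlap: track %d ends at frame %d, track %d starts at %d",
      a_id, max(a$frames), b_id, min(b$frames)))
  if (as_division) {
    if (!is.null(b$parent_id))
      stop(sprintf("track %d already has a parent", b_id))
    kids <- children_of(lin, a_id)
    if (length(kids) + 1L > max_children)
      stop(sprintf("track %d already has %d children (cap %d)",
                   a_id, length(kids), max_children))
    lin$tracks[[as.character(b_id)]]$parent_id <- as.integer(a_id)
    return(lin)
  }
  if (!is.null(b$parent_id))
    stop(sprintf("track %d has a parent; cut that link first", b_id))
  if (length(children_of(lin, a_id)))
    stop(sprintf("track %d has children after its end; cannot extend", a_id))
  merged <- track(a$track_id, c(a$frames, b$frames),
                  c(a$roi_ids, b$roi_ids), parent_id = a$parent_id)
  for (k in children_of(lin, b_id))
    lin$tracks[[as.character(k)]]$parent_id <- a$track_id
  lin$tracks[[as.character(a_id)]] <- merged
  lin$tracks[[as.character(b_id)]] <- NULL
  lin
}

#' Set or clear a track's parent
#'
#' @param lin a `lineage`.
#' @param child_id track to re-parent.
#' @param parent_id new parent id, or 0/`NULL` to clear.
#' @param max_children division cap.
#' @export
set_parent <- function(lin, child_id, parent_id, max_children = 2L) {
  child <- get_track(lin, child_id)
  if (is.null(parent_id) || (length(parent_id) == 1L && parent_id == 0)) {
    lin$tracks[[as.character(child_id)]]$parent_id <- NULL
    return(lin)
  }
  lin$tracks[[as.character(child_id)]]$parent_id <- NULL
  link_tracks(lin, parent_id, child_id, as_division = TRUE,
              max_children = max_children)
}

#' Delete one roi node from a lineage
#'
#' Removes the `(frame, roi_id)` node from the track that owns it. An
#' interior deletion splits the track at the hole (cut semantics, never a
#' silently bridged identity); deleting a track's only node removes the
#' track and orphans its daughters.
#'
#' @param lin a `lineage`.
#' @param frame,roi_id the node to delete.
#' @return the edited lineage.
#' @export
delete_roi_node <- function(lin, frame, roi_id) {
  owner <- NULL
  for (t in lin$tracks)
    if (any(t$frames == frame & t$roi_ids == roi_id)) { owner <- t; break }
  if (is.null(owner))
    stop(sprintf("no track contains roi %d in frame %d", roi_id, frame))
  pos <- which(owner$frames == frame & owner$roi_ids == roi_id)
  n <- length(owner$frames)
  if (n == 1L) return(delete_track(lin, owner$track_id))
  if (pos == 1L || pos == n) {
    keep <- setdiff(seq_len(n), pos)
    lin$tracks[[as.character(owner$track_id)]] <-
      track(owner$track_id, owner$frames[keep], owner$roi_ids[keep],
            parent_id = owner$parent_id)
    return(lin)
  }
  lin <- cut_track(lin, owner$track_id, owner$frames[pos])
  # the cut kept the deleted node as the tail of segment A; drop it
  a <- get_track(lin, owner$track_id)
  keep <- seq_len(length(a$frames) - 1L)
  lin$tracks[[as.character(a$track_id)]] <-
    track(a$track_id, a$frames[keep], a$roi_ids[keep],
          parent_id = a$parent_id)
  lin
}

#' Delete a whole track
#'
#' Daughters are orphaned (their parent link is cleared) rather than
#' deleted; pass `cascade = TRUE` to remove the whole subtree.
#'
#' @param lin a `lineage`.
#' @param track_id track to remove.
#' @param cascade also remove all descendants.
#' @export
delete_track <- function(lin, track_id, cascade = FALSE) {
  get_track(lin, track_id)  # existence check
  kids <- children_of(lin, track_id)
  if (cascade) {
    for (k in kids) lin <- delete_track(lin, k, cascade = TRUE)
  } else {
    for (k in kids) lin$tracks[[as.character(k)]]$parent_id <- NULL
  }
  lin$tracks[[as.character(track_id)]] <- NULL
  lin
}

#' Add a roi to the per-frame roi lists
#'
#' The programmatic stand-in for drawing a new roi: accepts a bare
#' centroid, or imported geometry (a polygon-free pixel region, e.g. from
#' a freehand/pen annotation tool).
#'
#' @param rois_by_frame per-frame roi lists.
#' @param frame frame index.
#' @param centroid numeric `(row, col)` (ignored when `region` given).
#' @param region optional `n x 2` pixel coordinate matrix.
#' @param roi_id id for the new roi; default one above the frame's maximum.
#' @return the updated roi lists, with the new id in attribute
#'   `"new_roi_id"`.
#' @export
add_roi <- function(rois_by_frame, frame, centroid = NULL, region = NULL,
                    roi_id = NULL) {
  if (frame < 1L || frame > length(rois_by_frame))
    stop("frame outside the movie")
  ids <- vapply(rois_by_frame[[frame]], function(r) r$roi_id, integer(1))
  if (is.null(roi_id))
    roi_id <- if (length(ids)) max(ids) + 1L else 1L
  if (roi_id %in% ids)
    stop(sprintf("roi id %d already exists in frame %d", roi_id, frame))
  r <- roi(roi_id = roi_id, frame = frame, centroid = centroid,
           region = region)
  rois_by_frame[[frame]] <- c(rois_by_frame[[frame]], list(r))
  structure(rois_by_frame, new_roi_id = roi_id)
}

#' Move a roi to a new centroid
#'
#' @param rois_by_frame per-frame roi lists.
#' @param frame,roi_id the roi to move.
#' @param centroid new `(row, col)` position.
#' @export
move_roi <- function(rois_by_frame, frame, roi_id, centroid) {
  for (i in seq_along(rois_by_frame[[frame]])) {
    r <- rois_by_frame[[frame]][[i]]
    if (r$roi_id == roi_id) {
      shift <- centroid - r$centroid
      r$centroid <- as.numeric(centroid)
      r$bbox <- r$bbox + rep(shift, 2)
      if (!is.null(r$region)) {
        r$region <- cbind(r$region[, 1] + round(shift[1]),
                          r$region[, 2] + round(shift[2]))
        r$centroid <- c(mean(r$region[, 1]), mean(r$region[, 2]))
        r$bbox <- c(min(r$region[, 1]), min(r$region[, 2]),
                    max(r$region[, 1]), max(r$region[, 2]))
      }
      rois_by_frame[[frame]][[i]] <- r
      return(rois_by_frame)
    }
  }
  stop(sprintf("no roi %d in frame %d", roi_id, frame))
}

#' Remove a roi from the per-frame lists
#' @param rois_by_frame per-frame roi lists.
#' @param frame,roi_id the roi to remove.
#' @export
remove_roi <- function(rois_by_frame, frame, roi_id) {
  ids <- vapply(rois_by_frame[[frame]], function(r) r$roi_id, integer(1))
  hit <- which(ids == roi_id)
  if (!length(hit)) stop(sprintf("no roi %d in frame %d", roi_id, frame))
  rois_by_frame[[frame]] <- rois_by_frame[[frame]][-hit]
  rois_by_frame
}

#' Parse an edit script
#'
#' Line-oriented plain-text commands, one per line (`#` starts a comment):
#' \preformatted{
#' add_roi <frame> <row> <col> [roi_id]
#' move_roi <frame> <roi_id> <row> <col>
#' delete_roi <frame> <roi_id>
#' delete_track <track_id>
#' cut <track_id> <frame>
#' link <a_id> <b_id>
#' divide <parent_id> <child_id>
#' set_parent <child_id> <parent_id|0>
#' }
#'
#' @param text a character vector of lines, or a file path.
#' @return a list of parsed commands.
#' @export
parse_edit_script <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]
  lapply(text, function(line) {
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    list(cmd = parts[1], args = as.numeric(parts[-1]))
  })
}

#' Apply an edit script atomically
#'
#' Commands are applied in order to working copies of the lineage and roi
#' lists; the first failing command aborts the whole script (reporting its
#' index and reason) and leaves the inputs untouched.
#'
#' @param lin a `lineage`.
#' @param rois_by_frame per-frame roi lists.
#' @param script output of [parse_edit_script()], or raw script text.
#' @param max_children division cap.
#' @return a list with the edited `lineage` and `rois`.
#' @export
apply_script <- function(lin, rois_by_frame, script, max_children = 2L) {
  if (is.character(script)) script <- parse_edit_script(script)
  lin2 <- lin
  rois2 <- rois_by_frame
  for (i in seq_along(script)) {
    cmd <- script[[i]]$cmd
    a <- script[[i]]$args
    res <- tryCatch({
      switch(cmd,
        add_roi = {
          rois2 <- add_roi(rois2, frame = a[1], centroid = a[2:3],
                            roi_id = if (length(a) >= 4) a[4] else NULL)
        },
        move_roi = {
          rois2 <- move_roi(rois2, frame = a[1], roi_id = a[2],
                             centroid = a[3:4])
        },
        delete_roi = {
          # drop from the lineage if tracked, then from the roi lists
          tracked <- any(vapply(lin2$tracks, function(t)
            any(t$frames == a[1] & t$roi_ids == a[2]), logical(1)))
          if (tracked) lin2 <- delete_roi_node(lin2, a[1], a[2])
          rois2 <- remove_roi(rois2, frame = a[1], roi_id = a[2])
        },
        delete_track = lin2 <- delete_track(lin2, a[1]),
        cut = lin2 <- cut_track(lin2, a[1], a[2]),
        link = lin2 <- link_tracks(lin2, a[1], a[2], as_division = FALSE,
                                    max_children = max_children),
        divide = lin2 <- link_tracks(lin2, a[1], a[2], as_division = TRUE,
                                      max_children = max_children),
        set_parent = lin2 <- set_parent(lin2, a[1],
                                         if (a[2] == 0) NULL else a[2],
                                         max_children = max_children),
        stop(sprintf("unknown command \"%s\"", cmd))
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res))
      stop(sprintf("edit script failed at command %d (%s): %s",
                   i, cmd, res))
  }
  list(lineage = lin2, rois = rois2)
}
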