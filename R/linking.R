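#' Linking parameters
#'
#' Parameters of the two-stage assignment linker. Stage 1 links detections
#' between adjacent frames; stage 2 closes gaps left by missed detections
#' and resolves divisions into mother-daughter edges.
#'
#' @param max_link_dist maximum centroid displacement per frame (pixels).
#' @param alt_cost_factor multiplier for the birth/death alternative cost;
#'   the alternative is priced at `alt_cost_factor` times the largest
#'   finite candidate cost, so values just above 1 accept almost every
#'   plausible link while still allowing appearances/disappearances.
#' @param cost_area_weight,cost_intensity_weight optional weights for
#'   relative area / mean-intensity change penalties added to the squared
#'   distance cost; useful when two cells travel in close contact and
#'   geometry alone cannot keep their identities apart.
#' @param max_gap_frames how many missed frames stage 2 may bridge.
#' @param max_split_dist search radius for division candidates (pixels).
#' @param allow_splits resolve divisions in stage 2?
#' @export
link_params <- function(max_link_dist = 15, alt_cost_factor = 1.05,
                        cost_area_weight = 0, cost_intensity_weight = 0,
                        max_gap_frames = 2L, max_split_dist = 15,
                        allow_splits = TRUE) {
  if (max_link_dist <= 0) stop("max_link_dist must be positive")
  if (alt_cost_factor <= 1) stop("alt_cost_factor must exceed 1")
  if (max_gap_frames < 0) stop("max_gap_frames must be non-negative")
  structure(list(max_link_dist = max_link_dist,
                 alt_cost_factor = alt_cost_factor,
                 cost_area_weight = cost_area_weight,
                 cost_intensity_weight = cost_intensity_weight,
                 max_gap_frames = as.integer(max_gap_frames),
                 max_split_dist = max_split_dist,
                 allow_splits = isTRUE(allow_splits)),
            class = "link_params")
}

roi_centroids <- function(rois) {
  if (!length(rois)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, lapply(rois, function(r) r$centroid))
}

roi_feature <- function(rois, name) {
  vapply(rois, function(r) {
    v <- r$features[[name]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Build the augmented cost matrix for one frame pair
#'
#' Standard assignment-with-alternatives construction: an
#' `(n+m) x (n+m)` block matrix whose upper-left block holds the link
#' costs (squared centroid distance, optionally inflated by relative area
#' and intensity change), whose diagonal death/birth blocks hold the
#' alternative cost `b = alt_cost_factor * max(finite link cost)` (or
#' `max_link_dist^2` when no link is feasible), and whose lower-right
#' block mirrors the feasibility of the link block at zero cost.
#' Forbidden entries are `Inf`.
#'
#' @param rois_t,rois_t1 roi lists of the two frames (either may be empty).
#' @param params a [link_params()] object.
#' @return the augmented cost matrix with attributes `n` and `m`.
#' @export
frame_cost_matrix <- function(rois_t, rois_t1, params = link_params()) {
  n <- length(rois_t); m <- length(rois_t1)
  link <- matrix(Inf, n, m)
  if (n && m) {
    a <- roi_centroids(rois_t); b <- roi_centroids(rois_t1)
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    pen <- matrix(0, n, m)
    if (params$cost_area_weight > 0) {
      fa <- roi_feature(rois_t, "area"); fb <- roi_feature(rois_t1, "area")
      if (!anyNA(fa) && !anyNA(fb))
        pen <- pen + params$cost_area_weight *
          abs(outer(fa, fb, "-")) / outer(fa, fb, pmax)
    }
    if (params$cost_intensity_weight > 0) {
      fa <- roi_feature(rois_t, "mean_c1")
      fb <- roi_feature(rois_t1, "mean_c1")
      if (!anyNA(fa) && !anyNA(fb))
        pen <- pen + params$cost_intensity_weight *
          abs(outer(fa, fb, "-")) / outer(fa, fb, pmax)
    }
    link <- d2 * (1 + pen)
    link[sqrt(d2) > params$max_link_dist] <- Inf
  }
  finite <- link[is.finite(link)]
  alt <- params$alt_cost_factor *
    if (length(finite)) max(finite) else params$max_link_dist^2

  cm <- matrix(Inf, n + m, n + m)
  if (n && m) cm[1:n, 1:m] <- link
  if (n) cm[cbind(1:n, m + 1:n)] <- alt       # deaths
  if (m) cm[cbind(n + 1:m, 1:m)] <- alt       # births
  if (n && m) {
    lr <- matrix(Inf, m, n)
    lr[t(is.finite(link))] <- 0
    cm[n + 1:m, m + 1:n] <- lr
  } else if (n || m) {
    cm[n + seq_len(m), m + seq_len(n)] <- 0
  }
  attr(cm, "n") <- n
  attr(cm, "m") <- m
  cm
}

#' Solve a linear assignment problem
#'
#' Minimum-total-cost complete assignment of a square cost matrix with
#' `Inf` marking forbidden pairings (Jonker-Volgenant shortest augmenting
#' paths). When the matrix was built by [frame_cost_matrix()] (or `dims`
#' is supplied), the solution is decomposed into links, births and deaths.
#'
#' @param cost square numeric matrix; `Inf` = forbidden.
#' @param dims optional `c(n, m)` giving the source/target block sizes.
#' @return an object of class `lap_assignment`: `pairs` (two-column matrix
#'   of source/target indices), `births`, `deaths`, `total_cost` and the
#'   raw `col4row` permutation.
#' @export
solve_lap <- function(cost, dims = NULL) {
  if (is.null(dims)) {
    n <- attr(cost, "n"); m <- attr(cost, "m")
    if (!is.null(n) && !is.null(m)) dims <- c(n, m)
  }
  sol <- lap_solve_cpp(unclass(cost))
  if (!isTRUE(sol$feasible)) stop("assignment problem is infeasible")
  col4row <- sol$col4row
  total <- if (length(col4row))
    sum(cost[cbind(seq_along(col4row), col4row)]) else 0

  if (is.null(dims)) {
    pairs <- cbind(source = seq_along(col4row), target = col4row)
    out <- list(pairs = pairs, births = integer(0), deaths = integer(0),
                total_cost = total, col4row = col4row)
  } else {
    n <- dims[1]; m <- dims[2]
    src <- seq_len(n)
    linked <- src[col4row[src] <= m]
    pairs <- cbind(source = linked, target = col4row[linked])
    deaths <- src[col4row[src] > m]
    births <- setdiff(seq_len(m), pairs[, 2])
    out <- list(pairs = pairs, births = births, deaths = deaths,
                total_cost = total, col4row = col4row)
  }
  class(out) <- "lap_assignment"
  out
}

#' @export
print.lap_assignment <- function(x, ...) {
  cat(sprintf("<lap_assignment> %d links, %d births, %d deaths, cost %.4g\n",
              nrow(x$pairs), length(x$births), length(x$deaths),
              x$total_cost))
  invisible(x)
}

#' Stage 1: link detections between adjacent frames
#'
#' Solves one assignment problem per adjacent frame pair and chains the
#' accepted links into maximal track segments. Every roi - detected,
#' imported or user-created alike - ends up in exactly one segment
#' (singletons allowed).
#'
#' @param rois_by_frame list of per-frame roi lists.
#' @param params a [link_params()] object.
#' @return a list of `track` objects (segments, no parents), ids 1..k in
#'   order of first frame then first roi id.
#' @export
link_all_frames <- function(rois_by_frame, params = link_params()) {
  T <- length(rois_by_frame)
  if (T < 1L) stop("need at least one frame of rois")
  succ <- new.env(hash = TRUE, parent = emptyenv())
  has_pred <- new.env(hash = TRUE, parent = emptyenv())

  for (t in seq_len(max(T - 1L, 0L))) {
    a <- rois_by_frame[[t]]; b <- rois_by_frame[[t + 1L]]
    if (!length(a) && !length(b)) next
    cm <- frame_cost_matrix(a, b, params)
    asg <- solve_lap(cm)
    if (nrow(asg$pairs)) for (k in seq_len(nrow(asg$pairs))) {
      i <- asg$pairs[k, 1]; j <- asg$pairs[k, 2]
      assign(paste(t, a[[i]]$roi_id, sep = ":"),
             c(t + 1L, b[[j]]$roi_id), envir = succ)
      assign(paste(t + 1L, b[[j]]$roi_id, sep = ":"), TRUE, envir = has_pred)
    }
  }

  segments <- list()
  for (t in seq_len(T)) for (r in rois_by_frame[[t]]) {
    if (!is.null(has_pred[[paste(t, r$roi_id, sep = ":")]])) next
    frames <- t; ids <- r$roi_id
    cur <- c(t, r$roi_id)
    repeat {
      nxt <- succ[[paste(cur[1], cur[2], sep = ":")]]
      if (is.null(nxt)) break
      frames <- c(frames, nxt[1]); ids <- c(ids, nxt[2])
      cur <- nxt
    }
    segments[[length(segments) + 1L]] <-
      track(length(segments) + 1L, frames, ids)
  }
  segments
}

#' Stage 2: close gaps and resolve divisions
#'
#' A second assignment over segment endpoints. Candidate events are
#' gap closings (segment end to a segment start `g` frames later,
#' `1 <= g - 1 <= max_gap_frames`, within `max_link_dist`; cost = squared
#' distance times the number of skipped frames) and divisions (a segment
#' start one frame after another segment's node within `max_split_dist`;
#' cost = squared distance). Each anchor node may adopt at most two
#' daughters in total, so an anchor in the middle of a segment - whose
#' own continuation is the first daughter - enters the problem once,
#' while a segment end enters twice. The no-event alternative costs
#' `alt_cost_factor` times the largest finite candidate. Gap-closed
#' tracks keep no interpolated nodes for skipped frames.
#'
#' With `allow_splits = FALSE` and `max_gap_frames = 0` the stage is the
#' identity: one track per input segment, no parents.
#'
#' @param segments track segments from [link_all_frames()].
#' @param rois_by_frame the roi lists the segments refer to.
#' @param params a [link_params()] object.
#' @return a valid `lineage`.
#' @export
close_gaps_and_split <- function(segments, rois_by_frame,
                                 params = link_params()) {
  idx <- roi_index(rois_by_frame)
  nseg <- length(segments)
  if (!nseg) return(lineage())

  seg_first <- vapply(segments, function(s) s$frames[1], integer(1))
  seg_last <- vapply(segments, function(s)
    s$frames[length(s$frames)], integer(1))
  start_pos <- t(vapply(segments, function(s)
    lookup_roi(idx, s$frames[1], s$roi_ids[1])$centroid, numeric(2)))
  end_pos <- t(vapply(segments, function(s)
    lookup_roi(idx, s$frames[length(s$frames)],
               s$roi_ids[length(s$roi_ids)])$centroid, numeric(2)))

  # candidate rows: (kind, segment, node position-in-segment)
  rows <- list()
  costs <- list()  # per row: named numeric vector over start indices
  add_row <- function(kind, seg, node, cost_vec) {
    rows[[length(rows) + 1L]] <<- list(kind = kind, seg = seg, node = node)
    costs[[length(costs) + 1L]] <<- cost_vec
  }

  starts <- seq_len(nseg)
  if (params$max_gap_frames > 0L) {
    for (e in seq_len(nseg)) {
      cv <- rep(Inf, nseg)
      for (s in starts) {
        if (s == e) next
        g <- seg_first[s] - seg_last[e]
        skipped <- g - 1L
        if (skipped < 1L || skipped > params$max_gap_frames) next
        d <- sqrt(sum((end_pos[e, ] - start_pos[s, ])^2))
        if (d > params$max_link_dist) next
        cv[s] <- d^2 * skipped
      }
      if (any(is.finite(cv))) add_row("gap", e, NA_integer_, cv)
    }
  }
  if (params$allow_splits) {
    for (p in seq_len(nseg)) {
      sp <- segments[[p]]
      for (k in seq_along(sp$frames)) {
        f <- sp$frames[k]
        anchor <- lookup_roi(idx, f, sp$roi_ids[k])$centroid
        cv <- rep(Inf, nseg)
        for (s in starts) {
          if (s == p) next
          if (seg_first[s] != f + 1L) next
          d <- sqrt(sum((anchor - start_pos[s, ])^2))
          if (d > params$max_split_dist) next
          cv[s] <- d^2
        }
        if (!any(is.finite(cv))) next
        copies <- if (k == length(sp$frames)) 2L else 1L
        for (cc in seq_len(copies)) add_row("split", p, k, cv)
      }
    }
  }

  events <- list()
  if (length(rows)) {
    R <- length(rows); C <- nseg
    cand <- do.call(rbind, costs)
    alt <- params$alt_cost_factor * max(cand[is.finite(cand)])
    cm <- matrix(Inf, R + C, R + C)
    cm[1:R, 1:C] <- cand
    cm[cbind(1:R, C + 1:R)] <- alt
    cm[cbind(R + 1:C, 1:C)] <- alt
    lr <- matrix(Inf, C, R)
    lr[t(is.finite(cand))] <- 0
    cm[R + 1:C, C + 1:R] <- lr
    asg <- solve_lap(cm, dims = c(R, C))
    if (nrow(asg$pairs)) for (k in seq_len(nrow(asg$pairs))) {
      ri <- asg$pairs[k, 1]; s <- asg$pairs[k, 2]
      events[[length(events) + 1L]] <- c(rows[[ri]], list(start = s))
    }
  }

  build_lineage_from_events(segments, events)
}

# Applies accepted gap/split events to the segments and renumbers.
build_lineage_from_events <- function(segments, events) {
  nseg <- length(segments)
  nodes <- lapply(segments, function(s) cbind(s$frames, s$roi_ids))
  parent_seg <- rep(NA_integer_, nseg)   # provisional, by segment index
  absorbed_into <- rep(NA_integer_, nseg)

  # group split events by (anchor segment, anchor node)
  split_ev <- Filter(function(e) e$kind == "split", events)
  gap_ev <- Filter(function(e) e$kind == "gap", events)

  if (length(split_ev)) {
    segs_involved <- unique(vapply(split_ev, function(e) e$seg, integer(1)))
    for (p in segs_involved) {
      ev_p <- Filter(function(e) e$seg == p, split_ev)
      ks <- sort(unique(vapply(ev_p, function(e) e$node, integer(1))))
      orig_len <- nrow(nodes[[p]])
      cur <- p        # segment currently holding nodes k..end of p
      offset <- 0L    # nodes dropped from cur's head so far
      end_divided <- FALSE
      for (k in ks) {
        kids <- vapply(Filter(function(e) e$node == k, ev_p),
                       function(e) e$start, integer(1))
        at_end <- k == orig_len
        if (at_end && length(kids) == 1L) {
          # a lone adoption at a segment end is a wider-radius continuation
          gap_ev[[length(gap_ev) + 1L]] <- list(kind = "gap", seg = cur,
                                                node = NA, start = kids[1])
          next
        }
        if (!at_end) {
          # cut: the anchor segment's own continuation is daughter one
          kk <- k - offset
          cont <- nodes[[cur]][(kk + 1):nrow(nodes[[cur]]), , drop = FALSE]
          nodes[[cur]] <- nodes[[cur]][1:kk, , drop = FALSE]
          nseg <- nseg + 1L
          nodes[[nseg]] <- cont
          parent_seg <- c(parent_seg, cur)
          absorbed_into <- c(absorbed_into, NA_integer_)
          for (s in kids) parent_seg[s] <- cur
          cur <- nseg
          offset <- k
        } else {
          for (s in kids) parent_seg[s] <- cur
          end_divided <- TRUE
        }
      }
      # the original end of p now belongs to `cur`: re-target (or drop,
      # when that end became a mother) any gap continuation recorded for p
      if (end_divided) {
        gap_ev <- Filter(function(e) e$seg != p, gap_ev)
      } else if (cur != p) {
        gap_ev <- lapply(gap_ev, function(e) {
          if (e$kind == "gap" && e$seg == p) e$seg <- cur
          e
        })
      }
    }
  }

  if (length(gap_ev)) {
    # chain merges: follow absorbed_into to the surviving head
    head_of <- function(i) {
      while (!is.na(absorbed_into[i])) i <- absorbed_into[i]
      i
    }
    # apply in temporal order of the absorbed start
    ord <- order(vapply(gap_ev, function(e) nodes[[e$start]][1, 1], numeric(1)))
    for (e in gap_ev[ord]) {
      h <- head_of(e$seg)
      s <- e$start
      if (h == s) next
      nodes[[h]] <- rbind(nodes[[h]], nodes[[s]])
      absorbed_into[s] <- h
      if (!is.na(parent_seg[s]) && is.na(parent_seg[h]))
        parent_seg[h] <- parent_seg[s]
      # children pointing at s re-point to h
      parent_seg[!is.na(parent_seg) & parent_seg == s] <- h
    }
  }

  alive <- which(is.na(absorbed_into))
  # renumber deterministically: by first frame, then first roi id
  ordk <- order(vapply(alive, function(i) nodes[[i]][1, 1], numeric(1)),
                vapply(alive, function(i) nodes[[i]][1, 2], numeric(1)))
  alive <- alive[ordk]
  newid <- rep(NA_integer_, length(nodes))
  newid[alive] <- seq_along(alive)

  tracks <- vector("list", length(alive))
  for (j in seq_along(alive)) {
    i <- alive[j]
    nd <- nodes[[i]]
    nd <- nd[order(nd[, 1]), , drop = FALSE]
    pid <- parent_seg[i]
    if (!is.na(pid)) {
      while (!is.na(absorbed_into[pid])) pid <- absorbed_into[pid]
      pid <- newid[pid]
    }
    tracks[[j]] <- track(j, nd[, 1], nd[, 2],
                         parent_id = if (is.na(pid)) NULL else pid)
  }
  lineage(tracks)
}

#' Track a movie end to end (detect, link, close gaps, split)
#'
#' Convenience wrapper for the full tracking-by-detection pipeline.
#' Detections may come from the built-in recognition or from imported
#' label masks.
#'
#' @param stack a `frame_stack` (ignored when `masks` are supplied and
#'   features are not needed).
#' @param detection a [detection_params()] object.
#' @param linking a [link_params()] object.
#' @param masks optional externally produced per-frame label masks; when
#'   given, detection is skipped and the masks define the rois.
#' @return a list with `lineage`, `rois` (per frame) and `masks`.
#' @export
track_movie <- function(stack = NULL, detection = detection_params(),
                        linking = link_params(), masks = NULL) {
  if (is.null(masks)) {
    if (is.null(stack)) stop("need a stack or masks")
    det <- detect_movie(stack, detection)
    rois <- det$rois
    masks <- det$masks
  } else {
    rois <- rois_from_masks(masks, stack)
  }
  segments <- link_all_frames(rois, linking)
  lin <- close_gaps_and_split(segments, rois, linking)
  list(lineage = lin, rois = rois, masks = masks)
}
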