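#' Synthetic movie configuration
#'
#' Describes a simulated fluorescence nuclear time-lapse: Gaussian-blob
#' cells moving by Brownian diffusion plus a common drift with reflecting
#' boundaries, occasional divisions (a dividing cell swells for the two
#' frames before it splits into two daughters), Poisson-Gaussian noise,
#' and the two error-prone regimes seen in dense epithelial recordings:
#' pairs of cells travelling in close contact, and division-time swelling
#' that invites over-segmentation.
#'
#' The defaults describe a benign, well-separated field of view: 15 cells
#' of sigma 3-4 px and amplitude 80-120 over a background of 10, mild
#' diffusion (0.8 px/frame) and drift, and two scheduled divisions, on a
#' 256 x 256 field over 30 frames.
#'
#' @param n_frames,height,width movie geometry.
#' @param n_cells number of initial cells.
#' @param blob_sigma_range,amplitude_range per-cell appearance ranges
#'   (drawn uniformly).
#' @param background constant background level.
#' @param noise_gaussian_sigma additive Gaussian read-noise sigma.
#' @param noise_poisson apply Poisson shot noise to the clean image?
#' @param diffusion_sigma Brownian step sigma, px/frame.
#' @param drift common drift `(d_row, d_col)`, px/frame.
#' @param division_prob per-cell per-frame division probability.
#' @param scheduled_divisions list of `c(cell, frame)` pairs forcing a
#'   division of that (initial) cell to complete at that frame.
#' @param division_separation distance between daughter centers at the
#'   split, px.
#' @param daughter_drift persistent post-mitotic separation speed of each
#'   daughter along the division axis, px/frame (daughter cells migrate
#'   apart after cytokinesis rather than staying adjacent).
#' @param swell_factor mitotic shape-change strength. During the two
#'   pre-split frames the mother is rendered as a two-lobed (dumbbell)
#'   figure elongating along the division axis, with lobe separation
#'   `(swell_factor - 1) * 2 * sigma * tau` (`tau` = 1/3 then 2/3); its
#'   ground-truth mask is still the single half-maximum region of the
#'   whole figure. Values near 1 keep the figure compact; large values
#'   make the late mitotic figure bilobed enough to invite
#'   over-segmentation by a blob detector.
#' @param contact_fraction fraction of cells seeded as close-contact
#'   pairs that travel together.
#' @param contact_distance center distance within a contact pair, px.
#' @param min_separation minimum initial center distance between
#'   non-contact cells, px.
#' @param rng_seed integer seed; the movie is fully determined by it.
#' @export
synth_config <- function(n_frames = 30L, height = 256L, width = 256L,
                         n_cells = 15L,
                         blob_sigma_range = c(3, 4),
                         amplitude_range = c(80, 120),
                         background = 10,
                         noise_gaussian_sigma = 4, noise_poisson = TRUE,
                         diffusion_sigma = 0.8, drift = c(0.2, -0.1),
                         division_prob = 0,
                         scheduled_divisions = list(c(3L, 12L), c(7L, 20L)),
                         division_separation = 12,
                         daughter_drift = 0.4,
                         swell_factor = 1.5,
                         contact_fraction = 0, contact_distance = 6,
                         min_separation = 30,
                         rng_seed = 42L) {
  stopifnot(n_frames >= 1, n_cells >= 0, division_prob >= 0,
            division_prob <= 1, contact_fraction >= 0,
            contact_fraction <= 1)
  structure(list(n_frames = as.integer(n_frames),
                 height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 blob_sigma_range = blob_sigma_range,
                 amplitude_range = amplitude_range,
                 background = background,
                 noise_gaussian_sigma = noise_gaussian_sigma,
                 noise_poisson = isTRUE(noise_poisson),
                 diffusion_sigma = diffusion_sigma, drift = drift,
                 division_prob = division_prob,
                 scheduled_divisions = scheduled_divisions,
                 division_separation = division_separation,
                 daughter_drift = daughter_drift,
                 swell_factor = swell_factor,
                 contact_fraction = contact_fraction,
                 contact_distance = contact_distance,
                 min_separation = min_separation,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

#' Generate a synthetic time-lapse movie with exact ground truth
#'
#' Simulation draw order (fixed, so an external consumer of the same RNG
#' stream can replay it):
#' 1. per-cell appearance: sigma then amplitude, cells in id order;
#' 2. initial placement: `(row, col)` uniform draws per cell in id order,
#'    redrawn until the separation constraint holds (contact-pair
#'    followers take no draws: they sit `contact_distance` from their
#'    leader);
#' 3. one uniform division-axis angle per scheduled division, in list
#'    order;
#' 4. per frame `t = 2..T`, cells in id order: two N(0, diffusion_sigma)
#'    draws each (followers draw too but copy the leader's step), then -
#'    if `division_prob > 0` - one uniform division draw per live cell;
#'    a division that fires immediately draws its uniform axis angle;
#' 5. per frame: the noise field(s), Poisson then Gaussian.
#'
#' Ground-truth masks are the 50%-amplitude contour of each noiseless
#' blob (pixels contested by overlapping cells go to the stronger
#' contribution), labelled by track id. A dividing cell swells by
#' `swell_factor` for the two frames before the split, then is replaced
#' by two daughters `division_separation` apart; the mother-daughter
#' relation is recorded in the ground-truth lineage. Divisions never
#' complete in the last two frames.
#'
#' @param config a [synth_config()].
#' @return a list with `stack` (a `frame_stack`), `masks` (per-frame
#'   ground-truth label matrices, labels = track ids), `lineage` (the
#'   ground-truth lineage) and `division_log` / `contact_pairs`
#'   bookkeeping.
#' @export
generate_movie <- function(config = synth_config()) {
  cf <- config
  H <- cf$height; W <- cf$width; TT <- cf$n_frames
  set.seed(cf$rng_seed)

  n0 <- cf$n_cells
  sigmas <- runif(n0, cf$blob_sigma_range[1], cf$blob_sigma_range[2])
  amps <- runif(n0, cf$amplitude_range[1], cf$amplitude_range[2])

  n_pairs <- floor(cf$contact_fraction * n0 / 2)
  leader <- rep(NA_integer_, n0)
  if (n_pairs > 0)
    for (p in seq_len(n_pairs)) leader[2 * p] <- 2L * p - 1L

  margin <- 15
  pos <- matrix(NA_real_, n0, 2)
  for (i in seq_len(n0)) {
    if (!is.na(leader[i])) {
      pos[i, ] <- pos[leader[i], ] + c(0, cf$contact_distance)
      next
    }
    for (try in 1:200) {
      p <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      placed <- pos[seq_len(i - 1), , drop = FALSE]
      placed <- placed[stats::complete.cases(placed), , drop = FALSE]
      if (!nrow(placed) ||
          min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)) >=
            cf$min_separation) {
        pos[i, ] <- p
        break
      }
      if (try == 200)
        stop("cannot place the requested number of cells in the field")
    }
  }

  # cell state tables (grow as divisions add daughters)
  cells <- data.frame(id = seq_len(n0), sigma = sigmas, amp = amps,
                      leader = leader,
                      born = 1L, died = NA_integer_,
                      parent = NA_integer_,
                      own_drift_r = 0, own_drift_c = 0)
  positions <- vector("list", TT)      # per frame: matrix cell x 2
  swollen <- vector("list", TT)        # per frame: logical per cell
  alive_at <- function(t, tab) !is.na(tab$born) & tab$born <= t &
    (is.na(tab$died) | tab$died >= t)

  sched <- cf$scheduled_divisions
  sched_cell <- vapply(sched, function(x) as.integer(x[1]), integer(1))
  sched_frame <- vapply(sched, function(x) as.integer(x[2]), integer(1))
  division_log <- list()
  pending <- data.frame(cell = integer(0), split_frame = integer(0),
                        theta = numeric(0))
  if (length(sched_cell)) {
    bad <- sched_frame > TT - 2L | sched_frame < 3L
    if (any(bad)) stop("scheduled divisions must complete in frames 3..T-2")
    pending <- data.frame(cell = sched_cell, split_frame = sched_frame,
                          theta = runif(length(sched_cell), 0, 2 * pi))
  }

  cur_pos <- pos
  for (t in seq_len(TT)) {
    if (t > 1L) {
      ncell <- nrow(cells)
      steps <- matrix(0, ncell, 2)
      for (i in seq_len(ncell)) {
        s <- rnorm(2, sd = cf$diffusion_sigma)
        steps[i, ] <- s
      }
      for (i in seq_len(ncell))
        if (!is.na(cells$leader[i])) steps[i, ] <- steps[cells$leader[i], ]
      live <- alive_at(t - 1L, cells) | alive_at(t, cells)
      cur_pos[live, 1] <- cur_pos[live, 1] + steps[live, 1] + cf$drift[1] +
        cells$own_drift_r[live]
      cur_pos[live, 2] <- cur_pos[live, 2] + steps[live, 2] + cf$drift[2] +
        cells$own_drift_c[live]
      # reflecting boundaries
      cur_pos[, 1] <- reflect(cur_pos[, 1], margin, H - margin)
      cur_pos[, 2] <- reflect(cur_pos[, 2], margin, W - margin)

      if (cf$division_prob > 0) {
        for (i in which(alive_at(t, cells))) {
          u <- runif(1)
          if (u < cf$division_prob && t + 2L <= TT - 2L &&
              !i %in% pending$cell)
            pending <- rbind(pending,
                             data.frame(cell = i, split_frame = t + 2L,
                                        theta = runif(1, 0, 2 * pi)))
        }
      }
    }

    # apply divisions completing at this frame
    due <- pending$cell[pending$split_frame == t]
    for (i in due) {
      if (!alive_at(t, cells)[i]) next
      theta <- pending$theta[pending$cell == i][1]
      off <- cf$division_separation / 2 * c(cos(theta), sin(theta))
      cells$died[i] <- t - 1L
      for (s in c(1, -1)) {
        cells <- rbind(cells, data.frame(
          id = nrow(cells) + 1L, sigma = cells$sigma[i],
          amp = cells$amp[i], leader = NA_integer_, born = t,
          died = NA_integer_, parent = i,
          own_drift_r = s * cf$daughter_drift * cos(theta),
          own_drift_c = s * cf$daughter_drift * sin(theta)))
        cur_pos <- rbind(cur_pos, cur_pos[i, ] + s * off)
      }
      division_log[[length(division_log) + 1L]] <-
        list(mother = i, daughters = c(nrow(cells) - 1L, nrow(cells)),
             split_frame = t)
    }
    pending <- pending[!pending$cell %in% due, , drop = FALSE]

    # mitotic figure: lobe offset vector per cell (0 = interphase)
    lobe <- matrix(0, nrow(cells), 2)
    for (k in seq_len(nrow(pending))) {
      tau <- (3L - (pending$split_frame[k] - t)) / 3
      if (tau > 0) {
        i <- pending$cell[k]
        d <- (cf$swell_factor - 1) * 2 * cells$sigma[i] * tau
        lobe[i, ] <- d / 2 * c(cos(pending$theta[k]), sin(pending$theta[k]))
      }
    }
    positions[[t]] <- cur_pos
    swollen[[t]] <- lobe
  }

  # render frames + ground-truth masks
  frames <- vector("list", TT)
  masks <- vector("list", TT)
  for (t in seq_len(TT)) {
    live <- which(alive_at(t, cells))
    img <- matrix(cf$background, H, W)
    contrib_best <- matrix(0, H, W)
    lab <- matrix(0L, H, W)
    for (i in live) {
      p <- positions[[t]][i, ]
      s <- cells$sigma[i]
      a <- cells$amp[i]
      off <- swollen[[t]][i, ]
      halfspan <- ceiling(4 * s + sqrt(sum(off^2)))
      rows <- max(1, floor(p[1] - halfspan)):min(H, ceiling(p[1] + halfspan))
      cols <- max(1, floor(p[2] - halfspan)):min(W, ceiling(p[2] + halfspan))
      if (all(off == 0)) {
        d2 <- outer((rows - p[1])^2, (cols - p[2])^2, "+")
        g <- a * exp(-d2 / (2 * s^2))
      } else {
        # late-mitotic dumbbell: two lobes along the division axis
        d2a <- outer((rows - p[1] - off[1])^2, (cols - p[2] - off[2])^2, "+")
        d2b <- outer((rows - p[1] + off[1])^2, (cols - p[2] + off[2])^2, "+")
        g <- a * (exp(-d2a / (2 * s^2)) + exp(-d2b / (2 * s^2)))
      }
      img[rows, cols] <- img[rows, cols] + g
      inmask <- g >= a / 2
      better <- inmask & g > contrib_best[rows, cols]
      lab[rows, cols][better] <- cells$id[i]
      contrib_best[rows, cols][better] <- g[better]
    }
    masks[[t]] <- lab
    frames[[t]] <- img
  }
  for (t in seq_len(TT)) {
    img <- frames[[t]]
    if (cf$noise_poisson)
      img <- matrix(rpois(H * W, lambda = pmax(img, 0)), H, W)
    if (cf$noise_gaussian_sigma > 0)
      img <- img + matrix(rnorm(H * W, sd = cf$noise_gaussian_sigma), H, W)
    frames[[t]] <- pmax(img, 0)
  }

  tracks <- list()
  for (i in seq_len(nrow(cells))) {
    b <- cells$born[i]
    e <- if (is.na(cells$died[i])) TT else cells$died[i]
    if (e < b) next
    tracks[[length(tracks) + 1L]] <-
      track(cells$id[i], b:e, rep(cells$id[i], e - b + 1L),
            parent_id = if (is.na(cells$parent[i])) NULL
                        else cells$parent[i])
  }

  list(stack = frame_stack(frames), masks = masks,
       lineage = lineage(tracks),
       division_log = division_log,
       contact_pairs = if (n_pairs > 0)
         lapply(seq_len(n_pairs), function(p) c(2L * p - 1L, 2L * p))
       else list(),
       positions = positions, cells = cells, config = cf)
}

reflect <- function(x, lo, hi) {
  x <- ifelse(x < lo, 2 * lo - x, x)
  ifelse(x > hi, 2 * hi - x, x)
}

#' Deterministically corrupt a tracking result
#'
#' Injects named error types into a (masks, lineage) pair and logs what
#' was injected, for testing that the evaluation metrics and the repair
#' workflow respond as documented. Supported types:
#' \describe{
#'   \item{merge}{`frame`, `labels = c(keep, absorb)`: the second mask is
#'     absorbed into the first in that frame (two touching cells
#'     misidentified as one), and the absorbed node leaves its track.}
#'   \item{split}{`frame`, `label`: the mask is split in two along its
#'     centroid column (over-segmentation); the new fragment becomes a
#'     one-node track.}
#'   \item{drop_link}{`track`, `frame`: the track is cut after `frame`.}
#'   \item{drop_object}{`frame`, `label`: the node and its pixels vanish.}
#'   \item{false_division}{`parent`, `child`: a spurious mother-daughter
#'     edge.}
#' }
#'
#' @param result list with `masks` and `lineage` (labels = track ids).
#' @param errors list of error specifications (each a list with `type`
#'   plus the fields above). An empty list returns the input unchanged.
#' @return a list with corrupted `masks`, `lineage` and a `log` data
#'   frame.
#' @export
inject_errors <- function(result, errors = list()) {
  masks <- result$masks
  lin <- result$lineage
  log <- list()
  for (e in errors) {
    if (is.null(e$type)) stop("error spec needs a type")
    switch(e$type,
      merge = {
        f <- e$frame; keep <- e$labels[1]; absorb <- e$labels[2]
        m <- masks[[f]]
        if (!any(m == absorb)) stop("merge: absorbed label not in frame")
        m[m == absorb] <- keep
        masks[[f]] <- m
        upd <- remove_node_and_sync(masks, lin, f, absorb)
        masks <- upd$masks; lin <- upd$lineage
        log[[length(log) + 1L]] <- data.frame(
          type = "merge", frame = f, label = keep, aux = absorb)
      },
      split = {
        f <- e$frame; l <- e$label
        m <- masks[[f]]
        px <- which(m == l, arr.ind = TRUE)
        if (!nrow(px)) stop("split: label not in frame")
        newl <- max(unlist(lapply(masks, max)),
                    vapply(lin$tracks, function(t) t$track_id,
                           integer(1))) + 1L
        right <- px[, 2] > mean(px[, 2])
        if (!any(right) || all(right))
          right <- px[, 2] >= stats::median(px[, 2])
        m[px[right, , drop = FALSE]] <- newl
        masks[[f]] <- m
        lin$tracks[[as.character(newl)]] <- track(newl, f, newl)
        log[[length(log) + 1L]] <- data.frame(
          type = "split", frame = f, label = l, aux = newl)
      },
      drop_link = {
        lin <- cut_track(lin, e$track, e$frame)
        # the tail keeps the same mask labels but a new track id:
        # relabel its masks so labels stay equal to track ids
        newid <- max(vapply(lin$tracks, function(t) t$track_id,
                            integer(1)))
        tl <- get_track(lin, newid)
        for (ff in tl$frames) {
          m <- masks[[ff]]
          m[m == e$track] <- newid
          masks[[ff]] <- m
        }
        lin$tracks[[as.character(newid)]] <-
          track(newid, tl$frames, rep(newid, length(tl$frames)))
        log[[length(log) + 1L]] <- data.frame(
          type = "drop_link", frame = e$frame, label = e$track,
          aux = newid)
      },
      drop_object = {
        f <- e$frame; l <- e$label
        m <- masks[[f]]
        if (!any(m == l)) stop("drop_object: label not in frame")
        m[m == l] <- 0L
        masks[[f]] <- m
        upd <- remove_node_and_sync(masks, lin, f, l)
        masks <- upd$masks; lin <- upd$lineage
        log[[length(log) + 1L]] <- data.frame(
          type = "drop_object", frame = f, label = l, aux = NA_integer_)
      },
      false_division = {
        lin <- set_parent(lin, e$child, e$parent)
        log[[length(log) + 1L]] <- data.frame(
          type = "false_division", frame = NA_integer_, label = e$parent,
          aux = e$child)
      },
      stop(sprintf("unknown error type \"%s\"", e$type))
    )
  }
  list(masks = masks, lineage = lin,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(type = character(0), frame = integer(0),
                    label = integer(0), aux = integer(0)))
}

# Remove a (frame, label) node from a label-keyed result, keeping mask
# labels equal to track ids: an interior removal splits the track, so the
# tail's frames are relabelled to the tail's fresh id.
remove_node_and_sync <- function(masks, lin, frame, label) {
  before_ids <- vapply(lin$tracks, function(t) t$track_id, integer(1))
  lin2 <- delete_roi_node(lin, frame, label)
  after_ids <- vapply(lin2$tracks, function(t) t$track_id, integer(1))
  newid <- setdiff(after_ids, before_ids)
  if (length(newid) == 1L) {
    tl <- get_track(lin2, newid)
    for (ff in tl$frames) {
      m <- masks[[ff]]
      m[m == label] <- newid
      masks[[ff]] <- m
    }
    lin2$tracks[[as.character(newid)]] <-
      track(newid, tl$frames, rep(newid, length(tl$frames)))
  }
  list(masks = masks, lineage = lin2)
}
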