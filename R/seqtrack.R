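#' Sequential tracking parameters
#'
#' The sequential tracker follows one user-selected roi through the movie
#' by particle filtering: candidate positions are propagated by a Gaussian
#' random walk and weighted by the similarity of the luminance pattern
#' around them to a template taken at the starting roi.
#'
#' @param n_particles number of particles (default 300).
#' @param motion_sigma random-walk standard deviation, px/frame.
#' @param patch_half template half-size in pixels; `NULL` derives it from
#'   the seed roi's bounding box.
#' @param similarity appearance score: `"ncc"` (normalized
#'   cross-correlation, illumination-robust, bounded in \[-1, 1\]) or
#'   `"ssd"` (negative sum of squared differences scaled by the template
#'   variance).
#' @param beta weight sharpness; particle weights are
#'   proportional to `exp(beta * similarity)`.
#' @param template_update `"none"` (drift-safe default) or `"ema"`
#'   (exponential moving average at the estimate).
#' @param ema_alpha EMA learning rate in \[0, 1\].
#' @param resample_threshold systematic resampling triggers when the
#'   effective sample size falls below this fraction of `n_particles`.
#' @param rng_seed integer seed; fixed seed gives bit-identical tracks.
#' @export
seqtrack_params <- function(n_particles = 300L, motion_sigma = 5,
                            patch_half = NULL,
                            similarity = c("ncc", "ssd"), beta = 10,
                            template_update = c("none", "ema"),
                            ema_alpha = 0.2, resample_threshold = 0.5,
                            rng_seed = 1L) {
  similarity <- match.arg(similarity)
  template_update <- match.arg(template_update)
  if (n_particles < 1L) stop("n_particles must be at least 1")
  if (motion_sigma <= 0) stop("motion_sigma must be positive")
  if (ema_alpha < 0 || ema_alpha > 1) stop("ema_alpha must be in [0, 1]")
  structure(list(n_particles = as.integer(n_particles),
                 motion_sigma = motion_sigma, patch_half = patch_half,
                 similarity = similarity, beta = beta,
                 template_update = template_update, ema_alpha = ema_alpha,
                 resample_threshold = resample_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "seqtrack_params")
}

# Patch of side 2h+1 centered at (row, col) (rounded), replicate-padded at
# the image border.
extract_patch <- function(frame, center, half) {
  r0 <- round(center[1]); c0 <- round(center[2])
  rows <- pmin(pmax((r0 - half):(r0 + half), 1L), nrow(frame))
  cols <- pmin(pmax((c0 - half):(c0 + half), 1L), ncol(frame))
  frame[rows, cols, drop = FALSE]
}

#' Normalized cross-correlation of two equally sized patches
#'
#' Zero-variance patches score 0 (rather than NaN), so flat background
#' neither attracts nor repels the tracker.
#' @param a,b numeric matrices of identical size.
#' @export
ncc <- function(a, b) {
  av <- a - mean(a); bv <- b - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

patch_similarity <- function(template, patch, method) {
  if (method == "ncc") return(ncc(template, patch))
  v <- stats::var(as.vector(template))
  if (v == 0) return(0)
  -mean((template - patch)^2) / v
}

# Similarity of the template to the patch around every particle at once
# (replicate-padded at the border, like extract_patch).
particle_similarities <- function(frame, pos, template, half, method) {
  n <- nrow(pos)
  H <- nrow(frame); W <- ncol(frame)
  s <- 2L * half + 1L
  offs <- (-half):half
  rows <- pmin(pmax(outer(round(pos[, 1]), offs, "+"), 1L), H)
  cols <- pmin(pmax(outer(round(pos[, 2]), offs, "+"), 1L), W)
  lin <- rows[, rep(seq_len(s), times = s), drop = FALSE] +
    (cols[, rep(seq_len(s), each = s), drop = FALSE] - 1L) * H
  P <- matrix(frame[lin], n, s * s)
  tv <- as.vector(template)
  if (method == "ncc") {
    tc <- tv - mean(tv)
    st <- sum(tc^2)
    Pc <- P - rowMeans(P)
    den <- sqrt(rowSums(Pc^2) * st)
    num <- as.vector(Pc %*% tc)
    ifelse(den == 0, 0, num / den)
  } else {
    v <- stats::var(tv)
    if (v == 0) return(rep(0, n))
    -rowMeans((P - rep(tv, each = n))^2) / v
  }
}

#' Initialize the sequential tracker on a roi
#'
#' @param stack a `frame_stack`.
#' @param seed_roi the roi to follow (its centroid seeds the template).
#' @param params a [seqtrack_params()] object.
#' @param channel image channel to track on.
#' @return an object of class `particle_cloud`: particle positions,
#'   normalized weights, the template, the current estimate and the
#'   private RNG state.
#' @export
init_tracker <- function(stack, seed_roi, params = seqtrack_params(),
                         channel = 1L) {
  stopifnot(inherits(stack, "frame_stack"), inherits(seed_roi, "roi"))
  ctr <- seed_roi$centroid
  if (ctr[1] < 1 || ctr[1] > stack$height ||
      ctr[2] < 1 || ctr[2] > stack$width)
    stop("roi lies outside the image")
  half <- params$patch_half
  if (is.null(half)) {
    bb <- seed_roi$bbox
    half <- max(3L, ceiling(max(bb[3] - bb[1], bb[4] - bb[2]) / 2))
  }
  frame <- get_frame(stack, seed_roi$frame, channel)
  template <- extract_patch(frame, ctr, half)

  n <- params$n_particles
  cloud <- structure(list(
    positions = matrix(rep(ctr, each = n), ncol = 2),
    weights = rep(1 / n, n),
    template = template, half = half,
    estimate = ctr, confidence = 1,
    frame_dim = c(stack$height, stack$width),
    params = params, channel = channel, lost = FALSE,
    rng_state = NULL), class = "particle_cloud")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(params$rng_seed)
  cloud$rng_state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  cloud
}

#' Advance the particle cloud to the next frame
#'
#' Propagates particles with the Gaussian random walk, scores the patch
#' around each by similarity to the template, converts scores to
#' normalized weights `exp(beta * sim)`, resamples systematically when the
#' effective sample size drops below the configured fraction, and places
#' the estimate at the weighted mean. If every weight degenerates to zero
#' the cloud is flagged lost and keeps the last good estimate.
#'
#' @param cloud a `particle_cloud`.
#' @param next_frame the next frame as a 2D matrix.
#' @return the updated `particle_cloud`.
#' @export
step_tracker <- function(cloud, next_frame) {
  stopifnot(inherits(cloud, "particle_cloud"))
  p <- cloud$params
  n <- p$n_particles
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", cloud$rng_state, globalenv())

  pos <- cloud$positions +
    matrix(rnorm(2 * n, sd = p$motion_sigma), ncol = 2)
  pos[, 1] <- pmin(pmax(pos[, 1], 1), cloud$frame_dim[1])
  pos[, 2] <- pmin(pmax(pos[, 2], 1), cloud$frame_dim[2])

  sims <- particle_similarities(next_frame, pos, cloud$template,
                                cloud$half, p$similarity)
  w <- exp(p$beta * sims)
  if (!any(is.finite(w)) || sum(w) == 0) {
    cloud$lost <- TRUE
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    return(cloud)
  }
  w <- w / sum(w)
  est <- c(sum(w * pos[, 1]), sum(w * pos[, 2]))
  ess <- 1 / sum(w^2)
  if (ess < p$resample_threshold * n) {
    u <- (runif(1) + 0:(n - 1)) / n
    idx <- findInterval(u, cumsum(w)) + 1L
    idx[idx > n] <- n
    pos <- pos[idx, , drop = FALSE]
    w <- rep(1 / n, n)
  }
  cloud$positions <- pos
  cloud$weights <- w
  cloud$estimate <- est
  cloud$confidence <- max(sims)
  if (p$template_update == "ema") {
    patch <- extract_patch(next_frame, est, cloud$half)
    cloud$template <- (1 - p$ema_alpha) * cloud$template +
      p$ema_alpha * patch
  }
  cloud$rng_state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  cloud
}

#' @export
print.particle_cloud <- function(x, ...) {
  cat(sprintf(
    "<particle_cloud> %d particles, estimate (%.2f, %.2f)%s\n",
    nrow(x$positions), x$estimate[1], x$estimate[2],
    if (x$lost) " [LOST]" else ""))
  invisible(x)
}

#' Follow one roi through a frame range
#'
#' Runs the particle filter from `start_frame` to `end_frame`; when
#' `end_frame < start_frame` the movie is traversed backward in time.
#' One spot-only roi is emitted per visited frame (bounding box = template
#' footprint, `roi_id` inherited from the seed roi). On tracking loss the
#' partial track up to the last good frame is returned.
#'
#' @param stack a `frame_stack`.
#' @param seed_roi roi in `start_frame` to follow.
#' @param start_frame,end_frame inclusive frame range.
#' @param params a [seqtrack_params()] object.
#' @param channel image channel to track on.
#' @return an object of class `seq_track`: `track` (a `track` whose id is
#'   the seed roi id), `rois` (per visited frame), `confidence`
#'   (best particle similarity per frame), `frames` (visit order) and
#'   `lost` flag.
#' @export
track_sequential <- function(stack, seed_roi, start_frame, end_frame,
                             params = seqtrack_params(), channel = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (start_frame < 1 || start_frame > stack$n_frames ||
      end_frame < 1 || end_frame > stack$n_frames)
    stop("frame range outside the stack")
  seed_roi$frame <- as.integer(start_frame)
  cloud <- init_tracker(stack, seed_roi, params, channel)
  frames <- seq(start_frame, end_frame)
  half <- cloud$half

  est <- matrix(NA_real_, length(frames), 2)
  conf <- rep(NA_real_, length(frames))
  est[1, ] <- cloud$estimate
  conf[1] <- 1
  n_done <- 1L
  if (length(frames) > 1L) for (k in 2:length(frames)) {
    cloud <- step_tracker(cloud, get_frame(stack, frames[k], channel))
    if (cloud$lost) break
    est[k, ] <- cloud$estimate
    conf[k] <- cloud$confidence
    n_done <- k
  }
  frames <- frames[seq_len(n_done)]
  est <- est[seq_len(n_done), , drop = FALSE]
  conf <- conf[seq_len(n_done)]

  rois <- lapply(seq_along(frames), function(k) {
    bb <- c(max(1, est[k, 1] - half), max(1, est[k, 2] - half),
            min(stack$height, est[k, 1] + half),
            min(stack$width, est[k, 2] + half))
    roi(roi_id = seed_roi$roi_id, frame = frames[k],
        centroid = est[k, ], bbox = bb,
        features = list(confidence = conf[k]))
  })
  ord <- order(frames)
  tr <- track(seed_roi$roi_id, frames[ord],
              rep(seed_roi$roi_id, length(frames)))
  structure(list(track = tr, rois = rois[ord], frames = frames,
                 estimates = est, confidence = conf,
                 lost = isTRUE(cloud$lost),
                 seed_roi = seed_roi, params = params, channel = channel,
                 start_frame = start_frame, end_frame = end_frame,
                 stack = stack),
            class = "seq_track")
}

#' @export
print.seq_track <- function(x, ...) {
  cat(sprintf("<seq_track> roi %d, frames %d..%d (%d visited)%s\n",
              x$seed_roi$roi_id, x$start_frame, x$end_frame,
              length(x$frames), if (x$lost) " [LOST]" else ""))
  invisible(x)
}

#' Cancel, correct and resume a sequential track
#'
#' The correction workflow for sequential tracking: when the tracker
#' drifts off target, the run is cancelled at a frame, the position in
#' that frame is corrected, and tracking resumes from the corrected
#' position to the original end. Nodes before the correction frame (in
#' visiting order) are kept unchanged.
#'
#' @param st a `seq_track` result.
#' @param frame the frame (within the planned range) to resume from.
#' @param corrected_position numeric `(row, col)` of the target in `frame`.
#' @param params optional parameter override; the resumed leg derives a
#'   fresh RNG substream from the original seed and the resume frame.
#' @return an updated `seq_track` covering the original range.
#' @export
resume_from <- function(st, frame, corrected_position, params = NULL) {
  stopifnot(inherits(st, "seq_track"))
  planned <- seq(st$start_frame, st$end_frame)
  if (!frame %in% planned) stop("frame outside the planned range")
  if (is.null(params)) params <- st$params
  params$rng_seed <- as.integer(
    (params$rng_seed + 7919 * frame) %% .Machine$integer.max)

  keep <- which(match(st$frames, planned) < match(frame, planned))
  half <- max(3L, ceiling((st$rois[[1]]$bbox[3] - st$rois[[1]]$bbox[1]) / 2))
  if (!is.null(params$patch_half)) half <- params$patch_half
  seed2 <- roi(roi_id = st$seed_roi$roi_id, frame = frame,
               centroid = corrected_position,
               bbox = c(corrected_position[1] - half,
                        corrected_position[2] - half,
                        corrected_position[1] + half,
                        corrected_position[2] + half))
  tail_run <- track_sequential(st$stack, seed2, frame, st$end_frame,
                               params, st$channel)

  frames <- c(st$frames[keep], tail_run$frames)
  est <- rbind(st$estimates[keep, , drop = FALSE], tail_run$estimates)
  conf <- c(st$confidence[keep], tail_run$confidence)
  # rebuild rois from the concatenated estimates
  rois <- lapply(seq_along(frames), function(k) {
    bb <- c(max(1, est[k, 1] - half), max(1, est[k, 2] - half),
            min(st$stack$height, est[k, 1] + half),
            min(st$stack$width, est[k, 2] + half))
    roi(roi_id = st$seed_roi$roi_id, frame = frames[k],
        centroid = est[k, ], bbox = bb,
        features = list(confidence = conf[k]))
  })
  ord <- order(frames)
  tr <- track(st$seed_roi$roi_id, frames[ord],
              rep(st$seed_roi$roi_id, length(frames)))
  structure(list(track = tr, rois = rois[ord], frames = frames,
                 estimates = est, confidence = conf,
                 lost = tail_run$lost, seed_roi = st$seed_roi,
                 params = st$params, channel = st$channel,
                 start_frame = st$start_frame, end_frame = st$end_frame,
                 stack = st$stack),
            class = "seq_track")
}
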