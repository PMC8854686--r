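#' Detection parameters
#'
#' @param sigma LoG scale in pixels; should match the blob radius/sqrt(2),
#'   i.e. roughly the Gaussian sigma of the nuclei being detected.
#' @param threshold minimum scale-normalized LoG response at a maximum.
#'   For a Gaussian blob of amplitude A whose sigma matches `sigma`, the
#'   peak response is about A/2, so a threshold well below half the dimmest
#'   expected amplitude keeps all true spots.
#' @param min_distance minimum separation between returned spots (pixels).
#' @param make_regions grow a watershed region around each spot?
#' @param fg_method foreground rule for region formation: `"halfmax"`
#'   (default: Otsu foreground, then each watershed region is trimmed to
#'   the pixels above half its own peak height over the background - the
#'   FWHM contour, the natural extent definition for Gaussian-like
#'   nuclei), `"otsu"` (threshold of the smoothed frame chosen by Otsu's
#'   method) or `"fixed"` (absolute threshold `fg_threshold`).
#' @param fg_threshold absolute foreground threshold when
#'   `fg_method = "fixed"`.
#' @param smoothing_sigma Gaussian pre-smoothing of the watershed relief.
#' @param detect_channel channel used for detection (features are computed
#'   on all channels).
#' @export
detection_params <- function(sigma = 3.5, threshold = 8, min_distance = 5,
                             make_regions = TRUE,
                             fg_method = c("halfmax", "otsu", "fixed"),
                             fg_threshold = NULL, smoothing_sigma = 1,
                             detect_channel = 1L) {
  fg_method <- match.arg(fg_method)
  if (sigma <= 0) stop("sigma must be positive")
  if (min_distance < 1) stop("min_distance must be at least 1")
  if (threshold < 0) stop("threshold must be non-negative")
  if (fg_method == "fixed" && is.null(fg_threshold))
    stop("fg_method = \"fixed\" requires fg_threshold")
  structure(list(sigma = sigma, threshold = threshold,
                 min_distance = min_distance, make_regions = make_regions,
                 fg_method = fg_method, fg_threshold = fg_threshold,
                 smoothing_sigma = smoothing_sigma,
                 detect_channel = as.integer(detect_channel)),
            class = "detection_params")
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- (-radius):radius
  g <- dnorm(x, sd = sigma)
  g / sum(g)
}

# 2D Gaussian smoothing with replicate boundary handling.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  radius <- min(ceiling(4 * sigma), floor((min(dim(x)) - 1) / 2))
  g <- gaussian_kernel_1d(sigma, radius)
  k <- outer(g, g)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

#' Scale-normalized negated Laplacian-of-Gaussian response
#'
#' Convolves a frame with `-sigma^2 * LoG(sigma)` so that bright blobs of
#' radius ~ `sigma * sqrt(2)` produce positive peaks whose height is
#' comparable across scales. The kernel is corrected to zero sum, so a
#' constant image gives an (numerically) all-zero response, and the
#' operator is linear in the input.
#'
#' @param frame 2D intensity matrix with finite entries.
#' @param sigma LoG scale in pixels.
#' @return a response matrix of the same size as `frame`.
#' @export
log_response <- function(frame, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!all(is.finite(frame))) stop("frame contains non-finite pixels")
  radius <- min(ceiling(4 * sigma), floor((min(dim(frame)) - 1) / 2))
  x <- (-radius):radius
  g <- dnorm(x, sd = sigma)
  g <- g / sum(g)
  # second derivative of the (discretely normalized) 1D Gaussian
  g2 <- g * (x^2 / sigma^4 - 1 / sigma^2)
  k <- -sigma^2 * (outer(g2, g) + outer(g, g2))
  k <- k - mean(k)  # exact zero sum: constant images map to zero
  as.matrix(EBImage::filter2(frame, k, boundary = "replicate"))
}

#' Detect spots as LoG response maxima
#'
#' Finds local maxima (3x3 neighborhood) of [log_response()] above
#' `threshold`, then greedily suppresses weaker maxima closer than
#' `min_distance` to an accepted one. The survivor order is descending
#' response; equal responses are broken lexicographically by (row, col)
#' so the result is reproducible across platforms. Peak positions are
#' refined to sub-pixel accuracy by a one-dimensional parabolic fit along
#' each axis.
#'
#' @param frame 2D intensity matrix.
#' @param params a [detection_params()] object.
#' @return a list of spot-only `roi` objects (square bbox of side
#'   `2*ceiling(2*sigma)+1`, no region), sorted by descending response.
#' @export
detect_spots <- function(frame, params = detection_params()) {
  resp <- log_response(frame, params$sigma)
  H <- nrow(resp); W <- ncol(resp)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- resp
  ismax <- resp > params$threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ismax <- ismax & (resp >= pad[(2 + dr):(H + 1 + dr),
                                  (2 + dc):(W + 1 + dc)])
  }
  cand <- which(ismax, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list())
  vals <- resp[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]

  keep <- logical(nrow(cand))
  acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0L ||
        min(sqrt((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2)) >=
          params$min_distance) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]

  side <- 2L * ceiling(2 * params$sigma) + 1L
  half <- (side - 1L) / 2
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    ctr <- c(r + parabolic_offset(pad[r:(r + 2), c + 1]),
             c + parabolic_offset(pad[r + 1, c:(c + 2)]))
    bb <- c(max(1, r - half), max(1, c - half),
            min(H, r + half), min(W, c + half))
    out[[i]] <- roi(roi_id = i, frame = 1L, centroid = ctr, bbox = bb,
                    features = list(response = vals[i]))
  }
  out
}

# Restrict a label's pixels to the 8-connected component containing the
# marker (flood fill on the label's own pixels).
keep_marker_component <- function(labels, lab, marker) {
  px <- which(labels == lab, arr.ind = TRUE)
  if (!nrow(px)) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  inlab <- matrix(FALSE, H, W)
  inlab[px] <- TRUE
  seen <- matrix(FALSE, H, W)
  if (!inlab[marker[1], marker[2]]) {
    # marker trimmed away (can happen on a flat, noisy basin): keep the
    # pixel nearest the marker as the component seed
    d <- (px[, 1] - marker[1])^2 + (px[, 2] - marker[2])^2
    marker <- px[which.min(d), ]
  }
  queue <- matrix(marker, ncol = 2)
  seen[marker[1], marker[2]] <- TRUE
  while (nrow(queue)) {
    p <- queue[nrow(queue), ]
    queue <- queue[-nrow(queue), , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      rr <- p[1] + dr; cc <- p[2] + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (inlab[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue <- rbind(queue, c(rr, cc))
      }
    }
  }
  labels[inlab & !seen] <- 0L
  labels
}

# sub-pixel peak offset from three samples (clamped to +-0.5)
parabolic_offset <- function(y3) {
  if (!all(is.finite(y3))) return(0)
  den <- y3[1] - 2 * y3[2] + y3[3]
  if (den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (y3[1] - y3[3]) / den))
}

#' Grow regions around spots by marker-controlled watershed
#'
#' Region formation for fluorescence imagery: the frame is smoothed, a
#' foreground is delimited (Otsu or fixed threshold), and the inverted
#' smoothed intensity is flooded starting from the spot centroids so that
#' each marker claims the basin around it. Regions are disjoint, restricted
#' to the foreground, and each contains its seeding spot. Spots whose
#' marker pixel falls on background produce no region and are reported in
#' the `background_markers` attribute.
#'
#' @param frame 2D intensity matrix.
#' @param spots list of `roi` objects whose centroids lie inside the frame.
#' @param params a [detection_params()] object.
#' @return a list with `masks` (a label matrix; label i = i-th spot) and
#'   `rois` (the input rois updated with their regions and geometry).
#' @export
segment_regions <- function(frame, spots, params = detection_params()) {
  H <- nrow(frame); W <- ncol(frame)
  sm <- gaussian_smooth(frame, params$smoothing_sigma)
  if (params$fg_method %in% c("otsu", "halfmax")) {
    rng <- range(sm)
    thr <- if (diff(rng) == 0) rng[2] else
      EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng))) *
        diff(rng) + rng[1]
  } else {
    thr <- params$fg_threshold
  }
  fg <- sm > thr

  markers <- matrix(0L, H, W)
  for (i in seq_along(spots)) {
    p <- round(spots[[i]]$centroid)
    if (p[1] < 1 || p[1] > H || p[2] < 1 || p[2] > W)
      stop(sprintf("spot %d lies outside the frame", i))
    markers[p[1], p[2]] <- i
  }
  labels <- marker_watershed_cpp(-sm, markers, fg)

  if (params$fg_method == "halfmax" && length(spots)) {
    # trim each basin to the FWHM contour of its own cell: pixels above
    # background + half the peak height, keeping the marker's component
    bg <- stats::median(sm)
    for (i in seq_along(spots)) {
      px <- which(labels == i, arr.ind = TRUE)
      if (!nrow(px)) next
      peak <- max(sm[px])
      cut <- bg + 0.5 * (peak - bg)
      drop <- px[sm[px] < cut, , drop = FALSE]
      if (nrow(drop)) labels[drop] <- 0L
      labels <- keep_marker_component(labels, i,
                                      round(spots[[i]]$centroid))
    }
  }

  bg_markers <- integer(0)
  rois <- spots
  for (i in seq_along(spots)) {
    px <- which(labels == i, arr.ind = TRUE)
    if (nrow(px) == 0L) {
      bg_markers <- c(bg_markers, i)
      next
    }
    r <- spots[[i]]
    r2 <- roi(roi_id = r$roi_id, frame = r$frame, region = px,
              features = r$features)
    rois[[i]] <- r2
  }
  structure(list(masks = labels, rois = rois),
            background_markers = bg_markers)
}

#' Quantify a region of interest
#'
#' Computes area (region pixel count, or bounding-box area for spot-only
#' rois), centroid, per-channel mean and integrated intensity, and
#' circularity `4*pi*A / P^2`. The perimeter `P` is the Freeman chain-code
#' estimate of the outer boundary (straight steps count 1, diagonal steps
#' `sqrt(2)`); on rasterized disks this estimator lands circularity near
#' 0.9, the expected bias of chain-code length on smooth contours.
#'
#' @param x a `roi`.
#' @param frame an `H x W` matrix or `H x W x C` array of intensities.
#' @return a named list of features.
#' @export
compute_features <- function(x, frame) {
  stopifnot(inherits(x, "roi"))
  if (is.matrix(frame)) frame <- array(frame, dim = c(dim(frame), 1L))
  if (is.null(x$region)) {
    bb <- round(x$bbox)
    px <- as.matrix(expand.grid(row = bb[1]:bb[3], col = bb[2]:bb[4]))
  } else {
    px <- x$region
  }
  if (nrow(px) == 0L) stop("empty region")
  feats <- list(area = nrow(px),
                centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  for (ch in seq_len(dim(frame)[3])) {
    v <- frame[cbind(px, ch)]
    feats[[paste0("mean_c", ch)]] <- mean(v)
    feats[[paste0("sum_c", ch)]] <- sum(v)
  }
  P <- chain_code_perimeter(px)
  feats$circularity <- 4 * pi * nrow(px) / max(P, 4)^2
  feats
}

# Outer-boundary length by Moore tracing with Freeman chain-code weights.
chain_code_perimeter <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(4)
  rmin <- min(px[, 1]); cmin <- min(px[, 2])
  H <- max(px[, 1]) - rmin + 3L
  W <- max(px[, 2]) - cmin + 3L
  m <- matrix(FALSE, H, W)
  m[cbind(px[, 1] - rmin + 2L, px[, 2] - cmin + 2L)] <- TRUE
  # start: topmost-leftmost pixel; trace clockwise around the component
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  # neighbor order (clockwise beginning east)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  cur <- start
  dir <- 7L  # enter scanning from the north-east
  P <- 0
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8L
      nr <- cur[1] + dr[d + 1L]; nc <- cur[2] + dc[d + 1L]
      if (m[nr, nc]) {
        P <- P + if (d %% 2L == 0L) 1 else sqrt(2)
        cur <- c(nr, nc)
        dir <- (d + 6L) %% 8L  # backtrack then continue clockwise
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel
    if (all(cur == start) && P > 0) break
    if (P > 8 * n) break   # safety: cannot trace (degenerate region)
  }
  P
}

# ---- detector plugin registry -------------------------------------------

.detector_registry <- new.env(parent = emptyenv())

#' Register a detector plugin
#'
#' A plugin is a function `(frame, params) -> list of roi` that can replace
#' the built-in recognition. The built-ins `"log_spots"` (spot-only LoG
#' detection), `"log_watershed"` (spots plus watershed regions) and
#' `"masks"` (wraps [rois_from_masks()] for externally produced label
#' images, e.g. a deep-learning segmenter run out of process; pass the
#' frame's label matrix as `params$mask`) are pre-registered.
#'
#' @param name plugin name.
#' @param fun function taking `(frame, params)` and returning a list of
#'   `roi` objects.
#' @export
register_detector <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .detector_registry)
  invisible(name)
}

#' List registered detector plugins
#' @export
detector_names <- function() sort(ls(.detector_registry))

#' Run a registered detector plugin on one frame
#'
#' Dispatches to the named plugin and checks its output against the `roi`
#' structural invariants; a violating plugin is reported by name.
#'
#' @param name registered plugin name.
#' @param frame 2D intensity matrix.
#' @param params parameter object passed through to the plugin.
#' @export
run_detector_plugin <- function(name, frame, params = detection_params()) {
  if (!exists(name, envir = .detector_registry, inherits = FALSE))
    stop(sprintf("no detector plugin registered under \"%s\"", name))
  fun <- get(name, envir = .detector_registry)
  out <- fun(frame, params)
  if (!is.list(out))
    stop(sprintf("plugin \"%s\" did not return a list of rois", name))
  for (r in out) {
    msgs <- validate_roi(r)
    if (length(msgs))
      stop(sprintf("plugin \"%s\" returned an invalid roi: %s",
                   name, paste(msgs, collapse = "; ")))
  }
  out
}

register_builtin_detectors <- function() {
  register_detector("log_spots", function(frame, params) {
    detect_spots(frame, params)
  })
  register_detector("log_watershed", function(frame, params) {
    spots <- detect_spots(frame, params)
    if (!length(spots)) return(spots)
    seg <- segment_regions(frame, spots, params)
    keep <- !seq_along(seg$rois) %in% attr(seg, "background_markers")
    seg$rois[keep]
  })
  register_detector("masks", function(frame, params) {
    if (is.null(params$mask)) stop("the masks plugin needs params$mask")
    rois_from_masks(list(params$mask))[[1]]
  })
}

#' Detect objects in every frame of a movie
#'
#' Runs the built-in recognition (or any registered plugin) frame by frame
#' on the configured detection channel. With `make_regions = TRUE` the
#' result also carries per-frame label masks.
#'
#' @param stack a `frame_stack`.
#' @param params a [detection_params()] object.
#' @param detector plugin name; default follows `params$make_regions`.
#' @return a list with `rois` (per-frame roi lists, ids reassigned
#'   1..n per frame) and `masks` (per-frame label matrices, or `NULL`
#'   for spot-only detection).
#' @export
detect_movie <- function(stack, params = detection_params(),
                         detector = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(detector))
    detector <- if (params$make_regions) "log_watershed" else "log_spots"
  rois <- vector("list", stack$n_frames)
  masks <- if (params$make_regions) vector("list", stack$n_frames) else NULL
  for (t in seq_len(stack$n_frames)) {
    frame <- get_frame(stack, t, params$detect_channel)
    rs <- run_detector_plugin(detector, frame, params)
    for (i in seq_along(rs)) {
      rs[[i]]$frame <- t
      rs[[i]]$roi_id <- i
      rs[[i]]$features <- compute_features(rs[[i]], stack$frames[[t]])
    }
    rois[[t]] <- rs
    if (!is.null(masks))
      masks[[t]] <- masks_from_rois(list(rs), c(stack$height, stack$width))[[1]]
  }
  list(rois = rois, masks = masks)
}
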