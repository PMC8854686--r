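#' Read a grayscale TIFF stack
#'
#' Accepts a multi-page TIFF or a directory of per-frame TIFFs
#' (lexicographic name order). 8/16-bit integer data are read as integer
#' intensities; 32-bit float data as stored. RGB/multi-sample TIFFs are
#' rejected explicitly rather than silently converted.
#'
#' @param path file or directory.
#' @return a `frame_stack`.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF files in directory")
    pages <- unlist(lapply(files, function(f)
      tiff::readTIFF(f, all = TRUE, as.is = TRUE)), recursive = FALSE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L)
      stop("multi-sample (RGB) TIFF is not supported; supply grayscale")
    p
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed shapes")
  frame_stack(frames)
}

#' Write a grayscale TIFF stack
#'
#' `bits = 16` stores integer intensities 0..65535 losslessly;
#' `bits = 32` stores float data in \[0, 1\].
#'
#' @param stack a `frame_stack` (channel 1 is written).
#' @param path output file (multi-page) .
#' @param bits 16 or 32.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "frame_stack"))
  mats <- lapply(seq_len(stack$n_frames), function(t) get_frame(stack, t))
  if (bits == 16L) {
    for (m in mats) {
      if (any(m != round(m)) || any(m < 0) || any(m > 65535))
        stop("16-bit output needs integer intensities in 0..65535")
    }
    mats <- lapply(mats, function(m) m / 65535)
  } else if (bits == 32L) {
    for (m in mats) if (any(m < 0) || any(m > 1))
      stop("32-bit float output needs intensities in [0, 1]")
  } else stop("bits must be 16 or 32")
  tiff::writeTIFF(mats, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Round a stack to integers for 16-bit storage
#' @param stack a `frame_stack`.
#' @export
quantize_stack <- function(stack) {
  frame_stack(lapply(seq_len(stack$n_frames), function(t)
    pmin(pmax(round(get_frame(stack, t)), 0), 65535)))
}

read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) stop("label TIFF must be single-channel")
  storage.mode(m) <- "integer"
  m
}

write_label_tiff <- function(m, path) {
  if (max(m) > 65535) stop("label overflow: more than 65535 labels")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
}

#' Write a lineage + masks in Cell Tracking Challenge layout
#'
#' One 16-bit labeled TIFF per frame (`mask%03d.tif`, or
#' `man_track%03d.tif` for ground truth; frame numbers 0-based) plus a
#' 4-column track table (`res_track.txt` / `man_track.txt`): label, begin
#' frame, end frame, parent label (0 = none). Mask labels must equal
#' track ids and stay stable across frames; a gap-closed track simply
#' lacks its label in the skipped frames.
#'
#' @param lin a `lineage` whose roi ids equal its track ids.
#' @param masks per-frame label matrices (labels = track ids).
#' @param dir output directory (created if needed).
#' @param gt write ground-truth file names instead of result names.
#' @param pad zero-padding width of frame numbers.
#' @export
write_ctc <- function(lin, masks, dir, gt = FALSE, pad = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- if (gt) "man_track" else "mask"
  for (t in seq_along(masks))
    write_label_tiff(masks[[t]],
                     file.path(dir, sprintf("%s%0*d.tif", prefix, pad,
                                            t - 1L)))
  tab <- summary(lin)
  tab$parent_id[is.na(tab$parent_id)] <- 0L
  tab <- tab[order(tab$track_id), ]
  lines <- sprintf("%d %d %d %d", tab$track_id, tab$begin - 1L,
                   tab$end - 1L, tab$parent_id)
  writeLines(lines, file.path(dir, if (gt) "man_track.txt"
                                   else "res_track.txt"))
  invisible(dir)
}

#' Read a Cell Tracking Challenge directory
#'
#' The exact inverse of [write_ctc()]: reconstructs the per-frame label
#' masks and the lineage. A track's nodes are the frames inside its
#' `[begin, end]` span where its label actually occurs, so gap-closed
#' tracks round-trip.
#'
#' @param dir directory holding the labeled TIFFs and the track table.
#' @return a list with `masks` and `lineage`.
#' @export
read_ctc <- function(dir) {
  txt <- file.path(dir, c("res_track.txt", "man_track.txt"))
  txt <- txt[file.exists(txt)][1]
  if (is.na(txt)) stop("no res_track.txt or man_track.txt in directory")
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(files)) stop("no mask TIFFs in directory")
  masks <- lapply(files, read_label_tiff)

  rows <- utils::read.table(txt, col.names = c("label", "begin", "end",
                                               "parent"))
  ids <- rows$label
  tracks <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    span <- (rows$begin[i] + 1L):(rows$end[i] + 1L)
    present <- span[vapply(span, function(t)
      any(masks[[t]] == rows$label[i]), logical(1))]
    if (!length(present))
      stop(sprintf("label %d never appears in its span", rows$label[i]))
    par <- rows$parent[i]
    if (par != 0L && !par %in% ids)
      stop(sprintf("track %d references missing parent %d",
                   rows$label[i], par))
    tracks[[i]] <- track(rows$label[i], present,
                         rep(rows$label[i], length(present)),
                         parent_id = if (par == 0L) NULL else par)
  }
  list(masks = masks, lineage = lineage(tracks))
}

#' Relabel per-frame masks so labels equal track ids
#'
#' Takes detection masks (labels = per-frame roi ids) plus the lineage
#' over them, and produces track-labeled masks suitable for
#' [write_ctc()] and the evaluation metrics, together with the matching
#' label-keyed lineage.
#'
#' @param lin a `lineage` over `(frame, roi_id)` nodes.
#' @param masks per-frame label matrices keyed by roi id.
#' @return list with relabelled `masks` and the label-keyed `lineage`.
#' @export
as_ctc_result <- function(lin, masks) {
  out <- lapply(masks, function(m) matrix(0L, nrow(m), ncol(m)))
  for (t in lin$tracks)
    for (k in seq_along(t$frames)) {
      f <- t$frames[k]
      out[[f]][masks[[f]] == t$roi_ids[k]] <- t$track_id
    }
  lin2 <- lineage(lapply(lin$tracks, function(t)
    track(t$track_id, t$frames, rep(t$track_id, length(t$frames)),
          parent_id = t$parent_id)))
  list(masks = out, lineage = lin2)
}

#' Write per-ROI and per-track CSV tables
#'
#' `rois.csv`: frame, track_id, roi_id, centroid (4 decimals, i.e.
#' 1e-4 px), bounding box and every feature column present (6
#' significant digits). `tracks.csv`: track_id, parent_id, begin, end,
#' length.
#'
#' @param lin a `lineage`.
#' @param rois_by_frame per-frame roi lists.
#' @param dir output directory.
#' @return the two file paths, invisibly.
#' @export
write_tables <- function(lin, rois_by_frame, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- roi_index(rois_by_frame)
  owner <- new.env(hash = TRUE, parent = emptyenv())
  for (t in lin$tracks)
    for (k in seq_along(t$frames))
      assign(paste(t$frames[k], t$roi_ids[k], sep = ":"), t$track_id,
             envir = owner)

  rows <- list()
  feat_names <- unique(unlist(lapply(rois_by_frame, function(rs)
    lapply(rs, function(r) names(r$features)))))
  # centroids and ids already have dedicated (higher-precision) columns
  feat_names <- setdiff(feat_names,
                        c("centroid_row", "centroid_col", "frame",
                          "track_id", "roi_id"))
  for (t in seq_along(rois_by_frame)) for (r in rois_by_frame[[t]]) {
    tid <- owner[[paste(t, r$roi_id, sep = ":")]]
    row <- data.frame(frame = t,
                      track_id = if (is.null(tid)) NA_integer_ else tid,
                      roi_id = r$roi_id,
                      centroid_row = round(r$centroid[1], 4),
                      centroid_col = round(r$centroid[2], 4),
                      bbox_rmin = r$bbox[1], bbox_cmin = r$bbox[2],
                      bbox_rmax = r$bbox[3], bbox_cmax = r$bbox[4])
    for (fn in feat_names) {
      v <- r$features[[fn]]
      row[[fn]] <- if (is.null(v)) NA_real_ else signif(as.numeric(v), 6)
    }
    rows[[length(rows) + 1L]] <- row
  }
  roi_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), track_id = integer(0),
               roi_id = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), bbox_rmin = numeric(0),
               bbox_cmin = numeric(0), bbox_rmax = numeric(0),
               bbox_cmax = numeric(0))
  roi_path <- file.path(dir, "rois.csv")
  write.csv(roi_df, roi_path, row.names = FALSE)

  tr_df <- summary(lin)
  tr_df$length <- tr_df$n_nodes
  tr_df$n_nodes <- NULL
  tr_path <- file.path(dir, "tracks.csv")
  write.csv(tr_df, tr_path, row.names = FALSE)
  invisible(c(roi_path, tr_path))
}

#' Read the per-ROI table back
#' @param path path to a `rois.csv` written by [write_tables()].
#' @export
read_roi_table <- function(path) read.csv(path)

# ---- run configuration ---------------------------------------------------

#' Default run configuration
#'
#' A flat-sectioned list mirroring the parameter objects of each stage;
#' this is what a YAML config file may override.
#' @export
default_config <- function() {
  list(
    detection = unclass(detection_params()),
    linking = unclass(link_params()),
    seqtrack = unclass(seqtrack_params()),
    weights = unclass(aogm_weights()),
    synthetic = unclass(synth_config()),
    rng_seed = 1L
  )
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected (they are almost always typos); known keys
#' override the defaults section-wise.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop(sprintf("unknown config section \"%s\"", sec))
    if (!is.list(user[[sec]])) {
      cfg[[sec]] <- user[[sec]]
      next
    }
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop(sprintf("unknown config key \"%s.%s\"", sec, key))
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

config_params <- function(cfg) {
  build <- function(fn, args)
    do.call(fn, args[!vapply(args, is.null, logical(1))])
  list(
    detection = build(detection_params, cfg$detection),
    linking = build(link_params, cfg$linking),
    seqtrack = build(seqtrack_params, cfg$seqtrack),
    weights = build(aogm_weights, cfg$weights),
    synthetic = build(synth_config, cfg$synthetic)
  )
}
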