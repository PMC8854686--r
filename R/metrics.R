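#' AOGM edit-operation weights
#'
#' Weights of the graph-edit operations that transform a tracking result
#' graph into the ground-truth graph: node split (`ns`), false-negative
#' node (`fn`), false-positive node (`fp`), redundant-edge deletion
#' (`ed`), missing-edge addition (`ea`) and edge-semantics change (`ec`,
#' a link edge where a parent edge belongs or vice versa). Defaults are
#' the published values used by the Cell Tracking Challenge evaluation.
#'
#' @param ns,fn,fp,ed,ea,ec non-negative weights.
#' @export
aogm_weights <- function(ns = 5, fn = 10, fp = 1, ed = 1, ea = 1.5, ec = 1) {
  w <- c(ns = ns, fn = fn, fp = fp, ed = ed, ea = ea, ec = ec)
  if (any(w < 0)) stop("weights must be non-negative")
  structure(as.list(w), class = "aogm_weights")
}

#' Match ground-truth objects to result objects in one frame
#'
#' A ground-truth object G is matched to the result object R that covers
#' strictly more than half of G's pixels; the strict-majority rule makes
#' the match unique (ties at exactly half are non-matches). Result objects
#' claiming more than one ground-truth object this way are node-split
#' contributors; result objects claiming none are false positives.
#'
#' @param gt_mask,res_mask integer label matrices of the same size.
#' @return a list with `gt` (data frame: `gt_label`, `size`, `res_label`
#'   or NA, `overlap`, `jaccard`) and `res` (data frame: `res_label`,
#'   `n_gt_matched`).
#' @export
match_objects <- function(gt_mask, res_mask) {
  if (!all(dim(gt_mask) == dim(res_mask)))
    stop("ground-truth and result masks must share dimensions")
  gt_labs <- sort(unique(gt_mask[gt_mask > 0]))
  res_labs <- sort(unique(res_mask[res_mask > 0]))
  n <- length(gt_labs)
  out <- data.frame(gt_label = gt_labs, size = rep(NA_integer_, n),
                    res_label = rep(NA_integer_, n),
                    overlap = rep(0L, n), jaccard = rep(0, n))
  res_sizes <- vapply(res_labs, function(l) sum(res_mask == l), integer(1))
  names(res_sizes) <- as.character(res_labs)
  for (i in seq_len(n)) {
    inG <- gt_mask == gt_labs[i]
    out$size[i] <- sum(inG)
    cover <- res_mask[inG]
    cover <- cover[cover > 0]
    if (!length(cover)) next
    tab <- table(cover)
    best <- which.max(tab)
    if (tab[best] * 2L > out$size[i]) {
      rl <- as.integer(names(tab)[best])
      out$res_label[i] <- rl
      out$overlap[i] <- as.integer(tab[best])
      un <- out$size[i] + res_sizes[[as.character(rl)]] - tab[best]
      out$jaccard[i] <- as.numeric(tab[best]) / un
    }
  }
  res_df <- data.frame(res_label = res_labs,
                       n_gt_matched = vapply(res_labs, function(l)
                         sum(out$res_label == l, na.rm = TRUE), integer(1)))
  list(gt = out, res = res_df)
}

#' SEG score
#'
#' Mean, over every ground-truth object in every frame, of the Jaccard
#' index with its matched result object (0 for unmatched objects).
#'
#' @param gt_masks,res_masks frame-aligned lists of label matrices.
#' @export
seg_score <- function(gt_masks, res_masks) {
  if (length(gt_masks) != length(res_masks))
    stop("mask stacks must have the same number of frames")
  js <- unlist(lapply(seq_along(gt_masks), function(t)
    match_objects(gt_masks[[t]], res_masks[[t]])$gt$jaccard))
  if (!length(js)) stop("SEG is undefined: no ground-truth objects")
  mean(js)
}

# Edge list of a tracking graph: one row per edge, endpoints are
# (frame, label) pairs, type "link" (within a track, including jumps over
# closed gaps) or "parent" (mother to daughter).
lineage_edges <- function(lin) {
  out <- list()
  for (t in lin$tracks) {
    n <- length(t$frames)
    if (n >= 2L) {
      out[[length(out) + 1L]] <- data.frame(
        f1 = t$frames[-n], l1 = t$roi_ids[-n],
        f2 = t$frames[-1], l2 = t$roi_ids[-1], type = "link")
    }
    if (!is.null(t$parent_id)) {
      p <- lin$tracks[[as.character(t$parent_id)]]
      if (!is.null(p) && length(p$frames)) {
        np <- length(p$frames)
        out[[length(out) + 1L]] <- data.frame(
          f1 = p$frames[np], l1 = p$roi_ids[np],
          f2 = t$frames[1], l2 = t$roi_ids[1], type = "parent")
      }
    }
  }
  if (!length(out))
    return(data.frame(f1 = integer(0), l1 = integer(0), f2 = integer(0),
                      l2 = integer(0), type = character(0)))
  do.call(rbind, out)
}

lineage_nodes <- function(lin) {
  out <- lapply(lin$tracks, function(t)
    data.frame(frame = t$frames, label = t$roi_ids))
  if (!length(out)) return(data.frame(frame = integer(0), label = integer(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' AOGM graph-edit cost between two tracking results
#'
#' Builds the ground-truth and result tracking graphs (a node is one
#' object in one frame, identified by its mask label; edges are track
#' links and parent links), matches nodes frame-wise with
#' [match_objects()], and counts the weighted edit operations needed to
#' turn the result graph into the ground-truth graph: node splits (NS),
#' false negatives (FN), false positives (FP), redundant edge deletions
#' (ED), missing edge additions (EA) and edge semantics changes (EC).
#'
#' @param gt,res lists with elements `masks` (per-frame label matrices,
#'   labels = track ids) and `lineage`.
#' @param weights an [aogm_weights()] object.
#' @return a list with `counts`, `cost`, the empty-graph baseline
#'   `aogm0`, and the node-only variants `cost_d` / `aogm_d0` behind DET.
#' @export
aogm <- function(gt, res, weights = aogm_weights()) {
  if (length(gt$masks) != length(res$masks))
    stop("ground truth and result must cover the same frames")
  TT <- length(gt$masks)

  # frame-wise node matching
  gt2res <- new.env(hash = TRUE, parent = emptyenv())
  counts <- c(ns = 0, fn = 0, fp = 0, ed = 0, ea = 0, ec = 0)
  n_gt_nodes <- 0L
  for (t in seq_len(TT)) {
    m <- match_objects(gt$masks[[t]], res$masks[[t]])
    n_gt_nodes <- n_gt_nodes + nrow(m$gt)
    counts["fn"] <- counts["fn"] + sum(is.na(m$gt$res_label))
    counts["fp"] <- counts["fp"] + sum(m$res$n_gt_matched == 0L)
    counts["ns"] <- counts["ns"] +
      sum(pmax(m$res$n_gt_matched - 1L, 0L))
    hit <- which(!is.na(m$gt$res_label))
    for (i in hit)
      assign(paste(t, m$gt$gt_label[i], sep = ":"),
             m$gt$res_label[i], envir = gt2res)
  }

  ge <- lineage_edges(gt$lineage)
  re <- lineage_edges(res$lineage)
  re_key <- paste(re$f1, re$l1, re$f2, re$l2, sep = ":")
  matched_res_edge <- rep(FALSE, nrow(re))

  for (i in seq_len(nrow(ge))) {
    a <- gt2res[[paste(ge$f1[i], ge$l1[i], sep = ":")]]
    b <- gt2res[[paste(ge$f2[i], ge$l2[i], sep = ":")]]
    if (is.null(a) || is.null(b)) {
      counts["ea"] <- counts["ea"] + 1
      next
    }
    pos <- match(paste(ge$f1[i], a, ge$f2[i], b, sep = ":"), re_key)
    if (!is.na(pos)) {
      matched_res_edge[pos] <- TRUE
      if (re$type[pos] != ge$type[i]) counts["ec"] <- counts["ec"] + 1
    } else {
      counts["ea"] <- counts["ea"] + 1
    }
  }
  counts["ed"] <- sum(!matched_res_edge)

  w <- unlist(weights)
  cost <- sum(w * counts[names(w)])
  aogm0 <- w[["fn"]] * n_gt_nodes + w[["ea"]] * nrow(ge)
  cost_d <- w[["ns"]] * counts[["ns"]] + w[["fn"]] * counts[["fn"]] +
    w[["fp"]] * counts[["fp"]]
  aogm_d0 <- w[["fn"]] * n_gt_nodes
  list(counts = counts, cost = unname(cost), aogm0 = unname(aogm0),
       cost_d = cost_d, aogm_d0 = aogm_d0,
       n_gt_nodes = n_gt_nodes, n_gt_edges = nrow(ge))
}

#' TRA score
#'
#' `1 - min(AOGM, AOGM0) / AOGM0`, where AOGM0 is the cost of building
#' the ground-truth graph from scratch (every node a false negative,
#' every edge missing). 1 means the result graph is identical to the
#' ground truth under the matching; 0 means it contributes nothing.
#'
#' @inheritParams aogm
#' @export
tra_score <- function(gt, res, weights = aogm_weights()) {
  a <- aogm(gt, res, weights)
  if (a$aogm0 == 0) stop("TRA is undefined: empty ground truth")
  1 - min(a$cost, a$aogm0) / a$aogm0
}

#' DET score
#'
#' The node-only counterpart of [tra_score()]: edge operations are
#' ignored, so DET isolates detection quality from linking quality.
#'
#' @inheritParams aogm
#' @export
det_score <- function(gt, res, weights = aogm_weights()) {
  a <- aogm(gt, res, weights)
  if (a$aogm_d0 == 0) stop("DET is undefined: empty ground truth")
  1 - min(a$cost_d, a$aogm_d0) / a$aogm_d0
}

#' Evaluate a tracking result against ground truth
#'
#' Computes SEG, DET and TRA plus the edit-operation counts behind the
#' graph scores.
#'
#' @param gt,res lists with `masks` (per-frame label matrices, labels =
#'   track ids) and `lineage`, e.g. as returned by [read_ctc()].
#' @param weights an [aogm_weights()] object.
#' @return an object of class `metrics_report`.
#' @export
evaluate_tracking <- function(gt, res, weights = aogm_weights()) {
  a <- aogm(gt, res, weights)
  seg <- seg_score(gt$masks, res$masks)
  det <- if (a$aogm_d0 > 0) 1 - min(a$cost_d, a$aogm_d0) / a$aogm_d0
         else stop("DET is undefined: empty ground truth")
  tra <- if (a$aogm0 > 0) 1 - min(a$cost, a$aogm0) / a$aogm0
         else stop("TRA is undefined: empty ground truth")
  structure(list(seg = seg, det = det, tra = tra, counts = a$counts,
                 aogm = a$cost, aogm0 = a$aogm0,
                 n_gt_nodes = a$n_gt_nodes, n_gt_edges = a$n_gt_edges),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SEG %.4f  DET %.4f  TRA %.4f\n", x$seg, x$det, x$tra))
  cat(sprintf("  AOGM %.2f / empty-graph baseline %.2f (%d nodes, %d edges)\n",
              x$aogm, x$aogm0, x$n_gt_nodes, x$n_gt_edges))
  cat("  operations:",
      paste(sprintf("%s=%g", toupper(names(x$counts)), x$counts),
            collapse = " "), "\n")
  invisible(x)
}
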