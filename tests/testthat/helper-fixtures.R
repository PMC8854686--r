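# Fixture builders shared across the test files. Everything is built in
# code, deterministically.

# paint an axis-aligned square of side `size` with `label`
sq <- function(m, r0, c0, size, label) {
  m[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- as.integer(label)
  m
}

blank <- function(H = 24, W = 24) matrix(0L, H, W)

disk_mask <- function(H, W, center, radius, label = 1L) {
  m <- matrix(0L, H, W)
  d2 <- outer((1:H - center[1])^2, (1:W - center[2])^2, "+")
  m[d2 <= radius^2] <- as.integer(label)
  m
}

gauss_frame <- function(H, W, centers, amp = 100, sigma = 3, bg = 0) {
  f <- matrix(bg, H, W)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((1:H - centers[k, 1])^2, (1:W - centers[k, 2])^2, "+")
    f <- f + amp * exp(-d2 / (2 * sigma^2))
  }
  f
}

# brute-force minimum assignment cost over all permutations
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

brute_lap <- function(M) {
  n <- nrow(M)
  best <- Inf
  best_p <- NULL
  for (p in perms(n)) {
    v <- sum(M[cbind(seq_len(n), p)])
    if (v < best) { best <- v; best_p <- p }
  }
  list(cost = best, perm = best_p)
}

# two-cell movie on a small field, deterministic (no noise) -- handy for
# linking tests whose expected chains are known by construction
drifting_rois <- function(n_cells, n_frames, start, step, spread = 12) {
  lapply(seq_len(n_frames), function(t) {
    lapply(seq_len(n_cells), function(i) {
      ctr <- start + (i - 1) * c(0, spread) + (t - 1) * step
      roi(i, t, centroid = ctr,
          bbox = c(ctr[1] - 2, ctr[2] - 2, ctr[1] + 2, ctr[2] + 2))
    })
  })
}

# ---- metrics parity fixtures --------------------------------------------
# Small hand-built ground-truth/result pairs covering the error taxonomy.
# The frozen reference scores in metrics_reference.json were produced by
# an independently written evaluator run once on the CTC export of these
# exact fixtures.

fx_perfect <- function() {
  gtm <- lapply(0:2, function(k)
    sq(sq(blank(), 3, 3 + 2 * k, 4, 1), 15 + 2 * k, 15, 4, 2))
  resm <- lapply(gtm, function(m) {
    m2 <- m
    m2[m == 1L] <- 5L
    m2[m == 2L] <- 9L
    m2
  })
  gt <- list(masks = gtm, lineage = lineage(list(
    track(1, 1:3, rep(1, 3)), track(2, 1:3, rep(2, 3)))))
  res <- list(masks = resm, lineage = lineage(list(
    track(5, 1:3, rep(5, 3)), track(9, 1:3, rep(9, 3)))))
  list(gt = gt, res = res)
}

fx_broken_link <- function() {
  fx <- fx_perfect()
  res <- fx$res
  # cut track 5 after frame 2: tail becomes track 11
  m3 <- res$masks[[3]]
  m3[m3 == 5L] <- 11L
  res$masks[[3]] <- m3
  res$lineage <- lineage(list(
    track(5, 1:2, rep(5, 2)), track(11, 3, 11), track(9, 1:3, rep(9, 3))))
  list(gt = fx$gt, res = res)
}

fx_missing_cell <- function() {
  fx <- fx_perfect()
  res <- fx$res
  res$masks <- lapply(res$masks, function(m) { m[m == 9L] <- 0L; m })
  res$lineage <- lineage(list(track(5, 1:3, rep(5, 3))))
  list(gt = fx$gt, res = res)
}

fx_missed_division <- function() {
  # mother (frames 1-2) divides into daughters at frame 3; the result
  # follows one daughter as a continuation and leaves the other orphaned
  gtm <- list(
    sq(blank(), 10, 10, 4, 1),
    sq(blank(), 10, 10, 4, 1),
    sq(sq(blank(), 5, 5, 4, 2), 16, 16, 4, 3),
    sq(sq(blank(), 5, 5, 4, 2), 16, 16, 4, 3))
  gt <- list(masks = gtm, lineage = lineage(list(
    track(1, 1:2, rep(1, 2)),
    track(2, 3:4, rep(2, 2), parent_id = 1),
    track(3, 3:4, rep(3, 2), parent_id = 1))))
  resm <- list(
    sq(blank(), 10, 10, 4, 1),
    sq(blank(), 10, 10, 4, 1),
    sq(sq(blank(), 5, 5, 4, 1), 16, 16, 4, 7),
    sq(sq(blank(), 5, 5, 4, 1), 16, 16, 4, 7))
  res <- list(masks = resm, lineage = lineage(list(
    track(1, 1:4, rep(1, 4)),
    track(7, 3:4, rep(7, 2)))))
  list(gt = gt, res = res)
}

fx_overseg <- function() {
  gtm <- list(sq(blank(), 8, 8, 8, 1), sq(blank(), 8, 8, 8, 1))
  gt <- list(masks = gtm, lineage = lineage(list(
    track(1, 1:2, rep(1, 2)))))
  m1 <- sq(blank(), 8, 8, 8, 1)
  m1[8:15, 13:15] <- 4L  # right third recognized as a second object
  res <- list(masks = list(m1, gtm[[2]]),
              lineage = lineage(list(track(1, 1:2, rep(1, 2)),
                                     track(4, 1, 4))))
  list(gt = gt, res = res)
}

fx_spurious <- function() {
  gtm <- lapply(0:2, function(k) sq(blank(), 3, 3 + 2 * k, 4, 1))
  gt <- list(masks = gtm, lineage = lineage(list(
    track(1, 1:3, rep(1, 3)))))
  resm <- lapply(gtm, function(m) sq(m, 17, 17, 3, 6))
  res <- list(masks = resm, lineage = lineage(list(
    track(1, 1:3, rep(1, 3)), track(6, 1:3, rep(6, 3)))))
  list(gt = gt, res = res)
}

fx_merged <- function() {
  gtm <- lapply(1:2, function(k)
    sq(sq(blank(), 8, 6, 4, 1), 8, 11, 4, 2))
  gt <- list(masks = gtm, lineage = lineage(list(
    track(1, 1:2, rep(1, 2)), track(2, 1:2, rep(2, 2)))))
  resm <- lapply(1:2, function(k) sq(blank(), 8, 6, 4, 9) |>
                   sq(8, 11, 4, 9))
  res <- list(masks = resm, lineage = lineage(list(
    track(9, 1:2, rep(9, 2)))))
  list(gt = gt, res = res)
}

metrics_parity_fixtures <- function() {
  list(perfect = fx_perfect(),
       broken_link = fx_broken_link(),
       missing_cell = fx_missing_cell(),
       missed_division = fx_missed_division(),
       overseg = fx_overseg(),
       spurious = fx_spurious(),
       merged = fx_merged())
}
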