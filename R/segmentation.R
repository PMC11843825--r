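# Homogeneity-based wound segmentation: partition the masked wound area into
# connected segments homogeneous in the 8 secondary-parameter channels.
# A fine deterministic over-segmentation (grid blocks split into 4-connected
# components) is greedily merged: at each step the adjacent pair with the
# lowest merged within-region SD (max over channels) is merged while that
# score stays below the homogeneity threshold tau. Undersized regions are
# then absorbed into their most similar neighbor. The result is an exact
# partition of the mask.

# 4-connected components of a logical mask, labeled in row-major discovery
# order (deterministic).
connectedComponents <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1L], d[2L])
  nxt <- 0L
  idx <- which(mask)          # column-major order, deterministic
  for (s in idx) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- (p - 1L) %% d[1L] + 1L
      c <- (p - 1L) %/% d[1L] + 1L
      for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (nb[1L] < 1L || nb[1L] > d[1L] || nb[2L] < 1L || nb[2L] > d[2L]) next
        q <- (nb[2L] - 1L) * d[1L] + nb[1L]
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Homogeneity score of a pixel set
#'
#' The maximum over parameter channels of the within-set population standard
#' deviation; 0 for constant maps.
#'
#' @param pixels logical matrix selecting pixels, or integer vector of linear
#'   (column-major) pixel indices into the image plane.
#' @param maps H x W x C parameter array.
#' @return scalar score >= 0.
#' @export
homogeneity <- function(pixels, maps) {
  d <- dim(maps)
  idx <- if (is.matrix(pixels) && is.logical(pixels)) which(pixels) else as.integer(pixels)
  if (!length(idx)) stopDegenerate("empty pixel set")
  plane <- d[1L] * d[2L]
  vals <- vapply(seq_len(d[3L]), function(ch) {
    x <- maps[idx + (ch - 1L) * plane]
    m <- mean(x)
    sqrt(max(0, mean(x * x) - m * m))
  }, 1.0)
  max(vals)
}

# merged population SD (max channel) from sufficient statistics
.mergedScore <- function(n, s, ss) {
  m <- s / n
  max(sqrt(pmax(0, ss / n - m * m)))
}

#' Segment a wound into parameter-homogeneous regions
#'
#' @param maps H x W x C secondary-parameter array ([paramMaps()]).
#' @param mask logical matrix of wound pixels.
#' @param tau homogeneity threshold: every accepted segment has max-channel
#'   within-segment SD <= tau.
#' @param min_area minimum segment size in pixels; smaller regions are merged
#'   into the most similar 4-adjacent neighbor.
#' @param block side length (pixels) of the initial over-segmentation blocks.
#' @param pixel_pitch pixel pitch in mm (default 0.5 mm), used for areas.
#' @return list with \code{labels} (integer matrix, 0 = background) and
#'   \code{segments} (data.frame: segment_id, n_pixels, area_cm2,
#'   homogeneity, and per-channel means).
#' @export
segmentWound <- function(maps, mask, tau = 0.06, min_area = 8L, block = 4L,
                         pixel_pitch = 0.5) {
  d <- dim(maps)
  if (!identical(dim(mask), d[1:2])) stopDegenerate("maps and mask shapes differ")
  if (!any(mask)) stopDegenerate("empty mask")
  nC <- d[3L]
  plane <- d[1L] * d[2L]

  # initial over-segmentation: grid blocks intersected with the mask, split
  # into connected components
  lab <- matrix(0L, d[1L], d[2L])
  nxt <- 0L
  br <- ceiling(d[1L] / block); bc <- ceiling(d[2L] / block)
  for (bj in seq_len(bc)) for (bi in seq_len(br)) {
    rows <- ((bi - 1L) * block + 1L):min(bi * block, d[1L])
    cols <- ((bj - 1L) * block + 1L):min(bj * block, d[2L])
    sub <- matrix(FALSE, d[1L], d[2L]); sub[rows, cols] <- mask[rows, cols]
    if (!any(sub)) next
    cc <- connectedComponents(sub)
    k <- max(cc)
    lab[cc > 0L] <- cc[cc > 0L] + nxt
    nxt <- nxt + k
  }

  # sufficient statistics per region
  stats_n <- integer(nxt)
  stats_s <- matrix(0, nxt, nC)
  stats_ss <- matrix(0, nxt, nC)
  idxAll <- which(mask)
  for (ch in seq_len(nC)) {
    x <- maps[idxAll + (ch - 1L) * plane]
    l <- lab[idxAll]
    stats_s[, ch] <- as.numeric(rowsum(x, l)[, 1L])
    stats_ss[, ch] <- as.numeric(rowsum(x * x, l)[, 1L])
  }
  stats_n <- as.integer(table(factor(lab[idxAll], levels = seq_len(nxt))))

  # adjacency of regions under 4-connectivity
  adj <- new.env(parent = emptyenv(), hash = TRUE)
  addEdge <- function(a, b) {
    if (a == b) return(invisible())
    key <- paste0(min(a, b), "_", max(a, b))
    assign(key, TRUE, envir = adj)
  }
  for (s in idxAll) {
    r <- (s - 1L) %% d[1L] + 1L; c <- (s - 1L) %/% d[1L] + 1L
    if (r < d[1L] && mask[s + 1L]) addEdge(lab[s], lab[s + 1L])
    if (c < d[2L] && mask[s + d[1L]]) addEdge(lab[s], lab[s + d[1L]])
  }
  alive <- rep(TRUE, nxt)
  parent <- seq_len(nxt)          # for relabeling at the end

  pairKeys <- function() ls(envir = adj)
  pairScore <- function(key) {
    ab <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
    .mergedScore(stats_n[ab[1L]] + stats_n[ab[2L]],
                 stats_s[ab[1L], ] + stats_s[ab[2L], ],
                 stats_ss[ab[1L], ] + stats_ss[ab[2L], ])
  }

  mergeInto <- function(a, b) {
    # merge b into a (a < b); update stats and adjacency
    stats_n[a] <<- stats_n[a] + stats_n[b]
    stats_s[a, ] <<- stats_s[a, ] + stats_s[b, ]
    stats_ss[a, ] <<- stats_ss[a, ] + stats_ss[b, ]
    alive[b] <<- FALSE
    parent[parent == b] <<- a
    # rewire edges of b to a
    for (key in pairKeys()) {
      ab <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
      if (b %in% ab) {
        other <- setdiff(ab, b)
        rm(list = key, envir = adj)
        if (length(other) && other != a) addEdge(a, other)
      }
    }
  }

  # greedy merging: lowest merged score first, ties by lowest region ids
  repeat {
    keys <- pairKeys()
    if (!length(keys)) break
    scores <- vapply(keys, pairScore, 1.0)
    ord <- order(scores,
                 vapply(keys, function(k) as.integer(strsplit(k, "_", fixed = TRUE)[[1L]][1L]), 1L),
                 vapply(keys, function(k) as.integer(strsplit(k, "_", fixed = TRUE)[[1L]][2L]), 1L))
    bestKey <- keys[ord[1L]]
    if (scores[ord[1L]] > tau) break
    ab <- as.integer(strsplit(bestKey, "_", fixed = TRUE)[[1L]])
    rm(list = bestKey, envir = adj)
    mergeInto(ab[1L], ab[2L])
  }

  # absorb undersized regions into the most similar neighbor
  repeat {
    small <- which(alive & stats_n < min_area)
    if (!length(small)) break
    merged_any <- FALSE
    for (b in small) {
      if (!alive[b]) next
      keys <- pairKeys()
      nbrs <- integer()
      for (key in keys) {
        ab <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
        if (b %in% ab) nbrs <- c(nbrs, setdiff(ab, b))
      }
      nbrs <- sort(unique(nbrs))
      if (!length(nbrs)) next     # isolated mask island smaller than min_area
      mb <- stats_s[b, ] / stats_n[b]
      dist <- vapply(nbrs, function(a) sqrt(sum((stats_s[a, ] / stats_n[a] - mb)^2)), 1.0)
      a <- nbrs[order(dist, nbrs)[1L]]
      key <- paste0(min(a, b), "_", max(a, b))
      if (exists(key, envir = adj)) rm(list = key, envir = adj)
      mergeInto(min(a, b), max(a, b))
      merged_any <- TRUE
    }
    if (!merged_any) break
  }

  # compact relabeling (1..K in order of original ids) and summaries
  finalIds <- which(alive)
  relab <- integer(nxt)
  relab[finalIds] <- seq_along(finalIds)
  labels <- matrix(0L, d[1L], d[2L])
  labels[idxAll] <- relab[parent[lab[idxAll]]]

  segs <- lapply(seq_along(finalIds), function(k) {
    idx <- idxAll[labels[idxAll] == k]
    means <- vapply(seq_len(nC), function(ch) mean(maps[idx + (ch - 1L) * plane]), 1.0)
    chn <- dimnames(maps)[[3L]]
    if (is.null(chn)) chn <- paste0("ch", seq_len(nC))
    row <- data.frame(segment_id = k, n_pixels = length(idx),
                      area_cm2 = length(idx) * (pixel_pitch / 10)^2,
                      homogeneity = homogeneity(idx, maps))
    row[chn] <- as.list(means)
    row
  })
  list(labels = labels, segments = do.call(rbind, segs))
}

#' Masked box smoothing of parameter maps
#'
#' Mean filter over the (2r+1) x (2r+1) neighborhood restricted to masked
#' pixels; unmasked pixels stay NA. Used to suppress per-pixel inversion
#' noise before segmentation.
#'
#' @param maps H x W x C array.
#' @param mask logical matrix.
#' @param radius neighborhood radius r (default 1).
#' @return smoothed array of the same shape.
#' @export
smoothMaps <- function(maps, mask, radius = 1L) {
  d <- dim(maps)
  out <- array(NA_real_, d, dimnames = dimnames(maps))
  H <- d[1L]; W <- d[2L]
  off <- -radius:radius
  for (ch in seq_len(d[3L])) {
    x <- maps[, , ch]
    x[!mask] <- 0
    m <- mask * 1
    acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
    for (di in off) for (dj in off) {
      ri <- max(1, 1 + di):min(H, H + di)
      si <- max(1, 1 - di):min(H, H - di)
      rj <- max(1, 1 + dj):min(W, W + dj)
      sj <- max(1, 1 - dj):min(W, W - dj)
      acc[ri, rj] <- acc[ri, rj] + x[si, sj]
      cnt[ri, rj] <- cnt[ri, rj] + m[si, sj]
    }
    sm <- ifelse(cnt > 0, acc / cnt, NA_real_)
    sm[!mask] <- NA_real_
    out[, , ch] <- sm
  }
  out
}

#' Check that a segment covers a single reference class
#'
#' TRUE iff at least \code{tol} of the segment's pixels share one label in
#' the reference label map.
#'
#' @param pixels logical matrix or linear pixel indices of the segment.
#' @param labels_map integer/character matrix of reference labels.
#' @param tol majority tolerance (default 0.95).
#' @return logical flag.
#' @export
singleClassCheck <- function(pixels, labels_map, tol = 0.95) {
  idx <- if (is.matrix(pixels) && is.logical(pixels)) which(pixels) else as.integer(pixels)
  if (!length(idx)) stopDegenerate("empty pixel set")
  tabu <- table(labels_map[idx])
  max(tabu) / length(idx) >= tol
}
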