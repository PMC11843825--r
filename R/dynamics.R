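# Per-class, per-day distribution analysis in the two parameter spaces:
# Gaussian kernel densities on the unit square, highest-density kernel
# regions, convex-hull abstraction, directional overlap of class regions,
# and per-segment trajectories across days.

#' Gaussian kernel density on the unit square
#'
#' Separable Gaussian KDE evaluated on an n x n grid of cell centers over
#' [0,1]^2, renormalized after boundary truncation so that
#' sum(density) * cell_area = 1.
#'
#' @param points numeric matrix (m x 2) of (x, y) in the unit square.
#' @param bandwidth scalar or length-2 bandwidth(s); \code{NULL} uses
#'   Silverman's rule per axis with a floor of \code{bw_floor}.
#' @param n grid resolution per axis (default 200).
#' @param bw_floor lower bound on the bandwidth (default 0.02).
#' @return list: \code{x}, \code{y} cell-center coordinates, \code{z} n x n
#'   density matrix (rows = x cells, cols = y cells), \code{cell_area},
#'   \code{bandwidth}.
#' @export
kdeGrid <- function(points, bandwidth = NULL, n = 200L, bw_floor = 0.02) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 5L) stopDegenerate("kernel density needs at least 5 points")
  if (is.null(bandwidth)) {
    bandwidth <- vapply(1:2, function(j) {
      1.06 * stats::sd(points[, j]) * m^(-1 / 5)
    }, 1.0)
  }
  bandwidth <- rep_len(bandwidth, 2L)
  bandwidth <- pmax(bandwidth, bw_floor)
  if (any(bandwidth <= 0)) stopDegenerate("bandwidth must be > 0")
  step <- 1 / n
  ctr <- seq(step / 2, 1 - step / 2, length.out = n)
  Dx <- stats::dnorm(outer(ctr, points[, 1L], "-") / bandwidth[1L]) # n x m
  Dy <- stats::dnorm(outer(ctr, points[, 2L], "-") / bandwidth[2L])
  z <- (Dx %*% t(Dy)) / (m * bandwidth[1L] * bandwidth[2L])
  cell_area <- step * step
  tot <- sum(z) * cell_area
  if (tot <= 0) stopDegenerate("degenerate density")
  z <- z / tot
  list(x = ctr, y = ctr, z = z, cell_area = cell_area, bandwidth = bandwidth)
}

#' Highest-density kernel region of a density grid
#'
#' The smallest set of highest-density cells whose accumulated mass reaches
#' the requested fraction; ties in density are broken by grid (column-major)
#' order.
#'
#' @param density a grid as returned by [kdeGrid()].
#' @param mass target mass fraction in (0, 1).
#' @return integer matrix (k x 2) of (x-index, y-index) cell coordinates.
#' @export
kernelRegion <- function(density, mass = 0.68) {
  if (mass <= 0 || mass >= 1) stopDegenerate("mass must be in (0, 1)")
  z <- as.numeric(density$z)
  ord <- order(-z, seq_along(z))   # density desc, ties by grid order
  cum <- cumsum(z[ord]) * density$cell_area
  k <- which(cum >= mass)[1L]
  if (is.na(k)) k <- length(ord)
  sel <- ord[seq_len(k)]
  n <- nrow(density$z)
  cbind(ix = (sel - 1L) %% n + 1L, iy = (sel - 1L) %/% n + 1L)
}

# orientation of the triple (o, a, b): >0 counter-clockwise
.orient <- function(o, a, b) {
  (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
}

#' Convex hull of a point set
#'
#' Andrew's monotone-chain hull. Vertices are returned counter-clockwise
#' starting from the lowest-then-leftmost point; collinear boundary points
#' are dropped.
#'
#' @param points numeric matrix (m x 2).
#' @return matrix of hull vertices (k x 2), counter-clockwise.
#' @export
convexHull <- function(points) {
  pts <- unique(as.matrix(points))
  if (nrow(pts) < 3L) stopDegenerate("convex hull needs >= 3 distinct points")
  ord <- order(pts[, 1L], pts[, 2L])
  pts <- pts[ord, , drop = FALSE]
  build <- function(seq_idx) {
    h <- integer(0)
    for (i in seq_idx) {
      while (length(h) >= 2L &&
             .orient(pts[h[length(h) - 1L], ], pts[h[length(h)], ], pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(nrow(pts)))
  upper <- build(rev(seq_len(nrow(pts))))
  hidx <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hidx) < 3L) stopDegenerate("degenerate hull: all points collinear")
  hull <- pts[hidx, , drop = FALSE]
  # rotate to start at lowest-then-leftmost vertex
  start <- order(hull[, 2L], hull[, 1L])[1L]
  hull <- hull[c(start:nrow(hull), seq_len(start - 1L))[seq_len(nrow(hull))], , drop = FALSE]
  dimnames(hull) <- list(NULL, c("x", "y"))
  hull
}

# Sutherland-Hodgman clip of polygon subj by convex polygon clip (both CCW)
clipConvex <- function(subj, clip) {
  out <- subj
  nC <- nrow(clip)
  for (i in seq_len(nC)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nC) 1L else i + 1L, ]
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    nI <- nrow(inp)
    for (j in seq_len(nI)) {
      p <- inp[j, ]; q <- inp[if (j == nI) 1L else j + 1L, ]
      pin <- .orient(a, b, p) >= -1e-12
      qin <- .orient(a, b, q) >= -1e-12
      if (pin) out <- rbind(out, p)
      if (pin != qin) {
        # intersection of segment pq with line ab
        d1 <- .orient(a, b, p); d2 <- .orient(a, b, q)
        t <- d1 / (d1 - d2)
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

#' Directional overlap of two class regions
#'
#' \code{area(a intersect b) / area(a)} by exact convex-polygon clipping.
#' Asymmetric: it measures how much of region \code{a} is covered by
#' \code{b}. A symmetric intersection-over-union variant is available via
#' \code{method = "iou"}.
#'
#' @param a,b [ClassRegion-class] objects (or plain CCW vertex matrices).
#' @param method "directional" (default) or "iou".
#' @return overlap fraction in [0, 1].
#' @export
regionOverlap <- function(a, b, method = c("directional", "iou")) {
  method <- match.arg(method)
  pa <- if (is(a, "ClassRegion")) a@hull else as.matrix(a)
  pb <- if (is(b, "ClassRegion")) b@hull else as.matrix(b)
  inter <- clipConvex(pa, pb)
  ai <- if (nrow(inter) >= 3L) abs(polygonArea(inter)) else 0
  aa <- abs(polygonArea(pa)); ab <- abs(polygonArea(pb))
  if (method == "directional") {
    if (aa <= 0) return(0)
    min(1, ai / aa)
  } else {
    u <- aa + ab - ai
    if (u <= 0) return(0)
    min(1, ai / u)
  }
}

#' Per-class kernel regions abstracted to convex hulls
#'
#' For each class present on the given day: KDE of its points, the
#' highest-density region capturing \code{mass}, and the convex hull of the
#' selected cell centers.
#'
#' @param tab data.frame with columns \code{class, day, x, y} (points in one
#'   parameter space).
#' @param day day to analyze.
#' @param space "PS1" or "PS2" (recorded in the output).
#' @param mass kernel-region mass fraction (default 0.68).
#' @param n KDE grid resolution.
#' @param bandwidth optional fixed bandwidth, else Silverman per class.
#' @param min_points minimum points per class (default 5); classes below it
#'   are omitted with a warning.
#' @return named list of [ClassRegion-class], one per qualifying class.
#' @export
classRegions <- function(tab, day, space = "PS2", mass = 0.68, n = 200L,
                         bandwidth = NULL, min_points = 5L) {
  sub <- tab[tab$day == day, , drop = FALSE]
  out <- list()
  min_points <- max(min_points, 5L)   # the KDE needs at least 5 points
  for (cl in burnClasses()) {
    pts <- as.matrix(sub[sub$class == cl, c("x", "y"), drop = FALSE])
    if (nrow(pts) < min_points) {
      if (nrow(pts) > 0L) {
        warning(sprintf("class %s on day %d has %d < %d points; region omitted",
                        cl, day, nrow(pts), min_points))
      }
      next
    }
    dens <- kdeGrid(clamp01(pts), bandwidth = bandwidth, n = n)
    cells <- kernelRegion(dens, mass)
    centers <- cbind(dens$x[cells[, 1L]], dens$y[cells[, 2L]])
    hull <- convexHull(centers)
    out[[cl]] <- new("ClassRegion", burnClass = cl, day = as.integer(day),
                     space = space, hull = clamp01(hull), mass = mass)
  }
  out
}

#' Pairwise overlap matrix of class regions
#'
#' @param regions named list of [ClassRegion-class] for one day and space.
#' @return list: \code{matrix} (directional overlaps, diagonal 1) and
#'   \code{summary} (mean off-diagonal overlap).
#' @export
discriminationTable <- function(regions) {
  cls <- names(regions)
  k <- length(cls)
  m <- matrix(NA_real_, k, k, dimnames = list(cls, cls))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- if (i == j) 1 else regionOverlap(regions[[i]], regions[[j]])
  }
  off <- m[row(m) != col(m)]
  list(matrix = m, summary = if (length(off)) mean(off) else NA_real_)
}

#' Per-segment trajectories across days
#'
#' One trajectory per segment observed on at least two days; points are the
#' per-day segment-mean coordinates in the chosen space.
#'
#' @param tab data.frame with columns \code{segment_id, class, day, x, y}.
#' @return list of trajectories: each has \code{segment_id}, \code{class},
#'   and a data.frame \code{path} (day, x, y, ordered by day).
#' @export
segmentTrajectories <- function(tab) {
  out <- list()
  for (sid in unique(tab$segment_id)) {
    sub <- tab[tab$segment_id == sid, , drop = FALSE]
    agg <- stats::aggregate(sub[c("x", "y")], by = list(day = sub$day), FUN = mean)
    if (nrow(agg) < 2L) next
    agg <- agg[order(agg$day), , drop = FALSE]
    out[[length(out) + 1L]] <- list(segment_id = sid, class = sub$class[1L],
                                    path = agg)
  }
  out
}

#' Serialize / read class regions as GeoJSON-style polygon records
#'
#' @param regions list of [ClassRegion-class].
#' @param path JSON file path.
#' @export
writeRegionsJson <- function(regions, path) {
  recs <- lapply(regions, function(r) {
    list(class = r@burnClass, day = r@day, space = r@space, mass = r@mass,
         vertices = unname(apply(r@hull, 1L, function(v) c(v[1L], v[2L]),
                                 simplify = FALSE)))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRegionsJson
#' @export
readRegionsJson <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    hull <- do.call(rbind, lapply(r$vertices, function(v) as.numeric(unlist(v))))
    dimnames(hull) <- list(NULL, c("x", "y"))
    new("ClassRegion", burnClass = r$class, day = as.integer(r$day),
        space = r$space, hull = hull, mass = as.numeric(r$mass))
  })
  names(out) <- vapply(out, function(r) r@burnClass, "")
  out
}

setMethod("show", "ClassRegion", function(object) {
  cat(sprintf("ClassRegion %s day %d %s: %d hull vertices, area %.4f, mass %.2f\n",
              object@burnClass, object@day, object@space, nrow(object@hull),
              abs(polygonArea(object@hull)), object@mass))
})

#' Plot class regions and points in a parameter space
#'
#' Scatter of points colored by class with convex-hull overlays (the style of
#' the per-day parameter-space figures).
#'
#' @param regions list of [ClassRegion-class].
#' @param points optional data.frame \code{class, x, y}.
#' @param main plot title.
#' @export
plotClassRegions <- function(regions, points = NULL, main = "") {
  pal <- c("2a" = "blue", "2b1" = "green3", "2b2" = "gold", "3" = "red")
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "x", ylab = "y", main = main)
  if (!is.null(points)) {
    graphics::points(points$x, points$y, col = pal[points$class], pch = 16,
                     cex = 0.5)
  }
  for (r in regions) {
    h <- rbind(r@hull, r@hull[1L, ])
    graphics::lines(h[, 1L], h[, 2L], col = pal[r@burnClass], lwd = 2)
  }
  graphics::legend("topleft", legend = names(pal), col = pal, lwd = 2, cex = 0.7)
}
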