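# shared model objects (loading the packaged table once keeps the suite fast)
.lib <- loadChromophores()
.model <- defaultLayerModel()

# group-structured random profile: the bar-profile structure used throughout
randGroupProfile <- function() {
  perfusionProfile(rep(stats::runif(3, 0.05, 0.8), each = 2),
                   rep(stats::runif(3, 0.2, 0.9), each = 2))
}

# add seeded gaussian noise to a spectrum, clamped to [0, 1]
noisySpectrum <- function(sp, sd, z = NULL) {
  if (is.null(z)) z <- stats::rnorm(length(sp@remission))
  new("RemissionSpectrum", wavelengths = sp@wavelengths,
      remission = pmin(1, pmax(0, sp@remission + sd * z)))
}

# O(n^3) supporting-line convex hull oracle: a point pair (i, j) is a hull
# edge iff every other point lies strictly on one side (or on the segment).
bruteHullVertices <- function(pts) {
  n <- nrow(pts)
  onHull <- rep(FALSE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- 0L; edge <- TRUE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
            (pts[j, 2] - pts[i, 2]) * (pts[k, 1] - pts[i, 1])
      if (abs(cr) < 1e-12) next
      if (s == 0L) s <- sign(cr)
      else if (sign(cr) != s) { edge <- FALSE; break }
    }
    if (edge) onHull[c(i, j)] <- TRUE
  }
  pts[onHull, , drop = FALSE]
}

# point-in-convex-polygon (CCW hull), boundary inclusive
inHull <- function(p, hull, eps = 1e-9) {
  n <- nrow(hull)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    if ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) < -eps) {
      return(FALSE)
    }
  }
  TRUE
}

# axis-aligned rectangle as a CCW polygon
rectPoly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
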