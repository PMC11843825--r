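test_that("kernel density normalizes to unit mass on the unit square", {
  set.seed(61)
  pts <- cbind(runif(50, 0.2, 0.8), runif(50, 0.2, 0.8))
  d <- kdeGrid(pts, n = 100)
  expect_equal(sum(d$z) * d$cell_area, 1, tolerance = 1e-6)
  expect_true(all(d$z >= 0))
  expect_error(kdeGrid(pts[1:3, ]), "at least 5")
})

test_that("coincident points concentrate mass at their cell", {
  pts <- matrix(rep(c(0.3, 0.7), each = 6), ncol = 2)
  d <- kdeGrid(pts, bandwidth = 0.02, n = 50)
  peak <- which(d$z == max(d$z), arr.ind = TRUE)
  expect_lt(abs(d$x[peak[1, 1]] - 0.3), 0.011)
  expect_lt(abs(d$y[peak[1, 2]] - 0.7), 0.011)
})

test_that("a wide-bandwidth density of a uniform sample is nearly flat", {
  set.seed(71)
  pts <- cbind(runif(1e4), runif(1e4))
  d <- kdeGrid(pts, bandwidth = 1, n = 50)
  expect_lt(max(d$z) / min(d$z), 2)
})

test_that("highest-density region follows the greedy-by-density rule", {
  # hand-built density grids make the greedy oracle exact
  mk <- function(z) {
    n <- nrow(z)
    z <- z / (sum(z) * (1 / n)^2)
    list(x = seq(0.5 / n, 1 - 0.5 / n, length.out = n), y = NULL, z = z,
         cell_area = (1 / n)^2)
  }
  z <- matrix(0, 4, 4); z[2, 2] <- 4; z[2, 3] <- 2; z[3, 2] <- 1; z[1, 1] <- 1
  d <- mk(z)
  # masses: cell(2,2)=0.5, (2,3)=0.25, (3,2)=0.125, (1,1)=0.125
  r <- kernelRegion(d, mass = 0.5)
  expect_equal(nrow(r), 1L)
  expect_equal(unname(r[1, ]), c(2L, 2L))
  r2 <- kernelRegion(d, mass = 0.7)
  expect_equal(nrow(r2), 2L)
  # ties (the two 0.125 cells) break by column-major grid order
  r3 <- kernelRegion(d, mass = 0.8)
  expect_equal(nrow(r3), 3L)
  expect_equal(unname(r3[3, ]), c(1L, 1L))  # linear index 1 precedes (3,2) = 7

  # mass near 1 selects all cells carrying density
  r4 <- kernelRegion(d, mass = 0.999)
  expect_equal(nrow(r4), 4L)

  # single-peak Gaussian: the half-mass region is a connected block
  set.seed(81)
  pts <- cbind(rnorm(500, 0.5, 0.05), rnorm(500, 0.5, 0.05))
  dg <- kdeGrid(pts, n = 40)
  cells <- kernelRegion(dg, 0.5)
  expect_true(all(abs(dg$x[cells[, 1]] - 0.5) < 0.2))
  # connectivity: every selected cell has a 4-neighbor in the set
  if (nrow(cells) > 1) {
    key <- paste(cells[, 1], cells[, 2])
    nb <- vapply(seq_len(nrow(cells)), function(i) {
      any(paste(cells[i, 1] + c(-1, 1, 0, 0),
                cells[i, 2] + c(0, 0, -1, 1)) %in% key)
    }, TRUE)
    expect_true(all(nb))
  }

  # two equal peaks split the region between both
  z2 <- matrix(0, 6, 6); z2[2, 2] <- 3; z2[5, 5] <- 3; z2[2, 3] <- 1; z2[5, 4] <- 1
  d2 <- mk(z2)
  r5 <- kernelRegion(d2, mass = 0.4)
  expect_true(all(c("2 2", "5 5") %in% paste(r5[, 1], r5[, 2])))
})

test_that("convex hull matches the brute-force supporting-line oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convexHull(sq)
  expect_equal(nrow(h), 4L)
  expect_equal(h[1, ], c(x = 0, y = 0))          # lowest-then-leftmost start
  expect_gt(polygonArea(h), 0)                   # counter-clockwise
  expect_equal(abs(polygonArea(h)), 1)

  set.seed(91)
  for (k in 1:5) {
    pts <- cbind(runif(20), runif(20))
    h <- convexHull(pts)
    brute <- bruteHullVertices(pts)
    expect_equal(nrow(h), nrow(brute))
    ord <- order(h[, 1], h[, 2]); ordb <- order(brute[, 1], brute[, 2])
    expect_equal(unname(h[ord, , drop = FALSE]),
                 unname(brute[ordb, , drop = FALSE]))
    # every input point lies inside or on the hull
    expect_true(all(apply(pts, 1, inHull, hull = h)))
  }

  expect_error(convexHull(rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(convexHull(rbind(c(0, 0), c(0.5, 0.5), c(1, 1))), "collinear")
})

test_that("region overlap is exact for analytic rectangle cases", {
  a <- rectPoly(0, 0, 0.5, 1)            # left half of the unit square
  b <- rectPoly(0.25, 0, 0.75, 1)
  expect_equal(regionOverlap(a, b), 0.5)
  expect_equal(regionOverlap(b, a), 0.5)
  expect_equal(regionOverlap(a, a), 1)
  expect_equal(regionOverlap(a, rectPoly(0.6, 0, 0.9, 1)), 0)
  # asymmetry: a small region inside a big one
  small <- rectPoly(0.1, 0.1, 0.2, 0.2)
  big <- rectPoly(0, 0, 1, 1)
  expect_equal(regionOverlap(small, big), 1)
  expect_equal(regionOverlap(big, small), 0.01)
  expect_equal(regionOverlap(a, b, method = "iou"), 0.25 / 0.75)
})

test_that("class regions contain their kernel cells and track separation", {
  set.seed(101)
  mkpts <- function(mx, my, n = 60) {
    data.frame(x = pmin(1, pmax(0, rnorm(n, mx, 0.05))), y = pmin(1, pmax(0, rnorm(n, my, 0.05))))
  }
  tab <- rbind(cbind(class = "2a", day = 0, mkpts(0.2, 0.2)),
               cbind(class = "3", day = 0, mkpts(0.8, 0.8)))
  regs <- classRegions(tab, day = 0, space = "PS2", n = 100)
  expect_named(regs, c("2a", "3"))
  expect_equal(regionOverlap(regs[["2a"]], regs[["3"]]), 0)  # disjoint clouds

  # hull containment: every kernel-region cell center is inside its hull
  dens <- kdeGrid(as.matrix(mkpts(0.2, 0.2)[c("x", "y")]), n = 100)
  cells <- kernelRegion(dens, 0.68)
  hull <- convexHull(cbind(dens$x[cells[, 1]], dens$y[cells[, 2]]))
  centers <- cbind(dens$x[cells[, 1]], dens$y[cells[, 2]])
  expect_true(all(apply(centers, 1, inHull, hull = hull)))

  # identical clouds for two classes give near-identical hulls
  set.seed(55); pa <- mkpts(0.5, 0.5)
  set.seed(55); pb <- mkpts(0.5, 0.5)
  tab2 <- rbind(cbind(class = "2b1", day = 1, pa),
                cbind(class = "2b2", day = 1, pb))
  regs2 <- classRegions(tab2, day = 1, space = "PS2", n = 100)
  h1 <- regs2[["2b1"]]@hull; h2 <- regs2[["2b2"]]@hull
  haus <- max(apply(h1, 1, function(p) min(sqrt(colSums((t(h2) - p)^2)))))
  expect_lt(haus, 2 / 100 * 2)

  # under-populated classes are omitted with a warning
  tab3 <- rbind(tab, data.frame(class = "2b1", day = 0,
                                x = runif(3), y = runif(3)))
  expect_warning(r3 <- classRegions(tab3, 0, "PS2", n = 50), "omitted")
  expect_named(r3, c("2a", "3"))
})

test_that("discrimination summary is 1 for identical and 0 for disjoint regions", {
  mkreg <- function(cl, poly) new("ClassRegion", burnClass = cl, day = 0L,
                                  space = "PS2", hull = poly, mass = 0.68)
  same <- list(`2a` = mkreg("2a", rectPoly(0.1, 0.1, 0.4, 0.4)),
               `2b1` = mkreg("2b1", rectPoly(0.1, 0.1, 0.4, 0.4)))
  expect_equal(discriminationTable(same)$summary, 1)
  disj <- list(`2a` = mkreg("2a", rectPoly(0, 0, 0.2, 0.2)),
               `2b1` = mkreg("2b1", rectPoly(0.5, 0.5, 0.8, 0.8)))
  dt <- discriminationTable(disj)
  expect_equal(dt$summary, 0)
  expect_equal(unname(diag(dt$matrix)), c(1, 1))
})

test_that("trajectories require at least two observed days", {
  tab <- data.frame(segment_id = c(rep("s1", 4), "s2"),
                    class = "2b1", day = c(0:3, 2),
                    x = c(0.2, 0.3, 0.4, 0.5, 0.9), y = c(0.1, 0.2, 0.3, 0.4, 0.9))
  tr <- segmentTrajectories(tab)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$path), 4L)
  expect_equal(tr[[1]]$path$day, 0:3)
})

test_that("class regions serialize to JSON and back unchanged", {
  reg <- new("ClassRegion", burnClass = "2b1", day = 2L, space = "PS2",
             hull = rectPoly(0.2, 0.1, 0.6, 0.5), mass = 0.68)
  p <- withr::local_tempfile(fileext = ".json")
  writeRegionsJson(list(`2b1` = reg), p)
  rt <- readRegionsJson(p)
  expect_equal(rt[["2b1"]]@hull, reg@hull, ignore_attr = TRUE)
  expect_equal(rt[["2b1"]]@day, 2L)
  expect_equal(rt[["2b1"]]@burnClass, "2b1")
})
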