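chans <- c("v1", "x1", "v2", "x2", "v3", "flow1", "flow2", "xRate")

constMaps <- function(H, W, vals) {
  array(rep(vals, each = H * W), c(H, W, 8L), dimnames = list(NULL, NULL, chans))
}

test_that("homogeneity equals the max-channel within-set SD", {
  maps <- constMaps(6, 6, rep(0.3, 8))
  expect_equal(homogeneity(matrix(TRUE, 6, 6), maps), 0)

  # two-point case: values a and a+d in one channel give d/2
  maps[1, 1, 3] <- 0.3 + 0.2
  expect_equal(homogeneity(c(1L, 2L), maps), 0.1)

  # random region against an independent per-channel SD recomputation
  set.seed(5)
  rmaps <- array(runif(6 * 6 * 8), c(6, 6, 8))
  idx <- sample(36, 12)
  manual <- max(vapply(1:8, function(ch) {
    x <- rmaps[, , ch][idx]
    sqrt(mean((x - mean(x))^2))
  }, 1.0))
  expect_equal(homogeneity(idx, rmaps), manual)

  expect_error(homogeneity(integer(0), rmaps), "empty")
})

test_that("constant maps yield a single segment covering the mask", {
  fx <- referenceScenarios()$uniform_wound
  seg <- segmentWound(fx$maps, fx$mask, tau = 0.06)
  expect_equal(max(seg$labels), 1L)
  expect_true(all(seg$labels[fx$mask] == 1L))
  expect_equal(seg$segments$n_pixels, sum(fx$mask))
  expect_equal(seg$segments$homogeneity, 0)
})

test_that("a two-class wound splits exactly at the fixture boundary", {
  fx <- referenceScenarios()$two_class_wound
  seg <- segmentWound(fx$maps, fx$mask, tau = 0.06)
  expect_equal(max(seg$labels), 2L)
  # boundary recovery: each detected segment matches one truth region exactly
  for (k in 1:2) {
    truth_k <- fx$truth[seg$labels == k]
    expect_equal(length(unique(truth_k)), 1L)
  }
  expect_equal(table(seg$labels[fx$mask]), table(fx$truth[fx$mask]),
               ignore_attr = TRUE)
})

test_that("noise below the merge threshold does not split a uniform wound", {
  fx <- referenceScenarios()$uniform_wound
  set.seed(13)
  tau <- 0.06
  noisy <- fx$maps + array(rnorm(length(fx$maps), 0, tau / 10),
                           dim(fx$maps))
  seg <- segmentWound(noisy, fx$mask, tau = tau)
  expect_equal(max(seg$labels), 1L)
})

test_that("every masked pixel belongs to exactly one segment", {
  set.seed(21)
  maps <- constMaps(16, 16, rep(0.4, 8)) +
    array(rnorm(16 * 16 * 8, 0, 0.05), c(16, 16, 8))
  mask <- matrix(FALSE, 16, 16); mask[3:14, 2:15] <- TRUE
  mask[5, 5] <- FALSE
  seg <- segmentWound(maps, mask, tau = 0.04, min_area = 4)
  expect_true(all(seg$labels[mask] > 0L))
  expect_true(all(seg$labels[!mask] == 0L))
  expect_equal(sum(seg$segments$n_pixels), sum(mask))
})

test_that("raising the homogeneity threshold never increases the segment count", {
  set.seed(31)
  maps <- constMaps(20, 20, rep(0.3, 8))
  maps[, 11:20, ] <- constMaps(20, 10, rep(0.55, 8))
  maps <- maps + array(rnorm(20 * 20 * 8, 0, 0.02), c(20, 20, 8))
  mask <- matrix(TRUE, 20, 20)
  counts <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.5), function(tau) {
    max(segmentWound(maps, mask, tau = tau)$labels)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is reproducible", {
  set.seed(41)
  maps <- constMaps(12, 12, rep(0.4, 8)) +
    array(rnorm(12 * 12 * 8, 0, 0.05), c(12, 12, 8))
  mask <- matrix(TRUE, 12, 12)
  s1 <- segmentWound(maps, mask, tau = 0.05)
  s2 <- segmentWound(maps, mask, tau = 0.05)
  expect_identical(s1$labels, s2$labels)
})

test_that("degenerate segmentation inputs error", {
  maps <- constMaps(4, 4, rep(0.4, 8))
  expect_error(segmentWound(maps, matrix(FALSE, 4, 4)), "empty mask")
  expect_error(segmentWound(maps, matrix(TRUE, 5, 5)), "shapes differ")
})

test_that("single-class check applies the majority tolerance", {
  labels <- matrix(1L, 10, 10)
  expect_true(singleClassCheck(matrix(TRUE, 10, 10), labels))
  labels[, 6:10] <- 2L
  expect_false(singleClassCheck(matrix(TRUE, 10, 10), labels))  # 50/50
  labels96 <- matrix(1L, 10, 10); labels96[1, 1:4] <- 2L
  expect_true(singleClassCheck(matrix(TRUE, 10, 10), labels96)) # 96/4
  expect_false(singleClassCheck(matrix(TRUE, 10, 10), labels96, tol = 0.99))
})

test_that("masked smoothing reduces noise without moving the mean", {
  set.seed(51)
  mask <- matrix(TRUE, 12, 12)
  maps <- constMaps(12, 12, rep(0.5, 8)) +
    array(rnorm(12 * 12 * 8, 0, 0.1), c(12, 12, 8))
  sm <- smoothMaps(maps, mask, radius = 1)
  expect_lt(sd(sm[, , 1][mask]), sd(maps[, , 1][mask]))
  expect_equal(mean(sm[, , 1][mask]), mean(maps[, , 1][mask]), tolerance = 0.02)
  mask[1, 1] <- FALSE
  sm2 <- smoothMaps(maps, mask, radius = 1)
  expect_true(is.na(sm2[1, 1, 1]))
})
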