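mkreg <- function(cl, poly) new("ClassRegion", burnClass = cl, day = 0L,
                                space = "PS2", hull = poly, mass = 0.68)

test_that("membership drives the estimate; severity breaks overlaps", {
  regs <- list(`2a` = mkreg("2a", rectPoly(0.0, 0.0, 0.4, 0.4)),
               `2b1` = mkreg("2b1", rectPoly(0.3, 0.3, 0.7, 0.7)),
               `2b2` = mkreg("2b2", rectPoly(0.75, 0.75, 0.95, 0.95)))
  # single membership
  est <- classifyPoint(c(0.1, 0.1), regs)
  expect_equal(est$class, "2a")
  expect_equal(est$ambiguous, "2a")
  expect_true(est$confidence > 0 && est$confidence <= 1)
  # overlap of 2a and 2b1: most severe contained class wins
  est2 <- classifyPoint(c(0.35, 0.35), regs)
  expect_equal(est2$class, "2b1")
  expect_setequal(est2$ambiguous, c("2a", "2b1"))
  expect_lt(est2$confidence, est$confidence + 1e-12)
  # the estimate is always a member of a non-empty ambiguous set
  expect_true(est2$class %in% est2$ambiguous)
})

test_that("points outside all hulls fall back to the nearest centroid", {
  regs <- list(`2a` = mkreg("2a", rectPoly(0.0, 0.0, 0.2, 0.2)),
               `3` = mkreg("3", rectPoly(0.8, 0.8, 1.0, 1.0)))
  est <- classifyPoint(c(0.65, 0.65), regs)
  expect_equal(est$class, "3")          # nearer to (0.9, 0.9) than (0.1, 0.1)
  expect_equal(est$confidence, 0)
  expect_length(est$ambiguous, 0L)
  expect_error(classifyPoint(c(0.5, 0.5), list()), "no class regions")
})

test_that("PS1 membership narrows ambiguous PS2 membership", {
  regs2 <- list(`2a` = mkreg("2a", rectPoly(0.0, 0.0, 0.5, 0.5)),
                `2b1` = mkreg("2b1", rectPoly(0.0, 0.0, 0.5, 0.5)))
  regs1 <- list(`2a` = mkreg("2a", rectPoly(0.0, 0.0, 0.3, 0.3)),
                `2b1` = mkreg("2b1", rectPoly(0.6, 0.6, 0.9, 0.9)))
  # PS2 is ambiguous; the PS1 point sits only in the 2a region
  est <- classifyPoint(c(0.25, 0.25), regs2, ps1_point = c(0.1, 0.1),
                       regions_ps1 = regs1)
  expect_equal(est$class, "2a")
  expect_setequal(est$ambiguous, c("2a", "2b1"))
  # without the tie-breaker, severity-first picks 2b1
  est2 <- classifyPoint(c(0.25, 0.25), regs2)
  expect_equal(est2$class, "2b1")
})

test_that("per-day evaluation: confusion counts, accuracy, recall conservation", {
  ref <- data.frame(segment_id = paste0("s", 1:8),
                    class = rep(burnClasses(), each = 2))
  perfect <- data.frame(segment_id = ref$segment_id, day = 0,
                        estimated_class = ref$class)
  ev <- evaluateDay(perfect, ref, 0)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(diag(ev$confusion)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(unname(ev$recall), rep(1, 4), ignore_attr = TRUE)

  all2a <- data.frame(segment_id = ref$segment_id, day = 0,
                      estimated_class = "2a")
  ev2 <- evaluateDay(all2a, ref, 0)
  expect_equal(ev2$accuracy, 0.25)
  # row sums equal the reference class counts
  expect_equal(unname(rowSums(ev2$confusion)), rep(2L, 4), ignore_attr = TRUE)

  expect_error(evaluateDay(data.frame(segment_id = "zz", day = 0,
                                      estimated_class = "2a"), ref, 0),
               "no matched")
})

test_that("leave-one-wound-out never trains on the held-out wound", {
  set.seed(111)
  # two well-separated classes; one contaminated wound whose own points
  # would (if leaked into training) shift its regions
  mk <- function(w, cl, mx, my, n = 6) {
    data.frame(segment_id = paste0(w, "_", seq_len(n)), wound_id = w,
               class = cl, day = 0,
               v1 = runif(n, 0.4, 0.6), xRate = runif(n, 0.4, 0.6),
               v2 = pmin(1, pmax(0, rnorm(n, mx, 0.03))),
               flow2 = pmin(1, pmax(0, rnorm(n, my, 0.03))))
  }
  segs <- rbind(mk("w1", "2a", 0.7, 0.7), mk("w2", "2a", 0.7, 0.7),
                mk("w3", "3", 0.15, 0.1), mk("w4", "3", 0.15, 0.1))
  est <- classifyCohortLOWO(segs, days = 0, use_ps1 = FALSE, n = 80)
  ref <- unique(segs[c("segment_id", "class")])
  ev <- evaluateDay(est, ref, 0)
  expect_gte(ev$accuracy, 0.9)
  expect_equal(nrow(est), nrow(segs))
})
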