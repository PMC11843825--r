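# Preliminary per-day burn-class estimation: membership of a segment's
# parameter-space point in the day's convex class regions. Deep perfusion
# (PS2) is primary; superficial perfusion (PS1) narrows ambiguous cases.
# Inside overlapping hulls the most severe contained class wins
# (severity-first: clinically conservative, since missing a deep burn is the
# costlier error). Points outside all hulls fall back to the nearest hull by
# centroid distance with confidence 0.

pointInConvex <- function(p, hull, eps = 1e-12) {
  n <- nrow(hull)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    if (.orient(a, b, p) < -eps) return(FALSE)
  }
  TRUE
}

hullCentroid <- function(hull) colMeans(hull)

#' Classify one parameter-space point against day-specific class regions
#'
#' @param ps2_point numeric(2) point in PS2 (primary evidence).
#' @param regions_ps2 named list of [ClassRegion-class] for the day in PS2.
#' @param ps1_point optional numeric(2) point in PS1 (tie-breaker).
#' @param regions_ps1 optional named list of PS1 regions.
#' @return list: \code{class}, \code{confidence} in [0, 1], \code{ambiguous}
#'   (classes whose PS2 regions contain the point; the estimate is a member
#'   whenever this set is non-empty).
#' @export
classifyPoint <- function(ps2_point, regions_ps2, ps1_point = NULL,
                          regions_ps1 = NULL) {
  if (!length(regions_ps2)) stopDegenerate("no class regions for this day")
  contains2 <- names(regions_ps2)[vapply(regions_ps2, function(r) {
    pointInConvex(ps2_point, r@hull)
  }, TRUE)]
  sev <- function(cls) match(cls, burnClasses())
  regionConfidence <- function(cl) {
    others <- regions_ps2[setdiff(names(regions_ps2), cl)]
    ov <- vapply(others, function(o) regionOverlap(regions_ps2[[cl]], o), 1.0)
    max(0, 1 - sum(ov))
  }
  if (length(contains2) == 0L) {
    d <- vapply(regions_ps2, function(r) {
      sqrt(sum((hullCentroid(r@hull) - ps2_point)^2))
    }, 1.0)
    nearest <- names(regions_ps2)[order(d, vapply(names(regions_ps2), sev, 1L))[1L]]
    return(list(class = nearest, confidence = 0, ambiguous = character(0)))
  }
  if (length(contains2) == 1L) {
    return(list(class = contains2, confidence = regionConfidence(contains2),
                ambiguous = contains2))
  }
  pick_from <- contains2
  if (!is.null(ps1_point) && length(regions_ps1)) {
    contains1 <- names(regions_ps1)[vapply(regions_ps1, function(r) {
      pointInConvex(ps1_point, r@hull)
    }, TRUE)]
    both <- intersect(contains2, contains1)
    if (length(both)) pick_from <- both
  }
  est <- pick_from[which.max(vapply(pick_from, sev, 1L))]
  conf <- regionConfidence(est) / length(contains2)
  list(class = est, confidence = conf, ambiguous = contains2)
}

#' Evaluate estimated classes against reference labels for one day
#'
#' @param estimates data.frame with columns \code{segment_id, day,
#'   estimated_class}.
#' @param reference data.frame with columns \code{segment_id, class}.
#' @param day day to evaluate.
#' @return list: \code{confusion} (4 x 4, rows = reference), \code{accuracy},
#'   \code{recall} (per reference class), \code{n}.
#' @export
evaluateDay <- function(estimates, reference, day) {
  est <- estimates[estimates$day == day, , drop = FALSE]
  m <- merge(est, reference[c("segment_id", "class")], by = "segment_id")
  if (!nrow(m)) stopDegenerate("no matched segment ids between estimates and reference")
  lv <- burnClasses()
  conf <- table(factor(m$class, levels = lv),
                factor(m$estimated_class, levels = lv))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("reference", "estimated")
  acc <- sum(diag(conf)) / sum(conf)
  rs <- rowSums(conf)
  recall <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
  list(confusion = conf, accuracy = acc, recall = recall, n = nrow(m))
}

#' Leave-one-wound-out per-day classification of a segment table
#'
#' For each wound, class regions are built from all other wounds' segments of
#' the same day (in both spaces) and the held-out wound's segments are
#' classified, so no segment contributes to the regions it is tested
#' against.
#'
#' @param segments data.frame with columns \code{segment_id, wound_id, class,
#'   day, v1, xRate, v2, flow2} (one row per segment-day).
#' @param days days to classify (default 0:3).
#' @param mass,n,bandwidth region-construction settings (see
#'   [classRegions()]).
#' @param use_ps1 use PS1 membership as tie-breaker (default TRUE).
#' @return data.frame: segment_id, wound_id, day, estimated_class,
#'   confidence, ambiguous_set.
#' @export
classifyCohortLOWO <- function(segments, days = 0:3, mass = 0.68, n = 200L,
                               bandwidth = NULL, use_ps1 = TRUE) {
  out <- list()
  for (d in days) {
    sub <- segments[segments$day == d, , drop = FALSE]
    for (w in sort(unique(sub$wound_id))) {
      train <- sub[sub$wound_id != w, , drop = FALSE]
      test <- sub[sub$wound_id == w, , drop = FALSE]
      if (!nrow(test) || !nrow(train)) next
      r2 <- classRegions(data.frame(class = train$class, day = d,
                                    x = train$v2, y = train$flow2),
                         day = d, space = "PS2", mass = mass, n = n,
                         bandwidth = bandwidth)
      r1 <- if (use_ps1) {
        classRegions(data.frame(class = train$class, day = d,
                                x = train$v1, y = train$xRate),
                     day = d, space = "PS1", mass = mass, n = n,
                     bandwidth = bandwidth)
      } else NULL
      for (i in seq_len(nrow(test))) {
        est <- classifyPoint(c(test$v2[i], test$flow2[i]), r2,
                             if (use_ps1) c(test$v1[i], test$xRate[i]),
                             r1)
        out[[length(out) + 1L]] <- data.frame(
          segment_id = test$segment_id[i], wound_id = w, day = d,
          estimated_class = est$class, confidence = est$confidence,
          ambiguous_set = paste(est$ambiguous, collapse = "|"))
      }
    }
  }
  do.call(rbind, out)
}
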