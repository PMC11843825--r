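# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: 4 burn classes x days 0-3 with class/day-specific mean
# 6-layer perfusion profiles and between-segment spread, wound/segment
# geometry at a fixed pixel pitch, optional rendered remission cubes with
# spectral noise, and healing records consistent with each class. All
# generative means/SDs/drifts are synthetic calibration constants (one
# versioned packaged table); they encode the qualitative class dynamics
# (hyperemic up-right drift of 2a/2b1 in deep perfusion, limited 2b2 drift
# with an upper-layer vHb peak, declining class 3, day-0 compactness), not
# measured values.

.calibEnv <- new.env(parent = emptyenv())

#' The synthetic calibration table
#'
#' Per (class, day): mean 6-layer profile and between-segment SD.
#'
#' @return data.frame with columns class, day, vHb_1..6, xHbO2_1..6, sd.
#' @export
syntheticCalibration <- function() {
  if (is.null(.calibEnv$tab)) {
    path <- system.file("extdata", "synthetic_calibration.csv", package = "burndyn")
    .calibEnv$tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                                     colClasses = c(class = "character"))
  }
  .calibEnv$tab
}

#' Draw a perfusion profile for a class and day
#'
#' Samples the 6-layer profile from the class/day Gaussian of the synthetic
#' calibration (truncated to [0, 1]). Uses the current RNG state; seed the
#' RNG (or use [generateCohort()]) for reproducibility.
#'
#' @param class burn class label.
#' @param day day 0-3.
#' @param sd_scale multiplier on the calibrated between-segment SD (0 gives
#'   the mean profile).
#' @return a [PerfusionProfile-class].
#' @export
sampleProfile <- function(class, day, sd_scale = 1) {
  cal <- syntheticCalibration()
  row <- cal[cal$class == class & cal$day == day, , drop = FALSE]
  if (nrow(row) != 1L) stopDegenerate(paste("no calibration for", class, "day", day))
  s <- row$sd * sd_scale
  v <- clamp01(as.numeric(row[paste0("vHb_", 1:6)]) + stats::rnorm(6L, 0, s))
  x <- clamp01(as.numeric(row[paste0("xHbO2_", 1:6)]) + stats::rnorm(6L, 0, s))
  perfusionProfile(v, x)
}

#' Cohort generator configuration
#'
#' Defaults mirror the cohort shape the analysis targets: 59 wounds with on
#' average 4.6 segments each (so every class accumulates well over 50
#' segments under a balanced mixture), measurement days 0-3, pixel pitch
#' 0.5 mm, spectral noise SD 0.005.
#'
#' @param n_wounds number of wounds.
#' @param seg_mean mean segments per wound (segments ~ 1 + Poisson(seg_mean - 1)).
#' @param class_mix class mixture probabilities (2a, 2b1, 2b2, 3); sums to 1.
#' @param days measurement days.
#' @param pixel_pitch mm per pixel.
#' @param noise_sd spectral noise SD added to rendered remission.
#' @param within_sd within-segment per-layer profile SD for rendered pixels.
#' @param render render remission cubes (slow; only needed for the imaging
#'   pipeline - distribution analyses use the true parameters directly).
#' @param wound_dim height/width in pixels of rendered wound masks.
#' @param seed master seed.
#' @return a validated config list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(n_wounds = 59L, seg_mean = 4.6,
                         class_mix = c(0.25, 0.25, 0.25, 0.25), days = 0:3,
                         pixel_pitch = 0.5, noise_sd = 0.005,
                         within_sd = 0.01, render = FALSE,
                         wound_dim = c(24L, 24L), seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-9) stopConfig("class_mix must sum to 1")
  if (any(class_mix < 0) || length(class_mix) != 4L) {
    stopConfig("class_mix must be 4 non-negative probabilities")
  }
  if (n_wounds < 1L) stopConfig("n_wounds must be >= 1")
  if (noise_sd < 0 || within_sd < 0) stopConfig("noise SDs must be >= 0")
  structure(list(n_wounds = as.integer(n_wounds), seg_mean = seg_mean,
                 class_mix = class_mix, days = as.integer(days),
                 pixel_pitch = pixel_pitch, noise_sd = noise_sd,
                 within_sd = within_sd, render = isTRUE(render),
                 wound_dim = as.integer(wound_dim), seed = as.integer(seed)),
            class = "CohortConfig")
}

# healing record consistent with a class under the reference rule
.drawHealing <- function(class, sid) {
  if (class == "2a") {
    data.frame(segment_id = sid, closure_day = sample(8:14, 1L),
               surgical = FALSE, clinical_grade3 = FALSE)
  } else if (class == "2b1") {
    data.frame(segment_id = sid, closure_day = sample(15:21, 1L),
               surgical = FALSE, clinical_grade3 = FALSE)
  } else if (class == "2b2") {
    surg <- stats::runif(1) < 0.7
    data.frame(segment_id = sid,
               closure_day = if (surg) NA_integer_ else sample(22:35, 1L),
               surgical = surg, clinical_grade3 = FALSE)
  } else {
    data.frame(segment_id = sid, closure_day = NA_integer_,
               surgical = TRUE, clinical_grade3 = TRUE)
  }
}

# split a wound rectangle into k vertical strips of >= min_w columns
.splitStrips <- function(W, k, min_w = 4L) {
  if (k * min_w > W) stopDegenerate("infeasible geometry: segments exceed wound area")
  extra <- W - k * min_w
  if (k == 1L) return(W)
  cuts <- sort(sample(0:extra, k - 1L, replace = TRUE))
  min_w + diff(c(0L, cuts, extra))
}

#' Generate a synthetic cohort
#'
#' Samples wounds, segment layouts, per-segment classes, per-day true
#' profiles, healing records consistent with each class under the reference
#' rule, and (optionally) rendered remission cubes with spectral noise.
#' Byte-reproducible from the master seed.
#'
#' @param cfg a [cohortConfig()] list.
#' @param lib,model chromophore library and layer model used for rendering
#'   (defaults loaded when \code{cfg$render}).
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(cfg = cohortConfig(), lib = NULL, model = NULL) {
  if (!inherits(cfg, "CohortConfig")) stopConfig("cfg must come from cohortConfig()")
  if (cfg$render) {
    if (is.null(lib)) lib <- loadChromophores()
    if (is.null(model)) model <- defaultLayerModel()
  }
  seeds <- seedSubstreams(cfg$seed, c("layout", "profiles", "healing", "render"))
  classes <- burnClasses()

  layout <- withSeed(seeds[["layout"]], function() {
    sid <- 0L
    rows <- list()
    for (w in seq_len(cfg$n_wounds)) {
      k <- 1L + stats::rpois(1L, max(0, cfg$seg_mean - 1))
      if (cfg$render) k <- min(k, cfg$wound_dim[2L] %/% 4L)
      cls <- sample(classes, k, replace = TRUE, prob = cfg$class_mix)
      for (i in seq_len(k)) {
        sid <- sid + 1L
        rows[[sid]] <- data.frame(segment_id = paste0("S", sid),
                                  wound_id = paste0("W", w), class = cls[i])
      }
    }
    do.call(rbind, rows)
  })

  profiles <- withSeed(seeds[["profiles"]], function() {
    out <- list()
    for (i in seq_len(nrow(layout))) {
      for (d in cfg$days) {
        out[[paste0(layout$segment_id[i], "_d", d)]] <-
          sampleProfile(layout$class[i], d)
      }
    }
    out
  })

  healing <- withSeed(seeds[["healing"]], function() {
    do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
      .drawHealing(layout$class[i], layout$segment_id[i])
    }))
  })

  xa <- if (is.null(model)) 0.98 else model@xa
  seg_rows <- lapply(seq_len(nrow(layout)), function(i) {
    do.call(rbind, lapply(cfg$days, function(d) {
      p <- secondaryParams(profiles[[paste0(layout$segment_id[i], "_d", d)]], xa = xa)
      cbind(layout[i, , drop = FALSE], day = d, as.data.frame(as.list(p)),
            row.names = NULL)
    }))
  })
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  wounds <- list()
  if (cfg$render) {
    wounds <- withSeed(seeds[["render"]], function() {
      out <- list()
      H <- cfg$wound_dim[1L]; W <- cfg$wound_dim[2L]
      for (w in unique(layout$wound_id)) {
        segs <- layout[layout$wound_id == w, , drop = FALSE]
        k <- nrow(segs)
        widths <- .splitStrips(W, k)
        labmap <- matrix(0L, H, W)
        col0 <- 0L
        for (i in seq_len(k)) {
          labmap[, (col0 + 1L):(col0 + widths[i])] <- i
          col0 <- col0 + widths[i]
        }
        mask <- labmap > 0L
        cubes <- list()
        for (d in cfg$days) {
          cube <- array(0, c(H, W, length(lib@wavelengths)))
          for (i in seq_len(k)) {
            prof <- profiles[[paste0(segs$segment_id[i], "_d", d)]]
            idx <- which(labmap == i)
            for (px in idx) {
              v <- clamp01(prof@vHb + stats::rnorm(6L, 0, cfg$within_sd))
              x <- clamp01(prof@xHbO2 + stats::rnorm(6L, 0, cfg$within_sd))
              r <- renderRemission(v, x, lib, model)
              r <- r + stats::rnorm(length(r), 0, cfg$noise_sd)
              rc <- arrayInd(px, c(H, W))
              cube[rc[1L], rc[2L], ] <- clamp01(r)
            }
          }
          cubes[[paste0("d", d)]] <- new("HyperspectralCube", data = cube,
                                         wavelengths = lib@wavelengths,
                                         mask = mask,
                                         metadata = list(wound_id = w, day = d,
                                                         source = "synthetic"))
        }
        out[[w]] <- list(mask = mask, labels = labmap,
                         segment_ids = segs$segment_id, cubes = cubes)
      }
      out
    })
  }

  new("SyntheticCohort", segments = segments, healing = healing,
      profiles = profiles, wounds = wounds,
      config = unclass(cfg), seed = cfg$seed)
}

#' @rdname generateCohort
#' @param object a SyntheticCohort.
#' @export
setGeneric("cohortSegments", function(object) standardGeneric("cohortSegments"))
#' @rdname generateCohort
#' @export
setMethod("cohortSegments", "SyntheticCohort", function(object) object@segments)

#' @rdname generateCohort
#' @export
setGeneric("cohortHealing", function(object) standardGeneric("cohortHealing"))
#' @rdname generateCohort
#' @export
setMethod("cohortHealing", "SyntheticCohort", function(object) object@healing)

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d segments / %d wounds, days %s, seed %d%s\n",
              length(unique(object@segments$segment_id)),
              length(unique(object@segments$wound_id)),
              paste(unique(object@segments$day), collapse = ","),
              object@seed,
              if (length(object@wounds)) ", rendered" else ""))
})

#' Deterministic reference scenarios for testing
#'
#' Small named fixtures used across the analysis stages:
#' \describe{
#'   \item{uniform_wound}{constant 8-channel parameter maps on a 20 x 20
#'     mask; segmentation must return one segment.}
#'   \item{two_class_wound}{24 x 24 wound whose left/right halves differ by
#'     5x the default homogeneity threshold in several channels; truth is the
#'     two-part label map.}
#'   \item{trajectory_demo}{one segment per class over days 0-3 at the
#'     calibrated deep-perfusion class means.}
#'   \item{day0_overlap}{per-class day-0 point clouds drawn from strongly
#'     overlapping distributions in the lower-left of deep perfusion space.}
#' }
#'
#' @param seed seed for the stochastic fixtures (default 7).
#' @return named list of fixtures.
#' @export
referenceScenarios <- function(seed = 7L) {
  chans <- c("v1", "x1", "v2", "x2", "v3", "flow1", "flow2", "xRate")
  constMaps <- function(H, W, vals) {
    maps <- array(rep(vals, each = H * W), c(H, W, 8L),
                  dimnames = list(NULL, NULL, chans))
    maps
  }
  uniform <- list(maps = constMaps(20L, 20L, rep(0.4, 8L)),
                  mask = matrix(TRUE, 20L, 20L))

  a <- rep(0.25, 8L); b <- a + 0.3      # 5 x default tau = 0.06
  two <- list(maps = constMaps(24L, 24L, a), mask = matrix(TRUE, 24L, 24L),
              truth = matrix(rep(c(1L, 2L), each = 24L * 12L), 24L, 24L))
  two$maps[, 13:24, ] <- constMaps(24L, 12L, b)

  cal <- syntheticCalibration()
  traj <- do.call(rbind, lapply(burnClasses(), function(cl) {
    do.call(rbind, lapply(0:3, function(d) {
      row <- cal[cal$class == cl & cal$day == d, ]
      p <- secondaryParams(perfusionProfile(as.numeric(row[paste0("vHb_", 1:6)]),
                                            as.numeric(row[paste0("xHbO2_", 1:6)])))
      data.frame(segment_id = paste0("T_", cl), class = cl, day = d,
                 x = p["v2"], y = p["flow2"], row.names = NULL)
    }))
  }))

  day0 <- withSeed(seed, function() {
    means <- list(`2a` = c(0.20, 0.085), `2b1` = c(0.19, 0.075),
                  `2b2` = c(0.18, 0.070), `3` = c(0.16, 0.060))
    do.call(rbind, lapply(names(means), function(cl) {
      data.frame(class = cl, day = 0L,
                 x = clamp01(stats::rnorm(40L, means[[cl]][1L], 0.05)),
                 y = clamp01(stats::rnorm(40L, means[[cl]][2L], 0.04)))
    }))
  })

  list(uniform_wound = uniform, two_class_wound = two,
       trajectory_demo = traj, day0_overlap = day0)
}
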