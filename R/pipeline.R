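# End-to-end pipeline: simulate -> invert -> params -> segment -> label ->
# dynamics -> classify -> report. Every stage reads its inputs from and
# writes its interface files into one run directory, so stages can be re-run
# individually; a JSON manifest records the config, seeds and content hashes
# of all outputs (no timestamps, so identical seeds give byte-identical
# manifests).

.runStages <- c("simulate", "invert", "params", "segment", "label",
                "dynamics", "classify", "report")

#' Default run configuration
#'
#' A nested list validated against a fixed schema (unknown keys are
#' rejected). The defaults describe a small fully-rendered demonstration
#' cohort so the complete imaging chain (rendering, per-pixel inversion,
#' segmentation) runs in minutes; distribution-level analyses of a full-size
#' cohort use [generateCohort()] directly.
#'
#' @param seed master seed.
#' @return config list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_wounds = 6L, seg_mean = 3, wound_dim = c(12L, 16L),
                  class_mix = c(0.5, 0, 0.5, 0),
                  noise_sd = 0.005, within_sd = 0.01),
    model = list(xa = 0.98),
    inverse = list(n_restarts = 2L, lambda_s = 0.1, maxit = 60L),
    segmentation = list(tau = 0.09, min_area = 8L, block = 4L,
                        pixel_pitch = 0.5, smooth = 1L),
    kde = list(n = 80L, mass = 0.68, bandwidth = 0.05),
    classify = list(use_ps1 = TRUE)
  ), class = "RunConfig")
}

.runSchema <- list(
  seed = "seed",
  cohort = c("n_wounds", "seg_mean", "wound_dim", "class_mix", "noise_sd",
             "within_sd"),
  model = "xa",
  inverse = c("n_restarts", "lambda_s", "maxit"),
  segmentation = c("tau", "min_area", "block", "pixel_pitch", "smooth"),
  kde = c("n", "mass", "bandwidth"),
  classify = "use_ps1"
)

#' Read and validate a YAML run configuration
#'
#' Missing sections fall back to [defaultRunConfig()]; unknown keys are a
#' configuration error.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return validated config list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stopConfig(paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  validateRunConfig(raw, seed = seed)
}

#' @rdname readRunConfig
#' @param raw a config list (possibly partial).
#' @export
validateRunConfig <- function(raw, seed = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.runSchema))
  if (length(unknown)) {
    stopConfig(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  for (sec in names(raw)) {
    if (sec == "seed") { cfg$seed <- as.integer(raw$seed); next }
    bad <- setdiff(names(raw[[sec]]), .runSchema[[sec]])
    if (length(bad)) {
      stopConfig(paste0("unknown key(s) in '", sec, "': ",
                        paste(bad, collapse = ", ")))
    }
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (cfg$kde$mass <= 0 || cfg$kde$mass >= 1) stopConfig("kde$mass must be in (0,1)")
  if (cfg$segmentation$tau <= 0) stopConfig("segmentation tau must be > 0")
  cfg
}

.stageDir <- function(out, stage) {
  d <- file.path(out, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the analysis pipeline
#'
#' @param cfg a run config (list from [defaultRunConfig()] /
#'   [readRunConfig()]) or a path to a YAML config.
#' @param out run directory (created if needed).
#' @param stages subset of stages to execute, in pipeline order; defaults to
#'   all. Later stages read earlier stages' files from \code{out}.
#' @return the manifest list, invisibly; all outputs are under \code{out}.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), out, stages = .runStages) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  if (!inherits(cfg, "RunConfig")) cfg <- validateRunConfig(cfg)
  stages <- match.arg(stages, .runStages, several.ok = TRUE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  lib <- loadChromophores()
  model <- defaultLayerModel(xa = cfg$model$xa)
  seeds <- seedSubstreams(cfg$seed, .runStages)

  stageFail <- function(stage, e) {
    stop(errorCondition(paste0("stage '", stage, "' failed: ",
                               conditionMessage(e)),
                        class = c("burndyn_stage_error", class(e)[1L], "error")))
  }
  runStage <- function(stage, fun) {
    message(sprintf("[burndyn] stage %s", stage))
    t0 <- proc.time()[3L]
    tryCatch(fun(), burndyn_config_error = function(e) stop(e),
             error = function(e) stageFail(stage, e))
    message(sprintf("[burndyn] stage %s done (%.1fs)", stage,
                    proc.time()[3L] - t0))
  }

  if ("simulate" %in% stages) runStage("simulate", function() {
    d <- .stageDir(out, "simulate")
    ccfg <- cohortConfig(n_wounds = cfg$cohort$n_wounds,
                         seg_mean = cfg$cohort$seg_mean,
                         class_mix = cfg$cohort$class_mix,
                         noise_sd = cfg$cohort$noise_sd,
                         within_sd = cfg$cohort$within_sd,
                         render = TRUE,
                         wound_dim = as.integer(cfg$cohort$wound_dim),
                         seed = as.integer(seeds[["simulate"]]))
    cohort <- generateCohort(ccfg, lib = lib, model = model)
    for (w in names(cohort@wounds)) {
      wd <- file.path(d, w); dir.create(wd, showWarnings = FALSE)
      wound <- cohort@wounds[[w]]
      writeLabelPng(wound$labels, file.path(wd, "truth_labels.png"))
      writeLabelPng(wound$mask * 1L, file.path(wd, "mask.png"))
      for (dn in names(wound$cubes)) {
        writeCube(wound$cubes[[dn]], file.path(wd, paste0("cube_", dn)),
                  dialect = "archive")
      }
      utils::write.csv(data.frame(label = seq_along(wound$segment_ids),
                                  segment_id = wound$segment_ids),
                       file.path(wd, "truth_segments.csv"), row.names = FALSE,
                       quote = FALSE)
    }
    utils::write.csv(cohort@segments, file.path(d, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    writeHealingCsv(cohort@healing, file.path(d, "healing.csv"))
  })

  woundDirs <- function(stage) {
    d <- file.path(out, stage)
    dirs <- list.dirs(d, recursive = FALSE)
    if (!length(dirs)) stopDegenerate(paste("no inputs found under", d,
                                            "- run earlier stages first"))
    sort(dirs)
  }

  if ("invert" %in% stages) runStage("invert", function() {
    d <- .stageDir(out, "invert")
    for (wd in woundDirs("simulate")) {
      w <- basename(wd)
      od <- file.path(d, w); dir.create(od, showWarnings = FALSE)
      mask <- readLabelPng(file.path(wd, "mask.png")) > 0L
      for (f in sort(list.files(wd, pattern = "^cube_d[0-9]+\\.rds$"))) {
        cube <- readCube(file.path(wd, sub("\\.rds$", "", f)))
        maps <- fitCube(cube, mask = mask, lib = lib, cfg = model,
                        seed = as.integer(seeds[["invert"]]),
                        n_restarts = cfg$inverse$n_restarts,
                        lambda_s = cfg$inverse$lambda_s,
                        maxit = cfg$inverse$maxit)
        writeMaps(maps, file.path(od, sub("^cube_", "profiles_", f)))
      }
    }
  })

  if ("params" %in% stages) runStage("params", function() {
    d <- .stageDir(out, "params")
    for (wd in woundDirs("invert")) {
      od <- file.path(d, basename(wd)); dir.create(od, showWarnings = FALSE)
      for (f in sort(list.files(wd, pattern = "^profiles_d[0-9]+\\.rds$"))) {
        maps <- readMaps(file.path(wd, f))
        writeMaps(paramMaps(maps, xa = model@xa),
                  file.path(od, sub("^profiles_", "params_", f)))
      }
    }
  })

  if ("segment" %in% stages) runStage("segment", function() {
    d <- .stageDir(out, "segment")
    rows <- list()
    for (wd in woundDirs("params")) {
      w <- basename(wd)
      od <- file.path(d, w); dir.create(od, showWarnings = FALSE)
      mask <- readLabelPng(file.path(out, "simulate", w, "mask.png")) > 0L
      # the partition is defined on the last measured day, when the class
      # patterns have reached their steady state, and reused for all days
      # (the wound geometry is fixed; the clinical reference is likewise
      # assigned at steady state and propagated retrospectively)
      files <- sort(list.files(wd, pattern = "^params_d[0-9]+\\.rds$"))
      mapsL <- readMaps(file.path(wd, files[length(files)]))
      mapsL <- smoothMaps(mapsL[, , 1:8, drop = FALSE], mask,
                          radius = cfg$segmentation$smooth)
      seg <- segmentWound(mapsL, mask,
                          tau = cfg$segmentation$tau,
                          min_area = cfg$segmentation$min_area,
                          block = cfg$segmentation$block,
                          pixel_pitch = cfg$segmentation$pixel_pitch)
      writeLabelPng(seg$labels, file.path(od, "labels.png"))
      for (f in files) {
        day <- as.integer(sub("^params_d([0-9]+)\\.rds$", "\\1", f))
        maps <- readMaps(file.path(wd, f))
        for (k in seq_len(max(seg$labels))) {
          idx <- which(seg$labels == k)
          vals <- vapply(1:8, function(ch) {
            mean(maps[idx + (ch - 1L) * prod(dim(mask))])
          }, 1.0)
          names(vals) <- dimnames(maps)[[3L]][1:8]
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(wound_id = w, seg_label = k,
                       segment_id = paste0(w, "_seg", k), day = day,
                       n_pixels = length(idx)),
            as.data.frame(as.list(vals)))
        }
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(d, "segments.csv"), row.names = FALSE,
                     quote = FALSE)
  })

  if ("label" %in% stages) runStage("label", function() {
    d <- .stageDir(out, "label")
    seg <- utils::read.csv(file.path(out, "segment", "segments.csv"),
                           stringsAsFactors = FALSE)
    healing <- readHealingCsv(file.path(out, "simulate", "healing.csv"))
    healing$class <- classifyHealing(healing$closure_day, healing$surgical,
                                     healing$clinical_grade3)
    # map detected segments to true segments by modal overlap of label maps
    ref <- list()
    for (w in unique(seg$wound_id)) {
      det <- readLabelPng(file.path(out, "segment", w, "labels.png"))
      tru <- readLabelPng(file.path(out, "simulate", w, "truth_labels.png"))
      lut <- utils::read.csv(file.path(out, "simulate", w, "truth_segments.csv"),
                             stringsAsFactors = FALSE)
      for (k in seq_len(max(det))) {
        idx <- which(det == k)
        modal <- as.integer(names(which.max(table(tru[idx]))))
        true_sid <- lut$segment_id[match(modal, lut$label)]
        ref[[length(ref) + 1L]] <- data.frame(
          segment_id = paste0(w, "_seg", k),
          class = healing$class[match(true_sid, healing$segment_id)],
          pure = singleClassCheck(idx, tru))
      }
    }
    ref <- do.call(rbind, ref)
    labeled <- assignRetrospective(seg[c("segment_id", "day")],
                                   ref[c("segment_id", "class")])
    labeled <- merge(seg, labeled, by = c("segment_id", "day"))
    labeled <- labeled[order(labeled$segment_id, labeled$day), ]
    utils::write.csv(labeled, file.path(d, "labeled_segments.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  if ("dynamics" %in% stages) runStage("dynamics", function() {
    d <- .stageDir(out, "dynamics")
    tab <- utils::read.csv(file.path(out, "label", "labeled_segments.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(class = "character"))
    for (space in c("PS1", "PS2")) {
      xy <- if (space == "PS1") c("v1", "xRate") else c("v2", "flow2")
      pts <- data.frame(class = tab$class, day = tab$day,
                        x = tab[[xy[1L]]], y = tab[[xy[2L]]])
      for (day in sort(unique(pts$day))) {
        regs <- suppressWarnings(
          classRegions(pts, day, space = space, mass = cfg$kde$mass,
                       n = cfg$kde$n, bandwidth = cfg$kde$bandwidth,
                       min_points = 3L))
        if (!length(regs)) next
        writeRegionsJson(regs, file.path(d, sprintf("regions_%s_d%d.json",
                                                    space, day)))
        dt <- discriminationTable(regs)
        utils::write.csv(as.data.frame(dt$matrix),
                         file.path(d, sprintf("overlap_%s_d%d.csv", space, day)),
                         quote = FALSE)
        grDevices::png(file.path(d, sprintf("regions_%s_d%d.png", space, day)),
                       width = 480, height = 480)
        plotClassRegions(regs, pts[pts$day == day, ],
                         main = sprintf("%s day %d", space, day))
        grDevices::dev.off()
      }
    }
    traj <- segmentTrajectories(data.frame(segment_id = tab$segment_id,
                                           class = tab$class, day = tab$day,
                                           x = tab$v2, y = tab$flow2))
    jsonlite::write_json(traj, file.path(d, "trajectories_PS2.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if ("classify" %in% stages) runStage("classify", function() {
    d <- .stageDir(out, "classify")
    tab <- utils::read.csv(file.path(out, "label", "labeled_segments.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(class = "character"))
    ests <- list(); evals <- list()
    for (day in sort(unique(tab$day))) {
      f2 <- file.path(out, "dynamics", sprintf("regions_PS2_d%d.json", day))
      if (!file.exists(f2)) next
      r2 <- readRegionsJson(f2)
      f1 <- file.path(out, "dynamics", sprintf("regions_PS1_d%d.json", day))
      r1 <- if (cfg$classify$use_ps1 && file.exists(f1)) readRegionsJson(f1)
      sub <- tab[tab$day == day, ]
      for (i in seq_len(nrow(sub))) {
        est <- classifyPoint(c(sub$v2[i], sub$flow2[i]), r2,
                             if (!is.null(r1)) c(sub$v1[i], sub$xRate[i]), r1)
        ests[[length(ests) + 1L]] <- data.frame(
          segment_id = sub$segment_id[i], day = day,
          estimated_class = est$class, confidence = est$confidence,
          ambiguous_set = paste(est$ambiguous, collapse = "|"))
      }
    }
    ests <- do.call(rbind, ests)
    if (is.null(ests)) {
      ests <- data.frame(segment_id = character(0), day = integer(0),
                         estimated_class = character(0),
                         confidence = numeric(0), ambiguous_set = character(0))
    }
    utils::write.csv(ests, file.path(d, "estimates.csv"), row.names = FALSE,
                     quote = FALSE)
    ref <- unique(tab[c("segment_id", "class")])
    for (day in sort(unique(ests$day))) {
      ev <- evaluateDay(ests, ref, day)
      evals[[length(evals) + 1L]] <- data.frame(day = day,
                                                accuracy = ev$accuracy,
                                                n = ev$n)
    }
    evals <- do.call(rbind, evals)
    if (is.null(evals)) {
      evals <- data.frame(day = integer(0), accuracy = numeric(0),
                          n = integer(0))
    }
    utils::write.csv(evals, file.path(d, "accuracy.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  manifest <- NULL
  if ("report" %in% stages) runStage("report", function() {
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          "manifest.json"))
    hashes <- as.list(tools::md5sum(file.path(out, files)))
    names(hashes) <- files
    manifest <<- list(package = "burndyn",
                      version = as.character(utils::packageVersion("burndyn")),
                      seed = cfg$seed,
                      stage_seeds = as.list(seeds),
                      config = unclass(cfg),
                      files = hashes)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(manifest)
}
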