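#' @import methods
NULL

#' ChromophoreLibrary: tabulated absorber and scattering spectra
#'
#' Holds the wavelength grid and per-wavelength optical properties used by the
#' layered skin model: molar-style extinction of oxy- and deoxyhemoglobin
#' (absorption per unit blood volume fraction per mm), baseline absorption of
#' melanin, water and fat (per unit volume fraction per mm), and the reduced
#' scattering coefficient (1/mm).
#'
#' @slot wavelengths numeric, nm, strictly ascending, covering 450-1000 nm.
#' @slot eps_hbo2,eps_hb numeric, extinction of HbO2 / Hb (1/mm per unit
#'   volume fraction).
#' @slot mu_melanin,mu_water,mu_fat numeric, baseline absorption (1/mm per
#'   unit volume fraction).
#' @slot mus_reduced numeric, reduced scattering coefficient (1/mm).
#' @exportClass ChromophoreLibrary
setClass("ChromophoreLibrary",
  representation(
    wavelengths = "numeric",
    eps_hbo2 = "numeric", eps_hb = "numeric",
    mu_melanin = "numeric", mu_water = "numeric", mu_fat = "numeric",
    mus_reduced = "numeric"
  )
)

setValidity("ChromophoreLibrary", function(object) {
  wl <- object@wavelengths
  n <- length(wl)
  msgs <- character()
  if (n < 2L || any(diff(wl) <= 0)) {
    msgs <- c(msgs, "wavelengths must be strictly ascending")
  }
  if (wl[1L] > 450 || wl[n] < 1000) {
    msgs <- c(msgs, "wavelength grid must cover [450, 1000] nm")
  }
  curves <- list(object@eps_hbo2, object@eps_hb, object@mu_melanin,
                 object@mu_water, object@mu_fat, object@mus_reduced)
  if (any(vapply(curves, length, 1L) != n)) {
    msgs <- c(msgs, "all curves must match the wavelength grid length")
  } else if (any(!vapply(curves, function(x) all(is.finite(x) & x >= 0), TRUE))) {
    msgs <- c(msgs, "all optical properties must be finite and >= 0")
  } else {
    # oxy/deoxy curves must cross at least once in 500-600 nm
    sel <- wl >= 500 & wl <= 600
    d <- object@eps_hbo2[sel] - object@eps_hb[sel]
    if (sum(abs(diff(sign(d))) > 0) < 1L && all(d != 0)) {
      msgs <- c(msgs, "no isosbestic crossing of HbO2/Hb in 500-600 nm")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LayerModelConfig: parameters of the 6-layer optical skin model
#'
#' @slot widths numeric(6), per-layer path-length weights (mm-equivalent).
#' @slot scale numeric(6), positive scale factors mapping the vHb index to a
#'   blood volume fraction (volume fraction = vHb / scale).
#' @slot backscatter numeric(6), per-layer backscatter fractions of the
#'   two-pass attenuation model; sum <= 1.
#' @slot xa arterial oxygen saturation, fraction in (0, 1].
#' @slot melanin,water,fat baseline volume fractions (melanin acts in layer 1
#'   only; water and fat in all layers).
#' @slot mus_ref reference reduced-scattering (1/mm) normalising the
#'   scattering-derived path-length factor.
#' @exportClass LayerModelConfig
setClass("LayerModelConfig",
  representation(
    widths = "numeric", scale = "numeric", backscatter = "numeric",
    xa = "numeric", melanin = "numeric", water = "numeric", fat = "numeric",
    mus_ref = "numeric"
  )
)

setValidity("LayerModelConfig", function(object) {
  msgs <- character()
  if (length(object@widths) != 6L || any(object@widths <= 0)) {
    msgs <- c(msgs, "widths must be 6 positive values")
  }
  if (length(object@scale) != 6L || any(object@scale <= 0)) {
    msgs <- c(msgs, "scale must be 6 positive values")
  }
  if (length(object@backscatter) != 6L || any(object@backscatter <= 0) ||
      sum(object@backscatter) > 1 + 1e-12) {
    msgs <- c(msgs, "backscatter must be 6 positive fractions summing to <= 1")
  }
  if (length(object@xa) != 1L || object@xa <= 0 || object@xa > 1) {
    msgs <- c(msgs, "xa must be in (0, 1]")
  }
  for (nm in c("melanin", "water", "fat")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v < 0 || v > 1) msgs <- c(msgs, paste(nm, "must be in [0, 1]"))
  }
  if (length(object@mus_ref) != 1L || object@mus_ref <= 0) {
    msgs <- c(msgs, "mus_ref must be a positive scalar")
  }
  if (length(msgs)) msgs else TRUE
})

#' PerfusionProfile: per-layer hemoglobin volume and oxygen saturation
#'
#' The 6-layer perfusion profile: for each layer, a hemoglobin volume index
#' vHb in [0, 1] and an oxygen saturation fraction xHbO2 in [0, 1]. By
#' convention xHbO2 is reported as 0 in layers with vHb = 0 (the saturation of
#' no blood is undefined).
#'
#' @slot vHb numeric(6) in [0, 1].
#' @slot xHbO2 numeric(6) in [0, 1].
#' @exportClass PerfusionProfile
setClass("PerfusionProfile",
  representation(vHb = "numeric", xHbO2 = "numeric"))

setValidity("PerfusionProfile", function(object) {
  msgs <- character()
  if (length(object@vHb) != 6L || length(object@xHbO2) != 6L) {
    msgs <- c(msgs, "vHb and xHbO2 must each have length 6")
  } else {
    if (any(!is.finite(object@vHb)) || any(object@vHb < 0 | object@vHb > 1)) {
      msgs <- c(msgs, "vHb values must be in [0, 1]")
    }
    if (any(!is.finite(object@xHbO2)) || any(object@xHbO2 < 0 | object@xHbO2 > 1)) {
      msgs <- c(msgs, "xHbO2 values must be in [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RemissionSpectrum: a reflectance spectrum
#'
#' @slot wavelengths numeric, nm, ascending.
#' @slot remission numeric, dimensionless reflectance in [0, 1].
#' @exportClass RemissionSpectrum
setClass("RemissionSpectrum",
  representation(wavelengths = "numeric", remission = "numeric"))

setValidity("RemissionSpectrum", function(object) {
  msgs <- character()
  if (length(object@wavelengths) != length(object@remission)) {
    msgs <- c(msgs, "wavelengths and remission must have equal length")
  }
  if (any(diff(object@wavelengths) <= 0)) {
    msgs <- c(msgs, "wavelengths must be strictly ascending")
  }
  r <- object@remission
  if (any(!is.finite(r)) || any(r < 0 | r > 1)) {
    msgs <- c(msgs, "remission values must be finite and in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' FitResult: result of the inverse perfusion-profile fit
#'
#' @slot profile the fitted [PerfusionProfile-class].
#' @slot residual root-mean-square spectral misfit (dimensionless, >= 0).
#' @slot converged logical convergence flag of the best restart.
#' @slot n_restarts_used number of multi-start restarts evaluated.
#' @exportClass FitResult
setClass("FitResult",
  representation(profile = "PerfusionProfile", residual = "numeric",
                 converged = "logical", n_restarts_used = "integer"))

setValidity("FitResult", function(object) {
  if (length(object@residual) != 1L || !is.finite(object@residual) ||
      object@residual < 0) {
    return("residual must be a single finite value >= 0")
  }
  TRUE
})

#' HyperspectralCube: an H x W x B remission image
#'
#' @slot data numeric array, height x width x bands, remission in [0, 1].
#' @slot wavelengths numeric(bands), nm, ascending.
#' @slot mask logical matrix (height x width) or of length 0 when absent.
#' @slot metadata list of provenance fields (source, day, wound id, ...).
#' @exportClass HyperspectralCube
setClass("HyperspectralCube",
  representation(data = "array", wavelengths = "numeric", mask = "matrix",
                 metadata = "list"))

setValidity("HyperspectralCube", function(object) {
  d <- dim(object@data)
  msgs <- character()
  if (length(d) != 3L) {
    msgs <- c(msgs, "data must be a 3D array (height x width x bands)")
  } else {
    if (d[3L] != length(object@wavelengths)) {
      msgs <- c(msgs, "band count must equal the number of wavelengths")
    }
    if (length(object@mask) && !identical(dim(object@mask), d[1:2])) {
      msgs <- c(msgs, "mask dimensions must match the image plane")
    }
  }
  if (any(diff(object@wavelengths) <= 0)) {
    msgs <- c(msgs, "wavelengths must be strictly ascending")
  }
  if (any(!is.finite(object@data))) msgs <- c(msgs, "data must be finite")
  if (length(msgs)) msgs else TRUE
})

#' ClassRegion: convex-hull abstraction of a kernel class region
#'
#' A density-thresholded kernel region of one burn class on one day in one
#' parameter space, abstracted to its convex hull.
#'
#' @slot class character, one of "2a", "2b1", "2b2", "3".
#' @slot day integer day post-burn (0-3).
#' @slot space character, "PS1" or "PS2".
#' @slot hull numeric matrix (n x 2) of vertices, counter-clockwise, within
#'   the unit square.
#' @slot mass fraction of distribution mass captured by the kernel region.
#' @exportClass ClassRegion
setClass("ClassRegion",
  representation(burnClass = "character", day = "integer", space = "character",
                 hull = "matrix", mass = "numeric"))

setValidity("ClassRegion", function(object) {
  msgs <- character()
  if (!object@burnClass %in% burnClasses()) msgs <- c(msgs, "unknown burn class")
  if (!object@space %in% c("PS1", "PS2")) msgs <- c(msgs, "space must be PS1 or PS2")
  h <- object@hull
  if (ncol(h) != 2L || nrow(h) < 3L) {
    msgs <- c(msgs, "hull must be an n x 2 matrix with n >= 3")
  } else {
    if (any(h < -1e-9 | h > 1 + 1e-9)) msgs <- c(msgs, "hull vertices must lie in the unit square")
    if (polygonArea(h) <= 0) msgs <- c(msgs, "hull vertices must be counter-clockwise")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: a generated study cohort
#'
#' Ground truth for testing every analysis stage: per-segment burn class,
#' per-day true perfusion profiles and secondary parameters, healing records,
#' optional rendered cubes, and full provenance (config + seed).
#'
#' @slot segments data.frame: one row per (segment, day) with the true
#'   composed parameters and parameter-space coordinates.
#' @slot healing data.frame: segment_id, closure_day, surgical, clinical_grade3.
#' @slot profiles list of true [PerfusionProfile-class]s keyed
#'   "<segment_id>_d<day>".
#' @slot wounds list of per-wound geometry (mask, segment label map) and, when
#'   rendered, per-day [HyperspectralCube-class]s.
#' @slot config the generating [CohortConfig] list.
#' @slot seed integer master seed.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(segments = "data.frame", healing = "data.frame",
                 profiles = "list", wounds = "list", config = "list",
                 seed = "integer"))

#' Ordered burn classes
#'
#' The four burn classes in increasing severity: 2a (superficial), 2b1
#' (superficial dermal), 2b2 (deep dermal), 3 (full thickness).
#'
#' @return character vector of class labels, least to most severe.
#' @export
burnClasses <- function() c("2a", "2b1", "2b2", "3")
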