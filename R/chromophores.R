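#' Load the packaged chromophore library
#'
#' Reads the packaged table of absorber extinction and reduced-scattering
#' curves and resamples it onto the model wavelength grid by linear
#' interpolation. The packaged asset is a synthetic table: analytic
#' approximations to the literature curve shapes of oxy-/deoxyhemoglobin,
#' melanin, water and fat absorption and Mie-like reduced scattering,
#' constructed so the usual qualitative features hold (alpha/beta HbO2 bands,
#' 555 nm Hb band, isosbestic crossings in 500-600 nm, 760 nm Hb band, NIR
#' water/fat bands).
#'
#' @param source path to a chromophore CSV with header
#'   \code{wavelength_nm,eps_hbo2,eps_hb,mu_melanin,mu_water,mu_fat,mus_reduced};
#'   defaults to the packaged asset.
#' @param grid target wavelength grid in nm (default 450-1000 nm step 5,
#'   111 bands).
#' @return a [ChromophoreLibrary-class].
#' @export
loadChromophores <- function(source = system.file("extdata", "chromophores_synthetic.csv",
                                                  package = "burndyn"),
                             grid = seq(450, 1000, by = 5)) {
  if (!nzchar(source) || !file.exists(source)) {
    stopDegenerate("chromophore table not found")
  }
  tab <- utils::read.csv(source)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb", "mu_melanin", "mu_water",
            "mu_fat", "mus_reduced")
  if (!all(need %in% names(tab))) {
    stopDegenerate(paste("chromophore table missing columns:",
                         paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(tab[need]))
  if (length(bad)) {
    wl <- tab$wavelength_nm[bad[1L]]
    stopDegenerate(paste0("missing/NaN chromophore entry at wavelength ",
                          ifelse(is.na(wl), "<unknown>", wl), " nm"))
  }
  if (min(tab$wavelength_nm) > min(grid) || max(tab$wavelength_nm) < max(grid)) {
    stopDegenerate("chromophore table does not cover the requested grid")
  }
  interp <- function(col) stats::approx(tab$wavelength_nm, tab[[col]], xout = grid)$y
  new("ChromophoreLibrary",
      wavelengths = grid,
      eps_hbo2 = interp("eps_hbo2"), eps_hb = interp("eps_hb"),
      mu_melanin = interp("mu_melanin"), mu_water = interp("mu_water"),
      mu_fat = interp("mu_fat"), mus_reduced = interp("mus_reduced"))
}

#' Default 6-layer optical model configuration
#'
#' Layer widths increase with depth (thin epidermis to thick subcutis);
#' per-layer scale factors map the dimensionless vHb index to a blood volume
#' fraction; backscatter fractions weight each layer's contribution to the
#' two-pass remission model. Melanin is confined to layer 1; water and fat act
#' in every layer.
#'
#' @param xa arterial oxygen saturation (default 0.98).
#' @return a [LayerModelConfig-class].
#' @export
defaultLayerModel <- function(xa = 0.98) {
  new("LayerModelConfig",
      widths = c(0.15, 0.20, 0.30, 0.40, 0.55, 0.70),
      scale = c(8, 8, 9, 9, 7, 7),
      backscatter = c(0.07, 0.09, 0.10, 0.14, 0.25, 0.32),
      xa = xa, melanin = 0.02, water = 0.65, fat = 0.15, mus_ref = 10)
}

#' Construct a perfusion profile
#'
#' @param vHb numeric(6) hemoglobin volume indices in [0, 1].
#' @param xHbO2 numeric(6) oxygen saturation fractions in [0, 1]. Layers with
#'   vHb = 0 are reported with xHbO2 = 0 by convention.
#' @return a [PerfusionProfile-class].
#' @export
perfusionProfile <- function(vHb, xHbO2) {
  vHb <- as.numeric(vHb); xHbO2 <- as.numeric(xHbO2)
  xHbO2[vHb == 0] <- 0
  new("PerfusionProfile", vHb = vHb, xHbO2 = xHbO2)
}

#' @rdname perfusionProfile
#' @param object a PerfusionProfile.
#' @export
setGeneric("vHb", function(object) standardGeneric("vHb"))
#' @rdname perfusionProfile
#' @export
setMethod("vHb", "PerfusionProfile", function(object) object@vHb)

#' @rdname perfusionProfile
#' @export
setGeneric("xHbO2", function(object) standardGeneric("xHbO2"))
#' @rdname perfusionProfile
#' @export
setMethod("xHbO2", "PerfusionProfile", function(object) object@xHbO2)

setMethod("show", "PerfusionProfile", function(object) {
  cat("PerfusionProfile (6 layers)\n")
  m <- rbind(vHb = round(object@vHb, 3), xHbO2 = round(object@xHbO2, 3))
  colnames(m) <- paste0("L", 1:6)
  print(m)
})

setMethod("show", "ChromophoreLibrary", function(object) {
  cat(sprintf("ChromophoreLibrary: %d bands, %g-%g nm\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
})

#' Per-layer absorption spectrum
#'
#' Absorption coefficient of one layer: the hemoglobin term
#' \code{(vHb/scale) * (xHbO2 * eps_hbo2 + (1 - xHbO2) * eps_hb)} plus the
#' baseline absorbers (melanin in layer 1 only; water and fat everywhere).
#'
#' @param profile a [PerfusionProfile-class].
#' @param layer layer index 1-6.
#' @param lib a [ChromophoreLibrary-class].
#' @param cfg a [LayerModelConfig-class].
#' @return numeric absorption spectrum (1/mm) on the library grid.
#' @export
layerAbsorption <- function(profile, layer, lib, cfg) {
  stopifnot(length(layer) == 1L, layer >= 1, layer <= 6)
  v <- profile@vHb[layer] / cfg@scale[layer]
  x <- profile@xHbO2[layer]
  mua <- v * (x * lib@eps_hbo2 + (1 - x) * lib@eps_hb) +
    cfg@water * lib@mu_water + cfg@fat * lib@mu_fat
  if (layer == 1L) mua <- mua + cfg@melanin * lib@mu_melanin
  mua
}

# Internal: 6 x B matrix of per-layer absorption; vectorized core shared by
# renderSpectrum and the inverse solver's objective/gradient.
layerAbsorptionMatrix <- function(vHb, xHbO2, lib, cfg) {
  B <- length(lib@wavelengths)
  hb <- outer(vHb / cfg@scale, rep(1, B)) *
    (outer(xHbO2, rep(1, B)) * rep(lib@eps_hbo2, each = 6L) +
     outer(1 - xHbO2, rep(1, B)) * rep(lib@eps_hb, each = 6L))
  base <- matrix(cfg@water * lib@mu_water + cfg@fat * lib@mu_fat,
                 nrow = 6L, ncol = B, byrow = TRUE)
  base[1L, ] <- base[1L, ] + cfg@melanin * lib@mu_melanin
  hb + base
}

#' Render a remission spectrum from a perfusion profile
#'
#' Two-pass layered attenuation model: light traverses layers 1..k and back,
#' and each layer k contributes a fixed backscatter fraction b_k attenuated by
#' \code{exp(-2 * sum_{j<=k} mua_j * w_j * d_j)}, where d_j is a
#' scattering-derived path-length factor \code{1 + mus'(lambda)/mus_ref}.
#' Output is clamped to [0, 1] and fully deterministic.
#'
#' @inheritParams layerAbsorption
#' @return a [RemissionSpectrum-class] on the library grid.
#' @export
renderSpectrum <- function(profile, lib, cfg) {
  r <- renderRemission(profile@vHb, profile@xHbO2, lib, cfg)
  new("RemissionSpectrum", wavelengths = lib@wavelengths, remission = clamp01(r))
}

# Internal numeric core (no S4 wrapping): returns remission vector.
renderRemission <- function(vHb, xHbO2, lib, cfg) {
  mua <- layerAbsorptionMatrix(vHb, xHbO2, lib, cfg)          # 6 x B
  d <- 1 + lib@mus_reduced / cfg@mus_ref                      # B
  od <- mua * (2 * cfg@widths)                                # 6 x B
  od <- sweep(od, 2L, d, `*`)
  cum <- apply(od, 2L, cumsum)                                # 6 x B
  as.numeric(colSums(cfg@backscatter * exp(-cum)))
}

#' Read or write a remission spectrum CSV
#'
#' CSV with header \code{wavelength_nm,remission}.
#'
#' @param path file path.
#' @return for the reader, a [RemissionSpectrum-class].
#' @export
readSpectrumCsv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "remission") %in% names(tab))) {
    stopDegenerate("spectrum CSV must have columns wavelength_nm,remission")
  }
  new("RemissionSpectrum", wavelengths = tab$wavelength_nm,
      remission = tab$remission)
}

#' @rdname readSpectrumCsv
#' @param spectrum a [RemissionSpectrum-class].
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum@wavelengths,
                              remission = spectrum@remission),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate an isosbestic wavelength of the packaged hemoglobin curves
#'
#' Finds a crossing of the oxy- and deoxyhemoglobin extinction curves within
#' a window by sign change plus linear interpolation.
#'
#' @param lib a [ChromophoreLibrary-class].
#' @param window numeric(2) wavelength window (default 550-600 nm).
#' @return the crossing wavelength in nm.
#' @export
isosbesticWavelength <- function(lib, window = c(550, 600)) {
  sel <- which(lib@wavelengths >= window[1L] & lib@wavelengths <= window[2L])
  d <- lib@eps_hbo2[sel] - lib@eps_hb[sel]
  i <- which(d[-length(d)] * d[-1L] <= 0)[1L]
  if (is.na(i)) stopDegenerate("no isosbestic crossing in window")
  w1 <- lib@wavelengths[sel[i]]; w2 <- lib@wavelengths[sel[i + 1L]]
  w1 + (w2 - w1) * d[i] / (d[i] - d[i + 1L])
}
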