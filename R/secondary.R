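# Secondary perfusion parameters: composed upper/deeper volume and saturation
# plus derived flow and oxygen-consumption indices, and the projection into
# the two 2D parameter spaces used for the class-distribution analysis:
#   PS1 (superficial perfusion): x = vHb_1, y = xRate
#   PS2 (deep perfusion):        x = vHb_2, y = flow_2
# All values are dimensionless indices clamped to [0, 1].

#' Compose upper/middle/deeper parameters from a perfusion profile
#'
#' Groups the 6 layers into upper (1-2), middle (3-4) and deeper (5-6):
#' volume parts are width-weighted sums of vHb over the group (default
#' weights 0.5 each, i.e. the group mean), clamped to [0, 1]; saturations
#' are vHb-weighted means of xHbO2 (0 when the group carries no blood).
#'
#' @param profile a [PerfusionProfile-class].
#' @param weights numeric(6) grouping weights (default 0.5 for every layer).
#' @return named numeric: v1, x1, v2, x2, v3.
#' @export
composeParams <- function(profile, weights = rep(0.5, 6)) {
  v <- profile@vHb; x <- profile@xHbO2
  groups <- list(upper = 1:2, middle = 3:4, deeper = 5:6)
  gv <- vapply(groups, function(g) min(1, sum(weights[g] * v[g])), 1.0)
  gx <- vapply(groups, function(g) {
    w <- v[g]
    if (sum(w) == 0) 0 else sum(w * x[g]) / sum(w)
  }, 1.0)
  c(v1 = unname(gv["upper"]), x1 = unname(gx["upper"]),
    v2 = unname(gv["deeper"]), x2 = unname(gx["deeper"]),
    v3 = unname(gv["middle"]))
}

#' Derived perfusion indices
#'
#' \code{flowIndex1 = v1 * x1 / (xa - x1)}: blood flow through the upper
#' layers. \code{flowIndex2 = v2 * (x2 - x1) / (xa - x2)}: flow through the
#' deeper layers. \code{oxygenRate = v3 * (xa - x1)}: oxygen consumption in
#' the upper layers. All are clamped to [0, 1]; the saturation pole
#' (x approaching xa) clamps to 1 when the numerator is positive, and
#' negative raw values clamp to 0.
#'
#' An alternative reading of the upper-flow formula,
#' \code{v1 * x1 * xa - x1}, is selectable via \code{variant = "product"};
#' the default quotient form is dimensionally consistent with the deep flow.
#'
#' @param v1,x1,v2,x2,v3 composed parameters in [0, 1] (vectorized).
#' @param xa arterial oxygen saturation (default 0.98).
#' @param variant formula variant for \code{flowIndex1}.
#' @return numeric index in [0, 1].
#' @export
flowIndex1 <- function(v1, x1, xa = 0.98, variant = c("quotient", "product")) {
  variant <- match.arg(variant)
  raw <- if (variant == "quotient") {
    ifelse(x1 >= xa, ifelse(v1 * x1 > 0, Inf, 0), v1 * x1 / (xa - x1))
  } else {
    v1 * x1 * xa - x1
  }
  clamp01(ifelse(v1 == 0 | x1 == 0, 0, raw))
}

#' @rdname flowIndex1
#' @export
flowIndex2 <- function(v2, x2, x1, xa = 0.98) {
  raw <- ifelse(x2 >= xa, ifelse(v2 * (x2 - x1) > 0, Inf, 0),
                v2 * (x2 - x1) / (xa - x2))
  clamp01(ifelse(v2 == 0, 0, raw))
}

#' @rdname flowIndex1
#' @export
oxygenRate <- function(v3, x1, xa = 0.98) {
  clamp01(v3 * (xa - x1))
}

#' Full secondary-parameter set for a profile
#'
#' @inheritParams composeParams
#' @param xa arterial oxygen saturation.
#' @return named numeric: v1, x1, v2, x2, v3, flow1, flow2, xRate.
#' @export
secondaryParams <- function(profile, xa = 0.98, weights = rep(0.5, 6)) {
  p <- composeParams(profile, weights)
  c(p,
    flow1 = unname(flowIndex1(p["v1"], p["x1"], xa)),
    flow2 = unname(flowIndex2(p["v2"], p["x2"], p["x1"], xa)),
    xRate = unname(oxygenRate(p["v3"], p["x1"], xa)))
}

#' Project secondary parameters into the two parameter spaces
#'
#' PS1 (superficial perfusion) is (v1, xRate); PS2 (deep perfusion) is
#' (v2, flow2). No transform, scale or flip is applied.
#'
#' @param params named numeric as returned by [secondaryParams()].
#' @return list with elements \code{PS1} and \code{PS2}, each a named numeric
#'   \code{c(x =, y =)} in the unit square.
#' @export
projectParams <- function(params) {
  list(PS1 = c(x = unname(params["v1"]), y = unname(params["xRate"])),
       PS2 = c(x = unname(params["v2"]), y = unname(params["flow2"])))
}

.paramChannels <- c("v1", "x1", "v2", "x2", "v3", "flow1", "flow2", "xRate")

#' Per-pixel secondary-parameter maps from fitted profile maps
#'
#' @param profileMaps H x W x 13 array as returned by [fitCube()].
#' @param xa arterial oxygen saturation.
#' @return H x W x 8 array with channels v1,x1,v2,x2,v3,flow1,flow2,xRate.
#' @export
paramMaps <- function(profileMaps, xa = 0.98) {
  d <- dim(profileMaps)
  out <- array(NA_real_, c(d[1:2], 8L), dimnames = list(NULL, NULL, .paramChannels))
  vhb <- profileMaps[, , 1:6, drop = FALSE]
  xhb <- profileMaps[, , 7:12, drop = FALSE]
  gmean <- function(a, g) (a[, , g[1L]] + a[, , g[2L]]) / 2
  wmean <- function(g) {
    w <- vhb[, , g[1L]] + vhb[, , g[2L]]
    num <- vhb[, , g[1L]] * xhb[, , g[1L]] + vhb[, , g[2L]] * xhb[, , g[2L]]
    ifelse(w == 0, 0, num / w)
  }
  v1 <- clamp01(gmean(vhb, 1:2)); v3 <- clamp01(gmean(vhb, 3:4))
  v2 <- clamp01(gmean(vhb, 5:6))
  x1 <- wmean(1:2); x2 <- wmean(5:6)
  out[, , "v1"] <- v1; out[, , "x1"] <- x1
  out[, , "v2"] <- v2; out[, , "x2"] <- x2; out[, , "v3"] <- v3
  out[, , "flow1"] <- flowIndex1(v1, x1, xa)
  out[, , "flow2"] <- flowIndex2(v2, x2, x1, xa)
  out[, , "xRate"] <- oxygenRate(v3, x1, xa)
  out
}

#' Write / read a per-segment parameter table
#'
#' CSV with columns \code{segment_id,day,v1,x1,v2,x2,v3,flow1,flow2,xRate}.
#'
#' @param tab data.frame with those columns.
#' @param path file path.
#' @export
writeSegmentParamsCsv <- function(tab, path) {
  need <- c("segment_id", "day", .paramChannels)
  missing <- setdiff(need, names(tab))
  if (length(missing)) stopDegenerate(paste("segment table missing:", paste(missing, collapse = ", ")))
  utils::write.csv(tab[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSegmentParamsCsv
#' @export
readSegmentParamsCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
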