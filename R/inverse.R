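# Approximate inverse of the layered remission model: bounded least squares
# over the 12 profile parameters (6 vHb, 6 xHbO2), multi-start, with a
# smoothness penalty tying adjacent layers. The inverse is depth-ambiguous,
# so only composed upper/deeper parameters are expected to be well recovered;
# the penalty regularizes the within-group ambiguity.

# second-difference penalty matrix operator (6 -> 4)
.D2 <- local({
  D <- matrix(0, 4L, 6L)
  for (i in 1:4) D[i, i:(i + 2L)] <- c(1, -2, 1)
  D
})
.D2tD2 <- crossprod(.D2)

# Penalized objective and analytic gradient for one spectrum.
# state p = c(vHb, xHbO2); robs observed remission.
.fitObjective <- function(p, robs, lib, cfg, lambda_s) {
  vHb <- p[1:6]; x <- p[7:12]
  B <- length(lib@wavelengths)
  d <- 1 + lib@mus_reduced / cfg@mus_ref
  e_mix <- outer(x, lib@eps_hbo2) + outer(1 - x, lib@eps_hb)   # 6 x B
  mua <- (vHb / cfg@scale) * e_mix +
    matrix(cfg@water * lib@mu_water + cfg@fat * lib@mu_fat, 6L, B, byrow = TRUE)
  mua[1L, ] <- mua[1L, ] + cfg@melanin * lib@mu_melanin
  a <- (2 * cfg@widths) * mua * rep(d, each = 6L)              # 6 x B
  cum <- a
  for (i in 2:6) cum[i, ] <- cum[i - 1L, ] + a[i, ]
  term <- cfg@backscatter * exp(-cum)                          # 6 x B
  r <- colSums(term)
  res <- r - robs
  # tail sums T_j = sum_{k>=j} term_k
  tailT <- term
  for (i in 5:1) tailT[i, ] <- tailT[i + 1L, ] + term[i, ]
  wfac <- (2 * cfg@widths) * rep(d, each = 6L)                  # 6 x B
  common <- tailT * wfac * rep(res, each = 6L)                  # 6 x B
  dvdt <- e_mix / cfg@scale                                     # d mua / d vHb
  dxdt <- (vHb / cfg@scale) *
    matrix(lib@eps_hbo2 - lib@eps_hb, 6L, B, byrow = TRUE)      # d mua / d x
  g_v <- -(2 / B) * rowSums(common * dvdt)
  g_x <- -(2 / B) * rowSums(common * dxdt)
  pen_v <- .D2 %*% vHb; pen_x <- .D2 %*% x
  # the penalty is expressed on the scale of the mean-square misfit so that
  # it resolves the depth-ambiguous (near-null) directions without competing
  # with the data term: weight = lambda_s * .penaltyScale
  w <- lambda_s * .penaltyScale
  val <- mean(res^2) + w * (sum(pen_v^2) + sum(pen_x^2))
  grad <- c(g_v + w * 2 * as.numeric(.D2tD2 %*% vHb),
            g_x + w * 2 * as.numeric(.D2tD2 %*% x))
  list(value = val, gradient = grad,
       residual = sqrt(mean(res^2)))
}

# penalty units: squared remission per squared second-difference; chosen so
# the default lambda_s = 0.1 acts only in the depth-ambiguous directions
# (penalty of a unit-rough profile ~ the misfit of a 0.001 RMS perturbation)
.penaltyScale <- 1e-5

#' Fit a perfusion profile to a remission spectrum
#'
#' Bounded multi-start least squares over the 12 profile parameters, with a
#' smoothness penalty (weight \code{lambda_s}) on second differences of vHb
#' and xHbO2 across layers. The restart with the lowest spectral residual is
#' returned (ties broken by lowest restart index). Deterministic for a given
#' (spectrum, seed).
#'
#' @param spectrum a [RemissionSpectrum-class]; resampled onto the library
#'   grid if necessary.
#' @param lib a [ChromophoreLibrary-class].
#' @param cfg a [LayerModelConfig-class].
#' @param seed integer seed for the multi-start initial points.
#' @param n_restarts number of starts (default 5).
#' @param lambda_s smoothness weight (default 0.1).
#' @param maxit maximum L-BFGS-B iterations per restart.
#' @return a [FitResult-class].
#' @export
fitProfile <- function(spectrum, lib, cfg, seed = 1L, n_restarts = 5L,
                       lambda_s = 0.1, maxit = 150L) {
  robs <- spectrum@remission
  if (all(robs <= 0)) stopDegenerate("degenerate input: all-zero remission spectrum")
  if (any(robs < 0)) stopDegenerate("degenerate input: negative remission values")
  if (!isTRUE(all.equal(spectrum@wavelengths, lib@wavelengths))) {
    if (min(spectrum@wavelengths) > min(lib@wavelengths) ||
        max(spectrum@wavelengths) < max(lib@wavelengths)) {
      stopDegenerate("spectrum does not cover the model wavelength grid")
    }
    robs <- stats::approx(spectrum@wavelengths, robs, xout = lib@wavelengths)$y
  }
  starts <- fitStarts(seed, n_restarts)
  best <- NULL
  cache <- new.env(parent = emptyenv())
  evalObj <- function(p) {
    if (!identical(p, cache$p)) {
      cache$p <- p
      cache$res <- .fitObjective(p, robs, lib, cfg, lambda_s)
    }
    cache$res
  }
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ],
                        fn = function(p) evalObj(p)$value,
                        gr = function(p) evalObj(p)$gradient,
                        method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(maxit = maxit, factr = 1e6))
    resid <- .fitObjective(opt$par, robs, lib, cfg, lambda_s)$residual
    if (is.null(best) || resid < best$residual - 1e-15) {
      best <- list(par = opt$par, residual = resid,
                   converged = opt$convergence == 0L)
    }
  }
  new("FitResult",
      profile = perfusionProfile(best$par[1:6], best$par[7:12]),
      residual = best$residual, converged = best$converged,
      n_restarts_used = as.integer(n_restarts))
}

# deterministic multi-start set: one smooth mid-range start + seeded uniforms
fitStarts <- function(seed, n_restarts) {
  starts <- matrix(NA_real_, n_restarts, 12L)
  starts[1L, ] <- c(rep(0.3, 6), rep(0.5, 6))
  if (n_restarts > 1L) {
    rng <- withSeed(seed, function() {
      matrix(stats::runif((n_restarts - 1L) * 12L), n_restarts - 1L, 12L)
    })
    starts[-1L, ] <- rng
  }
  starts
}

withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' @rdname fitProfile
#' @param object a FitResult.
#' @export
setGeneric("fittedProfile", function(object) standardGeneric("fittedProfile"))
#' @rdname fitProfile
#' @export
setMethod("fittedProfile", "FitResult", function(object) object@profile)

#' @rdname fitProfile
#' @export
setGeneric("fitResidual", function(object) standardGeneric("fitResidual"))
#' @rdname fitProfile
#' @export
setMethod("fitResidual", "FitResult", function(object) object@residual)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: residual %.5f, converged %s (%d restarts)\n",
              object@residual, object@converged, object@n_restarts_used))
  show(object@profile)
})

#' Fit perfusion profiles for every masked pixel of a cube
#'
#' Applies [fitProfile()] independently to each masked pixel; unmasked pixels
#' carry NA. Per-pixel seeds are derived deterministically from \code{seed}
#' and the pixel's linear index, so results are reproducible.
#'
#' @param cube a [HyperspectralCube-class] whose bands match the library grid.
#' @param mask logical matrix; defaults to the cube's own mask.
#' @inheritParams fitProfile
#' @return a 3D array H x W x 13 with channels \code{vHb_1..6},
#'   \code{xHbO2_1..6}, \code{residual}.
#' @export
fitCube <- function(cube, mask = NULL, lib, cfg, seed = 1L, n_restarts = 5L,
                    lambda_s = 0.1, maxit = 150L) {
  if (is.null(mask)) {
    if (!length(cube@mask)) stopDegenerate("no mask given and cube has none")
    mask <- cube@mask
  }
  d <- dim(cube@data)
  if (!identical(dim(mask), d[1:2])) stopDegenerate("mask dimensions mismatch cube")
  if (!any(mask)) stopDegenerate("empty mask")
  if (d[3L] != length(lib@wavelengths) ||
      !isTRUE(all.equal(cube@wavelengths, lib@wavelengths))) {
    stopDegenerate("cube band grid does not match the chromophore library grid")
  }
  channels <- c(paste0("vHb_", 1:6), paste0("xHbO2_", 1:6), "residual")
  maps <- array(NA_real_, c(d[1:2], 13L), dimnames = list(NULL, NULL, channels))
  idx <- which(mask)
  for (k in idx) {
    rc <- arrayInd(k, d[1:2])
    spx <- new("RemissionSpectrum", wavelengths = cube@wavelengths,
                remission = clamp01(cube@data[rc[1L], rc[2L], ]))
    pseed <- as.integer((as.numeric(seed) * 10007 + k) %% 2147483647)
    fit <- fitProfile(spx, lib, cfg, seed = pseed, n_restarts = n_restarts,
                      lambda_s = lambda_s, maxit = maxit)
    maps[rc[1L], rc[2L], ] <- c(fit@profile@vHb, fit@profile@xHbO2, fit@residual)
  }
  maps
}
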