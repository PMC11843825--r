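clamp01 <- function(x) {
  # preserves dim attributes (pmax(0, x) would copy attributes from 0)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopDegenerate <- function(msg) {
  stop(errorCondition(msg, class = c("burndyn_data_error", "error")))
}

stopConfig <- function(msg) {
  stop(errorCondition(msg, class = c("burndyn_config_error", "error")))
}

#' Derive per-stage substream seeds from one master seed
#'
#' All randomness in the package flows from a single master seed which is
#' split into named substreams, one per pipeline stage, so that each stage is
#' individually reproducible.
#'
#' @param master integer master seed.
#' @param names character vector of substream names.
#' @return named integer vector of seeds (all < 2^31).
#' @export
seedSubstreams <- function(master, names) {
  # deterministic arithmetic split (independent of the RNG state)
  h <- vapply(names, function(nm) {
    s <- sum(utf8ToInt(nm) * seq_along(utf8ToInt(nm)))
    as.integer((as.numeric(master) * 69069 + s * 2654435761) %% 2147483647)
  }, 1L)
  names(h) <- names
  h
}

#' Shoelace signed area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly n x 2 matrix of vertices.
#' @return signed area.
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}
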