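# On-disk formats. Two hyperspectral-cube dialects are supported: an
# ENVI-style header + raw float32 binary (BSQ/BIL/BIP interleaves) for
# interoperability with real HSI exports, and a compact array-archive (RDS)
# dialect used by tests and the pipeline. Label images are 8-bit grayscale
# PNGs (0 = background).

#' Construct a hyperspectral cube
#'
#' @param data H x W x B array of remission values in [0, 1].
#' @param wavelengths numeric(B) in nm, ascending.
#' @param mask optional logical matrix.
#' @param metadata provenance list.
#' @return a [HyperspectralCube-class].
#' @export
hyperspectralCube <- function(data, wavelengths, mask = NULL, metadata = list()) {
  new("HyperspectralCube", data = data, wavelengths = as.numeric(wavelengths),
      mask = if (is.null(mask)) matrix(logical(0), 0L, 0L) else mask,
      metadata = metadata)
}

#' @rdname hyperspectralCube
#' @param object a HyperspectralCube.
#' @export
setGeneric("cubeData", function(object) standardGeneric("cubeData"))
#' @rdname hyperspectralCube
#' @export
setMethod("cubeData", "HyperspectralCube", function(object) object@data)

#' @rdname hyperspectralCube
#' @export
setGeneric("cubeWavelengths", function(object) standardGeneric("cubeWavelengths"))
#' @rdname hyperspectralCube
#' @export
setMethod("cubeWavelengths", "HyperspectralCube", function(object) object@wavelengths)

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperspectralCube: %d x %d pixels, %d bands (%g-%g nm)%s\n",
              d[1L], d[2L], d[3L], min(object@wavelengths),
              max(object@wavelengths),
              if (length(object@mask)) sprintf(", %d masked px", sum(object@mask)) else ""))
})

#' Write a cube to disk
#'
#' ENVI dialect writes \code{<path>.hdr} (text header with samples, lines,
#' bands, data type 4, interleave, byte order 0 and the wavelength list) and
#' \code{<path>.dat} (little-endian float32). Archive dialect writes a single
#' RDS file.
#'
#' @param cube a [HyperspectralCube-class].
#' @param path output path (without extension for ENVI).
#' @param dialect "envi" or "archive".
#' @param interleave band interleave for ENVI: "bsq", "bil" or "bip".
#' @return the path, invisibly.
#' @export
writeCube <- function(cube, path, dialect = c("envi", "archive"),
                      interleave = "bsq") {
  dialect <- match.arg(dialect)
  if (dialect == "archive") {
    saveRDS(list(data = cube@data, wavelengths = cube@wavelengths,
                 mask = cube@mask, metadata = cube@metadata),
            paste0(path, ".rds"))
    return(invisible(paste0(path, ".rds")))
  }
  d <- dim(cube@data)
  H <- d[1L]; W <- d[2L]; B <- d[3L]
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  hdr <- c("ENVI",
           paste("samples =", W), paste("lines =", H), paste("bands =", B),
           "data type = 4", paste("interleave =", interleave),
           "byte order = 0",
           paste0("wavelength = { ", paste(cube@wavelengths, collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  # cube@data is [line, sample, band]
  vals <- switch(interleave,
    bsq = as.numeric(aperm(cube@data, c(2L, 1L, 3L))),   # sample, line, band
    bil = as.numeric(aperm(cube@data, c(2L, 3L, 1L))),   # sample, band, line
    bip = as.numeric(aperm(cube@data, c(3L, 2L, 1L))))   # band, sample, line
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}

.parseEnviHeader <- function(hdr_path) {
  lines <- readLines(hdr_path)
  txt <- paste(lines, collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (!length(m)) stopDegenerate(paste("ENVI header missing", key))
    as.integer(sub(".*=\\s*", "", m))
  }
  getStr <- function(key, default = NULL) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[a-zA-Z]+"), txt))
    if (!length(m)) return(default)
    sub(".*=\\s*", "", m)
  }
  wl <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  wavelengths <- if (length(wl)) {
    as.numeric(strsplit(gsub(".*\\{|\\}", "", wl), ",")[[1L]])
  } else numeric(0)
  list(samples = getNum("samples"), lines = getNum("lines"),
       bands = getNum("bands"),
       interleave = tolower(getStr("interleave", "bsq")),
       data_type = getNum("data type"),
       wavelengths = wavelengths)
}

#' Read a cube from disk
#'
#' @param path path as given to [writeCube()] (without extension for ENVI,
#'   with or without \code{.rds} for archive).
#' @param dialect "auto" (default; picks by existing files), "envi" or
#'   "archive".
#' @return a [HyperspectralCube-class].
#' @export
readCube <- function(path, dialect = c("auto", "envi", "archive")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (file.exists(paste0(path, ".hdr"))) "envi" else "archive"
  }
  if (dialect == "archive") {
    p <- if (file.exists(path)) path else paste0(path, ".rds")
    if (!file.exists(p)) stopDegenerate(paste("cube archive not found:", path))
    obj <- readRDS(p)
    return(new("HyperspectralCube", data = obj$data,
               wavelengths = obj$wavelengths, mask = obj$mask,
               metadata = obj$metadata))
  }
  hdr_path <- paste0(path, ".hdr"); dat_path <- paste0(path, ".dat")
  if (!file.exists(hdr_path)) stopDegenerate(paste("ENVI header not found:", hdr_path))
  h <- .parseEnviHeader(hdr_path)
  if (h$data_type != 4L) stopDegenerate("only ENVI data type 4 (float32) is supported")
  if (length(h$wavelengths) && length(h$wavelengths) != h$bands) {
    stopDegenerate(sprintf("ENVI header: %d wavelengths but %d bands",
                           length(h$wavelengths), h$bands))
  }
  nvals <- h$samples * h$lines * h$bands
  fsize <- file.info(dat_path)$size
  if (is.na(fsize) || fsize != nvals * 4L) {
    stopDegenerate(sprintf(
      "ENVI payload size mismatch: header implies %d bytes, file has %s bytes",
      nvals * 4L, ifelse(is.na(fsize), "no", fsize)))
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = nvals, size = 4L, endian = "little")
  arr <- switch(h$interleave,
    bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3L, 1L, 2L)),
    bip = aperm(array(vals, c(h$bands, h$samples, h$lines)), c(3L, 2L, 1L)),
    stopDegenerate(paste("unknown interleave:", h$interleave)))
  wl <- if (length(h$wavelengths)) h$wavelengths else seq_len(h$bands)
  new("HyperspectralCube", data = arr, wavelengths = wl,
      mask = matrix(logical(0), 0L, 0L), metadata = list(source = path))
}

#' Write / read an integer label image as grayscale PNG
#'
#' Labels 0-255 (0 = background).
#'
#' @param labels integer matrix.
#' @param path PNG path.
#' @export
writeLabelPng <- function(labels, path) {
  if (max(labels) > 255L) stopDegenerate("label image supports at most 255 labels")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname writeLabelPng
#' @export
readLabelPng <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Write / read fitted maps (profile or parameter channels) as array archive
#'
#' @param maps 3D array with channel dimnames.
#' @param path file path (.rds).
#' @export
writeMaps <- function(maps, path) {
  saveRDS(maps, path)
  invisible(path)
}

#' @rdname writeMaps
#' @export
readMaps <- function(path) readRDS(path)
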