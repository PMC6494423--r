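#' Render localizations as a STORM-style image
#'
#' Each localization is depicted as a 2D Gaussian of unit integral. Pixel
#' values are the Gaussian mass falling inside each pixel (product of
#' normal CDF differences along x and y), so the image sum equals the
#' localization count up to the mass clipped at the borders. The pixel
#' grid is 0-based with pixel centers at `(i + 0.5) * pixel_nm`.
#'
#' @param table a [loc_table()].
#' @param pixel_nm pixel size in nm.
#' @param sigma_nm Gaussian standard deviation in nm.
#' @param origin_nm `c(x0, y0)` of the image's (0,0) pixel corner; default
#'   places a `4 * sigma` margin around the data.
#' @param dim_px optional `c(nrow, ncol)`; default fits the data plus
#'   margin.
#' @return numeric matrix (rows = y, columns = x) with attributes
#'   `pixel_nm` and `origin_nm`.
#' @export
render_storm <- function(table, pixel_nm, sigma_nm, origin_nm = NULL,
                         dim_px = NULL) {
  stopifnot(inherits(table, "loc_table"))
  if (!is_scalar_pos(pixel_nm) || !is_scalar_pos(sigma_nm))
    stop("pixel_nm and sigma_nm must be positive", call. = FALSE)
  if (nrow(table) == 0L) {
    warning("empty localization table: returning zero image")
    img <- matrix(0, 1L, 1L)
    attr(img, "pixel_nm") <- pixel_nm
    attr(img, "origin_nm") <- c(0, 0)
    return(img)
  }
  pad <- 4 * sigma_nm + pixel_nm
  if (is.null(origin_nm))
    origin_nm <- c(min(table$x_nm) - pad, min(table$y_nm) - pad)
  if (is.null(dim_px))
    dim_px <- c(ceiling((max(table$y_nm) + pad - origin_nm[2]) / pixel_nm),
                ceiling((max(table$x_nm) + pad - origin_nm[1]) / pixel_nm))
  nr <- dim_px[1]; nc <- dim_px[2]
  img <- matrix(0, nr, nc)
  # per-localization accumulation over a +/- 7 sigma pixel window
  w <- ceiling(7 * sigma_nm / pixel_nm)
  xe <- origin_nm[1] + (0:nc) * pixel_nm   # column edges
  ye <- origin_nm[2] + (0:nr) * pixel_nm   # row edges
  for (i in seq_len(nrow(table))) {
    x0 <- table$x_nm[i]; y0 <- table$y_nm[i]
    ci <- floor((x0 - origin_nm[1]) / pixel_nm) + 1
    ri <- floor((y0 - origin_nm[2]) / pixel_nm) + 1
    cs <- max(1, ci - w):min(nc, ci + w)
    rs <- max(1, ri - w):min(nr, ri + w)
    if (length(cs) == 0 || length(rs) == 0) next
    px <- diff(stats::pnorm(xe[c(cs, cs[length(cs)] + 1)], x0, sigma_nm))
    py <- diff(stats::pnorm(ye[c(rs, rs[length(rs)] + 1)], y0, sigma_nm))
    img[rs, cs] <- img[rs, cs] + py %o% px
  }
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "origin_nm") <- origin_nm
  img
}

#' Write a single-channel image as 16-bit TIFF
#'
#' Values are scaled by `scale` (default: fit the maximum to the 16-bit
#' range) and written as one 16-bit grayscale TIFF. The pixel size and
#' the scale factor are recorded in a plain-text `<path>.meta` sidecar
#' (`key: value` lines), the same convention the localization tables use.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param pixel_nm pixel size recorded in metadata; taken from the image
#'   attribute when absent.
#' @param scale multiplier applied before 16-bit quantization; `NULL` fits
#'   the data range.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, pixel_nm = attr(img, "pixel_nm"),
                        scale = NULL) {
  stopifnot(is.matrix(img))
  mx <- max(img)
  if (is.null(scale)) scale <- if (mx > 0) 65535 / mx else 1
  norm <- pmin(pmax(img * scale / 65535, 0), 1)
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  meta <- list(scale = scale)
  if (!is.null(pixel_nm)) meta$pixel_nm <- pixel_nm
  write_meta_sidecar(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a single-channel image written by [write_image()] (or any
#' grayscale TIFF/PNG)
#'
#' @param path TIFF or PNG file; a `<path>.meta` sidecar, when present,
#'   restores the stored unit scale and pixel size.
#' @return numeric matrix in the stored unit scale, with a `pixel_nm`
#'   attribute when the sidecar carries one.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("png package required to read PNG", call. = FALSE)
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
  } else {
    x <- tiff::readTIFF(path)
  }
  sc <- 1
  px <- NULL
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    kv <- regmatches(readLines(meta_path),
                     regexec("^([^:]+): (.*)$", readLines(meta_path)))
    keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else "",
                   character(1))
    vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else "",
                   character(1))
    if ("scale" %in% keys) sc <- as.numeric(vals[keys == "scale"][1])
    if ("pixel_nm" %in% keys) px <- as.numeric(vals[keys == "pixel_nm"][1])
  }
  m <- matrix(as.numeric(x), nrow(x), ncol(x)) * 65535 / sc
  if (!is.null(px)) attr(m, "pixel_nm") <- px
  m
}
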