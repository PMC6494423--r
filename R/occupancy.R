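#' Binarize an intensity image
#'
#' @param image numeric matrix.
#' @param method `"otsu"` (default), `"fixed"`, or `"percentile"`.
#' @param threshold intensity cutoff for `"fixed"`.
#' @param prob quantile in `[0, 1]` for `"percentile"`.
#' @return logical mask with attribute `threshold` (the cutoff used;
#'   pixels strictly above it are foreground).
#' @export
binarize <- function(image, method = c("otsu", "fixed", "percentile"),
                     threshold = NULL, prob = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), length(image) > 0)
  rng <- range(image)
  th <- switch(method,
    otsu = {
      if (rng[1] == rng[2])
        stop("degenerate threshold: constant image under Otsu",
             call. = FALSE)
      norm <- (image - rng[1]) / (rng[2] - rng[1])
      t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1),
                           levels = 256L)
      rng[1] + t01 * (rng[2] - rng[1])
    },
    fixed = {
      if (!is.numeric(threshold) || length(threshold) != 1L)
        stop("fixed method needs a threshold", call. = FALSE)
      threshold
    },
    percentile = quantile(image, prob, names = FALSE))
  mask <- image > th
  attr(mask, "threshold") <- th
  attr(mask, "method") <- method
  mask
}

#' Count 8-connected foreground components of a binary mask
#'
#' Skeletons are 8-connected objects, so component bookkeeping around
#' [to_strokes()] uses 8-connectivity (diagonal neighbors touch).
#'
#' @param mask logical matrix.
#' @return integer component count.
#' @export
n_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE
  if (!any(mask)) return(0L)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    # BFS flood fill over the 8-neighborhood
    queue <- p
    lab[p] <- nxt
    while (length(queue) > 0) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% nr + 1L
      cc <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        q2 <- (c2 - 1L) * nr + rr
        if (mask[q2] && lab[q2] == 0L) {
          lab[q2] <- nxt
          queue <- c(queue, q2)
        }
      }
    }
  }
  nxt
}

# Zhang-Suen topology-preserving thinning to a 1-px skeleton
zhang_suen_thin <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    out[rs, max(1, 1 + dc):min(nc, nc + dc)] <-
      x[rs - dr, max(1, 1 + dc):min(nc, nc + dc) - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors p2..p9 clockwise from north
      p2 <- sh(m, 1, 0);  p3 <- sh(m, 1, -1); p4 <- sh(m, 0, -1)
      p5 <- sh(m, -1, -1); p6 <- sh(m, -1, 0); p7 <- sh(m, -1, 1)
      p8 <- sh(m, 0, 1);  p9 <- sh(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nr - 1L), 2:(nc - 1L)]
}

#' Convert a binarized tubulin mask into axon strokes
#'
#' Topology-preserving Zhang-Suen thinning reduces each axon to a 1-pixel
#' skeleton; the skeleton is then dilated by a disc of radius
#' `dilate_px` so the tubulin-marked region is a thin corridor around the
#' axon midline rather than its full (diffraction-broadened) width. The
#' 8-connected component count is unchanged for well-separated objects.
#'
#' @param mask logical tubulin mask with at least one foreground pixel.
#' @param dilate_px stroke half-width in pixels (default 2).
#' @return logical stroke mask.
#' @export
to_strokes <- function(mask, dilate_px = 2L) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE   # coerce, keep dims
  if (!any(mask)) stop("empty mask: nothing to skeletonize", call. = FALSE)
  skel <- zhang_suen_thin(mask)
  if (dilate_px > 0) {
    brush_size <- 2L * as.integer(dilate_px) + 1L
    out <- EBImage::dilate(EBImage::Image(skel * 1),
                           EBImage::makeBrush(brush_size, "disc"))
    skel <- matrix(as.numeric(EBImage::imageData(out)) > 0.5,
                   nrow(mask), ncol(mask))
  }
  skel
}

#' Register the spectrin channel to the tubulin channel
#'
#' Translation model (default, suited to stage drift): exhaustive search
#' over integer pixel shifts within `search_px`, maximizing binary
#' overlap. Affine model: least-squares refinement of a full 2x3 affine
#' transform, initialized at the translation optimum, by Nelder-Mead on
#' the sum of squared differences under bilinear interpolation. The
#' returned transform maps moving-image coordinates into the fixed frame;
#' nothing is resampled in place.
#'
#' @param moving,fixed logical masks or numeric intensity images of equal
#'   size (moving = spectrin, fixed = tubulin). Sub-pixel refinement is
#'   most precise on intensity images; binary masks quantize sub-pixel
#'   shifts.
#' @param model `"translation"` or `"affine"`.
#' @param search_px half-width of the integer search (default 15).
#' @return object of class `mps_transform`: list with `matrix` (2x3:
#'   `[a11 a12 tx; a21 a22 ty]` acting on (x = col, y = row) pixel
#'   coordinates), `model`, `status` (`"ok"` or `"failed"`), `score`.
#' @export
register_channels <- function(moving, fixed,
                              model = c("translation", "affine"),
                              search_px = 15L) {
  model <- match.arg(model)
  stopifnot(is.matrix(moving), is.matrix(fixed),
            all(dim(moving) == dim(fixed)))
  mv <- moving * 1; fx <- fixed * 1
  if (sum(mv) == 0 || sum(fx) == 0)
    stop("registration needs nonempty masks", call. = FALSE)
  best <- c(0L, 0L); best_score <- -Inf
  for (dy in -search_px:search_px) {
    for (dx in -search_px:search_px) {
      s <- shift_overlap(mv, fx, dy, dx)
      if (s > best_score) { best_score <- s; best <- c(dx, dy) }
    }
  }
  if (best_score <= 0)
    return(structure(list(matrix = matrix(c(1, 0, 0, 1, 0, 0), 2, 3),
                          model = model, status = "failed", score = 0),
                     class = "mps_transform"))
  tf <- matrix(c(1, 0, 0, 1, best), 2, 3)   # tx, ty = integer shift
  if (model == "affine") {
    fit <- gauss_newton_affine(mv, fx, init_shift = best)
    tf <- fit$matrix
    best_score <- -fit$ssd
  }
  structure(list(matrix = tf, model = model, status = "ok",
                 score = best_score),
            class = "mps_transform")
}

# Least-squares affine refinement (inverse-compositional flavor):
# optimize the sampling map s(x) = B (x - ctr) + ctr + c minimizing
# sum((mv(s(x)) - fx(x))^2) by damped Gauss-Newton on (B, c), image
# gradients taken by central differences at the sampled positions.
# Returns the forward 2x3 matrix (A = B^-1, t = ctr - B^-1 (ctr + c)).
gauss_newton_affine <- function(mv, fx, init_shift = c(0, 0),
                                max_iter = 50, tol = 1e-8) {
  nr <- nrow(mv); nc <- ncol(mv)
  ctr <- c((nc + 1) / 2, (nr + 1) / 2)
  xs0 <- rep(seq_len(nc), each = nr) - ctr[1]
  ys0 <- rep(seq_len(nr), nc) - ctr[2]
  fxv <- as.numeric(fx)
  sample_bilinear <- function(xx, yy) {
    x0 <- floor(xx); y0 <- floor(yy)
    fxr <- xx - x0; fyr <- yy - y0
    val <- function(r, cc) {
      ok <- r >= 1 & r <= nr & cc >= 1 & cc <= nc
      out <- numeric(length(r))
      out[ok] <- mv[cbind(r[ok], cc[ok])]
      out
    }
    (1 - fxr) * (1 - fyr) * val(y0, x0) +
      fxr * (1 - fyr) * val(y0, x0 + 1) +
      (1 - fxr) * fyr * val(y0 + 1, x0) +
      fxr * fyr * val(y0 + 1, x0 + 1)
  }
  # p = (B11, B12, B21, B22, c1, c2); moving toward fixed needs the
  # sampling map to undo the integer shift
  p <- c(1, 0, 0, 1, -init_shift[1], -init_shift[2])
  ssd_prev <- Inf
  for (it in seq_len(max_iter)) {
    sx <- p[1] * xs0 + p[2] * ys0 + ctr[1] + p[5]
    sy <- p[3] * xs0 + p[4] * ys0 + ctr[2] + p[6]
    w <- sample_bilinear(sx, sy)
    r <- w - fxv
    ssd <- sum(r^2)
    if (abs(ssd_prev - ssd) < tol * (ssd + 1e-12)) break
    ssd_prev <- ssd
    h <- 0.5
    gx <- (sample_bilinear(sx + h, sy) - sample_bilinear(sx - h, sy)) / (2 * h)
    gy <- (sample_bilinear(sx, sy + h) - sample_bilinear(sx, sy - h)) / (2 * h)
    J <- cbind(gx * xs0, gx * ys0, gy * xs0, gy * ys0, gx, gy)
    JtJ <- crossprod(J)
    diag(JtJ) <- diag(JtJ) * (1 + 1e-6) + 1e-9
    step <- tryCatch(solve(JtJ, crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    p <- p - as.numeric(step)
  }
  B <- matrix(p[1:4], 2, 2, byrow = TRUE)
  cshift <- p[5:6]
  A <- solve(B)
  t <- ctr - A %*% (ctr + cshift)
  list(matrix = cbind(A, t), ssd = ssd_prev)
}

# overlap of moving shifted by (dy, dx) with fixed
shift_overlap <- function(mv, fx, dy, dx) {
  nr <- nrow(mv); nc <- ncol(mv)
  r1 <- max(1, 1 + dy):min(nr, nr + dy)
  c1 <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(r1) == 0 || length(c1) == 0) return(0)
  sum(mv[r1 - dy, c1 - dx] * fx[r1, c1])
}

#' Apply a registration transform to an image
#'
#' Resamples `img` into the fixed frame by bilinear interpolation: the
#' output at fixed-frame pixel (x, y) is `img` sampled at
#' `A^{-1} ((x, y) - t)`, with out-of-range samples 0.
#'
#' @param img numeric or logical matrix.
#' @param tf an `mps_transform` from [register_channels()].
#' @return numeric matrix of the same size.
#' @export
apply_transform <- function(img, tf) {
  stopifnot(inherits(tf, "mps_transform"))
  warp_affine(img * 1, tf$matrix)
}

# bilinear warp; p is the 2x3 matrix giving the sampling coordinates
# (xs, ys) = A (x, y) + t for output pixel (x = col, y = row) when used by
# the forward-parameter objective (register), i.e. warp(mv, p) compares to
# fixed after moving each pixel by p. With inverse_given the matrix is
# applied as the sampling map directly.
warp_affine <- function(img, p, inverse_given = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  xy <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), nc))
  if (inverse_given) {
    xs <- p[1, 1] * xy[, 1] + p[1, 2] * xy[, 2] + p[1, 3]
    ys <- p[2, 1] * xy[, 1] + p[2, 2] * xy[, 2] + p[2, 3]
  } else {
    # forward map: output(x,y) gathers from the point that lands on (x,y);
    # for the near-identity transforms optimized here, invert exactly
    A <- p[, 1:2]; t <- p[, 3]
    Ainv <- solve(A)
    rel <- cbind(xy[, 1] - t[1], xy[, 2] - t[2])
    xs <- Ainv[1, 1] * rel[, 1] + Ainv[1, 2] * rel[, 2]
    ys <- Ainv[2, 1] * rel[, 1] + Ainv[2, 2] * rel[, 2]
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v <- (1 - fx) * (1 - fy) * val(y0, x0) +
       fx * (1 - fy) * val(y0, x0 + 1) +
       (1 - fx) * fy * val(y0 + 1, x0) +
       fx * fy * val(y0 + 1, x0 + 1)
  matrix(v, nr, nc)
}

#' Occupancy analysis configuration
#'
#' @param binarize_method,threshold,prob passed to [binarize()].
#' @param stroke_dilate_px stroke half-width, see [to_strokes()].
#' @param register_model `"translation"` (default) or `"affine"`.
#' @param search_px integer shift search half-width.
#' @return list of class `occupancy_config`.
#' @export
occupancy_config <- function(binarize_method = "otsu", threshold = NULL,
                             prob = 0.5, stroke_dilate_px = 2L,
                             register_model = "translation",
                             search_px = 10L) {
  structure(list(binarize_method = binarize_method, threshold = threshold,
                 prob = prob, stroke_dilate_px = stroke_dilate_px,
                 register_model = register_model, search_px = search_px),
            class = "occupancy_config")
}

#' Spectrin occupancy of tubulin-marked axon strokes
#'
#' Both channels are binarized; the tubulin mask is skeletonized into
#' strokes; the spectrin mask is registered to the tubulin mask and
#' resampled; spectrin signal outside the strokes is ignored. The
#' occupancy ratio is the fraction of stroke pixels covered by spectrin
#' signal.
#'
#' @param pair an [image_pair()].
#' @param cfg an [occupancy_config()].
#' @return object of class `occupancy_result`: list with `ratio`,
#'   `stroke_pixels`, `covered_pixels`, `transform` (2x3 matrix),
#'   `thresholds` (named, per channel), `flags` (character; e.g.
#'   `"empty_spectrin"`, `"registration_failed"`).
#' @export
occupancy_ratio <- function(pair, cfg = occupancy_config()) {
  stopifnot(inherits(pair, "image_pair"))
  tub_mask <- binarize(pair$tubulin, cfg$binarize_method,
                       threshold = cfg$threshold, prob = cfg$prob)
  spec_mask <- binarize(pair$spectrin, cfg$binarize_method,
                        threshold = cfg$threshold, prob = cfg$prob)
  strokes <- to_strokes(tub_mask, cfg$stroke_dilate_px)
  stroke_px <- sum(strokes)
  if (stroke_px == 0) stop("no stroke pixels", call. = FALSE)
  flags <- character(0)
  identity_tf <- structure(list(matrix = cbind(diag(2), c(0, 0)),
                                model = cfg$register_model, status = "ok",
                                score = NA_real_),
                           class = "mps_transform")
  if (!any(spec_mask)) {
    flags <- c(flags, "empty_spectrin")
    tf <- identity_tf
    covered <- 0L
  } else {
    tf <- register_channels(spec_mask, tub_mask,
                            model = cfg$register_model,
                            search_px = cfg$search_px)
    if (tf$status == "failed") {
      flags <- c(flags, "registration_failed")
      tf <- identity_tf
    }
    spec_al <- apply_transform(spec_mask, tf) > 0.5
    covered <- sum(spec_al & strokes)
  }
  structure(list(ratio = covered / stroke_px,
                 stroke_pixels = as.integer(stroke_px),
                 covered_pixels = as.integer(covered),
                 transform = tf$matrix,
                 thresholds = c(tubulin = attr(tub_mask, "threshold"),
                                spectrin = attr(spec_mask, "threshold")),
                 flags = flags),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy_result: ratio %.3f (%d / %d stroke px)%s\n",
              x$ratio, x$covered_pixels, x$stroke_pixels,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
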