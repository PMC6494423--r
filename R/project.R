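#' Define the axon axis used for 1D projection
#'
#' The periodicity statistic needs each localization's position *along*
#' the axon. For straight stretches the first principal axis of the (x, y)
#' cloud is used; for curved axons a user-supplied polyline backbone can be
#' traced instead, with positions measured as arc length.
#'
#' @param mode `"principal-axis"` (default) or `"polyline"`.
#' @param polyline matrix or data.frame with two columns (x, y in nm) and
#'   at least two rows; required when `mode = "polyline"`.
#' @return object of class `axis_spec`.
#' @export
axis_spec <- function(mode = c("principal-axis", "polyline"),
                      polyline = NULL) {
  mode <- match.arg(mode)
  if (mode == "polyline") {
    if (is.null(polyline)) stop("polyline mode needs a polyline",
                                call. = FALSE)
    polyline <- as.matrix(polyline)
    stopifnot(ncol(polyline) == 2, nrow(polyline) >= 2)
    seg_len <- sqrt(rowSums(diff(polyline)^2))
    if (sum(seg_len) <= 0)
      stop("polyline must have positive total length", call. = FALSE)
  }
  structure(list(mode = mode, polyline = polyline), class = "axis_spec")
}

#' Project localizations onto the axon axis
#'
#' Principal-axis mode: positions are the projections of the centered
#' (x, y) cloud onto its first principal axis, with the axis sign fixed so
#' it correlates positively with +x (ties broken toward +y) and the origin
#' shifted so the smallest retained position is 0. Polyline mode: each
#' localization maps to the arc length of the nearest point on the
#' polyline. In both modes, localizations farther than `corridor_nm` from
#' the axis are dropped and counted. z is ignored.
#'
#' @param table a [loc_table()] with at least 2 rows.
#' @param axis an [axis_spec()].
#' @param corridor_nm half-width (nm) of the corridor around the axis
#'   within which localizations are retained. The 500 nm default covers the
#'   700 nm axon-diameter selection ceiling with margin.
#' @return object of class `positions1d`: list with `s_nm` (sorted axial
#'   positions), `extent_nm = c(0, L)`, and `n_dropped`.
#' @export
project_to_axis <- function(table, axis = axis_spec(), corridor_nm = 500) {
  stopifnot(inherits(table, "loc_table"), inherits(axis, "axis_spec"))
  if (!is_scalar_pos(corridor_nm))
    stop("corridor_nm must be positive", call. = FALSE)
  if (nrow(table) < 2)
    stop("need at least 2 localizations to define an axis", call. = FALSE)
  xy <- cbind(table$x_nm, table$y_nm)
  if (axis$mode == "principal-axis") {
    ctr <- colMeans(xy)
    xc <- sweep(xy, 2L, ctr)
    cv <- crossprod(xc) / (nrow(xc) - 1L)
    if (sum(diag(cv)) <= 0)
      stop("degenerate cloud: zero variance, no principal axis",
           call. = FALSE)
    e <- eigen(cv, symmetric = TRUE)
    v <- e$vectors[, 1L]
    # sign convention: positive correlation with +x, ties toward +y
    if (v[1L] < 0 || (v[1L] == 0 && v[2L] < 0)) v <- -v
    s_raw <- xc %*% v
    perp <- abs(xc %*% c(-v[2L], v[1L]))
    keep <- perp <= corridor_nm
  } else {
    pp <- project_polyline(xy, axis$polyline)
    s_raw <- pp$s
    keep <- pp$dist <= corridor_nm
  }
  n_dropped <- sum(!keep)
  s <- as.numeric(s_raw[keep])
  if (length(s) == 0)
    stop("empty projection: all localizations outside the axis corridor",
         call. = FALSE)
  s <- sort(s - min(s))
  structure(list(s_nm = s, extent_nm = c(0, max(s)), n_dropped = n_dropped),
            class = "positions1d")
}

# nearest-point arc length and distance to a polyline, per point
project_polyline <- function(xy, poly) {
  nseg <- nrow(poly) - 1L
  seg_vec <- diff(poly)
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum0 <- c(0, cumsum(seg_len))
  n <- nrow(xy)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  for (j in seq_len(nseg)) {
    if (seg_len[j] == 0) next
    a <- poly[j, ]
    v <- seg_vec[j, ]
    t <- ((xy[, 1] - a[1]) * v[1] + (xy[, 2] - a[2]) * v[2]) / seg_len[j]^2
    t <- pmin(pmax(t, 0), 1)
    dx <- xy[, 1] - (a[1] + t * v[1])
    dy <- xy[, 2] - (a[2] + t * v[2])
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cum0[j] + t[upd] * seg_len[j]
  }
  list(s = best_s, dist = sqrt(best_d2))
}

#' @export
print.positions1d <- function(x, ...) {
  cat(sprintf("positions1d: %d localizations over %.0f nm (%d dropped)\n",
              length(x$s_nm), diff(x$extent_nm), x$n_dropped))
  invisible(x)
}
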