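#' Configuration of the autocorrelation periodicity analysis
#'
#' Holds the numeric choices of the amplitude statistic. Defaults follow
#' the standard MPS quantification: 10 nm histogram bins, 1900 nm adjacent
#' non-overlapping segments (ten lattice periods), the maximum searched
#' around the 190 nm lattice period in `[150, 230]` nm and the minimum
#' around the 95 nm half-period in `[50, 150]` nm.
#'
#' @param bin_nm histogram bin width, nm.
#' @param segment_nm segment length, nm; must be an integer multiple of
#'   `bin_nm`.
#' @param max_window_nm closed lag interval searched for the local maximum.
#' @param min_window_nm closed lag interval searched for the local minimum.
#' @param min_locs_per_segment segments with fewer localizations are
#'   dropped (near-empty segments carry no lattice signal, only shot
#'   noise).
#' @param max_lag_nm largest lag computed and reported.
#' @param per_segment_amplitude if `TRUE`, the axon amplitude is the mean
#'   of per-segment amplitudes instead of the amplitude of the averaged
#'   curve (non-default variant).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(bin_nm = 10, segment_nm = 1900,
                            max_window_nm = c(150, 230),
                            min_window_nm = c(50, 150),
                            min_locs_per_segment = 50,
                            max_lag_nm = 600,
                            per_segment_amplitude = FALSE) {
  cfg <- list(bin_nm = bin_nm, segment_nm = segment_nm,
              max_window_nm = as.numeric(max_window_nm),
              min_window_nm = as.numeric(min_window_nm),
              min_locs_per_segment = min_locs_per_segment,
              max_lag_nm = max_lag_nm,
              per_segment_amplitude = isTRUE(per_segment_amplitude))
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  if (!is_scalar_pos(cfg$bin_nm)) stop("bin_nm must be positive",
                                       call. = FALSE)
  if (!is_scalar_pos(cfg$segment_nm))
    stop("segment_nm must be positive", call. = FALSE)
  ratio <- cfg$segment_nm / cfg$bin_nm
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("segment_nm must be an integer multiple of bin_nm", call. = FALSE)
  for (wname in c("max_window_nm", "min_window_nm")) {
    w <- cfg[[wname]]
    if (length(w) != 2 || w[1] > w[2] || w[1] <= 0 || w[2] > cfg$max_lag_nm)
      stop(wname, " must be an interval within (0, max_lag_nm]",
           call. = FALSE)
  }
  if (!is_scalar_nonneg(cfg$min_locs_per_segment))
    stop("min_locs_per_segment must be >= 0", call. = FALSE)
  if (!is_scalar_pos(cfg$max_lag_nm))
    stop("max_lag_nm must be positive", call. = FALSE)
  invisible(cfg)
}

#' Bin 1D positions into a localization profile
#'
#' Histogram of the projected axial positions with half-open bins
#' `[origin + k*bin, origin + (k+1)*bin)` starting at the projection
#' origin (0). The sum of counts equals the number of positions.
#'
#' @param pos a [project_to_axis()] result (`positions1d`).
#' @param cfg an [analysis_config()].
#' @return object of class `profile1d`: list with integer `counts`,
#'   `bin_nm`, `origin_nm`.
#' @export
bin_profile <- function(pos, cfg = analysis_config()) {
  stopifnot(inherits(pos, "positions1d"))
  validate_analysis_config(cfg)
  s <- pos$s_nm
  if (length(s) == 0) stop("no positions to bin", call. = FALSE)
  idx <- floor(s / cfg$bin_nm) + 1L
  counts <- tabulate(idx, nbins = max(idx))
  structure(list(counts = as.integer(counts), bin_nm = cfg$bin_nm,
                 origin_nm = 0), class = "profile1d")
}

#' Cut a profile into adjacent non-overlapping segments
#'
#' Consecutive windows of `segment_nm / bin_nm` bins starting at the
#' profile origin; a trailing remainder shorter than one segment is
#' discarded. Segments whose total count falls below
#' `min_locs_per_segment` are dropped and counted.
#'
#' @param profile a [bin_profile()] result.
#' @param cfg an [analysis_config()].
#' @return list with `segments` (list of `profile1d`), `n_dropped`
#'   (low-count segments), and `status` (`"ok"` or `"too_short"`).
#' @export
segment_profile <- function(profile, cfg = analysis_config()) {
  stopifnot(inherits(profile, "profile1d"))
  validate_analysis_config(cfg)
  bins_per <- as.integer(round(cfg$segment_nm / cfg$bin_nm))
  n_total <- length(profile$counts) %/% bins_per
  if (n_total == 0L)
    return(list(segments = list(), n_dropped = 0L, status = "too_short"))
  segs <- vector("list", n_total)
  keep <- logical(n_total)
  for (k in seq_len(n_total)) {
    cs <- profile$counts[((k - 1L) * bins_per + 1L):(k * bins_per)]
    keep[k] <- sum(cs) >= cfg$min_locs_per_segment
    segs[[k]] <- structure(
      list(counts = cs, bin_nm = profile$bin_nm,
           origin_nm = profile$origin_nm + (k - 1L) * cfg$segment_nm),
      class = "profile1d")
  }
  list(segments = segs[keep], n_dropped = sum(!keep), status = "ok")
}

#' Normalized 1D spatial autocorrelation of one segment
#'
#' Mean-subtracted, variance-normalized (Pearson-style) autocorrelation of
#' the binned counts: with `d = counts - mean(counts)`,
#' `acf[k] = sum(d[i] * d[i+k]) / sum(d^2)`, the numerator summed over the
#' overlapping range and the denominator taken from the full segment
#' (biased estimator). `acf[0] = 1` by construction; the curve is
#' insensitive to multiplying all counts by a positive constant, so axons
#' of different labeling density are comparable.
#'
#' @param segment a `profile1d` segment.
#' @param cfg an [analysis_config()]; lags run from 0 to `max_lag_nm` in
#'   steps of `bin_nm`.
#' @return numeric vector of autocorrelation values with attribute
#'   `lags_nm`.
#' @export
segment_acf <- function(segment, cfg = analysis_config()) {
  stopifnot(inherits(segment, "profile1d"))
  validate_analysis_config(cfg)
  c0 <- as.numeric(segment$counts)
  n <- length(c0)
  d <- c0 - mean(c0)
  denom <- sum(d^2)
  if (denom == 0)
    stop("degenerate segment: zero count variance", call. = FALSE)
  max_k <- min(n - 1L, as.integer(floor(cfg$max_lag_nm / segment$bin_nm)))
  acf <- vapply(0:max_k, function(k) {
    sum(d[seq_len(n - k)] * d[seq_len(n - k) + k]) / denom
  }, numeric(1))
  attr(acf, "lags_nm") <- (0:max_k) * segment$bin_nm
  acf
}

#' Average autocorrelation curves over segments
#'
#' Unweighted arithmetic mean per lag; all curves must share one lag grid.
#'
#' @param curves list of [segment_acf()] results.
#' @return averaged curve with the common `lags_nm` attribute.
#' @export
average_acf <- function(curves) {
  if (length(curves) == 0) stop("no curves to average", call. = FALSE)
  lags <- attr(curves[[1]], "lags_nm")
  for (cv in curves) {
    lv <- attr(cv, "lags_nm")
    if (length(cv) != length(curves[[1]]) ||
        (!is.null(lags) && !isTRUE(all.equal(lv, lags))))
      stop("mismatched lag grids", call. = FALSE)
  }
  m <- rowMeans(do.call(cbind, lapply(curves, as.numeric)))
  attr(m, "lags_nm") <- lags
  m
}

# pick the extremum lag inside a window; ties toward the window center,
# then toward the smaller lag
pick_extremum <- function(vals, lags, window, what = c("max", "min")) {
  what <- match.arg(what)
  in_w <- lags >= window[1] & lags <= window[2]
  if (!any(in_w))
    stop("config error: no lag falls inside the search window",
         call. = FALSE)
  v <- vals[in_w]; l <- lags[in_w]
  target <- if (what == "max") max(v) else min(v)
  cand <- which(v == target)
  center <- mean(window)
  cand <- cand[order(abs(l[cand] - center), l[cand])]
  list(lag = l[cand[1]], value = v[cand[1]])
}

#' Autocorrelation amplitude of an averaged curve
#'
#' The periodicity score: the curve's maximum within the 190 nm window
#' minus its minimum within the 95 nm half-period window. Extrema are
#' window-global; exact ties resolve toward the lag nearest the window
#' center, then toward the smaller lag. Negative amplitudes are reported
#' as-is.
#'
#' @param acf_mean averaged curve from [average_acf()] (or a single
#'   [segment_acf()] curve) carrying a `lags_nm` attribute.
#' @param cfg an [analysis_config()].
#' @return list with `amplitude`, `lag_max_nm`, `lag_min_nm`.
#' @export
acf_amplitude <- function(acf_mean, cfg = analysis_config()) {
  validate_analysis_config(cfg)
  lags <- attr(acf_mean, "lags_nm")
  if (is.null(lags)) stop("curve lacks a lags_nm attribute", call. = FALSE)
  if (max(lags) < cfg$max_window_nm[2] || max(lags) < cfg$min_window_nm[2])
    stop("config error: curve does not cover the search windows",
         call. = FALSE)
  mx <- pick_extremum(acf_mean, lags, cfg$max_window_nm, "max")
  mn <- pick_extremum(acf_mean, lags, cfg$min_window_nm, "min")
  list(amplitude = mx$value - mn$value,
       lag_max_nm = mx$lag, lag_min_nm = mn$lag)
}

#' Midpoint convention for the half-period minimum lag
#'
#' On a 10 nm lag grid the 95 nm half-period falls between lags; a clean
#' lattice therefore shows its two lowest, symmetric curve values at the
#' two lags bracketing the half-period. This reporting helper finds the
#' adjacent lag pair with the smallest summed curve value inside the
#' minimum window and returns the pair's midpoint. It is a reporting
#' convention only; [acf_amplitude()] always uses the on-grid minimum.
#'
#' @param acf_mean averaged curve with `lags_nm` attribute.
#' @param cfg an [analysis_config()].
#' @return midpoint lag in nm.
#' @export
lag_min_midpoint <- function(acf_mean, cfg = analysis_config()) {
  validate_analysis_config(cfg)
  lags <- attr(acf_mean, "lags_nm")
  if (is.null(lags)) stop("curve lacks a lags_nm attribute", call. = FALSE)
  in_w <- which(lags >= cfg$min_window_nm[1] & lags <= cfg$min_window_nm[2])
  if (length(in_w) < 2)
    stop("config error: fewer than two lags inside the minimum window",
         call. = FALSE)
  pair_sum <- acf_mean[in_w[-length(in_w)]] + acf_mean[in_w[-1]]
  j <- which.min(pair_sum)
  (lags[in_w[j]] + lags[in_w[j + 1]]) / 2
}

#' Quantify MPS periodicity of one axon
#'
#' Full statistic: project the localizations onto the axon axis, bin at
#' `bin_nm`, cut into `segment_nm` segments, compute each retained
#' segment's normalized autocorrelation, average the curves, and take the
#' amplitude. Axons yielding no usable segment (too short, too sparse, or
#' fewer than 2 localizations) are flagged `"unquantifiable"` rather than
#' scored.
#'
#' @param table a [loc_table()].
#' @param axis an [axis_spec()].
#' @param cfg an [analysis_config()].
#' @param corridor_nm corridor half-width passed to [project_to_axis()].
#' @return object of class `acf_result`: list with `status`
#'   (`"ok"`/`"unquantifiable"`), `lags_nm`, `acf_segments` (matrix, one
#'   column per retained segment), `acf_mean`, `amplitude`, `lag_max_nm`,
#'   `lag_min_nm`, `n_segments_used`, `n_segments_dropped`, `n_locs`,
#'   `n_dropped_projection`, `axon_id`.
#' @examples
#' tab <- simulate_axon(lattice_params(axon_length_um = 5.7), seed = 2)
#' res <- quantify_axon(tab)
#' res$amplitude
#' @export
quantify_axon <- function(table, axis = axis_spec(),
                          cfg = analysis_config(), corridor_nm = 500) {
  stopifnot(inherits(table, "loc_table"))
  validate_analysis_config(cfg)
  base <- list(status = "unquantifiable", lags_nm = NULL,
               acf_segments = NULL, acf_mean = NULL, amplitude = NA_real_,
               lag_max_nm = NA_real_, lag_min_nm = NA_real_,
               n_segments_used = 0L, n_segments_dropped = 0L,
               n_locs = nrow(table), n_dropped_projection = NA_integer_,
               axon_id = if (nrow(table) > 0) table$axon_id[1] else NA_character_)
  if (nrow(table) == 0L) stop("empty localization table", call. = FALSE)
  if (nrow(table) < 2L) return(structure(base, class = "acf_result"))
  pos <- tryCatch(project_to_axis(table, axis, corridor_nm),
                  error = function(e) NULL)
  if (is.null(pos)) return(structure(base, class = "acf_result"))
  base$n_dropped_projection <- pos$n_dropped
  prof <- bin_profile(pos, cfg)
  seg <- segment_profile(prof, cfg)
  base$n_segments_dropped <- seg$n_dropped
  if (length(seg$segments) == 0L) return(structure(base, class = "acf_result"))
  curves <- list()
  for (sg in seg$segments) {
    cv <- tryCatch(segment_acf(sg, cfg), error = function(e) NULL)
    if (is.null(cv)) base$n_segments_dropped <- base$n_segments_dropped + 1L
    else curves[[length(curves) + 1L]] <- cv
  }
  if (length(curves) == 0L) return(structure(base, class = "acf_result"))
  acf_mean <- average_acf(curves)
  amp <- acf_amplitude(acf_mean, cfg)
  if (cfg$per_segment_amplitude) {
    per_seg <- vapply(curves, function(cv)
      acf_amplitude(cv, cfg)$amplitude, numeric(1))
    amp$amplitude <- mean(per_seg)
  }
  structure(list(status = "ok", lags_nm = attr(acf_mean, "lags_nm"),
                 acf_segments = do.call(cbind, lapply(curves, as.numeric)),
                 acf_mean = as.numeric(acf_mean),
                 amplitude = amp$amplitude, lag_max_nm = amp$lag_max_nm,
                 lag_min_nm = amp$lag_min_nm,
                 n_segments_used = length(curves),
                 n_segments_dropped = base$n_segments_dropped,
                 n_locs = base$n_locs,
                 n_dropped_projection = base$n_dropped_projection,
                 axon_id = base$axon_id),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("acf_result [%s]: unquantifiable (%d localizations)\n",
                x$axon_id, x$n_locs))
    return(invisible(x))
  }
  cat(sprintf("acf_result [%s]: amplitude %.3f (max at %g nm, min at %g nm)\n",
              x$axon_id, x$amplitude, x$lag_max_nm, x$lag_min_nm))
  cat(sprintf("  %d localizations, %d segments used, %d dropped\n",
              x$n_locs, x$n_segments_used, x$n_segments_dropped))
  invisible(x)
}

#' Extract the averaged autocorrelation curve from an `acf_result`
#'
#' Returns `res$acf_mean` with its `lags_nm` attribute restored, ready for
#' [acf_amplitude()] or [lag_min_midpoint()].
#'
#' @param res an `acf_result` from [quantify_axon()].
#' @return numeric curve with `lags_nm` attribute.
#' @export
result_curve <- function(res) {
  m <- res$acf_mean
  attr(m, "lags_nm") <- res$lags_nm
  m
}
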