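#' Simulate STORM localizations of spectrin along one axon
#'
#' Draws `N ~ Poisson(density_per_um * axon_length_um)` localizations.
#' Each complete ring `k` sits at `k * period + phase + N(0, jitter)`,
#' the phase displacement drawn once per ring. With probability
#' `periodic_fraction` a localization belongs to the comb: it picks a ring
#' uniformly and lands at the ring center plus an independent
#' `N(0, ring_width)` axial label spread; otherwise its axial coordinate
#' is uniform on `[0, length)`. Transverse (y) and z coordinates are
#' uniform across the axon diameter. Independent Gaussian localization
#' error (`loc_precision_xy_nm` on x and y, `loc_precision_z_nm` on z) is
#' added to every coordinate. Output is deterministic given
#' `(params, seed)`.
#'
#' @param params a [lattice_params()] object.
#' @param seed integer seed.
#' @param axon_id identifier stored with every row.
#' @return a [loc_table()] with columns `axon_id, x_nm, y_nm, z_nm` and
#'   metadata recording `params` and `seed`.
#' @examples
#' tab <- simulate_axon(lattice_params(axon_length_um = 2), seed = 7)
#' nrow(tab)
#' @export
simulate_axon <- function(params, seed, axon_id = "axon") {
  stopifnot(inherits(params, "lattice_params"))
  validate_lattice_params(params)
  length_nm <- params$axon_length_um * 1000
  nr <- n_rings(params)
  if (nr < 1L)
    stop("axon shorter than one lattice period: no complete ring",
         call. = FALSE)
  half_d <- params$axon_diameter_nm / 2
  with_seed(seed, {
    n <- rpois(1L, params$density_per_um * params$axon_length_um)
    ring_centers <- (seq_len(nr) - 1L) * params$period_nm + params$phase_nm
    if (params$jitter_nm > 0)
      ring_centers <- ring_centers + rnorm(nr, 0, params$jitter_nm)
    on_comb <- runif(n) < params$periodic_fraction
    x <- numeric(n)
    npc <- sum(on_comb)
    if (npc > 0) {
      k <- sample.int(nr, npc, replace = TRUE)
      x[on_comb] <- ring_centers[k]
      if (params$ring_width_nm > 0)
        x[on_comb] <- x[on_comb] + rnorm(npc, 0, params$ring_width_nm)
    }
    if (npc < n)
      x[!on_comb] <- runif(n - npc, 0, length_nm)
    y <- runif(n, -half_d, half_d)
    z <- runif(n, -half_d, half_d)
    if (params$loc_precision_xy_nm > 0) {
      x <- x + rnorm(n, 0, params$loc_precision_xy_nm)
      y <- y + rnorm(n, 0, params$loc_precision_xy_nm)
    }
    if (params$loc_precision_z_nm > 0)
      z <- z + rnorm(n, 0, params$loc_precision_z_nm)
    loc_table(x_nm = x, y_nm = y, z_nm = z, axon_id = axon_id,
              meta = list(params = unclass(params), seed = seed))
  })
}

#' Simulate a cohort of axons for one condition
#'
#' Per-axon seeds are derived from `spec$seed` with [derive_seeds()], so the
#' cohort is reproducible and independent of simulation order.
#'
#' @param spec a [condition_spec()].
#' @return list with `tables` (one [loc_table()] per axon, axon ids
#'   `<label>_ax<i>`) and `truth` (data.frame of per-axon seeds and the
#'   generative parameters).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  seeds <- derive_seeds(spec$seed, spec$n_axons)
  ids <- sprintf("%s_ax%03d", spec$label, seq_len(spec$n_axons))
  tables <- lapply(seq_len(spec$n_axons), function(i)
    simulate_axon(spec$params, seeds[i], axon_id = ids[i]))
  truth <- data.frame(axon_id = ids, label = spec$label, seed = seeds,
                      as.data.frame(unclass(spec$params)),
                      stringsAsFactors = FALSE)
  list(tables = tables, truth = truth)
}

#' Trophic-deprivation time-course preset
#'
#' A four-condition cohort design emulating progressive MPS disassembly
#' after NGF withdrawal: the periodic fraction declines from 1.0 (NGF,
#' intact lattice) to 0.2 (12 h of trophic deprivation, mostly disordered)
#' while all other lattice parameters are held fixed. Per-condition seeds
#' are derived from the top-level seed.
#'
#' @param n_axons axons per condition (default 20).
#' @param seed top-level seed.
#' @param labels condition labels, one per time point.
#' @param periodic_fractions comb fraction per condition, same length as
#'   `labels`.
#' @param params base [lattice_params()]; its `periodic_fraction` is
#'   overridden per condition.
#' @return list of [condition_spec()] objects.
#' @export
td_timecourse_preset <- function(n_axons = 20, seed = 1L,
                                 labels = c("NGF", "TD_3h", "TD_6h", "TD_12h"),
                                 periodic_fractions = c(1.0, 0.75, 0.45, 0.2),
                                 params = lattice_params()) {
  stopifnot(length(labels) == length(periodic_fractions),
            !anyDuplicated(labels))
  cond_seeds <- derive_seeds(seed, length(labels))
  lapply(seq_along(labels), function(i) {
    p <- params
    p$periodic_fraction <- periodic_fractions[i]
    validate_lattice_params(p)
    condition_spec(labels[i], n_axons, p, seed = cond_seeds[i])
  })
}

#' Simulate a registered two-channel wide-field image pair
#'
#' Renders the axon as a straight horizontal ribbon of the given diameter.
#' The tubulin channel carries signal along the whole ribbon; the spectrin
#' channel carries signal only on a subset of length blocks chosen
#' independently with probability `coverage` (so `coverage = 1` lights the
#' whole axon and `coverage = 0` none of it). Both channels are blurred
#' with a Gaussian PSF and corrupted with Poisson shot noise on top of a
#' uniform background. The realized covered length fraction is recorded in
#' the metadata.
#'
#' @param params a [lattice_params()]; only length and diameter are used.
#' @param pixel_nm pixel size (default 160 nm, a typical EMCCD back-projected
#'   pixel).
#' @param psf_sigma_nm Gaussian PSF standard deviation (default 250 nm,
#'   diffraction-limited visible-light imaging).
#' @param coverage ground-truth fraction in `[0, 1]` of axon length carrying
#'   spectrin signal.
#' @param seed integer seed.
#' @param signal,background mean photon counts on axon / off axon.
#' @param block_nm length of independently covered blocks.
#' @return object of class `image_pair`: list with `spectrin`, `tubulin`
#'   (numeric count matrices, rows = y), `pixel_nm`, and `meta` (including
#'   `coverage` and `realized_coverage`).
#' @export
simulate_widefield_pair <- function(params = lattice_params(),
                                    pixel_nm = 160, psf_sigma_nm = 250,
                                    coverage = 1, seed = 1L,
                                    signal = 120, background = 6,
                                    block_nm = 1900) {
  stopifnot(is_scalar_pos(pixel_nm), is_scalar_pos(psf_sigma_nm),
            is.numeric(coverage), coverage >= 0, coverage <= 1)
  validate_lattice_params(params)
  length_nm <- params$axon_length_um * 1000
  margin_nm <- 4 * psf_sigma_nm + 2 * pixel_nm
  ncol_img <- ceiling((length_nm + 2 * margin_nm) / pixel_nm)
  nrow_img <- ceiling((params$axon_diameter_nm + 2 * margin_nm) / pixel_nm)
  # pixel centers at (i - 0.5) * pixel_nm, 1-based
  xc <- (seq_len(ncol_img) - 0.5) * pixel_nm
  yc <- (seq_len(nrow_img) - 0.5) * pixel_nm
  cy <- nrow_img * pixel_nm / 2
  on_rows <- abs(yc - cy) <= params$axon_diameter_nm / 2
  in_axon <- xc >= margin_nm & xc < margin_nm + length_nm

  with_seed(seed, {
    n_blocks <- ceiling(length_nm / block_nm)
    blocks_on <- runif(n_blocks) < coverage
    block_idx <- pmin(floor((xc - margin_nm) / block_nm) + 1, n_blocks)
    spec_cols <- in_axon & blocks_on[pmax(block_idx, 1L)]
    realized <- if (any(in_axon)) sum(spec_cols) / sum(in_axon) else 0

    ribbon <- outer(on_rows, in_axon) * signal
    spec_ideal <- outer(on_rows, spec_cols) * signal
    sig_px <- psf_sigma_nm / pixel_nm
    tub <- gauss_blur(ribbon, sig_px) + background
    spc <- gauss_blur(spec_ideal, sig_px) + background
    tub_counts <- matrix(rpois(length(tub), tub), nrow = nrow_img)
    spc_counts <- matrix(rpois(length(spc), spc), nrow = nrow_img)
    image_pair(spectrin = spc_counts, tubulin = tub_counts,
               pixel_nm = pixel_nm,
               meta = list(coverage = coverage,
                           realized_coverage = realized,
                           psf_sigma_nm = psf_sigma_nm, seed = seed,
                           params = unclass(params)))
  })
}

# separable Gaussian blur with reflected boundaries (truncated at 4 sigma)
gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- seq_len(n)
    out <- numeric(n)
    for (j in -r:r) {
      ii <- idx + j
      ii <- ifelse(ii < 1L, 2L - ii, ifelse(ii > n, 2L * n - ii, ii))
      out <- out + k[j + r + 1L] * v[ii]
    }
    out
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}

#' Construct a two-channel image pair
#'
#' @param spectrin,tubulin numeric matrices of equal dimensions.
#' @param pixel_nm pixel size in nm.
#' @param meta free-form provenance list.
#' @return object of class `image_pair`.
#' @export
image_pair <- function(spectrin, tubulin, pixel_nm, meta = list()) {
  stopifnot(is.matrix(spectrin), is.matrix(tubulin),
            all(dim(spectrin) == dim(tubulin)), is_scalar_pos(pixel_nm))
  structure(list(spectrin = spectrin, tubulin = tubulin,
                 pixel_nm = pixel_nm, meta = meta),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("image_pair: %d x %d px, %g nm/px\n",
              nrow(x$tubulin), ncol(x$tubulin), x$pixel_nm))
  if (!is.null(x$meta$coverage))
    cat(sprintf("  synthetic, coverage %g (realized %.3f)\n",
                x$meta$coverage, x$meta$realized_coverage))
  invisible(x)
}
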