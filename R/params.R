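#' Generative parameters of a synthetic MPS lattice
#'
#' Describes one axon's membrane periodic skeleton as seen by SMLM: a comb
#' of actin-ring positions spaced `period_nm` apart along the axon, labeled
#' with finite density and localization precision, and degraded by two
#' disorder knobs -- the fraction of localizations that belong to the comb
#' (`periodic_fraction`, the remainder is uniform along the axon) and a
#' Gaussian axial displacement of each ring-bound localization
#' (`jitter_nm`).
#'
#' @param period_nm ring spacing in nm (default 190, the MPS lattice
#'   constant).
#' @param phase_nm comb offset in `[0, period_nm)`.
#' @param jitter_nm standard deviation (nm) of the Gaussian ring-phase
#'   displacement: each ring's center is displaced once, shared by all of
#'   that ring's localizations; 0 means rings sit exactly on the comb.
#' @param ring_width_nm standard deviation (nm) of the axial spread of
#'   individual labels around their ring center (epitope distribution
#'   along the spectrin tetramer plus primary/secondary antibody linkage).
#'   This is what makes measured spectrin profiles near-sinusoidal rather
#'   than a sharp comb; the 35 nm default matches the ~80 nm FWHM bands
#'   seen in immunolabeled STORM data. Set to 0 for a degenerate comb.
#' @param periodic_fraction fraction in `[0, 1]` of localizations drawn
#'   from the ring comb; `0` gives complete spatial randomness.
#' @param density_per_um expected localizations per micron of axon length
#'   (Poisson).
#' @param loc_precision_xy_nm,loc_precision_z_nm standard deviation (nm) of
#'   the Gaussian localization error added to lateral / axial-z coordinates.
#' @param axon_length_um axon segment length in microns; must contain at
#'   least one full period.
#' @param axon_diameter_nm axon diameter in nm; analysis targets unbundled
#'   distal axons, so at most 700 nm.
#' @return an object of class `lattice_params` (a validated named list).
#' @examples
#' p <- lattice_params(periodic_fraction = 0.5, jitter_nm = 20)
#' p$period_nm
#' @export
lattice_params <- function(period_nm = 190,
                           phase_nm = 0,
                           jitter_nm = 10,
                           ring_width_nm = 35,
                           periodic_fraction = 1,
                           density_per_um = 500,
                           loc_precision_xy_nm = 10,
                           loc_precision_z_nm = 20,
                           axon_length_um = 19,
                           axon_diameter_nm = 400) {
  p <- list(period_nm = period_nm, phase_nm = phase_nm,
            jitter_nm = jitter_nm, ring_width_nm = ring_width_nm,
            periodic_fraction = periodic_fraction,
            density_per_um = density_per_um,
            loc_precision_xy_nm = loc_precision_xy_nm,
            loc_precision_z_nm = loc_precision_z_nm,
            axon_length_um = axon_length_um,
            axon_diameter_nm = axon_diameter_nm)
  validate_lattice_params(p)
  structure(p, class = "lattice_params")
}

validate_lattice_params <- function(p) {
  if (!is_scalar_pos(p$period_nm))
    stop("period_nm must be a positive length", call. = FALSE)
  if (!is_scalar_nonneg(p$phase_nm) || p$phase_nm >= p$period_nm)
    stop("phase_nm must lie in [0, period_nm)", call. = FALSE)
  if (!is_scalar_nonneg(p$jitter_nm))
    stop("jitter_nm must be >= 0", call. = FALSE)
  if (!is_scalar_nonneg(p$ring_width_nm))
    stop("ring_width_nm must be >= 0", call. = FALSE)
  f <- p$periodic_fraction
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("periodic_fraction must lie in [0, 1]", call. = FALSE)
  if (!is_scalar_pos(p$density_per_um))
    stop("density_per_um must be positive", call. = FALSE)
  if (!is_scalar_nonneg(p$loc_precision_xy_nm) ||
      !is_scalar_nonneg(p$loc_precision_z_nm))
    stop("localization precisions must be >= 0", call. = FALSE)
  if (!is_scalar_pos(p$axon_length_um))
    stop("axon_length_um must be positive", call. = FALSE)
  if (!is_scalar_pos(p$axon_diameter_nm) || p$axon_diameter_nm > 700)
    stop("axon_diameter_nm must lie in (0, 700]: only unbundled axons ",
         "thinner than 700 nm are analyzed", call. = FALSE)
  invisible(p)
}

#' Number of complete rings implied by a lattice parameter set
#' @param params a [lattice_params()] object.
#' @return integer ring count, `floor(length / period)`.
#' @export
n_rings <- function(params) {
  as.integer(floor(params$axon_length_um * 1000 / params$period_nm))
}

#' @export
print.lattice_params <- function(x, ...) {
  cat("MPS lattice parameters\n")
  cat(sprintf("  period %g nm (phase %g nm), jitter %g nm, ring width %g nm, periodic fraction %g\n",
              x$period_nm, x$phase_nm, x$jitter_nm, x$ring_width_nm,
              x$periodic_fraction))
  cat(sprintf("  density %g /um over %g um (diameter %g nm), precision xy %g / z %g nm\n",
              x$density_per_um, x$axon_length_um, x$axon_diameter_nm,
              x$loc_precision_xy_nm, x$loc_precision_z_nm))
  invisible(x)
}

#' Specification of one simulated experimental condition
#'
#' Bundles a condition label (e.g. `"NGF"` or `"TD_6h"`), the number of
#' axons in the cohort, the lattice parameters shared by those axons, and
#' the top-level seed from which per-axon seeds are derived.
#'
#' @param label condition name; used as prefix of axon identifiers.
#' @param n_axons number of axons to simulate (>= 1).
#' @param params a [lattice_params()] object.
#' @param seed integer seed for the cohort.
#' @return an object of class `condition_spec`.
#' @export
condition_spec <- function(label, n_axons, params = lattice_params(),
                           seed = 1L) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string", call. = FALSE)
  if (!is.numeric(n_axons) || length(n_axons) != 1L || n_axons < 1 ||
      n_axons != round(n_axons))
    stop("n_axons must be a positive integer", call. = FALSE)
  stopifnot(inherits(params, "lattice_params"))
  validate_lattice_params(params)
  structure(list(label = label, n_axons = as.integer(n_axons),
                 params = params, seed = as.integer(seed)),
            class = "condition_spec")
}
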