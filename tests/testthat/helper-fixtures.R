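# Shared fixtures, all built in code.

# loc_table on the x-axis at given axial positions
axial_table <- function(x, y = 0, axon_id = "fix") {
  loc_table(x_nm = x, y_nm = rep_len(y, length(x)), axon_id = axon_id)
}

# positions1d object without going through projection
positions_fixture <- function(s) {
  structure(list(s_nm = sort(s), extent_nm = c(0, max(s)), n_dropped = 0L),
            class = "positions1d")
}

# profile1d from a count vector
profile_fixture <- function(counts, bin_nm = 10) {
  structure(list(counts = as.integer(counts), bin_nm = bin_nm,
                 origin_nm = 0), class = "profile1d")
}

# independent O(n^2) double-loop autocorrelation oracle
acf_oracle <- function(counts, max_lag_bins) {
  c0 <- as.numeric(counts)
  n <- length(c0)
  d <- c0 - mean(c0)
  denom <- sum(d * d)
  out <- numeric(max_lag_bins + 1)
  for (k in 0:max_lag_bins) {
    s <- 0
    for (i in 1:(n - k)) s <- s + d[i] * d[i + k]
    out[k + 1] <- s / denom
  }
  out
}

# exhaustive ECDF-based KS D oracle: evaluate both ECDFs on a fine grid of
# all pooled points and midpoints
ks_D_oracle <- function(a, b) {
  pts <- sort(c(a, b))
  eval_at <- sort(unique(c(pts, pts - 1e-9, pts + 1e-9)))
  Fa <- vapply(eval_at, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(eval_at, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# short clean-lattice parameters used across tests
clean_params <- function(axon_length_um = 19, ...) {
  lattice_params(periodic_fraction = 1, jitter_nm = 5,
                 loc_precision_xy_nm = 10,
                 axon_length_um = axon_length_um, ...)
}

# disordered (CSR) axon: 2 segments worth of length
null_params <- function(...) {
  lattice_params(periodic_fraction = 0, axon_length_um = 3.8, ...)
}

# amplitude of one simulated axon (NA if unquantifiable)
sim_amplitude <- function(params, seed, cfg = analysis_config()) {
  res <- quantify_axon(simulate_axon(params, seed), cfg = cfg)
  if (res$status == "ok") res$amplitude else NA_real_
}
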