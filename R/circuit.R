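# Rectified-linear disinhibition circuit model
#
# A state input (hypothalamic drive) inhibits a tonically active thalamic
# interneuron population; a contact input excites projection cells that the
# interneurons tonically suppress. Both populations are threshold-linear:
#   r_I(t) = max(0, b_I - w_MI * s_M(t - tau_I))
#   r_P(t) = max(0, b_P + w_SP * c(t) - w_IP * r_I(t - tau_P))
# Superadditivity of the projection response to the joint input arises purely
# from rectification: when baseline b_P - w_IP * b_I clips at zero, the two
# unimodal responses under-report the underlying linear drive and the
# multimodal response exceeds their sum.

#' Circuit parameters for the disinhibition rate model
#'
#' @param b_I Interneuron baseline rate (spikes/s). Default 20, the high
#'   tonic rate characteristic of putative inhibitory interneurons.
#' @param b_P Projection-cell baseline drive (spikes/s).
#' @param w_MI State-input to interneuron inhibitory weight (spikes/s per unit
#'   input).
#' @param w_SP Contact-input to projection-cell excitatory weight (spikes/s per
#'   unit input).
#' @param w_IP Interneuron to projection-cell inhibitory gain (dimensionless).
#' @param tau_I Latency of the state input onto interneurons (s).
#' @param tau_P Latency of interneuron output onto projection cells (s).
#' @param noise_sd Trial-to-trial additive rate jitter (spikes/s) used by the
#'   spiking simulator.
#' @param enforce_latency_order If `TRUE`, require `tau_I < tau_P` so that the
#'   interneuron trough precedes the projection-cell rise.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(b_I = 20, b_P = 2, w_MI = 20, w_SP = 10,
                           w_IP = 0.5, tau_I = 0.02, tau_P = 0.06,
                           noise_sd = 1, enforce_latency_order = TRUE) {
  for (nm in c("b_I", "b_P", "w_MI", "w_SP", "w_IP", "tau_I", "tau_P",
               "noise_sd")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  if (enforce_latency_order && !(tau_I < tau_P))
    stop_validation("tau_I must be < tau_P when latency ordering is enforced")
  structure(
    list(b_I = b_I, b_P = b_P, w_MI = w_MI, w_SP = w_SP, w_IP = w_IP,
         tau_I = tau_I, tau_P = tau_P, noise_sd = noise_sd),
    class = "circuit_params"
  )
}

# shift a series right by lag seconds, padding with its first value
# (inputs are zero before onset so the pad equals the resting input)
shift_series <- function(x, lag_s, dt) {
  n_lag <- as.integer(round(lag_s / dt))
  if (n_lag == 0L) return(x)
  c(rep(x[1L], n_lag), x[seq_len(length(x) - n_lag)])
}

#' Evaluate the circuit rate equations on input indicator series
#'
#' @param params A [circuit_params()] object.
#' @param s_M Numeric state-input indicator series (0/1) on a uniform grid.
#' @param c_in Numeric contact-input indicator series on the same grid.
#' @param dt Grid spacing in seconds.
#' @return A list with numeric vectors `r_I` and `r_P` (spikes/s) and `dt`.
#' @export
rate_traces <- function(params, s_M, c_in, dt = 0.001) {
  stopifnot(inherits(params, "circuit_params"))
  if (length(s_M) != length(c_in))
    stop_structural("s_M and c_in must share one time grid (lengths ",
                    length(s_M), " vs ", length(c_in), ")")
  check_scalar_number(dt, "dt", lower = 1e-9)
  r_I <- pmax(0, params$b_I - params$w_MI * shift_series(s_M, params$tau_I, dt))
  r_P <- pmax(0, params$b_P + params$w_SP * c_in -
                params$w_IP * shift_series(r_I, params$tau_P, dt))
  list(r_I = r_I, r_P = r_P, dt = dt)
}
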