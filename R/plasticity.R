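#' Parallel fiber - Purkinje cell plasticity parameters
#'
#' Supervised spike-timing plasticity at the PF->PC synapses, evaluated at
#' every Purkinje cell spike: if an inferior-olive (climbing fiber) spike for
#' that cell lies within the coincidence window, every PF synapse is
#' depressed by `ltd_scale` times the eligibility-kernel sum over its recent
#' spike history (LTD); otherwise every PF that was active within the
#' coincidence window is potentiated by the fixed step `ltp_step` (LTP).
#' Weights are clipped to `[weight_min, weight_max]` at every update.
#'
#' The eligibility kernel is a single non-negative lobe
#' `exp(-u/decay_tau) * sin(pi * u / lobe_width)^20` shifted and scaled so
#' that its argmax sits exactly `t0` before the evaluation time with maximum
#' 1: PF spikes preceding the climbing-fiber signal by about `t0` (100 ms)
#' are maximally depressed, capturing the sensory-motor latency between the
#' state that caused the response and the reward.
#'
#' @param ltp_step Fixed potentiation increment (dimensionless, >= 0);
#'   0.01 for the control genotype.
#' @param ltd_scale Depression scale (<= 0), -0.03.
#' @param t0 Kernel peak lag (ms) before the evaluation time.
#' @param lobe_width Width of the kernel's single lobe (ms).
#' @param decay_tau Exponential decay constant of the kernel (ms).
#' @param integration_window LTD spike-history window (ms); must exceed `t0`.
#' @param weight_min,weight_max Weight bounds (0 <= min < max).
#' @param coincidence_window Window (ms) within which a PC spike counts as
#'   coincident with an IO spike (and a PF spike as "active at" the PC
#'   spike). The evaluation is causal: only spikes at or before the PC spike
#'   are seen.
#' @return A `plasticity_params` object.
#' @export
plasticity_params <- function(ltp_step = 0.01, ltd_scale = -0.03, t0 = 100,
                              lobe_width = 100, decay_tau = 50,
                              integration_window = 300, weight_min = 0,
                              weight_max = 1, coincidence_window = 5) {
  if (ltp_step < 0) stop("ltp_step must be >= 0")
  if (ltd_scale > 0) stop("ltd_scale must be <= 0")
  if (weight_min < 0 || weight_max <= weight_min)
    stop("need 0 <= weight_min < weight_max")
  if (t0 >= integration_window) stop("t0 must be < integration_window")
  p <- list(ltp_step = ltp_step, ltd_scale = ltd_scale, t0 = t0,
            lobe_width = lobe_width, decay_tau = decay_tau,
            integration_window = integration_window,
            weight_min = weight_min, weight_max = weight_max,
            coincidence_window = coincidence_window)
  # numeric normalization of the kernel lobe: find the raw argmax at 0.01 ms
  # resolution, then shift so argmax = t0 and scale so max = 1
  u <- seq(0, lobe_width, by = 0.01)
  raw <- exp(-u / decay_tau) * sin(pi * u / lobe_width)^20
  i <- which.max(raw)
  p$u_star <- u[i]
  p$g_max <- raw[i]
  structure(p, class = "plasticity_params")
}

#' Eligibility kernel
#'
#' Non-negative, single dominant lobe, `K(t0) = 1` and argmax exactly at
#' `t0`; zero outside the lobe.
#'
#' @param z Lag (ms) between the evaluation (PC/IO) time and a PF spike.
#' @param params A [plasticity_params()].
#' @return Kernel values, same length as `z`.
#' @export
pfpc_kernel <- function(z, params = plasticity_params()) {
  u <- z - params$t0 + params$u_star
  out <- numeric(length(z))
  ok <- u >= 0 & u <= params$lobe_width
  out[ok] <- exp(-u[ok] / params$decay_tau) *
    sin(pi * u[ok] / params$lobe_width)^20 / params$g_max
  out
}

#' Kernel lookup table at simulation resolution
#' @param params A [plasticity_params()].
#' @param dt Simulation step (ms).
#' @return Kernel values at lags `seq(0, integration_window, by = dt)`.
#' @export
kernel_lut <- function(params = plasticity_params(), dt = 0.1) {
  pfpc_kernel(seq(0, params$integration_window, by = dt), params)
}

#' Genotype-specific plasticity constants
#'
#' The L7-PP2B knock-out (Purkinje-cell-specific impairment of PF->PC
#' potentiation) is modelled by reducing the LTP constant to 10% (0.001);
#' the LTD scale is unchanged.
#'
#' @param params A [plasticity_params()].
#' @param genotype `"control"` or `"l7pp2b"`.
#' @return Updated parameters.
#' @export
apply_genotype <- function(params = plasticity_params(),
                           genotype = c("control", "l7pp2b")) {
  if (!is.character(genotype) || !genotype[1] %in% c("control", "l7pp2b"))
    stop("unknown genotype: ", genotype[1])
  params$ltp_step <- if (genotype[1] == "control") 0.01 else 0.001
  params
}

#' Event-driven plasticity update at one PC spike
#'
#' Reference implementation of the learning rule (the engine applies the
#' identical update in C++ during closed-loop runs; the two are
#' cross-checked to machine precision on toy circuits).
#'
#' @param t PC spike time (ms).
#' @param io_spike_times Climbing-fiber spike times for this PC (ms), past
#'   spikes only.
#' @param pf_history List (one element per PF synapse) of PF spike times at
#'   or before `t`.
#' @param weights Numeric vector of current PF->PC weights (same length as
#'   `pf_history`).
#' @param params A [plasticity_params()].
#' @return Updated weight vector.
#' @export
on_pc_spike <- function(t, io_spike_times, pf_history, weights,
                        params = plasticity_params()) {
  w <- params$coincidence_window + 1e-9 # robust window edges
  coinc <- any(io_spike_times <= t & t - io_spike_times <= w)
  if (coinc) {
    for (i in seq_along(weights)) {
      lags <- t - pf_history[[i]]
      lags <- lags[lags >= 0 & lags <= params$integration_window + 1e-9]
      if (length(lags)) {
        ks <- sum(pfpc_kernel(lags, params))
        if (ks > 0) weights[i] <- weights[i] + params$ltd_scale * ks
      }
    }
  } else {
    for (i in seq_along(weights)) {
      if (any(pf_history[[i]] <= t & t - pf_history[[i]] <= w))
        weights[i] <- weights[i] + params$ltp_step
    }
  }
  pmin(pmax(weights, params$weight_min), params$weight_max)
}
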