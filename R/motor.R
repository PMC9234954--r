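#' Central pattern generator spike times
#'
#' The whisking pacemaker is a single neuron emitting strictly periodic
#' spikes in the lower-theta band (default 4 Hz), first spike one period
#' after time zero.
#'
#' @param duration Simulated duration (ms), >= 0.
#' @param rate CPG rate (Hz).
#' @return Numeric vector of spike times (ms).
#' @export
cpg_spike_times <- function(duration, rate = 4) {
  if (duration < 0) stop("duration must be >= 0")
  period <- 1000 / rate
  if (duration < period) return(numeric(0))
  seq(period, duration, by = period)
}

#' Spike-to-torque gains
#'
#' Gains of the linear rate-to-torque decoder
#' `torque = alpha_pro * FR_pro - alpha_ret * FR_ret`.
#'
#' @param alpha_pro Protractor gain (N m / Hz), default 1.5e-3.
#' @param alpha_ret Retractor gain (N m / Hz), default 1.0e-3.
#' @param bin_width Rate bin (ms) over which the instantaneous firing rates
#'   are computed and the torque is held (zero-order hold).
#' @return A `torque_gains` object.
#' @export
torque_gains <- function(alpha_pro = 1.5e-3, alpha_ret = 1.0e-3,
                         bin_width = 10) {
  if (alpha_pro <= 0 || alpha_ret <= 0) stop("gains must be > 0")
  structure(list(alpha_pro = alpha_pro, alpha_ret = alpha_ret,
                 bin_width = bin_width), class = "torque_gains")
}

#' Decode facial-nucleus rates into whisker torques
#'
#' Each whisker's torque combines its own protractor population rate with its
#' side's (shared) retractor population rate:
#' `torque_w = alpha_pro * FR_pro_w - alpha_ret * FR_ret_side(w)`.
#'
#' @param fr_pro Protractor instantaneous rates (Hz), named per whisker
#'   (L0, L1, R0, R1).
#' @param fr_ret Retractor instantaneous rates (Hz), named per side
#'   (left, right).
#' @param gains A [torque_gains()].
#' @return Named torque vector (N m) per whisker.
#' @export
decode_torque <- function(fr_pro, fr_ret, gains = torque_gains()) {
  side <- c(L0 = "left", L1 = "left", R0 = "right", R1 = "right")
  wn <- names(fr_pro)
  out <- gains$alpha_pro * fr_pro - gains$alpha_ret * fr_ret[side[wn]]
  names(out) <- wn
  out
}

#' Write a torque trace as CSV (`time_ms,whisker,torque_Nm`)
#' @param torques Data.frame with columns `time_ms`, `whisker`, `torque_Nm`
#'   (as returned in `run_trial(..., record = "spikes")$torques`).
#' @param path Output path.
#' @export
write_torque_trace <- function(torques, path) {
  utils::write.csv(torques[, c("time_ms", "whisker", "torque_Nm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the motor populations
#'
#' One CPG pacemaker neuron (generator), four protractor populations of 20
#' neurons (one per whisker) and two retractor populations of 20 neurons
#' (one per side, shared by its two whiskers): 30 facial-nucleus motoneurons
#' per whisker in total (20 protractors + 10 retractors).
#'
#' @param net Network.
#' @param params Neuron parameters for the facial nuclei.
#' @return List with `cpg`, `pro` (list per whisker), `ret` (list per side).
#' @export
build_motor <- function(net, params = neuron_params()) {
  cpg <- build_population(net, "CPG", 1, params, generator = TRUE)
  pro <- lapply(c("L0", "L1", "R0", "R1"), function(w)
    build_population(net, paste0("FN_pro_", w), 20, params))
  names(pro) <- c("L0", "L1", "R0", "R1")
  ret <- lapply(c("left", "right"), function(s)
    build_population(net, paste0("FN_ret_", s), 20, params))
  names(ret) <- c("left", "right")
  list(cpg = cpg, pro = pro, ret = ret)
}

#' Wire the motor pathway and trigeminal reflex
#'
#' CPG to all 80 protractors (delay 1 ms) and all 40 retractors (delay
#' 50 ms), both excitatory and calibrated suprathreshold so each CPG spike
#' elicits exactly one spike per target; this makes the free-whisking
#' mean FN rate equal the CPG rate, and the 49 ms delay difference yields
#' protraction followed by retraction within each cycle. The trigeminal
#' reflex connects each whisker's TN contact neuron to its 20 protractors
#' (excitatory, 7.5 ms delay) and its side's 20 retractors (inhibitory),
#' 80 + 80 synapses, pushing colliding whiskers against the object and
#' suppressing their rebound.
#'
#' @param net Network.
#' @param motor From [build_motor()].
#' @param tn_contact TN contact population (4 neurons, one per whisker,
#'   ordered L0, L1, R0, R1); `NULL` skips the reflex.
#' @param w_cpg Suprathreshold CPG->FN weight (mV).
#' @param w_reflex TN->protractor weight (mV).
#' @param w_reflex_inh TN->retractor inhibitory weight magnitude (mV).
#' @param reflex_delay Reflex latency (ms), default 7.5.
#' @return List of projections.
#' @export
wire_motor <- function(net, motor, tn_contact = NULL, w_cpg = 20,
                       w_reflex = 20, w_reflex_inh = 20, reflex_delay = 7.5) {
  projs <- list()
  for (w in names(motor$pro))
    projs[[paste0("cpg_pro_", w)]] <-
      connect(net, motor$cpg, motor$pro[[w]], "one_to_all", "excitatory",
              weight = w_cpg, delay = 1)
  for (s in names(motor$ret))
    projs[[paste0("cpg_ret_", s)]] <-
      connect(net, motor$cpg, motor$ret[[s]], "one_to_all", "excitatory",
              weight = w_cpg, delay = 50)
  if (!is.null(tn_contact)) {
    whiskers <- c("L0", "L1", "R0", "R1")
    side <- c(L0 = "left", L1 = "left", R0 = "right", R1 = "right")
    tn_g <- gids(tn_contact)
    for (i in seq_along(whiskers)) {
      w <- whiskers[i]
      pro_g <- gids(motor$pro[[w]])
      ret_g <- gids(motor$ret[[side[w]]])
      projs[[paste0("tn_pro_", w)]] <- structure(list(
        pre = tn_contact$name, post = motor$pro[[w]]$name,
        polarity = "excitatory", n_synapses = length(pro_g),
        proj_id = eng_add_projection(net$ptr, rep(tn_g[i], length(pro_g)),
                                     pro_g, rep(w_reflex, length(pro_g)),
                                     reflex_delay, FALSE, FALSE)),
        class = "projection")
      projs[[paste0("tn_ret_", w)]] <- structure(list(
        pre = tn_contact$name, post = motor$ret[[side[w]]]$name,
        polarity = "inhibitory", n_synapses = length(ret_g),
        proj_id = eng_add_projection(net$ptr, rep(tn_g[i], length(ret_g)),
                                     ret_g, rep(-w_reflex_inh, length(ret_g)),
                                     reflex_delay, FALSE, FALSE)),
        class = "projection")
      net$projs[[paste0("TN_contact->FN_pro_", w)]] <-
        projs[[paste0("tn_pro_", w)]]
      net$projs[[paste0("TN_contact->FN_ret_", w)]] <-
        projs[[paste0("tn_ret_", w)]]
    }
  }
  projs
}
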