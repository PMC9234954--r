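#' Cerebellar microcircuit specification
#'
#' Population sizes and connectivity of the adaptive cerebellar module:
#' 100 mossy fibers (MF), 2,000 granule cells (GrC), 72 Purkinje cells (PC),
#' 72 inferior-olive neurons (IO), 36 deep-cerebellar-nuclei neurons (DCN);
#' MF->GrC 8,000 synapses (convergence 4), PF->PC 115,200 (convergence
#' 1,600, plastic), IO->PC 72 one-to-one teaching, MF->DCN 3,600
#' (convergence 100), PC->DCN 72 (convergence 2, divergence 1, inhibitory).
#' A behavioural response is detected when the DCN population rate strictly
#' exceeds `dcn_threshold` (80 Hz).
#'
#' @param n_mf,n_grc,n_pc,n_io,n_dcn Population sizes.
#' @param conv_mf_grc,conv_pf_pc,conv_mf_dcn,conv_pc_dcn Convergences.
#' @param dcn_threshold Response threshold on the DCN population rate (Hz).
#' @param dcn_rate_window Rate window for response detection (ms).
#' @param w_mf_grc MF->GrC weight (mV); calibrated so a GrC needs several
#'   near-coincident active mossy-fiber inputs to fire (sparse recoding).
#' @param w_mf_relay TG pressure / TN phase -> MF relay weight (mV,
#'   suprathreshold).
#' @param w_mf_dcn MF->DCN weight (mV); calibrated so any sustained contact
#'   drives the naive DCN above threshold.
#' @param w_pc_dcn PC->DCN inhibitory weight magnitude (mV).
#' @param pc_baseline_rate Tonic Purkinje simple-spike rate (Hz) produced by
#'   a constant bias current.
#' @param reward_latency Delay (ms) from response detection to the IO reward
#'   signal.
#' @param reward_burst_n,reward_burst_isi IO reward burst: number of spikes
#'   per IO neuron and their spacing (ms).
#' @return A `cerebellum_spec` object.
#' @export
cerebellum_spec <- function(n_mf = 100, n_grc = 2000, n_pc = 72, n_io = 72,
                            n_dcn = 36, conv_mf_grc = 4, conv_pf_pc = 1600,
                            conv_mf_dcn = 100, conv_pc_dcn = 2,
                            dcn_threshold = 80, dcn_rate_window = 10,
                            w_mf_grc = 8.5, w_mf_relay = 20, w_mf_dcn = 2.6,
                            w_pc_dcn = 10, pc_baseline_rate = 50,
                            reward_latency = 10, reward_burst_n = 60,
                            reward_burst_isi = 5) {
  if (conv_mf_grc > n_mf || conv_pf_pc > n_grc || conv_mf_dcn > n_mf ||
      conv_pc_dcn > n_pc)
    stop("a convergence exceeds its presynaptic population size")
  if (n_pc != conv_pc_dcn * n_dcn)
    stop("n_pc must equal conv_pc_dcn * n_dcn (each PC contacts one DCN)")
  structure(as.list(environment()), class = "cerebellum_spec")
}

#' Build the cerebellar network
#'
#' Constructs the five cerebellar projections with the stated convergences
#' (sampling without replacement, seeded): the IO->PC projection is marked
#' teaching (it injects no current; IO spikes gate depression), the PF->PC
#' projection is plastic with weights initialised at `weight_min` (fully
#' depressed start, so naive PCs are quiet and the DCN responds to any
#' contact).
#'
#' @param net Network.
#' @param spec A [cerebellum_spec()].
#' @param plast A [plasticity_params()].
#' @param params Neuron parameters.
#' @param seed RNG seed for the sampled wiring.
#' @return List with populations (`mf`, `grc`, `pc`, `io`, `dcn`),
#'   projections, and the plastic projection id.
#' @export
build_cerebellum <- function(net, spec = cerebellum_spec(),
                             plast = plasticity_params(),
                             params = neuron_params(), seed = 1) {
  mf <- build_population(net, "MF", spec$n_mf, params)
  grc <- build_population(net, "GrC", spec$n_grc, params)
  pc <- build_population(net, "PC", spec$n_pc, params,
                         bias_mv = bias_for_rate(spec$pc_baseline_rate, params))
  io <- build_population(net, "IO", spec$n_io, params, generator = TRUE)
  dcn <- build_population(net, "DCN", spec$n_dcn, params)
  projs <- list(
    mf_grc = connect(net, mf, grc, "fixed_convergence", "excitatory",
                     weight = spec$w_mf_grc, delay = 1,
                     convergence = spec$conv_mf_grc, seed = seed + 1),
    pf_pc = connect(net, grc, pc, "fixed_convergence", "excitatory",
                    weight = plast$weight_min, delay = 1,
                    convergence = spec$conv_pf_pc, seed = seed + 2,
                    plastic = TRUE),
    io_pc = connect(net, io, pc, "one_to_one", "teaching", weight = 0,
                    delay = 1),
    mf_dcn = connect(net, mf, dcn, "fixed_convergence", "excitatory",
                     weight = spec$w_mf_dcn, delay = 1,
                     convergence = spec$conv_mf_dcn, seed = seed + 3),
    pc_dcn = connect(net, pc, dcn, "all_to_one", "inhibitory",
                     weight = spec$w_pc_dcn, delay = 1,
                     convergence = spec$conv_pc_dcn))
  list(mf = mf, grc = grc, pc = pc, io = io, dcn = dcn, projs = projs,
       plastic_proj = projs$pf_pc$proj_id)
}

#' Map whisker afferents onto mossy fibers
#'
#' The 80 TG pressure cells and the 80 TN phase cells each project
#' one-to-one onto the 100 MFs through a seeded injective map per source
#' population (160 synapses in total; overlap between the two maps is
#' allowed and, by pigeonhole, at least 60 MFs receive both a pressure and a
#' phase afferent).
#'
#' @param net Network.
#' @param tg_pressure,tn_phase Source populations (80 cells each).
#' @param mf MF population.
#' @param weight Relay weight (mV, suprathreshold).
#' @param seed RNG seed.
#' @return List of the two projections.
#' @export
map_afferents <- function(net, tg_pressure, tn_phase, mf, weight = 20,
                          seed = 1) {
  list(pressure_mf = connect(net, tg_pressure, mf, "one_to_one",
                             "excitatory", weight = weight, delay = 1,
                             seed = seed + 4),
       phase_mf = connect(net, tn_phase, mf, "one_to_one", "excitatory",
                          weight = weight, delay = 1, seed = seed + 5))
}

#' Encode reward on the inferior olive
#'
#' On a correctly generated response (GO trial only), every IO neuron emits
#' a short high-frequency burst starting `reward_latency` after detection;
#' responses in NOGO trials trigger nothing. The burst (rather than a lone
#' spike) makes the total depression commensurate with the potentiation
#' accumulated over a trial, mirroring climbing-fiber complex-spike bursts.
#'
#' @param response_time Detection time (ms), or `NA`.
#' @param trial_type `"GO"` or `"NOGO"`.
#' @param spec A [cerebellum_spec()].
#' @return Vector of per-IO spike times (ms; the same for every IO neuron),
#'   empty if no reward.
#' @export
encode_reward <- function(response_time, trial_type,
                          spec = cerebellum_spec()) {
  if (is.na(response_time) || trial_type != "GO") return(numeric(0))
  response_time + spec$reward_latency +
    (seq_len(spec$reward_burst_n) - 1) * spec$reward_burst_isi
}

#' Detect a behavioural response from DCN activity
#'
#' At most one response per trial, at the first bin in which the DCN
#' population instantaneous rate strictly exceeds the threshold within the
#' response window.
#'
#' @param dcn_spikes Spike data.frame of the DCN population.
#' @param dcn DCN population.
#' @param t_start,t_stop Response window (ms).
#' @param threshold Rate threshold (Hz), strict.
#' @param window Rate window (ms).
#' @return Response time (ms, end of the crossing bin) or `NA`.
#' @export
detect_response <- function(dcn_spikes, dcn, t_start = 0, t_stop = 2000,
                            threshold = 80, window = 10) {
  tr <- instantaneous_rate(dcn_spikes, dcn, bin_width = window,
                           t_start = t_start, t_stop = t_stop)
  hit <- which(tr$rate > threshold)
  if (length(hit) == 0) return(NA_real_)
  tr$bin_start[hit[1]] + window
}
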