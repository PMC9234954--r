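#' Leaky integrate-and-fire neuron parameters
#'
#' Point-neuron parameters used by every simulated population. Defaults are a
#' standard LIF set (10 ms membrane time constant, 15 mV threshold distance,
#' 2 ms refractoriness); the model's behavioural results are calibrated to be
#' insensitive to their exact values.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest Resting potential (mV).
#' @param v_thresh Spike threshold (mV); must exceed `v_reset`.
#' @param v_reset Post-spike reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param c_m Membrane capacitance (pF); kept for completeness (synapses are
#'   delta-current kicks expressed directly in mV, so `c_m` does not enter the
#'   update).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 10, v_rest = -70, v_thresh = -55,
                          v_reset = -70, t_ref = 2, c_m = 250) {
  if (tau_m <= 0) stop("tau_m must be > 0")
  if (t_ref < 0) stop("t_ref must be >= 0")
  if (v_thresh <= v_reset) stop("v_thresh must exceed v_reset")
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, t_ref = t_ref, c_m = c_m),
            class = "neuron_params")
}

#' Create an empty spiking network
#'
#' @param dt Simulation step (ms). All projection delays must be >= `dt`.
#' @return An object of class `snn_network` (an environment wrapping the
#'   C++ engine).
#' @export
network <- function(dt = 0.1) {
  net <- new.env(parent = emptyenv())
  net$ptr <- eng_create(dt)
  net$dt <- dt
  net$pops <- list()
  net$projs <- list()
  net$finalized <- FALSE
  class(net) <- "snn_network"
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> dt =", x$dt, "ms;", length(x$pops), "populations,",
      length(x$projs), "projections,",
      sum(vapply(x$projs, function(p) p$n_synapses, 0)), "synapses\n")
  invisible(x)
}

#' Build a neuron population
#'
#' Allocates `size` neurons with contiguous, globally unique ids (gids,
#' 0-based) and membrane potentials initialised at rest. Generator populations
#' (`generator = TRUE`) do not integrate; their spikes are injected with
#' [inject_spikes()] and propagated through outgoing projections like any
#' other spike.
#'
#' @param net A network from [network()].
#' @param name Population label.
#' @param size Number of neurons (>= 1).
#' @param params A [neuron_params()] object.
#' @param generator Logical; spike-source population driven from R.
#' @param bias_mv Constant tonic drive, expressed as the steady-state membrane
#'   depolarisation (mV) it produces. Values above `v_thresh - v_rest` make
#'   the population fire tonically (see [bias_for_rate()]).
#' @return A `population` object (`name`, `size`, `first_gid`, `params`).
#' @export
build_population <- function(net, name, size, params = neuron_params(),
                             generator = FALSE, bias_mv = 0) {
  stopifnot(inherits(net, "snn_network"))
  if (!is.numeric(size) || size < 1) stop("population size must be >= 1")
  first <- eng_add_population(net$ptr, name, as.integer(size), !generator,
                              params$tau_m, params$v_rest, params$v_thresh,
                              params$v_reset, params$t_ref, bias_mv)
  pop <- structure(list(name = name, size = as.integer(size),
                        first_gid = first, params = params,
                        generator = generator, bias_mv = bias_mv),
                   class = "population")
  net$pops[[name]] <- pop
  pop
}

#' Gids of a population
#' @param pop A `population` object.
#' @return Integer vector of 0-based global neuron ids.
#' @export
gids <- function(pop) pop$first_gid + seq_len(pop$size) - 1L

#' Connect two populations
#'
#' Connection rules mirror the convergence/divergence bookkeeping of the
#' network's wiring tables:
#' * `one_to_all`: every pre neuron contacts every post neuron,
#' * `all_to_one`: every pre neuron contacts one shared post target
#'   (round-robin over post for multi-target relays, i.e. pre block k maps to
#'   post k when `pre.size = convergence * post.size`),
#' * `one_to_one`: seeded injective map from pre onto post (requires
#'   `post.size >= pre.size`),
#' * `fixed_convergence`: each post neuron samples `convergence` distinct pre
#'   partners without replacement (at most one synapse per (pre, post) pair).
#'
#' @param net Network.
#' @param pre,post `population` objects.
#' @param rule Connection rule (see Details).
#' @param polarity `"excitatory"`, `"inhibitory"` (weight applied with
#'   negative sign) or `"teaching"` (no current; gates plasticity).
#' @param weight Synaptic efficacy, mV of instantaneous deflection (>= 0;
#'   the sign comes from `polarity`).
#' @param delay Transmission delay (ms), >= simulation step.
#' @param convergence Number of presynaptic partners per post neuron
#'   (`fixed_convergence` and `all_to_one` rules).
#' @param seed RNG seed for the sampled rules (reproducible wiring).
#' @param plastic Mark the projection plastic (at most one per network).
#' @return A `projection` object with the edge list and synapse count.
#' @export
connect <- function(net, pre, post,
                    rule = c("one_to_all", "all_to_one", "one_to_one",
                             "fixed_convergence"),
                    polarity = c("excitatory", "inhibitory", "teaching"),
                    weight = 1, delay = 1, convergence = NULL, seed = NULL,
                    plastic = FALSE) {
  rule <- match.arg(rule)
  polarity <- match.arg(polarity)
  pre_g <- gids(pre); post_g <- gids(post)
  if (rule == "one_to_all") {
    edges <- expand.grid(pre = pre_g, post = post_g)
  } else if (rule == "all_to_one") {
    conv <- if (is.null(convergence)) pre$size %/% post$size else convergence
    if (conv > pre$size) stop("convergence exceeds presynaptic population size")
    if (conv * post$size != pre$size)
      stop("all_to_one requires pre.size = convergence * post.size")
    edges <- data.frame(pre = pre_g,
                        post = rep(post_g, each = conv))
  } else if (rule == "one_to_one") {
    if (post$size < pre$size) stop("one_to_one requires post.size >= pre.size")
    if (!is.null(seed)) set.seed(seed)
    tgt <- if (post$size == pre$size) post_g else sample(post_g, pre$size)
    edges <- data.frame(pre = pre_g, post = tgt)
  } else {
    if (is.null(convergence)) stop("fixed_convergence requires `convergence`")
    if (convergence > pre$size)
      stop("convergence exceeds presynaptic population size")
    if (convergence == 0) {
      warning("convergence 0: empty projection")
      edges <- data.frame(pre = integer(0), post = integer(0))
    } else {
      if (!is.null(seed)) set.seed(seed)
      edges <- data.frame(
        pre = as.vector(vapply(seq_len(post$size),
                               function(i) sample(pre_g, convergence),
                               integer(convergence))),
        post = rep(post_g, each = convergence))
    }
  }
  sgn <- if (polarity == "inhibitory") -1 else 1
  w <- rep(sgn * weight, nrow(edges))
  proj_id <- eng_add_projection(net$ptr, as.integer(edges$pre),
                                as.integer(edges$post), w, delay,
                                polarity == "teaching", plastic)
  proj <- structure(list(pre = pre$name, post = post$name, rule = rule,
                         polarity = polarity, weight = weight, delay = delay,
                         n_synapses = nrow(edges), edges = edges,
                         proj_id = proj_id, plastic = plastic),
                    class = "projection")
  net$projs[[length(net$projs) + 1L]] <- proj
  names(net$projs)[length(net$projs)] <- paste0(pre$name, "->", post$name)
  proj
}

#' Finalize network construction
#'
#' Builds the delivery tables; no further populations or projections can be
#' added afterwards.
#' @param net Network.
#' @export
net_finalize <- function(net) {
  eng_finalize(net$ptr)
  net$finalized <- TRUE
  invisible(net)
}

#' Advance the simulation
#'
#' Runs the clock-driven engine up to absolute time `t_stop` (ms since the
#' last [reset_network()]). Each 0.1 ms step applies the exact exponential
#' leak, delivers delayed synaptic kicks, then evaluates thresholds;
#' simultaneous spikes across neurons are allowed, and a spiking neuron is
#' clamped at reset for its refractory period.
#'
#' @param net Network (finalized).
#' @param t_stop Absolute stop time (ms).
#' @export
net_run <- function(net, t_stop) {
  eng_run(net$ptr, t_stop)
  invisible(net)
}

#' Inject generator spikes
#'
#' @param net Network.
#' @param pop Generator population.
#' @param cell 1-based cell indices within `pop` (recycled against `times`).
#' @param times Spike times (ms); times at or before the current simulation
#'   time are moved to the next step.
#' @export
inject_spikes <- function(net, pop, cell, times) {
  if (length(times) == 0) return(invisible(net))
  g <- pop$first_gid + as.integer(cell) - 1L
  if (length(g) == 1) g <- rep(g, length(times))
  eng_inject(net$ptr, g, as.numeric(times))
  invisible(net)
}

#' Retrieve recorded spikes
#'
#' @param net Network.
#' @param clear Drop the returned spikes from the engine buffer.
#' @return A data.frame with columns `gid`, `time` (ms).
#' @export
get_spikes <- function(net, clear = TRUE) {
  sp <- eng_spikes(net$ptr, clear)
  data.frame(gid = sp$gid, time = sp$time)
}

#' Filter spikes of one population
#' @param spikes Spike data.frame (`gid`, `time`).
#' @param pop Population.
#' @return Spike data.frame restricted to `pop`, with a `cell` column
#'   (1-based index within the population).
#' @export
spikes_of <- function(spikes, pop) {
  sel <- spikes$gid >= pop$first_gid & spikes$gid < pop$first_gid + pop$size
  out <- spikes[sel, , drop = FALSE]
  out$cell <- out$gid - pop$first_gid + 1L
  out
}

#' Reset dynamic state
#'
#' Membrane potentials return to rest, buffers, pending injections, spike
#' records and plasticity eligibility histories are cleared, and time returns
#' to 0. Synaptic weights persist.
#' @param net Network.
#' @export
reset_network <- function(net) {
  eng_reset(net$ptr)
  invisible(net)
}

#' Population instantaneous firing rate
#'
#' The instantaneous rate of a population is the spike count per time bin
#' (default 10 ms) normalized by the number of cells, in Hz. With 20 neurons
#' and 10 ms bins the rate is quantized in steps of 5 Hz and spans 0-100 Hz
#' when each neuron fires at most once per bin.
#'
#' @param spikes Spike data.frame (`gid`, `time`).
#' @param pop Population (must be non-empty).
#' @param bin_width Bin width (ms), > 0.
#' @param t_start,t_stop Analysis window (ms); `t_stop` defaults to the last
#'   full bin containing a spike.
#' @return A data.frame of class `rate_trace` with columns `bin_start`
#'   (ms) and `rate` (Hz); attributes `population`, `bin_width`.
#' @export
instantaneous_rate <- function(spikes, pop, bin_width = 10, t_start = 0,
                               t_stop = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(pop$size) || pop$size < 1) stop("empty population")
  sp <- spikes_of(spikes, pop)
  if (is.null(t_stop)) {
    t_stop <- if (nrow(sp)) ceiling(max(sp$time) / bin_width) * bin_width
              else t_start + bin_width
  }
  breaks <- seq(t_start, t_stop, by = bin_width)
  if (length(breaks) < 2) breaks <- c(t_start, t_start + bin_width)
  tt <- sp$time[sp$time > t_start & sp$time <= t_stop]
  counts <- if (length(tt)) hist(tt, breaks = breaks, plot = FALSE)$counts
            else integer(length(breaks) - 1)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    rate = counts / (pop$size * bin_width) * 1000)
  attr(out, "population") <- pop$name
  attr(out, "bin_width") <- bin_width
  class(out) <- c("rate_trace", "data.frame")
  out
}

#' Tonic bias producing a target firing rate
#'
#' Inverts the LIF f-I relation
#' `rate = 1 / (t_ref + tau_m * log(d / (d - (v_thresh - v_rest))))`
#' for the steady-state depolarisation `d` (mV).
#'
#' @param rate Target tonic rate (Hz).
#' @param params [neuron_params()].
#' @return Bias in mV (steady-state depolarisation above rest).
#' @export
bias_for_rate <- function(rate, params = neuron_params()) {
  theta <- params$v_thresh - params$v_rest
  isi <- 1000 / rate
  k <- exp((isi - params$t_ref) / params$tau_m)
  theta * k / (k - 1)
}

#' Analytic LIF tonic rate under constant drive
#' @param bias_mv Steady-state depolarisation (mV).
#' @param params [neuron_params()].
#' @return Firing rate (Hz); 0 if subthreshold.
#' @export
lif_rate <- function(bias_mv, params = neuron_params()) {
  theta <- params$v_thresh - params$v_rest
  if (bias_mv <= theta) return(0)
  1000 / (params$t_ref + params$tau_m * log(bias_mv / (bias_mv - theta)))
}

#' Write / read spike rasters
#'
#' Plain-text raster: two whitespace-separated columns `gid time_ms`, one
#' spike per line, with a JSON population map alongside. The round trip is
#' bit-exact.
#'
#' @param spikes Spike data.frame.
#' @param pops List of `population` objects (for the population map).
#' @param path Raster file path; the population map goes to
#'   `paste0(path, ".popmap.json")`.
#' @export
write_raster <- function(spikes, pops, path) {
  writeLines(sprintf("%d %.17g", spikes$gid, spikes$time), path)
  pm <- lapply(pops, function(p)
    list(name = p$name, first_gid = p$first_gid, size = p$size))
  jsonlite::write_json(unname(pm), paste0(path, ".popmap.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @return `read_raster` returns `list(spikes, popmap)`.
#' @export
read_raster <- function(path) {
  m <- if (file.size(path) == 0) {
    matrix(numeric(0), ncol = 2)
  } else {
    matrix(scan(path, what = numeric(), quiet = TRUE), ncol = 2, byrow = TRUE)
  }
  pm <- jsonlite::read_json(paste0(path, ".popmap.json"), simplifyVector = TRUE)
  list(spikes = data.frame(gid = as.integer(m[, 1]), time = m[, 2]),
       popmap = pm)
}

#' Write a rate trace as CSV (`bin_start_ms,rate_hz`)
#' @param trace A `rate_trace`.
#' @param path Output path.
#' @export
write_rate_trace <- function(trace, path) {
  df <- data.frame(bin_start_ms = trace$bin_start, rate_hz = trace$rate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
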