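#' Default configuration
#'
#' Every tunable of the simulator in one nested list: neuron defaults, plant
#' mechanics, bar placement, encoder rates, motor gains and weights,
#' cerebellar sizes/weights, plasticity constants and the GO/NOGO protocol.
#' Values not fixed by the modelled system (wiring tables, rates, delays,
#' plasticity constants, protocol) are calibration choices documented in the
#' methods vignette.
#'
#' @param ... Named overrides, e.g. `default_config(cpg_rate = 5)`; nested
#'   lists are replaced wholesale only for the names given.
#' @return A nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    dt = 0.1,                    # ms, engine and plant step
    bin_width = 10,              # ms, rate bins / torque hold
    sensory_dt = 1,              # ms, encoder sampling
    cpg_rate = 4,                # Hz
    gains = list(alpha_pro = 1.5e-3, alpha_ret = 1.0e-3),
    w_cpg_fn = 20,               # mV, CPG->FN (one spike per cycle per cell)
    w_tg_tn = 2,                 # mV, TG contact -> TN contact
    tn_tau = 10, tn_ref = 2,     # TN contact relay dynamics
    w_reflex = 20, w_reflex_inh = 20, reflex_delay = 7.5,
    plant = list(inertia = 8e-5, damping = 2.5e-3, stiffness = 2e-2,
                 rest_angle = 0, restitution = 0.4, stick_velocity = 150,
                 release_margin = 4),
    bar = list(angular_position = 15, radial_distance = 10,
               start = 0, stop = 1000),
    bank = list(angle_min = -5, angle_max = 30, pressure_rate = 27,
                ht_rate = 50, whisking_peak_rate = 30),
    cerebellum = list(),         # overrides for cerebellum_spec()
    plasticity = list(),         # overrides for plasticity_params()
    genotype = "control",
    trial_duration = 2000,       # ms
    n_sessions = 27, trials_per_session = 10)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Load a configuration file
#'
#' A structured `key: value` (YAML) file whose entries override
#' [default_config()].
#' @param path Config file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Write the resolved-parameter manifest
#' @param sys A whisker system (or a config list).
#' @param path Output path (YAML).
#' @export
write_manifest <- function(sys, path) {
  cfg <- if (!is.null(sys$config)) sys$config else sys
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Assemble the full closed-loop whisker system
#'
#' Builds the whisker plant, the peripheral spiking network (TG generator
#' banks, TN contact relay and phase decoder, CPG, facial nuclei with the
#' trigeminal reflex) and the cerebellar module, wired per the default
#' connectivity tables.
#'
#' @param config From [default_config()].
#' @param seed Master seed; fans out to independent substreams for wiring,
#'   encoder sampling and schedules.
#' @param reflex Include the trigeminal reflex projections (ablation switch).
#' @return A `whisker_system` environment.
#' @export
build_whisker_system <- function(config = default_config(), seed = 1,
                                 reflex = TRUE) {
  sys <- new.env(parent = emptyenv())
  sys$config <- config
  sys$seed <- seed
  sys$geometry <- whisker_geometry()
  sys$whiskers <- sys$geometry$name
  sys$side <- stats::setNames(sys$geometry$side, sys$whiskers)
  sys$plant_params <- do.call(plant_params, config$plant)
  sys$bank <- do.call(tg_bank, config$bank)
  sys$gains <- do.call(torque_gains, config$gains)
  sys$plast <- apply_genotype(do.call(plasticity_params, config$plasticity),
                              config$genotype)
  sys$cspec <- do.call(cerebellum_spec, config$cerebellum)

  net <- network(config$dt)
  gen <- neuron_params(t_ref = 0)
  # TG banks: 5 classes x 20 cells per whisker (generators)
  sys$tg <- list()
  # class-major layout keeps each class contiguous across whiskers (the
  # pressure block is a valid 80-cell source for the mossy-fiber map)
  for (cl in c("contact", "detach", "pressure", "high_threshold", "whisking"))
    for (w in sys$whiskers)
      sys$tg[[paste(w, cl, sep = ".")]] <-
        build_population(net, paste0("TG_", cl, "_", w), 20, gen,
                         generator = TRUE)
  # TN: contact relay (LIF, 1/whisker) + phase decoder output (generators)
  sys$tn_contact <- build_population(net, "TN_contact", 4,
    neuron_params(tau_m = config$tn_tau, t_ref = config$tn_ref))
  sys$tn_phase <- list()
  for (w in sys$whiskers)
    sys$tn_phase[[w]] <- build_population(net, paste0("TN_phase_", w), 20,
                                          gen, generator = TRUE)
  # motor pathway
  sys$motor <- build_motor(net)
  wire_motor(net, sys$motor, if (reflex) sys$tn_contact else NULL,
             w_cpg = config$w_cpg_fn, w_reflex = config$w_reflex,
             w_reflex_inh = config$w_reflex_inh,
             reflex_delay = config$reflex_delay)
  # TG contact -> TN contact (all-to-one per whisker)
  tg_contact_gids <- unlist(lapply(sys$whiskers, function(w)
    gids(sys$tg[[paste(w, "contact", sep = ".")]])))
  connect_manual(net, "TG_contact", "TN_contact", tg_contact_gids,
                 rep(gids(sys$tn_contact), each = 20), config$w_tg_tn, 1)
  # composite source populations in afferent order (L0, L1, R0, R1)
  sys$tg_pressure_all <- composite_pop("TG_pressure",
    lapply(sys$whiskers, function(w) sys$tg[[paste(w, "pressure", sep = ".")]]))
  sys$tn_phase_all <- composite_pop("TN_phase", sys$tn_phase)
  # cerebellum
  set.seed(seed * 1000L + 17L)
  sys$cb <- build_cerebellum(net, sys$cspec, sys$plast, seed = seed * 1000L)
  map_afferents(net, sys$tg_pressure_all, sys$tn_phase_all, sys$cb$mf,
                weight = sys$cspec$w_mf_relay, seed = seed * 1000L)
  net_finalize(net)
  eng_set_io_map(net$ptr, gids(sys$cb$io), gids(sys$cb$pc))
  eng_set_plasticity(net$ptr, sys$plast$ltp_step, sys$plast$ltd_scale,
                     sys$plast$weight_min, sys$plast$weight_max,
                     kernel_lut(sys$plast, config$dt),
                     sys$plast$coincidence_window, TRUE)
  sys$net <- net
  sys$reflex <- reflex
  class(sys) <- "whisker_system"
  sys
}

# non-standard (per-whisker indexed) projection; bookkeeping only
connect_manual <- function(net, pre_name, post_name, pre_g, post_g, w, delay) {
  id <- eng_add_projection(net$ptr, as.integer(pre_g), as.integer(post_g),
                           rep(w, length(pre_g)), delay, FALSE, FALSE)
  proj <- structure(list(pre = pre_name, post = post_name,
                         polarity = if (w < 0) "inhibitory" else "excitatory",
                         n_synapses = length(pre_g), proj_id = id),
                    class = "projection")
  net$projs[[paste0(pre_name, "->", post_name)]] <- proj
  proj
}

# view over contiguous populations (afferent blocks are laid out in order)
composite_pop <- function(name, pops) {
  first <- min(vapply(pops, function(p) p$first_gid, 0L))
  size <- sum(vapply(pops, function(p) p$size, 0L))
  structure(list(name = name, size = size, first_gid = first,
                 members = pops), class = "population")
}

#' Construction census
#'
#' Synapse counts per projection and population sizes of the default build,
#' for verification against the model's wiring tables.
#' @param sys A `whisker_system`.
#' @return List with `synapses` (named counts) and `populations`.
#' @export
construction_census <- function(sys) {
  net <- sys$net
  syn <- vapply(net$projs, function(p) p$n_synapses, 0)
  pops <- vapply(net$pops, function(p) p$size, 0L)
  list(synapses = syn, populations = pops)
}

#' GO/NOGO trial configuration
#' @param type `"GO"` (bar left) or `"NOGO"` (bar right).
#' @param config System configuration.
#' @return A `trial_config` object.
#' @export
trial_config <- function(type = c("GO", "NOGO"), config = default_config()) {
  type <- match.arg(type)
  bar_side <- if (type == "GO") "left" else "right"
  structure(list(type = type, duration = config$trial_duration,
                 bar = bar_stimulus(bar_side,
                                    config$bar$angular_position,
                                    config$bar$radial_distance,
                                    config$bar$start, config$bar$stop),
                 response_window = c(0, config$trial_duration)),
            class = "trial_config")
}

#' Build a randomized GO/NOGO protocol
#'
#' Sessions of `trials_per_session` trials, half GO and half NOGO in a
#' seeded random order per session (default 27 sessions of 10 trials:
#' 270 trials).
#'
#' @param n_sessions Number of sessions.
#' @param trials_per_session Trials per session (even).
#' @param genotype `"control"` or `"l7pp2b"`.
#' @param seed Schedule seed.
#' @return A `protocol` object with the trial table.
#' @export
make_protocol <- function(n_sessions = 27, trials_per_session = 10,
                          genotype = "control", seed = 1) {
  if (trials_per_session %% 2 != 0)
    stop("trials_per_session must be even (5 GO / 5 NOGO split per 10)")
  set.seed(seed * 1000L + 101L)
  half <- trials_per_session / 2
  trials <- do.call(rbind, lapply(seq_len(n_sessions), function(s)
    data.frame(session = s, trial = seq_len(trials_per_session),
               type = sample(rep(c("GO", "NOGO"), half)),
               stringsAsFactors = FALSE)))
  structure(list(n_sessions = n_sessions,
                 trials_per_session = trials_per_session,
                 genotype = genotype, seed = seed, trials = trials),
            class = "protocol")
}

map_tg_spikes <- function(sys, sp) {
  # spike data.frame (whisker, class, cell, time) -> gids
  key <- paste(sp$whisker, sp$class, sep = ".")
  phase <- sp$class == "phase"
  first <- integer(nrow(sp))
  if (any(!phase))
    first[!phase] <- vapply(key[!phase],
                            function(k) sys$tg[[k]]$first_gid, 0L)
  if (any(phase))
    first[phase] <- vapply(sp$whisker[phase],
                           function(w) sys$tn_phase[[w]]$first_gid, 0L)
  first + sp$cell - 1L
}

#' Run one closed-loop trial
#'
#' Orchestrates the full loop at the rate-bin resolution (10 ms): facial
#' nucleus rates of the previous bin are decoded into torques (zero-order
#' hold), the plant is integrated at 0.1 ms, its kinematics drive the TG
#' encoders and the TN phase decoder, their spikes are injected into the
#' network together with the scheduled CPG drive, and the engine advances
#' one bin. DCN activity is monitored through the whole response window; the
#' first threshold crossing latches the (single) response, and in GO trials
#' triggers the IO reward burst, whose coincidence with PC spikes drives
#' depression at the PF->PC synapses. Plasticity persists on the engine
#' across trials; plant and membrane state are reset per trial.
#'
#' @param sys A `whisker_system`.
#' @param trial A [trial_config()].
#' @param trial_seed Seed for this trial's encoder sampling.
#' @param record `"none"`, or `"spikes"` to also return the full raster.
#' @return A list: `type`, `responded`, `response_time`, `rewarded`, and
#'   optionally `spikes`, `kinematics`.
#' @export
run_trial <- function(sys, trial, trial_seed = 1, record = "none") {
  cfg <- sys$config
  net <- sys$net
  reset_network(net)
  set.seed(trial_seed)
  # desynchronize tonically active Purkinje cells
  pcg <- gids(sys$cb$pc)
  pp <- sys$cb$pc$params
  eng_set_V(net$ptr, pcg,
            stats::runif(length(pcg), pp$v_rest, pp$v_thresh))
  inject_spikes(net, sys$motor$cpg, 1L,
                cpg_spike_times(trial$duration, cfg$cpg_rate))
  state <- plant_init(sys$geometry, sys$plant_params)
  bw <- cfg$bin_width
  nbins <- ceiling(trial$duration / bw)
  steps_per_bin <- round(bw / cfg$dt)
  rec_every <- round(cfg$sensory_dt / cfg$dt)
  torque <- stats::setNames(rep(0, 4), sys$whiskers)
  responded <- FALSE
  response_time <- NA_real_
  all_spikes <- if (record == "spikes") vector("list", nbins) else NULL
  kin_list <- if (record == "spikes") vector("list", nbins) else NULL
  torque_list <- if (record == "spikes") vector("list", nbins) else NULL
  prev_contact <- stats::setNames(rep(FALSE, 4), sys$whiskers)
  pressure_recent <- stats::setNames(rep(-Inf, 4), sys$whiskers)
  dcn <- sys$cb$dcn
  dcn_need <- cfg$bin_width * dcn$size * sys$cspec$dcn_threshold / 1000
  bank <- sys$bank
  first_of <- function(w, cl) sys$tg[[paste(w, cl, sep = ".")]]$first_gid
  for (b in seq_len(nbins)) {
    t0 <- (b - 1) * bw
    pr <- plant_run(state, torque[sys$whiskers], trial$bar, dt = cfg$dt,
                    n_steps = steps_per_bin, record_every = rec_every)
    state <- pr$state
    tr <- pr$traj
    gid_acc <- vector("list", 24L); tm_acc <- vector("list", 24L); na <- 0L
    add <- function(core, first) {
      if (length(core$time)) {
        na <<- na + 1L
        gid_acc[[na]] <<- first + core$cell - 1L
        tm_acc[[na]] <<- core$time
      }
    }
    ev <- tr$events
    for (wi in seq_along(sys$whiskers)) {
      w <- sys$whiskers[wi]
      ct <- tr$contact[, wi] == 1
      # contact/detach bursts at the plant's exact event times
      evw <- ev$whisker == wi
      add(enc_burst_core(ev$time[evw & ev$type == 1], bank$n_per_class,
                         bank$burst_jitter), first_of(w, "contact"))
      add(enc_burst_core(ev$time[evw & ev$type == 2], bank$n_per_class,
                         bank$burst_jitter), first_of(w, "detach"))
      prs <- enc_pressure_core(tr$time, ct, cfg$sensory_dt, bank)
      add(prs, first_of(w, "pressure"))
      add(enc_ht_core(tr$time, ct,
                      ifelse(ct, tr$contact_distance, NA_real_),
                      cfg$sensory_dt, bank), first_of(w, "high_threshold"))
      wk <- enc_whisk_core(tr$time, tr$angle[, wi], cfg$sensory_dt, bank)
      add(wk, first_of(w, "whisking"))
      # phase decoder: gate on pressure activity incl. the previous bin
      pt <- prs$time
      if (is.finite(pressure_recent[w])) pt <- c(pressure_recent[w], pt)
      add(phase_core(wk$cell, wk$time, pt, bank$gating_window),
          sys$tn_phase[[w]]$first_gid)
      if (length(prs$time))
        pressure_recent[w] <- max(prs$time)
    }
    prev_contact[] <- state$in_contact
    if (na > 0) {
      g <- unlist(gid_acc[seq_len(na)], use.names = FALSE)
      tt <- unlist(tm_acc[seq_len(na)], use.names = FALSE)
      eng_inject(net$ptr, g, pmax(tt, t0 + cfg$dt))
    }
    net_run(net, t0 + bw)
    bin_sp <- get_spikes(net, clear = TRUE)
    if (record == "spikes") {
      all_spikes[[b]] <- bin_sp
      kin_list[[b]] <- kinematics_frame(tr, sys$geometry)
      torque_list[[b]] <- data.frame(time_ms = t0, whisker = sys$whiskers,
                                     torque_Nm = unname(torque[sys$whiskers]))
    }
    # torque for the next bin from this bin's FN rates (Eq. of the decoder)
    fr_pro <- vapply(sys$whiskers, function(w) {
      p <- sys$motor$pro[[w]]
      sum(bin_sp$gid >= p$first_gid & bin_sp$gid < p$first_gid + p$size) /
        p$size / bw * 1000 }, 0)
    fr_ret <- vapply(c("left", "right"), function(s) {
      p <- sys$motor$ret[[s]]
      sum(bin_sp$gid >= p$first_gid & bin_sp$gid < p$first_gid + p$size) /
        p$size / bw * 1000 }, 0)
    torque <- decode_torque(fr_pro, fr_ret, sys$gains)
    # response detection (latched)
    if (!responded && t0 + bw >= trial$response_window[1] &&
        t0 < trial$response_window[2]) {
      ndcn <- sum(bin_sp$gid >= dcn$first_gid &
                    bin_sp$gid < dcn$first_gid + dcn$size)
      if (ndcn > dcn_need) {
        responded <- TRUE
        response_time <- t0 + bw
        io_times <- encode_reward(response_time, trial$type, sys$cspec)
        if (length(io_times)) {
          iog <- gids(sys$cb$io)
          eng_inject(net$ptr, rep(iog, each = length(io_times)),
                     rep(io_times, times = length(iog)))
        }
      }
    }
  }
  out <- list(type = trial$type, responded = responded,
              response_time = response_time,
              rewarded = responded && trial$type == "GO")
  if (record == "spikes") {
    out$spikes <- do.call(rbind, all_spikes)
    out$kinematics <- do.call(rbind, kin_list)
    out$torques <- do.call(rbind, torque_list)
  }
  out
}

#' Run free whisking
#'
#' Closed-loop run with no object in the whisker field (motor pathway and
#' plant only drive the dynamics; all contact-dependent populations stay
#' silent).
#'
#' @param sys A `whisker_system`.
#' @param duration Simulated time (ms).
#' @param seed Encoder-sampling seed.
#' @return `list(spikes, kinematics)`.
#' @export
run_free_whisking <- function(sys, duration = 10000, seed = 1) {
  cfg <- sys$config
  trial <- structure(list(type = "FREE", duration = duration,
                          bar = bar_stimulus("none"),
                          response_window = c(Inf, Inf)),
                     class = "trial_config")
  res <- run_trial(sys, trial, trial_seed = seed, record = "spikes")
  list(spikes = res$spikes, kinematics = res$kinematics)
}

#' Run a full learning experiment
#'
#' Sequential execution of a protocol's trials with plasticity persisting
#' across trials (plant and membrane state are reset per trial, synaptic
#' weights never are). Per session, the hit rate (% of GO trials with a
#' response) and false-alarm rate (% of NOGO trials with a response) are
#' recorded.
#'
#' @param protocol From [make_protocol()].
#' @param config Configuration; the protocol's genotype overrides the
#'   config's.
#' @param outdir Optional output directory (`metrics.csv`, manifest, final
#'   weight snapshot).
#' @param verbose Print per-session metrics.
#' @return A data.frame `session, hit_rate, false_alarm_rate` (class
#'   `session_metrics`), with the per-trial results as attribute `trials`.
#' @export
run_experiment <- function(protocol, config = default_config(),
                           outdir = NULL, verbose = FALSE) {
  config$genotype <- protocol$genotype
  config$n_sessions <- protocol$n_sessions
  config$trials_per_session <- protocol$trials_per_session
  sys <- build_whisker_system(config, seed = protocol$seed)
  tr <- protocol$trials
  tr$responded <- FALSE
  tr$response_time <- NA_real_
  tr$rewarded <- FALSE
  for (i in seq_len(nrow(tr))) {
    res <- run_trial(sys, trial_config(tr$type[i], config),
                     trial_seed = protocol$seed * 100000L + i)
    tr$responded[i] <- res$responded
    tr$response_time[i] <- res$response_time
    tr$rewarded[i] <- res$rewarded
  }
  metrics <- do.call(rbind, lapply(split(tr, tr$session), function(s)
    data.frame(session = s$session[1],
               hit_rate = 100 * mean(s$responded[s$type == "GO"]),
               false_alarm_rate = 100 * mean(s$responded[s$type == "NOGO"]))))
  rownames(metrics) <- NULL
  if (verbose)
    for (i in seq_len(nrow(metrics)))
      message(sprintf("session %d: hit %.0f%%, FA %.0f%%",
                      metrics$session[i], metrics$hit_rate[i],
                      metrics$false_alarm_rate[i]))
  attr(metrics, "trials") <- tr
  attr(metrics, "genotype") <- protocol$genotype
  class(metrics) <- c("session_metrics", "data.frame")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    write_manifest(sys, file.path(outdir, "manifest.yaml"))
    w <- eng_weights(sys$net$ptr, sys$cb$plastic_proj)
    ed <- sys$cb$projs$pf_pc$edges
    utils::write.csv(data.frame(session = protocol$n_sessions,
                                pc = ed$post - sys$cb$pc$first_gid + 1L,
                                pf = ed$pre - sys$cb$grc$first_gid + 1L,
                                weight = w),
                     file.path(outdir, "pf_pc_weights.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  metrics
}

#' Compare control and plasticity-impaired genotypes
#'
#' Runs paired experiments (identical seeds, hence identical wiring,
#' schedules and encoder noise; only the LTP constant differs) for both
#' genotypes over several repeats.
#'
#' @param n_repeats Number of paired repeats.
#' @param n_sessions,trials_per_session Protocol size.
#' @param config Configuration.
#' @param seeds Optional explicit seeds (length `n_repeats`).
#' @return A data.frame `genotype, repeat, session, hit_rate,
#'   false_alarm_rate`; per-session mean and SD in attribute `summary`.
#' @export
compare_genotypes <- function(n_repeats = 10, n_sessions = 27,
                              trials_per_session = 10,
                              config = default_config(), seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  out <- list()
  for (g in c("control", "l7pp2b"))
    for (r in seq_len(n_repeats)) {
      m <- run_experiment(make_protocol(n_sessions, trials_per_session,
                                        genotype = g, seed = seeds[r]),
                          config)
      m$genotype <- g
      m$repeat_id <- r
      out[[paste(g, r)]] <- as.data.frame(m)
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  summ <- do.call(rbind, lapply(split(res, list(res$genotype, res$session)),
    function(d) data.frame(genotype = d$genotype[1], session = d$session[1],
                           hit_mean = mean(d$hit_rate),
                           hit_sd = stats::sd(d$hit_rate),
                           fa_mean = mean(d$false_alarm_rate),
                           fa_sd = stats::sd(d$false_alarm_rate))))
  summ <- summ[order(summ$genotype, summ$session), ]
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  res
}
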