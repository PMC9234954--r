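# Independent reference implementations used as oracles.

# Brute-force clock-driven LIF stepper mirroring the documented update
# semantics: exact exponential leak toward v_rest + bias, delayed delta
# kicks (ignored during refractoriness), threshold after input application,
# reset + refractory clamp with first eligible spike at t + t_ref + dt.
ref_lif_run <- function(n, params, bias_mv, edges, injections, n_steps,
                        dt = 0.1) {
  tau <- params$tau_m; vr <- params$v_rest; vth <- params$v_thresh
  vre <- params$v_reset
  tref_steps <- round(params$t_ref / dt)
  vinf <- vr + bias_mv
  decay <- exp(-dt / tau)
  V <- rep(vr, n)
  refrac_until <- rep(-Inf, n)
  pending <- list() # per future step: list of c(gid, w)
  sp <- list()
  schedule <- function(g, s) {
    sel <- edges$pre == g
    if (!any(sel)) return()
    for (i in which(sel)) {
      key <- as.character(s + edges$delay_steps[i])
      pending[[key]] <<- rbind(pending[[key]],
                               c(edges$post[i], edges$w[i]))
    }
  }
  inj <- split(injections$gid, injections$step)
  for (s in seq_len(n_steps)) {
    for (g in inj[[as.character(s)]]) {
      sp[[length(sp) + 1]] <- c(g, s)
      schedule(g, s)
    }
    refr <- s < refrac_until
    V <- ifelse(refr, vre, vinf + (V - vinf) * decay)
    key <- as.character(s)
    if (!is.null(pending[[key]])) {
      for (r in seq_len(nrow(pending[[key]]))) {
        g <- pending[[key]][r, 1] + 1
        if (s >= refrac_until[g]) V[g] <- V[g] + pending[[key]][r, 2]
      }
      pending[[key]] <- NULL
    }
    for (g in which(V >= vth & !refr)) {
      sp[[length(sp) + 1]] <- c(g - 1, s)
      V[g] <- vre
      refrac_until[g] <- s + tref_steps + 1
      schedule(g - 1, s)
    }
  }
  list(V = V,
       spikes = if (length(sp)) {
         m <- do.call(rbind, sp)
         data.frame(gid = m[, 1], time = m[, 2] * dt)
       } else data.frame(gid = integer(0), time = numeric(0)))
}

# Dense-time reference of the PF->PC plasticity rule: at every PC spike the
# LTD integral is recomputed from the full spike trains (no history buffer).
ref_plasticity_dense <- function(pc_times, io_times, pf_trains, w0, params) {
  w <- w0
  cw <- params$coincidence_window + 1e-9
  for (t in sort(pc_times)) {
    coinc <- any(io_times <= t & t - io_times <= cw)
    if (coinc) {
      for (i in seq_along(w)) {
        lags <- t - pf_trains[[i]]
        lags <- lags[lags >= 0 & lags <= params$integration_window + 1e-9]
        if (length(lags)) {
          ks <- sum(pfpc_kernel(lags, params))
          if (ks > 0) w[i] <- w[i] + params$ltd_scale * ks
        }
      }
    } else {
      for (i in seq_along(w))
        if (any(pf_trains[[i]] <= t & t - pf_trains[[i]] <= cw))
          w[i] <- w[i] + params$ltp_step
    }
    w <- pmin(pmax(w, params$weight_min), params$weight_max)
  }
  w
}

# Closed-form trajectory of the (underdamped) whisker joint under constant
# torque: I th'' + c th' + k (th - rest) = tau.
ref_joint_response <- function(t_s, torque, inertia, damping, stiffness,
                               rest_rad = 0, th0 = 0, om0 = 0) {
  thp <- rest_rad + torque / stiffness
  wn <- sqrt(stiffness / inertia)
  z <- damping / (2 * sqrt(stiffness * inertia))
  stopifnot(z < 1)
  wd <- wn * sqrt(1 - z^2)
  A <- th0 - thp
  B <- (om0 + z * wn * A) / wd
  thp + exp(-z * wn * t_s) * (A * cos(wd * t_s) + B * sin(wd * t_s))
}

# Minimal kinematics stream builder (one whisker, uniform 1 ms sampling).
make_kin <- function(whisker = "L0", duration = 1000, angle = 0,
                     contact_from = NA, contact_to = NA, distance = 10) {
  tms <- seq(1, duration, by = 1)
  ct <- if (is.na(contact_from)) rep(FALSE, length(tms)) else
    tms >= contact_from & tms <= contact_to
  data.frame(time_ms = tms, whisker = whisker,
             angle_deg = if (length(angle) == 1) rep(angle, length(tms))
                         else angle,
             velocity_deg_s = 0,
             in_contact = ct,
             contact_distance_cm = ifelse(ct, distance, NA_real_),
             stringsAsFactors = FALSE)
}

expect_spike_df <- function(sp) {
  expect_true(all(c("whisker", "class", "cell", "time") %in% names(sp)))
}
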