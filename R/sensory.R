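#' Trigeminal ganglion encoder bank
#'
#' Five labeled-line afferent classes per whisker, 20 cells each (100 cells
#' per whisker): contact (burst at contact onset), detach (burst at contact
#' offset), pressure (tonic Poisson-like firing while in contact),
#' high-threshold (fixed-rate firing only when the contact is closer than
#' 2 cm to the snout) and whisking cells (Gaussian angular tuning; preferred
#' angles form a monotone grid over the whisker's motion range, tuning width
#' equal to the grid spacing).
#'
#' @param n_per_class Cells per class per whisker.
#' @param angle_min,angle_max Span of the whisking-cell preferred-angle grid
#'   (deg); default rest - 5 to rest + the calibrated free amplitude.
#' @param pressure_rate Tonic pressure rate during contact (Hz per cell).
#' @param ht_rate Fixed high-threshold rate (Hz per cell).
#' @param ht_distance Proximity threshold (cm); strict `<` comparison.
#' @param whisking_peak_rate Peak of the Gaussian tuning (Hz per cell),
#'   calibrated so the trial-mean whisking rate lands near 4 Hz.
#' @param burst_jitter Max jitter (ms) of contact/detach burst spikes.
#' @param gating_window Pressure-gating window of the phase decoder (ms).
#' @return A `tg_bank` object.
#' @export
tg_bank <- function(n_per_class = 20, angle_min = -5, angle_max = 30,
                    pressure_rate = 27, ht_rate = 50, ht_distance = 2,
                    whisking_peak_rate = 30, burst_jitter = 1,
                    gating_window = 10) {
  pref <- seq(angle_min, angle_max, length.out = n_per_class)
  structure(list(n_per_class = n_per_class, preferred_angle = pref,
                 tuning_width = diff(pref[1:2]),
                 pressure_rate = pressure_rate, ht_rate = ht_rate,
                 ht_distance = ht_distance,
                 whisking_peak_rate = whisking_peak_rate,
                 burst_jitter = burst_jitter, gating_window = gating_window),
            class = "tg_bank")
}

# ---- vectorized per-whisker encoder cores (lists of cell/time vectors) ----

enc_none <- list(cell = integer(0), time = numeric(0))

enc_burst_core <- function(event_times, n, jitter) {
  if (length(event_times) == 0) return(enc_none)
  list(cell = rep(seq_len(n), times = length(event_times)),
       time = rep(event_times, each = n) +
         stats::runif(n * length(event_times)) * jitter)
}

# Poisson thinning of per-(cell,time) intensities lam (n_cells x n_times, Hz).
# Spike times are spread uniformly over each sample interval; `back` caps the
# per-sample backward spread (0 pins the spike at the sample time).
enc_thin_core <- function(times, dt, lam, n, back = NULL) {
  if (length(times) == 0) return(enc_none)
  p <- as.vector(lam) * dt / 1000
  hit <- stats::runif(length(p)) < p
  if (!any(hit)) return(enc_none)
  if (is.null(back)) back <- rep(dt, length(times))
  list(cell = rep.int(seq_len(n), length(times))[hit],
       time = rep(times, each = n)[hit] -
         stats::runif(sum(hit)) * rep(back, each = n)[hit])
}

enc_pressure_core <- function(times, contact, dt, bank, prev = FALSE) {
  tc <- times[contact]
  if (length(tc) == 0) return(enc_none)
  # no backward spread on the first sample of a contact episode, so tonic
  # pressure never precedes the contact onset itself
  prev_ct <- c(prev, contact[-length(contact)])[contact]
  enc_thin_core(tc, dt, matrix(bank$pressure_rate, bank$n_per_class,
                               length(tc)), bank$n_per_class,
                back = ifelse(prev_ct, dt, 0))
}

enc_ht_core <- function(times, contact, dist, dt, bank) {
  sel <- contact & !is.na(dist) & dist < bank$ht_distance
  tc <- times[sel]
  if (length(tc) == 0) return(enc_none)
  isi <- 1000 / bank$ht_rate
  grid <- seq(isi, max(tc) + dt / 2, by = isi)
  keep <- grid[vapply(grid, function(g) any(abs(tc - g) <= dt / 2 + 1e-9),
                      logical(1))]
  if (length(keep) == 0) return(enc_none)
  list(cell = rep(seq_len(bank$n_per_class), times = length(keep)),
       time = rep(keep, each = bank$n_per_class))
}

enc_whisk_core <- function(times, angle, dt, bank) {
  if (length(times) == 0) return(enc_none)
  lam <- bank$whisking_peak_rate *
    exp(-outer(bank$preferred_angle, angle, "-")^2 /
          (2 * bank$tuning_width^2))
  enc_thin_core(times, dt, lam, bank$n_per_class)
}

# phase gate: whisking spikes with a same-whisker pressure spike in the
# trailing window; pure gating (subset of the whisking spike set)
phase_core <- function(w_cell, w_time, p_time, window) {
  if (length(w_time) == 0 || length(p_time) == 0) return(enc_none)
  pt <- sort(p_time)
  idx <- findInterval(w_time, pt)
  ok <- idx >= 1 & (w_time - pt[pmax(idx, 1L)]) < window
  list(cell = w_cell[ok], time = w_time[ok])
}

contact_edges_core <- function(times, contact, prev_contact) {
  prev <- c(prev_contact, contact[-length(contact)])
  list(onset = times[contact & !prev], offset = times[!contact & prev])
}

# ---- data.frame surface ----

empty_spikes <- function() data.frame(whisker = character(0),
                                      class = character(0),
                                      cell = integer(0), time = numeric(0))

as_spike_df <- function(core, whisker, class) {
  if (length(core$time) == 0) return(empty_spikes())
  data.frame(whisker = whisker, class = class, cell = core$cell,
             time = core$time)
}

kin_split <- function(kin) split(kin, kin$whisker)

prev_of <- function(prev_contact, w) {
  if (is.null(prev_contact)) FALSE else isTRUE(prev_contact[[w]])
}

kin_dt <- function(k) if (nrow(k) > 1) diff(k$time_ms[1:2]) else 1

#' Encode contact onsets
#'
#' Each of the 20 contact cells of a whisker emits one spike (with <= 1 ms
#' seeded jitter) at each contact onset; they are silent otherwise.
#'
#' @param kin Kinematics data.frame (`time_ms`, `whisker`, `angle_deg`,
#'   `in_contact`, `contact_distance_cm`), uniformly sampled per whisker.
#' @param bank A [tg_bank()].
#' @param prev_contact Named logical: contact state just before the first
#'   sample (for streamed, bin-by-bin encoding).
#' @return Spike data.frame `whisker`, `class`, `cell`, `time`.
#' @export
encode_contact <- function(kin, bank = tg_bank(), prev_contact = NULL) {
  out <- lapply(kin_split(kin), function(k) {
    ev <- contact_edges_core(k$time_ms, k$in_contact,
                             prev_of(prev_contact, k$whisker[1]))
    as_spike_df(enc_burst_core(ev$onset, bank$n_per_class,
                               bank$burst_jitter), k$whisker[1], "contact")
  })
  rbind(empty_spikes(), do.call(rbind, unname(out)))
}

#' Encode contact offsets
#'
#' Symmetric to [encode_contact()]: one spike per detach cell at each contact
#' offset (bar removed or whisker retracted). A contact truncated by the end
#' of the stream produces no detach spikes.
#' @inheritParams encode_contact
#' @export
encode_detach <- function(kin, bank = tg_bank(), prev_contact = NULL) {
  out <- lapply(kin_split(kin), function(k) {
    ev <- contact_edges_core(k$time_ms, k$in_contact,
                             prev_of(prev_contact, k$whisker[1]))
    as_spike_df(enc_burst_core(ev$offset, bank$n_per_class,
                               bank$burst_jitter), k$whisker[1], "detach")
  })
  rbind(empty_spikes(), do.call(rbind, unname(out)))
}

#' Encode tonic pressure
#'
#' Poisson-like tonic firing of the 20 pressure cells at the configured rate
#' for the whole duration of a contact; silent otherwise. The plant's
#' rigid-stop contact carries no force signal, so the force-dependent tonic
#' response is a fixed rate (default in the 27 Hz band).
#' @inheritParams encode_contact
#' @export
encode_pressure <- function(kin, bank = tg_bank(), prev_contact = NULL) {
  out <- lapply(kin_split(kin), function(k)
    as_spike_df(enc_pressure_core(k$time_ms, k$in_contact, kin_dt(k), bank,
                                  prev_of(prev_contact, k$whisker[1])),
                k$whisker[1], "pressure"))
  rbind(empty_spikes(), do.call(rbind, unname(out)))
}

#' Encode proximal (high-threshold) contacts
#'
#' Fixed-rate regular firing of the high-threshold cells if and only if the
#' whisker is in contact strictly closer than `ht_distance` (2 cm) to the
#' snout. At the default bar placement (10 cm) these cells are never active.
#' @inheritParams encode_contact
#' @export
encode_high_threshold <- function(kin, bank = tg_bank(),
                                  prev_contact = NULL) {
  out <- lapply(kin_split(kin), function(k)
    as_spike_df(enc_ht_core(k$time_ms, k$in_contact, k$contact_distance_cm,
                            kin_dt(k), bank),
                k$whisker[1], "high_threshold"))
  rbind(empty_spikes(), do.call(rbind, unname(out)))
}

#' Encode whisker position (whisking cells)
#'
#' Inhomogeneous Poisson firing with Gaussian angular tuning: cell i fires
#' with intensity `peak * exp(-(theta - pref_i)^2 / (2 width^2))`, so during
#' a sweep the cells activate in preferred-angle order, a labeled-line code
#' for whisker position.
#' @inheritParams encode_contact
#' @export
encode_whisking <- function(kin, bank = tg_bank(), prev_contact = NULL) {
  out <- lapply(kin_split(kin), function(k)
    as_spike_df(enc_whisk_core(k$time_ms, k$angle_deg, kin_dt(k), bank),
                k$whisker[1], "whisking"))
  rbind(empty_spikes(), do.call(rbind, unname(out)))
}

#' Run all five TG encoders
#' @inheritParams encode_contact
#' @return Combined spike data.frame.
#' @export
sensory_encode <- function(kin, bank = tg_bank(), prev_contact = NULL) {
  rbind(encode_contact(kin, bank, prev_contact),
        encode_detach(kin, bank, prev_contact),
        encode_pressure(kin, bank, prev_contact),
        encode_high_threshold(kin, bank, prev_contact),
        encode_whisking(kin, bank, prev_contact))
}

#' Trigeminal-nucleus phase decoder
#'
#' An array of coincidence detectors, one per whisking cell, gating whisking
#' spikes in a logical AND with the same whisker's pressure population: phase
#' cell i copies whisking cell i's spikes during windows in which at least
#' one pressure spike of that whisker occurred within the trailing gating
#' window (default 10 ms). Pure gating: the output spike set is a subset of
#' the whisking spike set, and the result is a labeled-line code of the
#' contact phase.
#'
#' @param whisking_spikes,pressure_spikes Spike data.frames as produced by
#'   the encoders (columns `whisker`, `class`, `cell`, `time`).
#' @param window Gating window (ms).
#' @return Spike data.frame with `class = "phase"`.
#' @export
phase_decode <- function(whisking_spikes, pressure_spikes, window = 10) {
  if (nrow(whisking_spikes) == 0) return(empty_spikes())
  out <- lapply(split(whisking_spikes, whisking_spikes$whisker),
                function(wsp) {
    pt <- pressure_spikes$time[pressure_spikes$whisker == wsp$whisker[1]]
    as_spike_df(phase_core(wsp$cell, wsp$time, pt, window),
                wsp$whisker[1], "phase")
  })
  rbind(empty_spikes(), do.call(rbind, unname(out)))
}
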