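#' Whisker geometry defaults
#'
#' Four rigid cylindrical whiskers anchored at the snout: the lower pair
#' (L0, R0) 50 cm long with an 11 degree roll, the upper pair (L1, R1) 25 cm
#' with 22 degrees, all 1 cm in diameter.
#'
#' @return A data.frame with columns `name`, `length_cm`, `roll_deg`,
#'   `diameter_cm`, `side`.
#' @export
whisker_geometry <- function() {
  data.frame(name = c("L0", "L1", "R0", "R1"),
             length_cm = c(50, 25, 50, 25),
             roll_deg = c(11, 22, 11, 22),
             diameter_cm = 1,
             side = c("left", "left", "right", "right"),
             stringsAsFactors = FALSE)
}

#' Whisker plant parameters
#'
#' A linear damped rotational joint per whisker. Inertia is of the order of a
#' light rigid rod; damping and return stiffness are calibrated so the default
#' motor drive produces a clear 4 Hz protraction-retraction cycle with a free
#' amplitude of a few tens of degrees. `restitution` and `stick_velocity`
#' shape the collision with the bar: fast impacts bounce, slow ones stick.
#'
#' @param inertia Joint inertia (kg m^2).
#' @param damping Viscous damping (N m s / rad).
#' @param stiffness Return-spring stiffness (N m / rad).
#' @param rest_angle Rest angle (deg); 0 = rest, positive = protraction.
#' @param restitution Velocity restitution coefficient at the bar (0-1).
#' @param stick_velocity Impact speed (deg/s) below which contact sticks.
#' @param release_margin Angular retreat (deg) below the stop at which an
#'   engaged contact is released (tip compliance; rebounds inside the margin
#'   do not toggle the contact flag).
#' @return A `plant_params` object.
#' @export
plant_params <- function(inertia = 8e-5, damping = 2.5e-3, stiffness = 2e-2,
                         rest_angle = 0, restitution = 0.4,
                         stick_velocity = 150, release_margin = 4) {
  if (inertia <= 0 || damping <= 0 || stiffness <= 0)
    stop("inertia, damping and stiffness must be > 0")
  structure(list(inertia = inertia, damping = damping, stiffness = stiffness,
                 rest_angle = rest_angle, restitution = restitution,
                 stick_velocity = stick_velocity,
                 release_margin = release_margin),
            class = "plant_params")
}

#' Bar stimulus
#'
#' A vertical bar placed in one whisker field: whiskers on that side are
#' stopped at `angular_position` while the bar is active. The contact
#' distance reported to the sensory encoders is the bar's radial placement
#' (default 10 cm, far enough from the snout that high-threshold afferents
#' stay silent).
#'
#' @param side `"left"`, `"right"` or `"none"`.
#' @param angular_position Protraction angle (deg) at which contact occurs.
#' @param radial_distance Contact distance from the snout (cm).
#' @param start,stop Active interval (ms).
#' @return A `bar_stimulus` object.
#' @export
bar_stimulus <- function(side = c("none", "left", "right"),
                         angular_position = 15, radial_distance = 10,
                         start = 0, stop = 1000) {
  side <- match.arg(side)
  structure(list(side = side, angular_position = angular_position,
                 radial_distance = radial_distance, start = start,
                 stop = stop),
            class = "bar_stimulus")
}

#' Initial plant state
#' @param geometry From [whisker_geometry()].
#' @param params From [plant_params()].
#' @return A `whisker_state` object: per-whisker angle (deg), angular
#'   velocity (deg/s) and contact flag.
#' @export
plant_init <- function(geometry = whisker_geometry(),
                       params = plant_params()) {
  structure(list(geometry = geometry, params = params,
                 angle = rep(params$rest_angle, nrow(geometry)),
                 velocity = rep(0, nrow(geometry)),
                 in_contact = rep(FALSE, nrow(geometry)),
                 time = 0),
            class = "whisker_state")
}

side_code <- function(side) switch(side, none = 0L, left = 1L, right = 2L)

#' Integrate the plant
#'
#' Semi-implicit Euler update of
#' `I d2theta/dt2 = torque - damping * dtheta/dt - stiffness * (theta - rest)`
#' per whisker, with the bar as a hard angular stop. Torques are held constant
#' over the call (zero-order hold).
#'
#' @param state A `whisker_state`.
#' @param torque Torque per whisker (N m), length 4.
#' @param bar A [bar_stimulus()].
#' @param dt Integration step (ms).
#' @param n_steps Number of steps.
#' @param record_every Record the trajectory every k-th step.
#' @return `list(state, traj)`: the updated state and a trajectory list with
#'   `time`, `angle`, `velocity`, `contact` matrices plus an `events`
#'   data.frame of contact onsets (`type` 1) and offsets (`type` 2).
#' @export
plant_run <- function(state, torque, bar = bar_stimulus(), dt = 0.1,
                      n_steps = 100, record_every = 10) {
  stopifnot(inherits(state, "whisker_state"))
  p <- state$params
  side_i <- ifelse(state$geometry$side == "left", 1L, 2L)
  out <- plant_run_cpp(state$angle, state$velocity, state$in_contact,
                       as.numeric(torque), side_i, p$inertia, p$damping,
                       p$stiffness, p$rest_angle, p$restitution,
                       p$stick_velocity, p$release_margin,
                       side_code(bar$side),
                       bar$angular_position, bar$radial_distance,
                       bar$start, bar$stop, state$time, dt,
                       as.integer(n_steps), as.integer(record_every))
  state$angle <- out$final_angle
  state$velocity <- out$final_velocity
  state$in_contact <- out$final_contact
  state$time <- state$time + n_steps * dt
  list(state = state,
       traj = list(time = out$time, angle = out$angle,
                   velocity = out$velocity, contact = out$contact,
                   events = out$events,
                   contact_distance = out$contact_distance))
}

#' Single plant step
#'
#' One `dt` update of the whisker joint dynamics (see [plant_run()]).
#' @inheritParams plant_run
#' @param t Unused; the state carries absolute time.
#' @return The updated `whisker_state`.
#' @export
step_plant <- function(state, torque, bar = bar_stimulus(), t = NULL,
                       dt = 0.1) {
  plant_run(state, torque, bar, dt = dt, n_steps = 1, record_every = 1)$state
}

#' Kinematics of a trajectory as a long data.frame
#'
#' @param traj A trajectory from [plant_run()].
#' @param geometry Whisker geometry (for names).
#' @return Data.frame `time_ms, whisker, angle_deg, velocity_deg_s,
#'   in_contact, contact_distance_cm`.
#' @export
kinematics_frame <- function(traj, geometry = whisker_geometry()) {
  nw <- ncol(traj$angle)
  do.call(rbind, lapply(seq_len(nw), function(wi) {
    ct <- traj$contact[, wi] == 1
    data.frame(time_ms = traj$time, whisker = geometry$name[wi],
               angle_deg = traj$angle[, wi],
               velocity_deg_s = traj$velocity[, wi],
               in_contact = ct,
               contact_distance_cm = ifelse(ct, traj$contact_distance, NA_real_),
               stringsAsFactors = FALSE)
  }))
}

#' Write kinematics CSV
#'
#' Format: `time_ms,whisker,angle_deg,in_contact,contact_distance_cm`. The
#' same format is accepted by [read_kinematics()] to drive the sensory
#' encoders open loop.
#' @param kin A kinematics data.frame from [kinematics_frame()].
#' @param path Output path.
#' @export
write_kinematics <- function(kin, path) {
  df <- kin[, c("time_ms", "whisker", "angle_deg", "in_contact",
                "contact_distance_cm")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_kinematics
#' @export
read_kinematics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$in_contact <- as.logical(df$in_contact)
  df
}
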