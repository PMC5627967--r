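#' Angular acceleration of the rigid compound pendulum
#'
#' Equation of motion of the pendulum body (uniform rod plus point tip mass)
#' about its pivot: `I * acc = -(M_tot * g * d_com) * sin(theta) - c * rate`,
#' with angle measured from the hanging vertical.
#'
#' @param spec A [pendulum_spec()].
#' @param state Numeric vector `c(angle, rate)` in radians and rad/s.
#' @return Angular acceleration, rad/s^2.
#' @examples
#' rigid_pendulum_rhs(pendulum_spec(), c(0, 0)) # stable equilibrium
#' @export
rigid_pendulum_rhs <- function(spec, state) {
  if (!all(is.finite(state)) || length(state) != 2) {
    stop("state must be a finite (angle, rate) pair", call. = FALSE)
  }
  pin <- pendulum_inertia(spec)
  -(pin$mass_moment * spec$gravity * sin(state[1]) +
      spec$pivot_damping * state[2]) / pin$inertia
}

#' Total mechanical energy of the rigid pendulum
#'
#' Kinetic plus gravitational potential energy (zero at the pivot height),
#' used by the energy-conservation checks of the undamped pendulum.
#'
#' @param spec A [pendulum_spec()].
#' @param angle,rate Pendulum state (vectors allowed).
#' @return Energy in joules.
#' @export
pendulum_energy <- function(spec, angle, rate) {
  pin <- pendulum_inertia(spec)
  0.5 * pin$inertia * rate^2 - pin$mass_moment * spec$gravity * cos(angle)
}

# Planar unit vectors for an angle measured from the hanging vertical
# (x horizontal, y up): along-segment u and tangential e_t (direction of
# increasing angle).
.u_vec <- function(phi) c(sin(phi), -cos(phi))
.t_vec <- function(phi) c(cos(phi), sin(phi))

#' Angular accelerations of the fabric chain
#'
#' The fabric is a serial chain of `K` uniform rigid segments hanging from the
#' pendulum tip. Coupling is one-way: the pendulum's tip kinematics drive the
#' chain and the chain does not back-react on the pendulum (the rig's own
#' control experiment shows the appendage leaves the pendulum motion
#' unchanged). Each segment is treated as a compound pendulum about its
#' proximal joint in the non-inertial frame of that joint, so it feels
#' gravity, the pseudo-force from the joint's translational acceleration,
#' torsional spring/damper torques towards its neighbours (the innermost
#' joint's reference angle is the pendulum angle), and translational drag at
#' its centre. Joint accelerations are propagated outwards segment by
#' segment, so the inertial load on segment i already includes the computed
#' accelerations of segments 1..i-1.
#'
#' @param fabric A [fabric_spec()].
#' @param base Named list with pendulum-tip kinematics: `angle`, `rate`
#'   (pendulum angle/rate, rad, rad/s), `vel`, `acc` (tip velocity and
#'   acceleration vectors, m/s and m/s^2, in the x-horizontal/y-up plane).
#' @param state Numeric vector `c(phi_1..phi_K, rate_1..rate_K)` of absolute
#'   segment angles (from vertical) and rates.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return Numeric vector of K angular accelerations, rad/s^2.
#' @examples
#' fb <- fabric_spec("jersey")
#' still <- list(angle = 0, rate = 0, vel = c(0, 0), acc = c(0, 0))
#' chain_rhs(fb, still, rep(0, 12)) # chain hanging at rest: all zero
#' @export
chain_rhs <- function(fabric, base, state, gravity = 9.81) {
  K <- fabric$segment_count
  if (K < 1) stop("fabric chain needs at least one segment", call. = FALSE)
  if (!all(is.finite(state)) || length(state) != 2 * K) {
    stop("state must be 2K finite values (angles then rates)", call. = FALSE)
  }
  phi <- state[seq_len(K)]
  rate <- state[K + seq_len(K)]
  seg_len <- fabric$taut_length / K
  seg_mass <- fabric$linear_density * seg_len
  inertia <- seg_mass * seg_len^2 / 3
  d_com <- seg_len / 2
  kappa <- fabric$bending_stiffness
  c_j <- fabric$joint_damping
  c_d <- fabric$drag_coefficient

  prev_ang <- c(base$angle, phi)
  prev_rate <- c(base$rate, rate)
  acc_out <- numeric(K)
  a_joint <- base$acc
  v_joint <- base$vel
  for (i in seq_len(K)) {
    tv <- .t_vec(phi[i])
    uv <- .u_vec(phi[i])
    tau <- -kappa * (phi[i] - prev_ang[i]) - c_j * (rate[i] - prev_rate[i])
    if (i < K) {
      tau <- tau + kappa * (phi[i + 1] - phi[i]) + c_j * (rate[i + 1] - rate[i])
    }
    # gravity + pseudo-force from joint acceleration, acting at the com
    tau <- tau - seg_mass * d_com *
      (gravity * sin(phi[i]) + sum(a_joint * tv))
    # translational drag at the com
    tau <- tau - c_d * d_com * (sum(v_joint * tv) + d_com * rate[i])
    acc_out[i] <- if (inertia > 0) tau / inertia else 0
    a_joint <- a_joint + seg_len * (acc_out[i] * tv - rate[i]^2 * uv)
    v_joint <- v_joint + seg_len * rate[i] * tv
  }
  acc_out
}

#' Static equilibrium shape of the fabric chain
#'
#' Solves the torque balance of the hanging-at-rest chain for a stationary
#' base held at `base_angle`: spring torques towards the neighbours against
#' segment gravity. Newton iteration on the tridiagonal system; converges in
#' a handful of steps from either the hanging or the aligned shape.
#'
#' @param fabric A [fabric_spec()].
#' @param base_angle Pendulum angle the chain hangs from, radians.
#' @param gravity m/s^2.
#' @return Numeric vector of K equilibrium segment angles.
#' @export
chain_equilibrium <- function(fabric, base_angle, gravity = 9.81) {
  K <- fabric$segment_count
  seg_len <- fabric$taut_length / K
  mgd <- fabric$linear_density * seg_len * gravity * seg_len / 2
  kappa <- fabric$bending_stiffness
  if (!is.finite(kappa)) return(rep(base_angle, K))
  if (kappa == 0) return(rep(0, K))
  resid <- function(phi) {
    prev <- c(base_angle, phi[-K])
    nxt_term <- c(kappa * diff(phi), 0)
    -kappa * (phi - prev) + nxt_term - mgd * sin(phi)
  }
  # start from whichever regime dominates
  phi <- if (kappa > mgd) rep(base_angle, K) else rep(0, K)
  for (it in 1:50) {
    r <- resid(phi)
    if (max(abs(r)) < 1e-12 * max(kappa, mgd)) break
    d_main <- -kappa - c(rep(kappa, K - 1), 0) - mgd * cos(phi)
    J <- diag(d_main, K)
    if (K > 1) {
      J[cbind(1:(K - 1), 2:K)] <- kappa
      J[cbind(2:K, 1:(K - 1))] <- kappa
    }
    phi <- phi - solve(J, r)
  }
  phi
}

# Combined ODE right-hand side for deSolve: state y = (theta, thetadot,
# phi_1..K, phidot_1..K); the chain block is absent for rigid material.
.rig_rhs <- function(t, y, parms) {
  pend <- parms$pendulum
  theta <- y[1]
  thetadot <- y[2]
  thetaacc <- rigid_pendulum_rhs(pend, c(theta, thetadot))
  if (parms$has_chain) {
    K <- parms$fabric$segment_count
    L <- pend$length
    tv <- .t_vec(theta)
    uv <- .u_vec(theta)
    base <- list(angle = theta, rate = thetadot,
                 vel = L * thetadot * tv,
                 acc = L * (thetaacc * tv - thetadot^2 * uv))
    ch <- chain_rhs(parms$fabric, base, y[-(1:2)], gravity = pend$gravity)
    list(c(thetadot, thetaacc, y[2 + K + seq_len(K)], ch))
  } else {
    list(c(thetadot, thetaacc))
  }
}

#' Integrate the rig dynamics and return sampled states
#'
#' Integrates the pendulum (and fabric chain unless the material is rigid)
#' with an adaptive-step stiffness-switching integrator ([deSolve::lsoda()]),
#' sampling the state at the configured rate. Initial condition: pendulum at
#' `release_angle` (plus any supplied jitter) with zero rate, fabric hanging
#' vertically at rest.
#'
#' @param config An [apparatus_config()].
#' @param release_angle Release angle actually used (defaults to the spec
#'   value; trial simulation passes the jittered value).
#' @param rtol,atol Integrator tolerances.
#' @param chain_init `"hanging"` (fabric drapes vertically at release, the
#'   rest shape of a gravity-dominated strip), `"aligned"` (chain along the
#'   pendulum axis), or `"equilibrium"` (exact static balance of springs
#'   and gravity via [chain_equilibrium()], used by the stiff-limit checks
#'   where the springs dominate and the rest shape is near-aligned).
#' @return List with `time` (length N), `theta`, `thetadot`, `thetaacc`
#'   (pendulum state and acceleration at the samples) and, when a chain is
#'   present, matrices `phi`, `phidot`, `phiacc` of dimension N x K.
#' @keywords internal
integrate_rig <- function(config, release_angle = NULL,
                          rtol = 1e-8, atol = 1e-8,
                          chain_init = c("hanging", "aligned", "equilibrium")) {
  pend <- config$pendulum
  chain_init <- match.arg(chain_init)
  if (is.null(release_angle)) release_angle <- pend$release_angle
  has_chain <- config$fabric$material != "rigid" &&
    is.finite(config$fabric$bending_stiffness)
  K <- config$fabric$segment_count
  n <- round(config$sample_rate * config$duration)
  times <- (seq_len(n) - 1) / config$sample_rate
  y0 <- c(release_angle, 0)
  if (has_chain) {
    phi0 <- switch(chain_init,
                   hanging = rep(0, K),
                   aligned = rep(release_angle, K),
                   equilibrium = chain_equilibrium(config$fabric, release_angle,
                                                   pend$gravity))
    y0 <- c(y0, phi0, rep(0, K))
  }
  parms <- list(pendulum = pend, fabric = config$fabric, has_chain = has_chain)
  # A very stiff chain rings at sqrt(kappa/I) rad/s; when that sits far above
  # the sampling rate the micro-oscillation is unobservable and lsoda would
  # spend its whole step budget resolving it. BDF damps those modes and
  # recovers the rigid-following envelope, which is the observable motion.
  method <- "lsoda"
  if (has_chain) {
    seg_len <- config$fabric$taut_length / K
    seg_inertia <- config$fabric$linear_density * seg_len^3 / 3
    if (seg_inertia > 0 &&
        sqrt(config$fabric$bending_stiffness / seg_inertia) / (2 * pi) >
          config$sample_rate) {
      method <- "bdf"
      # spring torques amplify state error by kappa/I when accelerations are
      # reconstructed, so the near-rigid regime needs a much tighter state
      # tolerance to keep reconstructed readings clean
      atol <- min(atol, 1e-12)
      rtol <- min(rtol, 1e-10)
    }
  }
  sol <- deSolve::ode(y = y0, times = times, func = .rig_rhs, parms = parms,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 500000)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < n) {
    stop("rig integration failed (material=", config$fabric$material,
         ", tip_load=", pend$tip_load, ", kappa=",
         config$fabric$bending_stiffness, ")", call. = FALSE)
  }
  theta <- sol[, 2]
  thetadot <- sol[, 3]
  pin <- pendulum_inertia(pend)
  thetaacc <- -(pin$mass_moment * pend$gravity * sin(theta) +
                  pend$pivot_damping * thetadot) / pin$inertia
  out <- list(time = times, theta = theta, thetadot = thetadot,
              thetaacc = thetaacc, has_chain = has_chain)
  if (has_chain) {
    phi <- sol[, 3 + seq_len(K), drop = FALSE]
    phidot <- sol[, 3 + K + seq_len(K), drop = FALSE]
    phiacc <- matrix(0, n, K)
    L <- pend$length
    for (r in seq_len(n)) {
      tv <- .t_vec(theta[r]); uv <- .u_vec(theta[r])
      base <- list(angle = theta[r], rate = thetadot[r],
                   vel = L * thetadot[r] * tv,
                   acc = L * (thetaacc[r] * tv - thetadot[r]^2 * uv))
      phiacc[r, ] <- chain_rhs(config$fabric, base,
                               c(phi[r, ], phidot[r, ]),
                               gravity = pend$gravity)
    }
    out$phi <- phi; out$phidot <- phidot; out$phiacc <- phiacc
  }
  out
}
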