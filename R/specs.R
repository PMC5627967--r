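#' @title Apparatus specification constructors
#' @name specs
#' @description Constructors and validators for the physical specification of
#'   the simulated test rig: a compound pendulum swinging in a vertical plane,
#'   an optional fabric appendage modelled as a serial chain of hinged
#'   segments, and single-axis virtual accelerometers placed along the arc.
NULL

#' Pendulum specification
#'
#' Describes the rigid compound pendulum: a uniform rod with a fixed tip
#' weight (the bob) and an optional additional tip load that defines the
#' motion class. The tip load is given in newtons, as weights are usually
#' labelled, and converted internally to mass via `gravity`.
#'
#' The bob mass matters: the rig is a *weighted* pendulum, so adding a few
#' newtons at the tip shifts the period and tangential amplitude modestly
#' rather than reshaping the motion wholesale. A rod-only pendulum would make
#' the added load dominate the inertia; a point-mass-only pendulum would read
#' identically zero on a tip-mounted tangential accelerometer (gravity and
#' inertial terms cancel exactly) and its period would not depend on the load
#' at all, leaving nothing to classify.
#'
#' @param length Rod length in metres (pivot to tip).
#' @param rod_mass Mass of the uniform rod, kg.
#' @param bob_mass Fixed tip weight, kg (part of the apparatus, not the class
#'   label).
#' @param tip_load Additional tip load in newtons; `0` for the unloaded class.
#' @param pivot_damping Viscous damping at the pivot, N m s/rad.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param release_angle Release angle in radians from the hanging vertical;
#'   `pi/2` is horizontal.
#' @param release_jitter_sd Standard deviation of per-trial release-angle
#'   jitter, radians.
#' @return An object of class `pendulum_spec`.
#' @examples
#' pendulum_spec(tip_load = 3)
#' @export
pendulum_spec <- function(length = 0.57, rod_mass = 0.2, bob_mass = 0.8,
                          tip_load = 0, pivot_damping = 0.02,
                          gravity = 9.81, release_angle = pi / 2,
                          release_jitter_sd = 0.5 * pi / 180) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(rod_mass), rod_mass > 0,
            is.numeric(bob_mass), bob_mass >= 0,
            is.numeric(tip_load), tip_load >= 0,
            is.numeric(pivot_damping), pivot_damping >= 0,
            is.numeric(gravity), gravity >= 0,
            is.numeric(release_jitter_sd), release_jitter_sd >= 0)
  if (!(release_angle > 0 && release_angle <= pi)) {
    stop("release_angle must lie in (0, pi]", call. = FALSE)
  }
  structure(list(length = length, rod_mass = rod_mass, bob_mass = bob_mass,
                 tip_load = tip_load, pivot_damping = pivot_damping,
                 gravity = gravity, release_angle = release_angle,
                 release_jitter_sd = release_jitter_sd),
            class = "pendulum_spec")
}

#' Moment of inertia and first mass moment of the pendulum
#'
#' The tip load (newtons) is converted to mass via the spec's gravity; when
#' gravity is zero the load contributes no mass (a weight labelled in newtons
#' is massless in a zero-g thought experiment, which keeps the zero-gravity
#' degenerate case well defined).
#'
#' @param spec A [pendulum_spec()].
#' @return List with `inertia` (kg m^2), `mass_moment` (kg m, i.e. total mass
#'   times centre-of-mass distance) and `equivalent_length` (m).
#' @export
pendulum_inertia <- function(spec) {
  L <- spec$length
  m_tip <- spec$bob_mass + if (spec$gravity > 0) spec$tip_load / spec$gravity else 0
  inertia <- spec$rod_mass * L^2 / 3 + m_tip * L^2
  mass_moment <- spec$rod_mass * L / 2 + m_tip * L
  list(inertia = inertia, mass_moment = mass_moment,
       equivalent_length = inertia / mass_moment)
}

# Material presets for the fabric chain. Drape constants of specific bolts of
# cloth are not tabulated anywhere, so these are surrogate values chosen once so that denim
# is the stiffest, heaviest, most damped of the three and roma the floppiest
# and lightest. Overridable field by field via fabric_spec().
.fabric_presets <- list(
  jersey = list(bending_stiffness = 2.8e-3, linear_density = 0.06,
                drag_coefficient = 3e-3, joint_damping = 2e-5),
  denim  = list(bending_stiffness = 8e-3, linear_density = 0.10,
                drag_coefficient = 5e-3, joint_damping = 8e-5),
  roma   = list(bending_stiffness = 5e-4, linear_density = 0.04,
                drag_coefficient = 1.5e-3, joint_damping = 8e-6),
  rigid  = list(bending_stiffness = Inf, linear_density = 0,
                drag_coefficient = 0, joint_damping = 0)
)

#' Fabric specification
#'
#' Describes the fabric strip hanging from the pendulum tip as a serial chain
#' of `segment_count` uniform rigid segments joined by torsional springs
#' (bending stiffness `kappa`, N m/rad) and dampers, with per-segment
#' translational drag standing in for air resistance. `material = "rigid"`
#' replaces the fabric by a rigid extension of the pendulum (the control
#' condition). Presets exist for `jersey`, `denim` and `roma`, ordered
#' denim > jersey > roma in stiffness; `custom` requires all constants.
#'
#' @param material One of `"jersey"`, `"denim"`, `"roma"`, `"rigid"`,
#'   `"custom"`.
#' @param taut_length Strip length when taut, metres.
#' @param segment_count Number of chain segments K (>= 1).
#' @param bending_stiffness,joint_damping,linear_density,drag_coefficient
#'   Physical constants; `NULL` takes the material preset.
#' @return An object of class `fabric_spec`.
#' @examples
#' fabric_spec("denim")
#' fabric_spec("jersey", bending_stiffness = 1e-3)
#' @export
fabric_spec <- function(material = c("jersey", "denim", "roma", "rigid", "custom"),
                        taut_length = 0.18, segment_count = 6,
                        bending_stiffness = NULL, joint_damping = NULL,
                        linear_density = NULL, drag_coefficient = NULL) {
  material <- match.arg(material)
  stopifnot(taut_length > 0)
  if (!(is.numeric(segment_count) && segment_count >= 1 &&
        segment_count == round(segment_count))) {
    stop("segment_count must be an integer >= 1", call. = FALSE)
  }
  preset <- if (material == "custom") list() else .fabric_presets[[material]]
  pick <- function(given, name) {
    val <- if (is.null(given)) preset[[name]] else given
    if (is.null(val)) stop("custom material requires ", name, call. = FALSE)
    stopifnot(val >= 0)
    val
  }
  structure(list(material = material, taut_length = taut_length,
                 segment_count = as.integer(segment_count),
                 bending_stiffness = pick(bending_stiffness, "bending_stiffness"),
                 joint_damping = pick(joint_damping, "joint_damping"),
                 linear_density = pick(linear_density, "linear_density"),
                 drag_coefficient = pick(drag_coefficient, "drag_coefficient")),
            class = "fabric_spec")
}

#' Sensor specification
#'
#' A single-axis virtual accelerometer at a given arc distance from the pivot,
#' measured along pendulum-plus-appendage. The sensed axis is the tangential
#' axis of the carrying segment (horizontal when the rig hangs at rest);
#' readings are in units of standard gravity, quantized to `adc_bits` over
#' `±full_scale` and clipped.
#'
#' @param id Sensor label, e.g. `"R1"`, `"F2"`, `"F3"`.
#' @param arc_position Metres from the pivot along the arc.
#' @param noise_sd Additive Gaussian noise standard deviation, standard
#'   gravities.
#' @param full_scale Measurement range, ± standard gravities.
#' @param adc_bits ADC resolution, bits.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(id, arc_position, noise_sd = 0.01,
                        full_scale = 3, adc_bits = 16) {
  stopifnot(is.character(id), length(id) == 1,
            is.numeric(arc_position), arc_position > 0,
            noise_sd >= 0, full_scale > 0,
            adc_bits == round(adc_bits), adc_bits >= 2)
  structure(list(id = id, arc_position = arc_position, noise_sd = noise_sd,
                 full_scale = full_scale, adc_bits = as.integer(adc_bits)),
            class = "sensor_spec")
}

#' Default sensor layout
#'
#' R1 at the pendulum tip; F2/F3 (or R2/R3 for the rigid control) at the
#' middle and tip of the appendage.
#'
#' @param pendulum A [pendulum_spec()].
#' @param fabric A [fabric_spec()].
#' @param noise_sd Noise level passed to every [sensor_spec()].
#' @return List of three `sensor_spec`s.
#' @export
default_sensors <- function(pendulum, fabric, noise_sd = 0.01) {
  L <- pendulum$length
  mid <- L + fabric$taut_length / 2
  tip <- L + fabric$taut_length
  ids <- if (fabric$material == "rigid") c("R1", "R2", "R3") else c("R1", "F2", "F3")
  list(sensor_spec(ids[1], L, noise_sd = noise_sd),
       sensor_spec(ids[2], mid, noise_sd = noise_sd),
       sensor_spec(ids[3], tip, noise_sd = noise_sd))
}

#' Full apparatus configuration for one condition
#'
#' @param pendulum A [pendulum_spec()].
#' @param fabric A [fabric_spec()].
#' @param sensors List of [sensor_spec()]s; default layout if `NULL`.
#' @param sample_rate Samples per second.
#' @param duration Record length, seconds.
#' @return An object of class `apparatus_config`.
#' @examples
#' cfg <- apparatus_config(pendulum_spec(tip_load = 3), fabric_spec("jersey"))
#' @export
apparatus_config <- function(pendulum = pendulum_spec(),
                             fabric = fabric_spec(),
                             sensors = NULL,
                             sample_rate = 600, duration = 10) {
  stopifnot(inherits(pendulum, "pendulum_spec"), inherits(fabric, "fabric_spec"),
            sample_rate > 0, duration > 0)
  if (is.null(sensors)) sensors <- default_sensors(pendulum, fabric)
  reach <- pendulum$length + fabric$taut_length
  for (s in sensors) {
    stopifnot(inherits(s, "sensor_spec"))
    if (s$arc_position > reach + 1e-9) {
      stop("sensor ", s$id, " lies beyond the pendulum-plus-appendage arc",
           call. = FALSE)
    }
  }
  structure(list(pendulum = pendulum, fabric = fabric, sensors = sensors,
                 sample_rate = sample_rate, duration = duration),
            class = "apparatus_config")
}
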