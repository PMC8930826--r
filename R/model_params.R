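#' Model parameters of the user-wheelchair system
#'
#' Constructs the full parameter set of the planar user-wheelchair model:
#' a four-bar mechanism formed by the upper arms, the forearms (including
#' hands), the rear wheels, and a fourth body lumping the remaining user
#' and wheelchair segments. Bilateral symmetry is assumed, so arm segment
#' masses and inertias are bilateral totals and the wheel inertia is the
#' two-wheel total.
#'
#' Defaults describe an average adult male (1.70 m, 70 kg) in a manual
#' wheelchair with 0.2988 m rear wheels and 0.2570 m pushrims, rolling
#' resistance of 20 N (vinyl-like pavement), level ground.
#'
#' @param upper_arm_length Upper arm length A (m).
#' @param forearm_length Forearm length B, elbow to pushrim grip, hand
#'   included in the segment (m).
#' @param pushrim_radius Pushrim radius Rp (m).
#' @param wheel_radius Rear wheel radius Rw (m).
#' @param shoulder_offset_h Horizontal shoulder-to-axle distance H (m),
#'   axle forward of the shoulder positive.
#' @param shoulder_offset_v Vertical shoulder-to-axle distance Y (m),
#'   shoulder above the axle.
#' @param upper_arm_mass,forearm_mass Bilateral segment masses (kg).
#' @param upper_arm_com,forearm_com Centre-of-mass distances from the
#'   proximal joint (m).
#' @param upper_arm_inertia,forearm_inertia Bilateral segment moments of
#'   inertia about the segment centre of mass (kg m^2).
#' @param wheel_inertia Bilateral (two-wheel) spin moment of inertia
#'   (kg m^2).
#' @param combined_mass Total translating mass, wheelchair plus user (kg).
#' @param rolling_resistance Rolling resistance force Fr (N), constant
#'   magnitude opposing motion.
#' @param gravity Gravitational acceleration (m/s^2).
#' @param ramp_angle Ramp inclination (rad), positive uphill.
#' @return An object of class `paw_params` (a named list).
#' @seealso [default_parameters()], [anthropometry()]
#' @export
paw_params <- function(upper_arm_length = 0.3162,
                       forearm_length = 0.3400,
                       pushrim_radius = 0.2570,
                       wheel_radius = 0.2988,
                       shoulder_offset_h = 0.05,
                       shoulder_offset_v = 0.75,
                       upper_arm_mass = 3.9200,
                       forearm_mass = 3.0800,
                       upper_arm_com = 0.1379,
                       forearm_com = 0.1693,
                       upper_arm_inertia = 0.0406,
                       forearm_inertia = 0.0416,
                       wheel_inertia = 2 * 0.1274,
                       combined_mass = 72.5200,
                       rolling_resistance = 20,
                       gravity = 9.81,
                       ramp_angle = 0) {
  p <- list(
    upper_arm_length = upper_arm_length,
    forearm_length = forearm_length,
    pushrim_radius = pushrim_radius,
    wheel_radius = wheel_radius,
    shoulder_offset_h = shoulder_offset_h,
    shoulder_offset_v = shoulder_offset_v,
    upper_arm_mass = upper_arm_mass,
    forearm_mass = forearm_mass,
    upper_arm_com = upper_arm_com,
    forearm_com = forearm_com,
    upper_arm_inertia = upper_arm_inertia,
    forearm_inertia = forearm_inertia,
    wheel_inertia = wheel_inertia,
    combined_mass = combined_mass,
    rolling_resistance = rolling_resistance,
    gravity = gravity,
    ramp_angle = ramp_angle
  )
  validate_paw_params(p)
  class(p) <- "paw_params"
  p
}

validate_paw_params <- function(p) {
  pos <- c("upper_arm_length", "forearm_length", "pushrim_radius",
           "wheel_radius", "upper_arm_mass", "forearm_mass",
           "upper_arm_com", "forearm_com", "upper_arm_inertia",
           "forearm_inertia", "wheel_inertia", "combined_mass", "gravity")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      stop("parameter '", f, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (p$rolling_resistance < 0) stop("rolling_resistance must be >= 0", call. = FALSE)
  if (p$combined_mass < p$upper_arm_mass + p$forearm_mass) {
    stop("combined_mass must be at least the sum of the arm segment masses",
         call. = FALSE)
  }
  if (p$upper_arm_com > p$upper_arm_length || p$forearm_com > p$forearm_length) {
    stop("segment centre of mass beyond segment length", call. = FALSE)
  }
  invisible(p)
}

#' Default adopted model parameters
#'
#' The parameter set used throughout the reference simulations: a 1.70 m,
#' 70 kg user, 72.52 kg combined mass, 20 N rolling resistance, level
#' ground. Wheel inertia is the per-wheel value (0.1274 kg m^2) doubled,
#' consistent with the bilateral lumping of the planar mechanism.
#'
#' @return A `paw_params` object.
#' @export
default_parameters <- function() paw_params()

#' @export
print.paw_params <- function(x, ...) {
  cat("User-wheelchair model parameters\n")
  cat(sprintf("  upper arm  A = %.4f m, m = %.4f kg (bilateral)\n",
              x$upper_arm_length, x$upper_arm_mass))
  cat(sprintf("  forearm    B = %.4f m, m = %.4f kg (bilateral)\n",
              x$forearm_length, x$forearm_mass))
  cat(sprintf("  pushrim Rp = %.4f m, wheel Rw = %.4f m\n",
              x$pushrim_radius, x$wheel_radius))
  cat(sprintf("  shoulder offset (H, Y) = (%.3f, %.3f) m\n",
              x$shoulder_offset_h, x$shoulder_offset_v))
  cat(sprintf("  combined mass %.4f kg, Fr = %.1f N, ramp = %.2f deg\n",
              x$combined_mass, x$rolling_resistance,
              x$ramp_angle * 180 / pi))
  invisible(x)
}

# mass of the lumped chassis body (everything translating that is not an
# arm segment; wheels' mass translates with the chassis)
chassis_mass <- function(p) p$combined_mass - p$upper_arm_mass - p$forearm_mass

#' Serialize / restore model parameters
#'
#' Flat mapping with SI units; the round trip is lossless.
#'
#' @param p A `paw_params` object.
#' @param path File path; extension `.yaml`/`.yml` or `.json`.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   a `paw_params` object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "paw_params"))
  vals <- unclass(p)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported extension for parameter file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported extension for parameter file: ", path, call. = FALSE)
  }
  do.call(paw_params, vals)
}

# Standard anthropometric fraction table used by anthropometry().
# Lengths scale with body height, masses with body mass; moments of
# inertia from radius-of-gyration fractions about the segment COM. The
# forearm segment includes the hand; its grip length (elbow to pushrim
# grip) is 0.200 H while COM and gyration fractions refer to the
# elbow-wrist length 0.146 H.
anthropometry_fractions <- function() {
  list(
    upper_arm_length = 0.186,      # of height
    upper_arm_mass = 0.028,        # of body mass, per side
    upper_arm_com = 0.436,         # of upper arm length, from shoulder
    upper_arm_rog = 0.322,         # of upper arm length, about COM
    forearm_grip_length = 0.200,   # of height (elbow to grip, incl. hand)
    forearm_wrist_length = 0.146,  # of height (elbow to wrist)
    forearm_hand_mass = 0.022,     # of body mass, per side
    forearm_hand_com = 0.682,      # of elbow-wrist length, from elbow
    forearm_hand_rog = 0.468       # of elbow-wrist length, about COM
  )
}

#' Anthropometric scaling of the arm segment parameters
#'
#' Generates the arm segment subset of the model parameters for a user of
#' given height and mass from standard anthropometric fractions (segment
#' lengths proportional to height, masses to body mass, inertias from
#' radius-of-gyration fractions). At (1.70 m, 70 kg) this reproduces the
#' adopted default segment values to four decimals.
#'
#' @param height Body height (m).
#' @param mass Total body mass (kg).
#' @return Named list with `upper_arm_length`, `upper_arm_mass`,
#'   `upper_arm_com`, `upper_arm_inertia`, `forearm_length`,
#'   `forearm_mass`, `forearm_com`, `forearm_inertia` (masses and
#'   inertias bilateral).
#' @export
anthropometry <- function(height, mass) {
  if (!is.numeric(height) || height <= 0 || !is.numeric(mass) || mass <= 0) {
    stop("height and mass must be positive", call. = FALSE)
  }
  fr <- anthropometry_fractions()
  la <- fr$upper_arm_length * height
  lw <- fr$forearm_wrist_length * height
  ma <- fr$upper_arm_mass * mass          # per side
  mf <- fr$forearm_hand_mass * mass
  list(
    upper_arm_length = la,
    upper_arm_mass = 2 * ma,
    upper_arm_com = fr$upper_arm_com * la,
    upper_arm_inertia = 2 * ma * (fr$upper_arm_rog * la)^2,
    forearm_length = fr$forearm_grip_length * height,
    forearm_mass = 2 * mf,
    forearm_com = fr$forearm_hand_com * lw,
    forearm_inertia = 2 * mf * (fr$forearm_hand_rog * lw)^2
  )
}
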