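#' Quantification configuration
#'
#' Fluid and operator constants used when converting site measurements to
#' volumetric flows. None of these is hard-coded downstream; every value
#' can be overridden per call.
#'
#' @param epsilon_degrees Operator uncertainty on the insonation angle,
#'   degrees (default 5, the repeat-placement standard deviation typical
#'   of jugular insonation).
#' @param viscosity Kinematic viscosity of blood, cm2/s (default 0.035).
#' @param heart_rate Beats per minute; sets the pulsation frequency for
#'   the arterial Womersley number (default 70).
#' @param respiratory_rate Breaths per minute; sets the modulation
#'   frequency for the venous Womersley number (default 15).
#' @param eta_override Optional named list mapping a vessel class
#'   (`"artery"`/`"vein"`) or a vessel name to a fixed velocity factor,
#'   bypassing the Womersley-derived value (for users with their own
#'   calibration curve).
#' @return A list of class `cvo_config`.
#' @export
flow_config <- function(epsilon_degrees = 5, viscosity = 0.035,
                        heart_rate = 70, respiratory_rate = 15,
                        eta_override = NULL) {
  stopifnot(epsilon_degrees >= 0, viscosity > 0, heart_rate > 0,
            respiratory_rate > 0)
  structure(list(epsilon_degrees = epsilon_degrees, viscosity = viscosity,
                 heart_rate = heart_rate, respiratory_rate = respiratory_rate,
                 eta_override = eta_override),
            class = "cvo_config")
}

#' Cross-sectional area of a circular artery from its diameter
#'
#' @param diameter Lumen diameter, cm.
#' @return Area pi (d/2)^2, cm2.
#' @export
arterial_csa <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("diameter must be > 0", call. = FALSE)
  pi * (diameter / 2)^2
}

#' Mean venous lumen area over one respiratory cycle
#'
#' Veins collapse and distend with respiration; the effective area is the
#' mean of the minimum and maximum traced areas.
#'
#' @param csa_min,csa_max Traced areas, cm2, with
#'   `0 <= csa_min <= csa_max`.
#' @return `(csa_min + csa_max)/2`, cm2.
#' @export
venous_csa <- function(csa_min, csa_max) {
  if (any(csa_min < 0) || any(csa_min > csa_max))
    stop("require 0 <= csa_min <= csa_max", call. = FALSE)
  (csa_min + csa_max) / 2
}

#' Womersley number
#'
#' alpha = r sqrt(omega / nu): the ratio of unsteady inertial to viscous
#' forces that governs how blunt the oscillatory velocity profile is.
#'
#' @param radius Vessel radius, cm.
#' @param angular_frequency Pulsation angular frequency, rad/s.
#' @param kinematic_viscosity cm2/s.
#' @return Dimensionless alpha.
#' @export
womersley_number <- function(radius, angular_frequency, kinematic_viscosity) {
  if (any(radius <= 0) || any(angular_frequency < 0) ||
      any(kinematic_viscosity <= 0))
    stop("radius and viscosity must be > 0, frequency >= 0", call. = FALSE)
  radius * sqrt(angular_frequency / kinematic_viscosity)
}

# J0 and J1 for complex argument via their integral representations,
# evaluated by Gauss-Legendre quadrature on [0, pi]. Accurate to ~1e-12
# (relative) for |z| up to a few hundred; the velocity factor only ever
# consumes ratios, so the e^{|Im z|} growth cancels.
gl_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(400, 0, pi)
    cache
  }
})

besselJ0_complex <- function(z) {
  gl <- gl_nodes()
  vapply(z, function(zz) sum(gl$w * cos(zz * sin(gl$x))) / pi,
         complex(1))
}

besselJ1_complex <- function(z) {
  gl <- gl_nodes()
  vapply(z, function(zz) sum(gl$w * cos(gl$x - zz * sin(gl$x))) / pi,
         complex(1))
}

#' Velocity factor bridging peak-envelope and spatial-mean velocity
#'
#' For the fundamental harmonic of oscillatory pipe flow the axial
#' velocity is u(y) = 1 - J0(Lambda y)/J0(Lambda) with
#' Lambda = i^(3/2) alpha. The velocity factor is the modulus ratio
#' between the sampling point of the peak envelope (the vessel axis,
#' where the Doppler sample volume is placed) and the cross-sectional
#' mean, eta = |u(0)| / |2/Lambda^2 integral|. It is 2 in the Poiseuille
#' limit (alpha -> 0), decays monotonically, and tends to 1 in the
#' plug-flow limit. The measured peak velocity divided by eta gives the
#' spatial mean that multiplies the lumen area.
#'
#' @param alpha Womersley number(s), >= 0.
#' @return eta in (1, 2], same length as `alpha`.
#' @export
velocity_factor <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be >= 0", call. = FALSE)
  out <- numeric(length(alpha))
  small <- alpha < 1e-3
  out[small] <- 2
  if (any(!small)) {
    a <- alpha[!small]
    lam <- complex(modulus = a, argument = 3 * pi / 4)  # i^(3/2) alpha
    j0 <- besselJ0_complex(lam)
    j1 <- besselJ1_complex(lam)
    centre <- 1 - 1 / j0
    spatial_mean <- 1 - 2 * j1 / (lam * j0)
    out[!small] <- Mod(centre) / Mod(spatial_mean)
  }
  out
}

#' Spatial-mean velocity from the peak-envelope velocity
#'
#' @param tavp Peak-envelope time-averaged velocity, cm/s (>= 0).
#' @param eta Velocity factor, >= 1.
#' @return `tavp / eta`, cm/s.
#' @export
tav_from_peak <- function(tavp, eta) {
  if (any(eta < 1)) stop("eta must be >= 1", call. = FALSE)
  if (any(tavp < 0)) stop("tavp must be >= 0", call. = FALSE)
  tavp / eta
}

#' Spatial-mean velocity from a five-point wall-to-wall profile
#'
#' Used at J1 when the flow is turbulent or nearly absent and a single
#' peak sample is unreliable. The five chord samples are completed with
#' zero-velocity no-slip nodes at both walls (7 equally spaced nodes) and
#' averaged by the composite trapezoid rule over the chord. Negative
#' samples are kept signed (reversed flow).
#'
#' @param velocities Exactly five finite velocities, cm/s, wall to wall.
#' @return Spatial mean velocity, cm/s. A constant profile v yields 5v/6.
#' @export
tav_from_profile <- function(velocities) {
  if (length(velocities) != 5L || any(!is.finite(velocities)))
    stop("exactly 5 finite velocities required", call. = FALSE)
  nodes <- c(0, velocities, 0)
  h <- 1 / 6
  sum((nodes[-7] + nodes[-1]) / 2 * h)
}

#' Velocity uncertainty from insonation-angle placement error
#'
#' The Doppler estimate scales with 1/cos(theta); an operator error
#' epsilon on the angle therefore inflates the velocity by
#' cos(theta)/cos(theta + epsilon). The uncertainty is
#' dTAV = TAV (cos(theta)/cos(theta + epsilon) - 1): zero iff
#' epsilon = 0, and strictly increasing in both angle and error on the
#' valid domain theta + epsilon < 90.
#'
#' @param tav Velocity, cm/s.
#' @param theta Insonation angle, degrees, in (0, 90).
#' @param epsilon Operator angle uncertainty, degrees, >= 0.
#' @return dTAV, cm/s (non-negative for tav >= 0).
#' @export
tav_uncertainty <- function(tav, theta, epsilon) {
  if (any(theta <= 0) || any(epsilon < 0) || any(theta + epsilon >= 90))
    stop("require 0 < theta, epsilon >= 0, theta + epsilon < 90",
         call. = FALSE)
  tav * (cos(theta * pi / 180) / cos((theta + epsilon) * pi / 180) - 1)
}

#' Flow uncertainty from velocity uncertainty
#'
#' @param dtav Velocity uncertainty, cm/s, >= 0.
#' @param csa Lumen area, cm2, >= 0.
#' @return dQ = dTAV x CSA, converted to ml/min.
#' @export
flow_uncertainty <- function(dtav, csa) {
  if (any(dtav < 0) || any(csa < 0)) stop("inputs must be >= 0", call. = FALSE)
  dtav * csa * 60
}

vessel_radius <- function(vessel, diameter, csa) {
  # arteries: from the measured diameter; veins: equivalent circular
  # radius of the mean lumen area
  ifelse(vessel %in% cvo_arteries, diameter / 2, sqrt(csa / pi))
}

site_eta <- function(vessel, alpha, config) {
  ov <- config$eta_override
  cls <- ifelse(vessel %in% cvo_arteries, "artery", "vein")
  eta <- velocity_factor(alpha)
  if (!is.null(ov)) {
    for (i in seq_along(vessel)) {
      hit <- ov[[vessel[i]]] %||% ov[[cls[i]]]
      if (!is.null(hit)) eta[i] <- hit
    }
  }
  eta
}

#' Quantify volumetric flow at one or more measured sites
#'
#' The core conversion Q = TAV x CSA: the lumen area is dispatched by
#' vessel class (circular from diameter for arteries, respiratory-mean
#' traced area for veins), the spatial-mean velocity comes from the
#' peak envelope corrected by the Womersley velocity factor (or from the
#' five-point profile when one was recorded), and the single cm3/s to
#' ml/min conversion (x60) is applied here. Sites flagged
#' `flow_state = "absent"` contribute zero flow with zero uncertainty.
#' The angle-placement uncertainty is propagated to `dq`.
#'
#' @param measurements Measurement tibble ([vessel_measurement()] schema).
#' @param config [flow_config()].
#' @return The measurements' subject columns plus site identity, `q`
#'   (ml/min), `dq`, `tav`, `csa`, `eta`, `alpha` and `method`
#'   (`peak_corrected`, `profile5` or `absent`) - a stack of subject flow
#'   sets ready for [cohort_table()].
#' @export
#' @examples
#' m <- vessel_measurement("s1", "HC", "supine", "IJV", "right", "J3",
#'                         tavp = 25, csa_min = 0.2, csa_max = 0.32,
#'                         doppler_angle = 55)
#' compute_flow(m)
compute_flow <- function(measurements, config = flow_config()) {
  diag <- validate_measurements(measurements)
  if (nrow(diag) > 0)
    stop("invalid measurements: ", paste(unique(diag$message), collapse = "; "),
         call. = FALSE)
  m <- measurements
  is_art <- m$vessel %in% cvo_arteries
  dia <- ifelse(is.na(m$diameter), 1, m$diameter)
  csa <- ifelse(is_art, arterial_csa(dia),
                venous_csa(ifelse(is.na(m$csa_min), 0, m$csa_min),
                           ifelse(is.na(m$csa_max), 0, m$csa_max)))
  omega <- ifelse(is_art, 2 * pi * config$heart_rate / 60,
                  2 * pi * config$respiratory_rate / 60)
  radius <- vessel_radius(m$vessel, m$diameter, csa)
  alpha <- ifelse(radius > 0, radius * sqrt(omega / config$viscosity), 0)
  eta <- site_eta(m$vessel, alpha, config)

  tav <- numeric(nrow(m))
  method <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    prof <- parse_profile(m$profile_velocities[i])
    if (m$flow_state[i] == "absent") {
      tav[i] <- 0; method[i] <- "absent"
    } else if (!is.null(prof)) {
      tav[i] <- tav_from_profile(prof); method[i] <- "profile5"
    } else {
      tav[i] <- tav_from_peak(m$tavp[i], eta[i]); method[i] <- "peak_corrected"
    }
  }
  q <- tav * csa * 60
  dtav <- abs(tav_uncertainty(abs(tav), m$doppler_angle,
                              config$epsilon_degrees))
  dq <- flow_uncertainty(dtav, csa)
  dq[method == "absent"] <- 0
  q[method == "absent"] <- 0

  subject_flow_set(
    subject_id = m$subject_id, group = m$group, posture = m$posture,
    vessel = m$vessel, side = m$side, segment = m$segment,
    q = q, dq = dq, tav = tav, csa = csa,
    eta = ifelse(method == "peak_corrected", eta, NA_real_),
    alpha = alpha, method = method)
}
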