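#' Literature reference cohort means
#'
#' Published cohort-level values from the pilot ultrasound study of
#' cervical venous drainage that this model targets: per-vessel arterial
#' mean flows (side-summed, mean and sd across subjects) for healthy
#' controls and CCSVI patients, and the per-site venous descriptives
#' (CSA, major axis, TAV, Q; mean and sd) for both postures. These
#' numbers parameterize the synthetic-cohort generator and are the
#' desk-check inputs for reproducing the published drainage rates.
#'
#' @return List with tibbles `arterial` (group, vessel, q_mean, q_sd in
#'   ml/min) and `venous` (group, posture, segment, side, csa_mean/sd in
#'   cm2, major_mean/sd in cm, tav_mean/sd in cm/s, q_mean/sd in
#'   ml/min).
#' @export
cohort_reference_means <- function() {
  arterial <- tibble::tribble(
    ~group, ~vessel, ~q_mean, ~q_sd,
    "HC",    "CCA", 843, 200,
    "HC",    "ICA", 462,  90,
    "HC",    "ECA", 255,  59,
    "HC",    "VA",  176,  72,
    "CCSVI", "CCA", 758, 138,
    "CCSVI", "ICA", 444, 123,
    "CCSVI", "ECA", 230,  83,
    "CCSVI", "VA",  192,  60)
  venous <- tibble::tribble(
    ~group, ~posture, ~segment, ~side,
    ~csa_mean, ~csa_sd, ~major_mean, ~major_sd,
    ~tav_mean, ~tav_sd, ~q_mean, ~q_sd,
    "HC",    "supine",  "J3",  "right", 0.26, 0.14, 0.79, 0.27, 25.28,  9.16, 190.72, 126.74,
    "HC",    "supine",  "J3",  "left",  0.21, 0.11, 0.74, 0.25, 25.32, 11.80, 167.41,  93.25,
    "CCSVI", "supine",  "J3",  "right", 0.29, 0.19, 0.85, 0.21, 17.33, 10.78, 139.29, 108.64,
    "CCSVI", "supine",  "J3",  "left",  0.18, 0.15, 0.68, 0.28, 18.08, 22.06,  77.73,  80.03,
    "HC",    "upright", "J3",  "right", 0.12, 0.10, 0.57, 0.32, 36.55, 21.10, 153.03,  97.15,
    "HC",    "upright", "J3",  "left",  0.13, 0.11, 0.56, 0.29, 23.75, 16.98,  94.43,  73.91,
    "CCSVI", "upright", "J3",  "right", 0.18, 0.04, 0.73, 0.07, 41.85, 38.82, 201.98, 171.83,
    "CCSVI", "upright", "J3",  "left",  0.12, 0.09, 0.52, 0.22, 23.51, 41.22,  96.09, 141.91,
    "HC",    "supine",  "J2",  "right", 0.37, 0.31, 1.09, 0.30, 27.54, 18.99, 238.94, 148.08,
    "HC",    "supine",  "J2",  "left",  0.28, 0.19, 0.94, 0.22, 47.91, 25.43, 293.36, 140.17,
    "CCSVI", "supine",  "J2",  "right", 0.28, 0.17, 0.96, 0.74, 34.32, 22.61, 273.12, 245.33,
    "CCSVI", "supine",  "J2",  "left",  0.25, 0.13, 0.91, 0.25, 44.07, 33.73, 219.73, 190.40,
    "HC",    "upright", "J2",  "right", 0.11, 0.04, 0.64, 0.30, 43.61, 30.02, 151.04, 119.50,
    "HC",    "upright", "J2",  "left",  0.07, 0.04, 0.56, 0.33, 55.64, 28.36, 162.55, 156.05,
    "CCSVI", "upright", "J2",  "right", 0.12, 0.09, 1.16, 0.52, 40.64, 50.23, 261.10, 247.47,
    "CCSVI", "upright", "J2",  "left",  0.06, 0.04, 0.75, 0.30, 38.91, 52.70, 126.66, 102.74,
    "HC",    "supine",  "J1",  "right", 0.48, 0.30, 1.24, 0.34, 51.69, 33.48, 712.56, 451.21,
    "HC",    "supine",  "J1",  "left",  0.50, 0.14, 1.09, 0.39, 51.20, 45.54, 606.27, 417.79,
    "CCSVI", "supine",  "J1",  "right", 0.45, 0.18, 1.32, 0.33, 15.40, 19.63, 151.61, 238.72,
    "CCSVI", "supine",  "J1",  "left",  0.36, 0.22, 0.63, 0.60, 16.10, 16.94, 117.87, 121.70,
    "HC",    "upright", "J1",  "right", 0.16, 0.16, 0.83, 0.33, 112.12, 47.99, 755.16, 690.26,
    "HC",    "upright", "J1",  "left",  0.17, 0.11, 0.87, 0.36,  86.31, 42.14, 469.62, 287.23,
    "CCSVI", "upright", "J1",  "right", 0.18, 0.10, 0.74, 0.16,  63.30, 61.73, 439.98, 319.58,
    "CCSVI", "upright", "J1",  "left",  0.16, 0.09, 0.73, 0.26,  42.00, 49.20, 334.23, 343.94,
    "HC",    "supine",  "C45", "right", 0.05, 0.03, NA, NA, 30.44, 27.73, 42.16, 40.42,
    "HC",    "supine",  "C45", "left",  0.04, 0.02, NA, NA, 22.33, 14.20, 24.38, 10.66,
    "CCSVI", "supine",  "C45", "right", 0.05, 0.04, NA, NA, 21.56, 21.81, 49.37, 72.27,
    "CCSVI", "supine",  "C45", "left",  0.04, 0.03, NA, NA, 23.15, 25.46, 39.70, 53.63,
    "HC",    "upright", "C45", "right", 0.04, 0.02, NA, NA, 52.72, 28.95, 53.72, 27.18,
    "HC",    "upright", "C45", "left",  0.05, 0.03, NA, NA, 50.69, 26.30, 81.33, 67.13,
    "CCSVI", "upright", "C45", "right", 0.03, 0.04, NA, NA, 22.07, 35.47, 68.58, 108.05,
    "CCSVI", "upright", "C45", "left",  0.03, 0.06, NA, NA, 16.93, 26.57, 58.65,  84.65)
  list(arterial = arterial, venous = venous)
}

#' Build the flow set of a cohort's published mean flows
#'
#' Convenience wrapper turning [cohort_reference_means()] into a
#' single pseudo-subject flow set per posture (arterial sums split
#' evenly across sides; venous per-site means taken verbatim), so the
#' aggregate quantities and indexes can be recomputed directly from the
#' published values.
#'
#' @param group `"HC"` or `"CCSVI"`.
#' @param posture `"supine"` or `"upright"`.
#' @return Subject flow set (subject id `<group>-means`).
#' @export
reference_flow_set <- function(group = c("HC", "CCSVI"),
                               posture = c("supine", "upright")) {
  group <- match.arg(group); posture <- match.arg(posture)
  ref <- cohort_reference_means()
  art <- ref$arterial[ref$arterial$group == group, ]
  ven <- ref$venous[ref$venous$group == group & ref$venous$posture == posture, ]
  ven$vessel <- ifelse(ven$segment == "C45", "VV", "IJV")
  subject_flow_set(
    subject_id = paste0(group, "-means"), group = group, posture = posture,
    vessel = c(rep(art$vessel, each = 2), ven$vessel),
    side = c(rep(cvo_sides, nrow(art)), ven$side),
    segment = c(rep(ifelse(art$vessel == "VA", "V2", "none"), each = 2),
                ven$segment),
    q = c(rep(art$q_mean / 2, each = 2), ven$q_mean))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# lognormal with prescribed arithmetic mean and sd
rlnorm_mm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Synthetic phenotype for one subject group
#'
#' The generative parameters of a simulated cohort. Defaults encode the
#' published study conditions: arterial per-vessel means/sds from
#' [cohort_reference_means()]; a baseline collateral-to-caval fraction
#' of 1 +- 3 % (healthy-control CFI); for CCSVI a J1 obstruction
#' multiplier drawn so the collateral fraction reaches about 61 +- 27 %
#' (the published patient CFI, equivalent to the reported ~70% J1 flow
#' deficit); segmental re-entry fractions reproducing the published
#' drainage rates (controls supine: 37% of inflow at J3, 55% at J2,
#' >90% at J1; patients: 24/54/32%); a vertebral-vein share of the main-
#' route outflow (7-10% supine, 15% upright); a postural shift moving
#' the collateral fraction by the published DCVO (+5 points HC, -42
#' CCSVI when upright); 10% multiplicative lognormal measurement noise
#' per site; and a uniform 45-60 degree insonation angle with a 2.5
#' degree operator placement error (so the 5 degree stated uncertainty
#' is a ~2 sigma bound).
#'
#' @param group `"HC"` or `"CCSVI"`.
#' @param ... Named overrides of any default listed above (see the
#'   returned object for field names).
#' @return List of class `cvo_phenotype`.
#' @export
synthetic_phenotype <- function(group = c("HC", "CCSVI"), ...) {
  group <- match.arg(group)
  ref <- cohort_reference_means()
  hc <- group == "HC"
  ph <- list(
    group = group,
    arterial = ref$arterial[ref$arterial$group == group, ],
    arterial_diameter = c(CCA = 0.60, ICA = 0.45, ECA = 0.35, VA = 0.33),
    venous_geometry = ref$venous[ref$venous$group == group, ],
    baseline_cfi_mean = 0.01, baseline_cfi_sd = 0.03,
    j1_obstruction_mean = if (hc) 0 else 0.652,
    j1_obstruction_sd = if (hc) 0 else 0.293,
    vv_frac = c(supine = if (hc) 0.07 else 0.10, upright = 0.15),
    reentry_f3 = c(supine = if (hc) 0.40 else 0.26,
                   upright = if (hc) 0.28 else 0.35),
    reentry_f2 = c(supine = if (hc) 0.60 else 0.59,
                   upright = if (hc) 0.36 else 0.45),
    dcvo_shift = if (hc) 0.05 else -0.42,
    noise_sd = 0.10,
    resp_var = 0.30,
    angle_range = c(45, 60),
    angle_error_sd = 2.5,
    side_share_vein = c(mean = 0.55, sd = 0.10),
    side_share_artery = c(mean = 0.50, sd = 0.03),
    lr_correlation = 0)
  dots <- list(...)
  bad <- setdiff(names(dots), names(ph))
  if (length(bad) > 0)
    stop("unknown phenotype field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ph[names(dots)] <- dots
  stopifnot(ph$noise_sd >= 0, all(ph$vv_frac >= 0 & ph$vv_frac <= 1),
            all(ph$reentry_f3 >= 0 & ph$reentry_f3 <= 1),
            all(ph$reentry_f2 >= 0 & ph$reentry_f2 <= 1))
  structure(ph, class = "cvo_phenotype")
}

venous_geom_lookup <- function(ph, posture, segment, side) {
  g <- ph$venous_geometry
  row <- g[g$posture == posture & g$segment == segment & g$side == side, ]
  row$csa_mean[1]
}

angle_bias <- function(theta, delta) {
  cos(theta * pi / 180) / cos(clamp(theta + delta, 1, 89) * pi / 180)
}

#' Simulate one subject: latent flows plus raw site measurements
#'
#' Draws the subject's latent truth (arterial inflows; a venous drainage
#' ladder in which flow grows J3 to J1 through collateral re-entry, with
#' the CCSVI phenotype suppressing J1 by the obstruction multiplier and
#' rerouting the blocked flow to the collateral-proximal channel so that
#' continuity holds in truth), then decomposes every site flow into the
#' raw quantities an operator records (peak-envelope velocity through
#' the velocity factor, min/max lumen areas, diameter, insonation
#' angle), applying multiplicative lognormal noise and the angle
#' placement error. With zero noise and zero angle error the
#' quantification pipeline recovers the latent flows exactly.
#'
#' @param phenotype [synthetic_phenotype()].
#' @param posture Character vector of postures to generate (default
#'   both; subject-level latents are shared across postures).
#' @param seed Integer seed.
#' @param subject_id Identifier (default derived from the seed).
#' @param config [flow_config()] used for the velocity-factor inversion.
#' @return List: `truth` (flow-set tibble of latent per-site flows),
#'   `measurements` (raw measurement tibble for [compute_flow()]),
#'   `latent` (tibble of subject-level parameters incl. the analytic
#'   collateral fraction per posture).
#' @export
generate_subject <- function(phenotype, posture = cvo_postures, seed,
                             subject_id = NULL,
                             config = flow_config()) {
  stopifnot(inherits(phenotype, "cvo_phenotype"))
  posture <- match.arg(posture, several.ok = TRUE)
  set.seed(as.integer(seed))
  ph <- phenotype
  subject_id <- subject_id %||% sprintf("synth-%d", as.integer(seed))

  art_total <- setNames(
    vapply(seq_len(nrow(ph$arterial)), function(i)
      rlnorm_mm(1, ph$arterial$q_mean[i], ph$arterial$q_sd[i]), numeric(1)),
    ph$arterial$vessel)
  b <- clamp(rnorm(1, ph$baseline_cfi_mean, ph$baseline_cfi_sd), -0.5, 0.95)
  o <- if (ph$j1_obstruction_sd == 0 && ph$j1_obstruction_mean == 0) 0 else
    clamp(rnorm(1, ph$j1_obstruction_mean, ph$j1_obstruction_sd), 0, 1)
  share_art <- clamp(rnorm(length(art_total), ph$side_share_artery["mean"],
                           ph$side_share_artery["sd"]), 0.3, 0.7)
  share_ijv <- clamp(rnorm(1, ph$side_share_vein["mean"],
                           ph$side_share_vein["sd"]), 0.2, 0.8)
  share_vv <- clamp(rnorm(1, ph$side_share_vein["mean"],
                          ph$side_share_vein["sd"]), 0.2, 0.8)

  truth <- list(); meas <- list(); latents <- list()
  for (p in posture) {
    b_p <- clamp(b + if (p == "upright") ph$dcvo_shift else 0, -0.5, 0.95)
    hbinf <- (art_total["CCA"] + art_total["ICA"] + art_total["ECA"]) / 2 +
      art_total["VA"]
    q_pot <- (1 - b_p) * hbinf
    vvf <- ph$vv_frac[[p]]
    q_vv <- vvf * q_pot
    q_j1_pot <- (1 - vvf) * q_pot
    q_j1 <- (1 - o) * q_j1_pot
    q_j3 <- ph$reentry_f3[[p]] * q_j1_pot
    q_j2 <- ph$reentry_f2[[p]] * q_j1_pot
    sides <- c(right = share_ijv, left = 1 - share_ijv)
    vside <- c(right = share_vv, left = 1 - share_vv)

    rows <- list()
    for (i in seq_along(art_total)) {
      v <- names(art_total)[i]
      for (s in cvo_sides) {
        qs <- art_total[[v]] * (if (s == "right") share_art[i] else
          1 - share_art[i])
        rows[[length(rows) + 1L]] <- list(
          vessel = v, side = s,
          segment = if (v == "VA") "V2" else "none", q = qs)
      }
    }
    for (seg in c("J3", "J2", "J1")) {
      qq <- switch(seg, J3 = q_j3, J2 = q_j2, J1 = q_j1)
      for (s in cvo_sides)
        rows[[length(rows) + 1L]] <- list(vessel = "IJV", side = s,
                                          segment = seg, q = qq * sides[[s]])
    }
    for (s in cvo_sides)
      rows[[length(rows) + 1L]] <- list(vessel = "VV", side = s,
                                        segment = "C45", q = q_vv * vside[[s]])
    rt <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    truth[[p]] <- subject_flow_set(subject_id, ph$group, p,
                                   rt$vessel, rt$side, rt$segment, rt$q)

    m <- lapply(seq_len(nrow(rt)), function(i) {
      v <- rt$vessel[i]; s <- rt$side[i]; seg <- rt$segment[i]; q <- rt$q[i]
      theta <- runif(1, ph$angle_range[1], ph$angle_range[2])
      bias <- angle_bias(theta, rnorm(1, 0, ph$angle_error_sd))
      nz <- function(sdfac = 1)
        if (ph$noise_sd == 0) 1 else exp(rnorm(1, 0, ph$noise_sd * sdfac))
      # one multiplicative lognormal factor per site governs the flow
      # error; the geometry jitter is compensated in the velocity so the
      # site flow noise is exactly noise_sd (plus the angle bias)
      site_f <- nz()
      if (v %in% cvo_arteries) {
        d <- ph$arterial_diameter[[v]]
        csa <- arterial_csa(d)
        omega <- 2 * pi * config$heart_rate / 60
        alpha <- womersley_number(d / 2, omega, config$viscosity)
        eta <- site_eta(v, alpha, config)
        d_m <- d * nz(0.5)
        tavp <- (q / (60 * csa)) * eta * site_f / (d_m / d)^2
        tibble::tibble(
          subject_id = subject_id, group = ph$group, posture = p,
          vessel = v, side = s, segment = seg,
          tavp = tavp * bias, profile_velocities = NA_character_,
          csa_min = NA_real_, csa_max = NA_real_,
          diameter = d_m, major_axis = NA_real_,
          doppler_angle = theta, flow_state = "normal")
      } else {
        csa <- venous_geom_lookup(ph, p, seg, s)
        omega <- 2 * pi * config$respiratory_rate / 60
        alpha <- womersley_number(sqrt(csa / pi), omega, config$viscosity)
        eta <- site_eta(v, alpha, config)
        tav <- q / (60 * csa)
        lo <- csa * (1 - ph$resp_var) * nz(0.5)
        hi <- csa * (1 + ph$resp_var) * nz(0.5)
        g <- (min(lo, hi) + max(lo, hi)) / 2 / csa
        absent <- q <= 0
        tibble::tibble(
          subject_id = subject_id, group = ph$group, posture = p,
          vessel = v, side = s, segment = seg,
          tavp = if (absent) 0 else tav * eta * site_f / g * bias,
          profile_velocities = NA_character_,
          csa_min = min(lo, hi), csa_max = max(lo, hi),
          major_axis = 2 * sqrt(csa / pi), doppler_angle = theta,
          diameter = NA_real_,
          flow_state = if (absent) "absent" else "normal")
      }
    })
    meas[[p]] <- dplyr::bind_rows(m)
    latents[[p]] <- tibble::tibble(
      subject_id = subject_id, group = ph$group, posture = p,
      hbinf = unname(hbinf), baseline_cfi = b_p, j1_obstruction = o,
      collateral_fraction = unname(1 - (q_j1 + q_vv) / hbinf),
      cfi = unname(100 * (1 - (q_j1 + q_vv) / hbinf)))
  }
  list(truth = dplyr::bind_rows(truth),
       measurements = dplyr::bind_rows(meas),
       latent = dplyr::bind_rows(latents))
}

#' Simulate a cohort of independent subjects
#'
#' Child seeds are derived deterministically from the master seed (one
#' `sample.int(2^31 - 1)` stream seeded with `seed`), so a cohort is
#' fully reproducible from `(phenotype, n, seed)` and disjoint seeds
#' give different cohorts.
#'
#' @param phenotype [synthetic_phenotype()].
#' @param n Number of subjects (`n = 0` gives empty tables).
#' @param seed Master integer seed.
#' @param posture Postures to generate.
#' @param config [flow_config()].
#' @return List: `truth` (cohort table of latent flows), `measurements`
#'   (raw measurement tibble), `latent` (per-subject parameters).
#' @export
generate_cohort <- function(phenotype, n, seed, posture = cvo_postures,
                            config = flow_config()) {
  stopifnot(n >= 0)
  if (n == 0) {
    empty <- generate_subject(phenotype, posture, seed = 1, config = config)
    return(list(truth = cohort_table(empty$truth[0, ]),
                measurements = empty$measurements[0, ],
                latent = empty$latent[0, ]))
  }
  set.seed(as.integer(seed))
  child <- sample.int(.Machine$integer.max, n)
  subs <- lapply(seq_len(n), function(i)
    generate_subject(phenotype, posture, seed = child[i],
                     subject_id = sprintf("synth-%03d", i), config = config))
  list(truth = cohort_table(dplyr::bind_rows(lapply(subs, `[[`, "truth")),
                            provenance = sprintf(
                              "synthetic %s cohort, n=%d, seed=%d",
                              phenotype$group, n, as.integer(seed))),
       measurements = dplyr::bind_rows(lapply(subs, `[[`, "measurements")),
       latent = dplyr::bind_rows(lapply(subs, `[[`, "latent")))
}

#' Synthesize a periodic peak-velocity envelope
#'
#' A sampled Doppler envelope whose time average over whole cycles
#' equals the target peak-envelope velocity: three cardiac cycles with
#' two pulsatile harmonics for arteries, one respiration-modulated cycle
#' for veins. Used to test envelope-averaging code.
#'
#' @param tavp Target time-averaged peak velocity, cm/s.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param heart_rate,respiratory_rate Cycle frequencies, per minute.
#' @param n Number of equally spaced samples over the acquisition.
#' @param seed Seed for the random harmonic phases.
#' @param modulation Scales the harmonic amplitudes; 0 gives a constant
#'   envelope.
#' @return Tibble with `time` (s) and `velocity` (cm/s).
#' @export
generate_doppler_trace <- function(tavp, vessel_class = c("artery", "vein"),
                                   heart_rate = 70, respiratory_rate = 15,
                                   n = 256, seed = 1, modulation = 1) {
  vessel_class <- match.arg(vessel_class)
  set.seed(as.integer(seed))
  if (vessel_class == "artery") {
    cycles <- 3; f <- heart_rate / 60
    amps <- modulation * c(0.5, 0.2)
  } else {
    cycles <- 1; f <- respiratory_rate / 60
    amps <- modulation * c(0.3)
  }
  total <- cycles / f
  t <- seq(0, total, length.out = n + 1)[-(n + 1)]
  phases <- runif(length(amps), 0, 2 * pi)
  mod <- rep(1, n)
  for (k in seq_along(amps))
    mod <- mod + amps[k] * cos(2 * pi * k * f * t + phases[k])
  tibble::tibble(time = t, velocity = tavp * mod)
}

#' Time-averaged velocity of a sampled envelope
#'
#' @param trace Tibble from [generate_doppler_trace()] (equally spaced
#'   samples over whole cycles).
#' @return Mean velocity, cm/s.
#' @export
tav_from_trace <- function(trace) mean(trace$velocity)
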