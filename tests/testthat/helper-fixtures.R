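# Fixtures are built in code, seeded where random.

default_site_q <- c(
  CCA_right_none = 420, CCA_left_none = 423,
  ICA_right_none = 230, ICA_left_none = 232,
  ECA_right_none = 128, ECA_left_none = 127,
  VA_right_V2 = 90, VA_left_V2 = 86,
  IJV_right_J3 = 190, IJV_left_J3 = 167,
  IJV_right_J2 = 240, IJV_left_J2 = 290,
  IJV_right_J1 = 440, IJV_left_J1 = 400,
  VV_right_C45 = 42, VV_left_C45 = 24)

# complete 16-site subject flow set; override any site by name
make_flows <- function(subject_id = "s1", group = "HC", posture = "supine",
                       q = NULL) {
  qq <- default_site_q
  if (!is.null(q)) qq[names(q)] <- q
  parts <- strsplit(names(qq), "_", fixed = TRUE)
  subject_flow_set(
    subject_id, group, posture,
    vessel = vapply(parts, `[[`, "", 1),
    side = vapply(parts, `[[`, "", 2),
    segment = vapply(parts, `[[`, "", 3),
    q = unname(qq))
}

random_flows <- function(subject_id = "f1", rng_max = 1500) {
  q <- runif(length(default_site_q), 0, rng_max)
  names(q) <- names(default_site_q)
  make_flows(subject_id, q = q)
}

# random valid measurement records across vessel classes
random_measurements <- function(n, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    artery <- runif(1) < 0.5
    if (artery) {
      v <- sample(c("CCA", "ICA", "ECA", "VA"), 1)
      vessel_measurement(
        sprintf("r%03d", i), sample(c("HC", "CCSVI"), 1),
        sample(c("supine", "upright"), 1), v, sample(c("right", "left"), 1),
        segment = if (v == "VA") "V2" else "none",
        tavp = runif(1, 5, 80), diameter = runif(1, 0.2, 0.8),
        doppler_angle = runif(1, 30, 70))
    } else {
      v <- sample(c("IJV", "VV"), 1)
      seg <- if (v == "IJV") sample(c("J1", "J2", "J3"), 1) else "C45"
      lo <- runif(1, 0.01, 0.4); hi <- lo + runif(1, 0, 0.3)
      use_profile <- runif(1) < 0.3
      vessel_measurement(
        sprintf("r%03d", i), sample(c("HC", "CCSVI"), 1),
        sample(c("supine", "upright"), 1), v, sample(c("right", "left"), 1),
        segment = seg,
        tavp = if (use_profile) NA_real_ else runif(1, 2, 60),
        profile_velocities = if (use_profile) runif(5, 0, 60) else NULL,
        csa_min = lo, csa_max = hi,
        major_axis = runif(1, 0.3, 1.4),
        doppler_angle = runif(1, 30, 70))
    }
  })
  dplyr::bind_rows(recs)
}

# independent Mann-Whitney oracle: enumerate group assignments, count
# pairwise wins directly (no rank-sum formula, no shared code path)
mw_oracle_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- n_a * length(b) / 2
  combos <- utils::combn(n, n_a)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
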