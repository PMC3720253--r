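#' Distal jugular and vertebral draining index
#'
#' DJVDI = 100 CVO / HBinF: the percentage of the head inflow already
#' drained by the main routes (IJV at J3 plus vertebral veins) at the
#' skull exit.
#'
#' @param cvo,hbinf ml/min; `hbinf > 0`.
#' @return Percent.
#' @export
compute_djvdi <- function(cvo, hbinf) {
  if (any(hbinf <= 0)) stop("hbinf must be > 0", call. = FALSE)
  100 * cvo / hbinf
}

#' Collateral flow index
#'
#' CFI = 100 Q_C-P / HBinF = 100 (1 - HBoutF/HBinF): the percentage of
#' the head inflow that bypasses both jugulars and vertebral veins and
#' re-enters the caval system through collaterals.
#'
#' @param q_cp Collateral-proximal flow, ml/min.
#' @param hbinf ml/min; `> 0`.
#' @return Percent.
#' @export
compute_cfi <- function(q_cp, hbinf) {
  if (any(hbinf <= 0)) stop("hbinf must be > 0", call. = FALSE)
  100 * q_cp / hbinf
}

#' Cerebral collateral draining index
#'
#' CCDI = 100 Q_C-D / CBF: the percentage of the brain inflow drained
#' through collaterals rather than through the main routes at J3/VV
#' level.
#'
#' @param q_cd Collateral-distal flow, ml/min.
#' @param cbf ml/min; `> 0`.
#' @return Percent.
#' @export
compute_ccdi <- function(q_cd, cbf) {
  if (any(cbf <= 0)) stop("cbf must be > 0", call. = FALSE)
  100 * q_cd / cbf
}

#' Delta cerebral venous outflow
#'
#' DCVO = 100 x ( (J1s + VVs)/HBinF supine minus the same ratio upright ):
#' the postural shift of the normalized main-route outflow measured at
#' J1 level. Positive when the supine posture drains more through the
#' main routes. Requires both postures; by default each posture uses its
#' own arterial denominator, with `denominator = "supine"` forcing the
#' supine HBinF on both terms (for datasets where arteries were only
#' measured supine).
#'
#' @param supine,upright `cvo_network` solutions of the same subject.
#' @param denominator `"matched"` (default) or `"supine"`.
#' @return Percent.
#' @export
compute_dcvo <- function(supine, upright, denominator = c("matched", "supine")) {
  denominator <- match.arg(denominator)
  den_sup <- supine$hbinf
  den_up <- if (denominator == "matched") upright$hbinf else supine$hbinf
  if (den_sup <= 0 || den_up <= 0) stop("hbinf must be > 0", call. = FALSE)
  100 * (supine$hboutf / den_sup - upright$hboutf / den_up)
}

#' All four drainage indexes for one subject
#'
#' @param solutions Named list of `cvo_network` solutions keyed by
#'   posture (`supine` and/or `upright`).
#' @param denominator Passed to [compute_dcvo()].
#' @return Tibble with one row per posture: `djvdi`, `cfi`, `ccdi`
#'   (per-posture), `dcvo` (identical on both rows; `NA` when a posture
#'   is missing - undefined, never zero), and the denominators used.
#' @export
subject_indexes <- function(solutions, denominator = c("matched", "supine")) {
  denominator <- match.arg(denominator)
  dcvo <- if (all(c("supine", "upright") %in% names(solutions)))
    compute_dcvo(solutions$supine, solutions$upright, denominator)
  else NA_real_
  dplyr::bind_rows(lapply(names(solutions), function(p) {
    s <- solutions[[p]]
    hbinf <- if (p == "upright" && denominator == "supine" &&
                 "supine" %in% names(solutions))
      solutions$supine$hbinf else s$hbinf
    tibble::tibble(
      subject_id = s$subject_id, group = s$group, posture = p,
      dcvo = dcvo,
      djvdi = compute_djvdi(s$cvo, hbinf),
      cfi = compute_cfi(hbinf - s$hboutf, hbinf),
      ccdi = compute_ccdi(s$cbf - s$cvo, s$cbf),
      hbinf_used = hbinf, cbf_used = s$cbf)
  }))
}

solve_cohort <- function(cohort, skip_incomplete = FALSE) {
  keys <- cohort |> dplyr::distinct(.data$subject_id, .data$posture)
  sols <- list()
  for (i in seq_len(nrow(keys))) {
    fl <- cohort |>
      dplyr::filter(.data$subject_id == keys$subject_id[i],
                    .data$posture == keys$posture[i])
    if (skip_incomplete && length(validate_subject(fl)) > 0) next
    sols[[length(sols) + 1L]] <- collateral_flows(fl)
  }
  names(sols) <- vapply(sols, function(s)
    paste(s$subject_id, s$posture, sep = "\r"), character(1))
  sols
}

#' Per-subject drainage indexes for a whole cohort
#'
#' Solves the collateral network for every subject-posture in the cohort
#' and computes the four indexes per subject, the paradigm used for
#' cohort reporting: indexes are averaged across subjects, not computed
#' from cohort-mean flows (ratio-then-average, the only path consistent
#' with per-subject index dispersion). For the alternative
#' aggregate-flows path see [aggregate_indexes()].
#'
#' @param cohort Cohort table of per-site flows.
#' @param denominator Passed to [subject_indexes()].
#' @return Tibble, one row per subject-posture, with a
#'   `"computation_path"` attribute `"per_subject"`.
#' @export
cohort_indexes <- function(cohort, denominator = c("matched", "supine")) {
  denominator <- match.arg(denominator)
  sols <- solve_cohort(cohort)
  ids <- unique(vapply(sols, function(s) s$subject_id, character(1)))
  out <- dplyr::bind_rows(lapply(ids, function(id) {
    mine <- sols[vapply(sols, function(s) s$subject_id == id, logical(1))]
    names(mine) <- vapply(mine, function(s) s$posture, character(1))
    subject_indexes(mine, denominator)
  }))
  attr(out, "computation_path") <- "per_subject"
  out
}

#' Drainage indexes from cohort-mean flows
#'
#' The ratio-of-means path: per-site flows are averaged across subjects
#' first, the network is solved once on the mean flows, and the indexes
#' are taken from that single solution. Kept for comparison with the
#' per-subject path ([cohort_indexes()]); reports label which path was
#' used.
#'
#' @param cohort Cohort table.
#' @param denominator Passed to [subject_indexes()].
#' @return Tibble as in [subject_indexes()], one row per posture, with
#'   `"computation_path"` attribute `"aggregate"`.
#' @export
aggregate_indexes <- function(cohort, denominator = c("matched", "supine")) {
  denominator <- match.arg(denominator)
  mean_flows <- cohort |>
    dplyr::group_by(.data$posture, .data$vessel, .data$side, .data$segment,
                    .data$site) |>
    dplyr::summarise(q = mean(.data$q), dq = mean(.data$dq),
                     .groups = "drop")
  sols <- list()
  for (p in unique(mean_flows$posture)) {
    fl <- mean_flows |> dplyr::filter(.data$posture == p)
    sols[[p]] <- collateral_flows(
      subject_flow_set("cohort-mean", cohort$group[1], p,
                       fl$vessel, fl$side, fl$segment, fl$q, fl$dq))
  }
  out <- subject_indexes(sols, denominator)
  attr(out, "computation_path") <- "aggregate"
  out
}
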