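#' Site keys and required model sites
#'
#' A site is a vessel + side + segment triple, e.g. `IJV_right_J1`. The
#' full network model needs 16 sites per subject-posture: the 8 arterial
#' sites feeding the head-inflow estimate (CCA, ICA, ECA, VA on both
#' sides) and the 8 venous sites of the jugular/vertebral drainage ladder
#' (IJV J1/J2/J3 and VV on both sides).
#'
#' @param vessel,side,segment Character vectors (recycled).
#' @return Character vector of site keys.
#' @export
site_key <- function(vessel, side, segment = "none") {
  paste(vessel, side, segment, sep = "_")
}

required_arterial_sites <- function() {
  c(site_key("CCA", cvo_sides, "none"),
    site_key("ICA", cvo_sides, "none"),
    site_key("ECA", cvo_sides, "none"),
    site_key("VA",  cvo_sides, "V2"))
}

required_venous_sites <- function() {
  c(site_key("IJV", rep(cvo_sides, each = 3), rep(c("J1", "J2", "J3"), 2)),
    site_key("VV", cvo_sides, "C45"))
}

#' Assemble a per-subject flow set
#'
#' A subject flow set is the long table of per-site volumetric flows for
#' one subject in one posture: one row per site with flow `q` (ml/min),
#' its propagated uncertainty `dq`, and the quantification intermediates
#' (`tav`, `csa`, `eta`, `alpha`, `method`).
#'
#' @param subject_id,group,posture Subject metadata (scalars).
#' @param vessel,side,segment Site identity vectors.
#' @param q Flows, ml/min.
#' @param dq Flow uncertainties, ml/min (default 0).
#' @param tav,csa,eta,alpha,method Optional quantification intermediates.
#' @return Tibble with one row per site.
#' @export
subject_flow_set <- function(subject_id, group, posture,
                             vessel, side, segment, q, dq = 0,
                             tav = NA_real_, csa = NA_real_,
                             eta = NA_real_, alpha = NA_real_,
                             method = NA_character_) {
  out <- tibble::tibble(
    subject_id = as.character(subject_id), group = group, posture = posture,
    vessel = vessel, side = side, segment = segment,
    site = site_key(vessel, side, segment),
    q = as.numeric(q), dq = as.numeric(dq), tav = as.numeric(tav),
    csa = as.numeric(csa), eta = as.numeric(eta), alpha = as.numeric(alpha),
    method = method)
  key <- paste(out$subject_id, out$posture, out$site)
  if (anyDuplicated(key))
    stop("duplicate site(s): ",
         paste(out$site[duplicated(key)], collapse = ", "), call. = FALSE)
  out
}

#' Check that a subject carries every site the network model needs
#'
#' Returns diagnostics (never throws): one entry per missing site among
#' the 8 arterial sites required by the head-inflow estimate and the 8
#' venous sites (J1, J2, J3, VV bilaterally) consumed by the aggregate
#' outflow quantities and the collateral-flow equations.
#'
#' @param flows Subject flow set (one subject, one posture).
#' @return Character vector of missing site keys; empty when complete.
#' @export
validate_subject <- function(flows) {
  need <- c(required_arterial_sites(), required_venous_sites())
  missing <- setdiff(need, flows$site)
  if (length(missing) == 0) character(0) else
    sprintf("missing site %s", missing)
}

#' Bundle subject flow sets into a cohort table
#'
#' @param records Tibble of stacked subject flow sets (or a list of them).
#' @param provenance Free-text provenance note.
#' @return Tibble of class `cvo_cohort` with `provenance` and
#'   `schema_version` attributes; subject ids must be unique per posture
#'   (each subject contributes one flow set per posture).
#' @export
cohort_table <- function(records, provenance = "") {
  if (is.list(records) && !is.data.frame(records))
    records <- dplyr::bind_rows(records)
  dup <- records |>
    dplyr::distinct(.data$subject_id, .data$posture, .data$site) |>
    dplyr::count(.data$subject_id, .data$posture, .data$site) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop("duplicate subject/posture/site rows", call. = FALSE)
  attr(records, "provenance") <- provenance
  attr(records, "schema_version") <- "1"
  class(records) <- unique(c("cvo_cohort", class(records)))
  records
}

#' Export a cohort table as JSON
#'
#' @param cohort Cohort table.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned instead.
#' @return `path` (invisibly) or a JSON string.
#' @export
cohort_to_json <- function(cohort, path = NULL) {
  payload <- list(
    provenance = attr(cohort, "provenance") %||% "",
    schema_version = attr(cohort, "schema_version") %||% "1",
    records = as.data.frame(cohort))
  if (is.null(path))
    return(jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                            auto_unbox = TRUE, na = "null"))
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
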