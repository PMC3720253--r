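#' Controlled vocabularies for measurement records
#'
#' The pipeline works on six cervical vessels. Arteries (CCA, ICA, ECA, VA)
#' are treated as circular and measured by diameter; veins (IJV, VV) are
#' elliptical and measured by minimum/maximum traced lumen area over one
#' respiratory cycle. The internal jugular vein is split into the consensus
#' segments J3 (upper, mandibular angle), J2 (middle, thyroid level) and J1
#' (lower, confluence with the brachio-cephalic trunk); the vertebral artery
#' is insonated at V2 and the vertebral vein at C4-C5.
#'
#' @name vocab
#' @keywords internal
NULL

cvo_vessels   <- c("CCA", "ICA", "ECA", "VA", "IJV", "VV")
cvo_arteries  <- c("CCA", "ICA", "ECA", "VA")
cvo_veins     <- c("IJV", "VV")
cvo_sides     <- c("right", "left")
cvo_segments  <- c("J1", "J2", "J3", "V2", "C45", "none")
cvo_groups    <- c("HC", "CCSVI")
cvo_postures  <- c("supine", "upright")
cvo_states    <- c("normal", "absent", "turbulent")

# segment vocabulary implied by each vessel
segment_for_vessel <- function(vessel) {
  switch(vessel,
    IJV = c("J1", "J2", "J3"),
    VA  = "V2",
    VV  = "C45",
    "none")
}

measurement_columns <- c(
  "subject_id", "group", "posture", "vessel", "side", "segment",
  "tavp", "profile_velocities", "csa_min", "csa_max", "diameter",
  "major_axis", "doppler_angle", "flow_state")

#' Build a single vessel measurement record
#'
#' One raw echo colour Doppler / B-mode observation at one site: the
#' peak-envelope time-averaged velocity (or a five-point wall-to-wall
#' velocity profile for turbulent/absent J1 flow), the lumen geometry and
#' the insonation angle. Units are fixed: velocities in cm/s, areas in cm2,
#' lengths in cm, angles in degrees. Conversion to ml/min happens once, in
#' [compute_flow()].
#'
#' @param subject_id Opaque subject identifier.
#' @param group `"HC"` or `"CCSVI"`.
#' @param posture `"supine"` or `"upright"`.
#' @param vessel One of CCA, ICA, ECA, VA, IJV, VV.
#' @param side `"right"` or `"left"`.
#' @param segment IJV segment (`J1`/`J2`/`J3`), `V2` for VA, `C45` for VV,
#'   `"none"` for the carotids.
#' @param tavp Peak-envelope time-averaged velocity, cm/s.
#' @param profile_velocities Numeric vector of exactly five wall-to-wall
#'   velocities, cm/s (alternative to `tavp`).
#' @param csa_min,csa_max Minimum/maximum traced lumen area over one
#'   respiratory cycle, cm2 (veins only).
#' @param diameter Lumen diameter, cm (arteries only).
#' @param major_axis Optional descriptive major axis of the elliptical vein
#'   lumen, cm.
#' @param doppler_angle Insonation angle, degrees, strictly inside (0, 90).
#' @param flow_state `"normal"`, `"absent"` or `"turbulent"`.
#' @return A one-row tibble with the full measurement schema.
#' @export
#' @examples
#' vessel_measurement("s1", "HC", "supine", "IJV", "right", "J3",
#'                    tavp = 25, csa_min = 0.2, csa_max = 0.32,
#'                    doppler_angle = 55)
vessel_measurement <- function(subject_id, group, posture, vessel, side,
                               segment = "none",
                               tavp = NA_real_, profile_velocities = NULL,
                               csa_min = NA_real_, csa_max = NA_real_,
                               diameter = NA_real_, major_axis = NA_real_,
                               doppler_angle = 60, flow_state = "normal") {
  prof <- if (is.null(profile_velocities)) NA_character_ else
    paste(format(profile_velocities, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ";")
  rec <- tibble::tibble(
    subject_id = as.character(subject_id),
    group = group, posture = posture, vessel = vessel, side = side,
    segment = segment, tavp = as.numeric(tavp),
    profile_velocities = prof,
    csa_min = as.numeric(csa_min), csa_max = as.numeric(csa_max),
    diameter = as.numeric(diameter), major_axis = as.numeric(major_axis),
    doppler_angle = as.numeric(doppler_angle), flow_state = flow_state)
  diag <- validate_measurements(rec)
  if (nrow(diag) > 0) {
    stop("invalid measurement: ", paste(diag$message, collapse = "; "),
         call. = FALSE)
  }
  rec
}

parse_profile <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Validate a table of measurement records
#'
#' Checks every type invariant row by row: vocabulary membership,
#' artery/vein geometry exclusivity, segment consistency with the vessel,
#' angle domain, CSA ordering, and the exactly-one-of tavp/profile rule
#' (waived when `flow_state = "absent"`).
#'
#' @param records Tibble in the [vessel_measurement()] schema.
#' @return Tibble of diagnostics with columns `row`, `field`, `message`;
#'   zero rows when everything is valid. Never throws.
#' @export
validate_measurements <- function(records) {
  out <- list()
  bad <- function(row, field, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      row = row, field = field, message = message)
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    chk_enum <- function(field, vocab) {
      v <- r[[field]]
      if (is.na(v) || !v %in% vocab) {
        bad(i, field, sprintf("%s '%s' not in {%s}", field, v,
                              paste(vocab, collapse = ", ")))
        return(FALSE)
      }
      TRUE
    }
    ok <- chk_enum("group", cvo_groups) & chk_enum("posture", cvo_postures) &
      chk_enum("vessel", cvo_vessels) & chk_enum("side", cvo_sides) &
      chk_enum("flow_state", cvo_states) & chk_enum("segment", cvo_segments)
    if (!ok) next
    seg_ok <- segment_for_vessel(r$vessel)
    if (!r$segment %in% seg_ok) {
      bad(i, "segment", sprintf("vessel %s requires segment in {%s}, got '%s'",
                                r$vessel, paste(seg_ok, collapse = ", "),
                                r$segment))
    }
    if (r$vessel %in% cvo_arteries) {
      if (is.na(r$diameter) || r$diameter <= 0)
        bad(i, "diameter", sprintf("artery %s requires diameter > 0", r$vessel))
      if (!is.na(r$csa_min) || !is.na(r$csa_max))
        bad(i, "csa_min", sprintf("artery %s must not carry csa_min/csa_max",
                                  r$vessel))
    } else {
      if (is.na(r$csa_min) || is.na(r$csa_max) ||
          r$csa_min < 0 || r$csa_min > r$csa_max)
        bad(i, "csa_min", "vein requires 0 <= csa_min <= csa_max")
      if (!is.na(r$diameter))
        bad(i, "diameter", "vein must not carry a diameter")
    }
    if (is.na(r$doppler_angle) || r$doppler_angle <= 0 || r$doppler_angle >= 90)
      bad(i, "doppler_angle", "doppler_angle must lie strictly in (0, 90)")
    prof <- parse_profile(r$profile_velocities)
    has_tavp <- !is.na(r$tavp)
    has_prof <- !is.null(prof)
    if (has_prof && length(prof) != 5L)
      bad(i, "profile_velocities",
          sprintf("profile must have exactly 5 velocities, got %d", length(prof)))
    if (r$flow_state != "absent" && has_tavp == has_prof)
      bad(i, "tavp", "exactly one of tavp / profile_velocities required")
  }
  if (length(out) == 0)
    return(tibble::tibble(row = integer(), field = character(),
                          message = character()))
  dplyr::bind_rows(out)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read measurement records from delimited text
#'
#' Accepts comma- (default) or tab-delimited UTF-8 text with a mandatory
#' header whose names match the measurement schema case-insensitively.
#' Rows violating a type invariant are rejected, not silently coerced;
#' the surviving records are returned with the rejects' diagnostics
#' attached as the `"diagnostics"` attribute (row-numbered, field-named).
#'
#' @param path Path to an existing file.
#' @param delim Field delimiter; `NULL` (default) sniffs comma vs tab from
#'   the header line.
#' @return Tibble of valid measurement records; attribute `"diagnostics"`
#'   holds the rejection table (zero rows when the file is clean).
#' @export
read_measurements <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(measurement_columns, names(raw))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  raw <- raw[measurement_columns]
  num_fields <- c("tavp", "csa_min", "csa_max", "diameter", "major_axis",
                  "doppler_angle")
  numdiag <- list()
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    badrow <- which(!is.na(raw[[f]]) & nzchar(trimws(raw[[f]])) & is.na(v))
    for (i in badrow)
      numdiag[[length(numdiag) + 1L]] <- tibble::tibble(
        row = i, field = f,
        message = sprintf("unparsable numeric '%s' in field %s", raw[[f]][i], f))
    raw[[f]] <- v
  }
  numdiag <- if (length(numdiag)) dplyr::bind_rows(numdiag) else
    tibble::tibble(row = integer(), field = character(), message = character())
  diag <- validate_measurements(raw)
  diag <- dplyr::bind_rows(numdiag, diag)
  keep <- setdiff(seq_len(nrow(raw)), unique(diag$row))
  out <- raw[keep, ]
  if (nrow(diag) > 0)
    warning(sprintf("%d row(s) rejected; see attr(, 'diagnostics')",
                    length(unique(diag$row))), call. = FALSE)
  attr(out, "diagnostics") <- diag
  out
}

#' Write measurement records to delimited text
#'
#' One row per record, fixed header, shortest round-trip float
#' representation so that [read_measurements()] recovers the records
#' exactly.
#'
#' @param records Valid measurement tibble.
#' @param path Output path.
#' @param delim `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, delim = ",") {
  diag <- validate_measurements(records)
  if (nrow(diag) > 0)
    stop("refusing to write invalid records: ",
         paste(unique(diag$message), collapse = "; "), call. = FALSE)
  records <- records[measurement_columns]
  readr::write_delim(records, path, delim = delim, na = "")
  invisible(path)
}
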