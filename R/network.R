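site_q <- function(flows, vessel, segment = NULL, side = NULL) {
  sel <- flows$vessel == vessel
  if (!is.null(segment)) sel <- sel & flows$segment == segment
  if (!is.null(side)) sel <- sel & flows$side == side
  flows$q[sel]
}

sum_sides <- function(flows, vessel, segment = NULL) {
  sum(site_q(flows, vessel, segment))
}

require_sites <- function(flows, need) {
  missing <- setdiff(need, flows$site)
  if (length(missing) > 0)
    stop("missing site(s): ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Total head blood inflow
#'
#' HBinF = (CCAs + ICAs + ECAs)/2 + VAs, sums over sides. Because the
#' common carotid feeds both carotid branches, averaging the parent with
#' the sum of its branches halves the independent measurement error of
#' the carotid inflow estimate.
#'
#' @param flows Subject flow set with all 8 arterial sites.
#' @return HBinF, ml/min.
#' @export
compute_hbinf <- function(flows) {
  require_sites(flows, required_arterial_sites())
  (sum_sides(flows, "CCA") + sum_sides(flows, "ICA") +
     sum_sides(flows, "ECA")) / 2 + sum_sides(flows, "VA")
}

#' Cerebral blood flow
#'
#' CBF = ICAs + VAs: the arterial flow actually entering the brain
#' compartment (the external carotids feed the face and neck).
#'
#' @param flows Subject flow set with the ICA and VA sites.
#' @return CBF, ml/min.
#' @export
compute_cbf <- function(flows) {
  require_sites(flows, c(site_key("ICA", cvo_sides, "none"),
                         site_key("VA", cvo_sides, "V2")))
  sum_sides(flows, "ICA") + sum_sides(flows, "VA")
}

#' Cerebral venous outflow
#'
#' CVO = J3s + VVs: the venous return already inside the main drainage
#' routes at the exit of the skull (upper jugular segment plus vertebral
#' veins).
#'
#' @param flows Subject flow set with both J3 and both VV sites.
#' @return CVO, ml/min.
#' @export
compute_cvo <- function(flows) {
  require_sites(flows, c(site_key("IJV", cvo_sides, "J3"),
                         site_key("VV", cvo_sides, "C45")))
  sum_sides(flows, "IJV", "J3") + sum_sides(flows, "VV", "C45")
}

#' Total head blood outflow
#'
#' HBoutF = J1s + VVs: what actually reaches the brachio-cephalic
#' confluence through the main routes.
#'
#' @param flows Subject flow set with both J1 and both VV sites.
#' @return HBoutF, ml/min.
#' @export
compute_hboutf <- function(flows) {
  require_sites(flows, c(site_key("IJV", cvo_sides, "J1"),
                         site_key("VV", cvo_sides, "C45")))
  sum_sides(flows, "IJV", "J1") + sum_sides(flows, "VV", "C45")
}

#' Solve the collateral network for one subject-posture
#'
#' Pure volumetric bookkeeping on the neck-vein model: given the measured
#' per-site flows, the five collateral flows are
#' \itemize{
#'   \item Q_C-D = CBF - CVO (brain outflow entering the collateral
#'     network distally),
#'   \item Q_FN = HBinF - CBF (facial/neck compartment drainage into the
#'     collaterals),
#'   \item Q_23 = Q_J2 - Q_J3 and Q_12 = Q_J1 - Q_J2 per jugular side
#'     (collateral re-entry into the IJV; positive toward the jugular),
#'   \item Q_C-P = HBinF - HBoutF (collateral outflow bypassing the
#'     jugulars straight into the caval system).
#' }
#' These satisfy the continuity identity
#' (Q_C-D + Q_FN) - (sum Q_23 + sum Q_12 + Q_C-P) = 0 algebraically; the
#' residual is computed and stored as a self-check. Negative values are
#' reported, never clipped: they are physiologically meaningful (flow
#' leaving the jugular toward collaterals, or an aggregate J1
#' overestimate).
#'
#' @param flows Subject flow set with all 16 model sites.
#' @return Object of class `cvo_network`: aggregate quantities (`hbinf`,
#'   `cbf`, `cvo`, `hboutf`), collateral flows (`q_cd`, `q_fn`, `q_cp`,
#'   per-side `q23` and `q12`), `continuity_residual` and the input
#'   `per_site_flows`, all flows in ml/min.
#' @export
collateral_flows <- function(flows) {
  miss <- validate_subject(flows)
  if (length(miss) > 0)
    stop(paste(miss, collapse = "; "), call. = FALSE)
  hbinf <- compute_hbinf(flows)
  cbf <- compute_cbf(flows)
  cvo <- compute_cvo(flows)
  hboutf <- compute_hboutf(flows)
  q23 <- vapply(cvo_sides, function(s)
    site_q(flows, "IJV", "J2", s) - site_q(flows, "IJV", "J3", s), numeric(1))
  q12 <- vapply(cvo_sides, function(s)
    site_q(flows, "IJV", "J1", s) - site_q(flows, "IJV", "J2", s), numeric(1))
  q_cd <- cbf - cvo
  q_fn <- hbinf - cbf
  q_cp <- hbinf - hboutf
  residual <- (q_cd + q_fn) - (sum(q23) + sum(q12) + q_cp)
  structure(list(
    subject_id = flows$subject_id[1], group = flows$group[1],
    posture = flows$posture[1],
    hbinf = hbinf, cbf = cbf, cvo = cvo, hboutf = hboutf,
    q_cd = q_cd, q_fn = q_fn, q_cp = q_cp, q23 = q23, q12 = q12,
    continuity_residual = residual, per_site_flows = flows),
    class = "cvo_network")
}

#' @export
print.cvo_network <- function(x, ...) {
  cat(sprintf("Neck venous network solution  [%s, %s, %s]\n",
              x$subject_id, x$group, x$posture))
  cat(sprintf("  HBinF %8.1f   CBF %8.1f   CVO %8.1f   HBoutF %8.1f ml/min\n",
              x$hbinf, x$cbf, x$cvo, x$hboutf))
  cat(sprintf("  Q_C-D %7.1f   Q_FN %7.1f   Q_C-P %7.1f ml/min\n",
              x$q_cd, x$q_fn, x$q_cp))
  cat(sprintf("  Q_23 (R/L) %7.1f / %7.1f   Q_12 (R/L) %7.1f / %7.1f ml/min\n",
              x$q23[["right"]], x$q23[["left"]],
              x$q12[["right"]], x$q12[["left"]]))
  cat(sprintf("  continuity residual %.3g ml/min\n", x$continuity_residual))
  invisible(x)
}

#' Export a network solution as JSON
#'
#' @param solution `cvo_network` object.
#' @param path Optional output path; when `NULL` a JSON string is
#'   returned.
#' @return `path` (invisibly) or JSON string.
#' @export
network_to_json <- function(solution, path = NULL) {
  payload <- solution[setdiff(names(solution), "per_site_flows")]
  payload$per_site_flows <- as.data.frame(solution$per_site_flows)
  if (is.null(path))
    return(jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                            auto_unbox = TRUE, na = "null"))
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

flow_map_edges <- function(solution) {
  f <- solution$per_site_flows
  lab <- function(v) sprintf("(%.0f)", v)
  tibble::tibble(
    edge = c("ICAs", "ECAs", "VAs", "J3s", "J2s", "J1s", "VVs",
             "Q_C-D", "Q_FN", "Q_23", "Q_12", "Q_C-P"),
    kind = c(rep("artery", 3), rep("vein", 4), rep("collateral", 5)),
    value = c(sum_sides(f, "ICA"), sum_sides(f, "ECA"), sum_sides(f, "VA"),
              sum_sides(f, "IJV", "J3"), sum_sides(f, "IJV", "J2"),
              sum_sides(f, "IJV", "J1"), sum_sides(f, "VV", "C45"),
              solution$q_cd, solution$q_fn, sum(solution$q23),
              sum(solution$q12), solution$q_cp)) |>
    dplyr::mutate(reversed = .data$kind == "collateral" & .data$value < 0,
                  label = paste(.data$edge, lab(.data$value)))
}

svg_line <- function(x1, y1, x2, y2, style, marker = TRUE) {
  sprintf(paste0('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" ',
                 'style="%s"%s/>'),
          x1, y1, x2, y2, style,
          if (marker) ' marker-end="url(#arr)"' else "")
}

svg_text <- function(x, y, s) {
  sprintf('<text x="%.1f" y="%.1f" font-size="11" font-family="sans-serif">%s</text>',
          x, y, s)
}

#' Render the subject's flow map
#'
#' A schematic of the neck drainage model: continuous arterial (red) and
#' venous (blue) tubes, dashed collateral channels, each of the 12 edges
#' labelled with its flow in ml/min. Collateral edges with negative flow
#' are drawn reversed (red, dashed, arrowhead flipped). Output is plain
#' SVG text plus the underlying edge table.
#'
#' @param solution `cvo_network` object.
#' @param path Optional `.svg` output path.
#' @return List with `svg` (character scalar), `edges` (tibble) and
#'   `table` (fixed-width text lines).
#' @export
render_flow_map <- function(solution, path = NULL) {
  e <- flow_map_edges(solution)
  val <- setNames(e$value, e$edge)
  rev <- setNames(e$reversed, e$edge)
  sty <- function(kind, reversed = FALSE) {
    col <- switch(kind, artery = "#c0392b", vein = "#2c5aa0",
                  collateral = if (reversed) "#c0392b" else "#666666")
    dash <- if (kind == "collateral") "stroke-dasharray:6 4;" else ""
    sprintf("stroke:%s;stroke-width:2.2;%s", col, dash)
  }
  # fixed topology: arterial column (x=60), jugular ladder (x=200),
  # collateral channel (x=320), vertebral vein (x=130)
  coll <- function(edge, y1, y2) {
    if (rev[[edge]]) svg_line(320, y2, 205, y1, sty("collateral", TRUE))
    else svg_line(205, y1, 320, y2, sty("collateral"))
  }
  body <- c(
    svg_line(60, 40, 60, 120, sty("artery")),   # ICA into brain
    svg_line(100, 40, 100, 120, sty("artery")), # ECA into face/neck
    svg_line(25, 40, 25, 120, sty("artery")),   # VA into brain
    svg_line(200, 60, 200, 130, sty("vein")),   # J3 segment
    svg_line(200, 130, 200, 200, sty("vein")),  # J2 segment
    svg_line(200, 200, 200, 280, sty("vein")),  # J1 segment
    svg_line(130, 60, 130, 280, sty("vein")),   # VV
    coll("Q_C-D", 60, 70),
    coll("Q_FN", 90, 100),
    coll("Q_23", 165, 165),
    coll("Q_12", 240, 240),
    if (rev[["Q_C-P"]]) svg_line(320, 300, 205, 285, sty("collateral", TRUE))
    else svg_line(320, 285, 230, 300, sty("collateral")),
    svg_line(320, 60, 320, 285, sty("collateral"), marker = FALSE),
    svg_text(40, 30, sprintf("ICAs (%.0f)", val[["ICAs"]])),
    svg_text(85, 20, sprintf("ECAs (%.0f)", val[["ECAs"]])),
    svg_text(5, 20, sprintf("VAs (%.0f)", val[["VAs"]])),
    svg_text(210, 95, sprintf("J3s (%.0f)", val[["J3s"]])),
    svg_text(210, 175, sprintf("J2s (%.0f)", val[["J2s"]])),
    svg_text(210, 250, sprintf("J1s (%.0f)", val[["J1s"]])),
    svg_text(90, 170, sprintf("VVs (%.0f)", val[["VVs"]])),
    svg_text(240, 55, sprintf("Q_C-D (%.0f)", val[["Q_C-D"]])),
    svg_text(240, 110, sprintf("Q_FN (%.0f)", val[["Q_FN"]])),
    svg_text(240, 160, sprintf("Q_23 (%.0f)", val[["Q_23"]])),
    svg_text(240, 235, sprintf("Q_12 (%.0f)", val[["Q_12"]])),
    svg_text(235, 315, sprintf("Q_C-P (%.0f)", val[["Q_C-P"]])),
    svg_text(10, 340, sprintf("%s  %s  %s   flows in ml/min",
                              solution$subject_id, solution$group,
                              solution$posture)))
  svg <- paste(c(
    '<svg xmlns="http://www.w3.org/2000/svg" width="420" height="360" viewBox="0 0 420 360">',
    '<defs><marker id="arr" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="6" markerHeight="6" orient="auto-start-reverse">',
    '<path d="M 0 0 L 10 5 L 0 10 z"/></marker></defs>',
    body, "</svg>"), collapse = "\n")
  txt <- c(sprintf("%-8s %-10s %12s %s", "edge", "kind", "Q [ml/min]",
                   "direction"),
           sprintf("%-8s %-10s %12.2f %s", e$edge, e$kind, e$value,
                   ifelse(e$reversed, "reversed", "forward")))
  if (!is.null(path)) writeLines(svg, path)
  list(svg = svg, edges = e, table = txt)
}
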