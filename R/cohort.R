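#' Per-stratum cohort summary (Table-2 style)
#'
#' Unweighted arithmetic mean and sample standard deviation (n-1
#' denominator) of CSA, TAV and Q per (group, posture, site) stratum.
#' Strata with a single subject report `sd = 0` and are flagged.
#'
#' @param cohort Cohort table of per-site flows.
#' @param measurements Optional measurement table; when supplied, the
#'   descriptive major axis is summarised too.
#' @return Tibble with one row per stratum: `n`, `mean_*`/`sd_*` for
#'   `csa`, `tav`, `q` (and `major_axis` when available), plus a
#'   `single_subject` flag.
#' @export
summarize_cohort <- function(cohort, measurements = NULL) {
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- cohort |>
    dplyr::group_by(.data$group, .data$posture, .data$vessel, .data$side,
                    .data$segment, .data$site) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_csa = mean(.data$csa), sd_csa = sd0(.data$csa),
      mean_tav = mean(.data$tav), sd_tav = sd0(.data$tav),
      mean_q = mean(.data$q), sd_q = sd0(.data$q),
      .groups = "drop") |>
    dplyr::mutate(single_subject = .data$n == 1L)
  if (!is.null(measurements)) {
    ma <- measurements |>
      dplyr::mutate(site = site_key(.data$vessel, .data$side, .data$segment)) |>
      dplyr::group_by(.data$group, .data$posture, .data$site) |>
      dplyr::summarise(mean_major_axis = mean(.data$major_axis),
                       sd_major_axis = sd0(.data$major_axis),
                       .groups = "drop")
    out <- dplyr::left_join(out, ma, by = c("group", "posture", "site"))
  }
  out
}

midranks <- function(x) rank(x, ties.method = "average")

# cache of exact permutation null distributions of the rank sum, keyed
# by group sizes + the pooled midrank multiset (tie pattern); under
# continuous data the key collapses to one entry per (n_a, n_b)
mw_cache <- new.env(parent = emptyenv())

exact_ranksum_tail <- function(ranks, n_a, w_obs) {
  n <- length(ranks)
  key <- paste(n_a, n, paste(signif(sort(ranks), 12), collapse = ","),
               sep = "|")
  dist <- mw_cache[[key]]
  if (is.null(dist)) {
    idx <- utils::combn(n, n_a)
    dist <- colSums(matrix(ranks[idx], nrow = n_a))
    mw_cache[[key]] <- dist
  }
  mu <- n_a * (n + 1) / 2
  # two-sided: permutations at least as extreme (in |W - mu|) as observed
  mean(abs(dist - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Wilcoxon-Mann-Whitney test for two independent samples
#'
#' U computed from midranks (ties get average ranks). The two-sided p is
#' obtained by full enumeration of the permutation distribution when the
#' combined sample size is at most `exact_limit` (default 20, so a
#' 10-vs-10 study is exact), and by the tie-corrected normal
#' approximation with continuity correction otherwise; both p-values are
#' always reported. When every pooled value is identical the test is
#' degenerate and p = 1.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param quantity Label carried into the result.
#' @param method `"auto"` (exact when feasible), `"exact"` or
#'   `"approx"` - selects which p-value populates `p_value`.
#' @param exact_limit Maximum combined n for enumeration.
#' @return One-row tibble: `quantity`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `u` (U statistic of sample a), `p_value`, `p_exact`, `p_approx`,
#'   `method`, `degenerate`, `significant` (p < 0.05).
#' @export
mann_whitney_u <- function(sample_a, sample_b, quantity = "value",
                           method = c("auto", "exact", "approx"),
                           exact_limit = 20L) {
  method <- match.arg(method)
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  n_a <- length(sample_a); n_b <- length(sample_b); n <- n_a + n_b
  pooled <- c(sample_a, sample_b)
  r <- midranks(pooled)
  w_a <- sum(r[seq_len(n_a)])
  u <- w_a - n_a * (n_a + 1) / 2
  degenerate <- length(unique(pooled)) == 1L

  p_exact <- NA_real_
  if (degenerate) {
    p_exact <- 1
  } else if (n <= exact_limit) {
    p_exact <- exact_ranksum_tail(r, n_a, w_a)
  } else if (method == "exact") {
    stop("exact enumeration limited to combined n <= ", exact_limit,
         call. = FALSE)
  }

  # normal approximation with tie correction and continuity correction
  if (degenerate) {
    p_approx <- 1
  } else {
    ties <- table(pooled)
    mu <- n_a * n_b / 2
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p_approx <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }

  p <- switch(method,
    auto = if (!is.na(p_exact)) p_exact else p_approx,
    exact = p_exact,
    approx = p_approx)
  used <- if (method == "approx" || is.na(p_exact)) "approx" else "exact"
  tibble::tibble(
    quantity = quantity, n_a = n_a, n_b = n_b,
    mean_a = mean(sample_a), mean_b = mean(sample_b),
    u = u, p_value = p, p_exact = p_exact, p_approx = p_approx,
    method = used, degenerate = degenerate, significant = p < 0.05)
}

subject_quantities <- function(cohort, denominator = "matched") {
  # subjects missing model sites keep their per-site quantities but get
  # no network aggregates or indexes (excluded from those comparisons)
  complete_ids <- unlist(lapply(split(cohort, cohort$subject_id),
                                function(fl) if (all(vapply(
                                  split(fl, fl$posture),
                                  function(x) length(validate_subject(x)) == 0,
                                  logical(1)))) fl$subject_id[1] else NULL))
  complete <- cohort[cohort$subject_id %in% complete_ids, ]
  idx <- cohort_indexes(cohort_table(complete), denominator)
  sols <- solve_cohort(cohort, skip_incomplete = TRUE)
  agg <- dplyr::bind_rows(lapply(sols, function(s) tibble::tibble(
    subject_id = s$subject_id, posture = s$posture,
    HBinF = s$hbinf, CBF = s$cbf, CVO = s$cvo, HBoutF = s$hboutf,
    Q_CP = s$q_cp, Q_CD = s$q_cd)))
  persite <- cohort |>
    dplyr::select("subject_id", "posture", "site", "q") |>
    tidyr::pivot_wider(names_from = "site", values_from = "q",
                       names_prefix = "Q_")
  cohort |>
    dplyr::distinct(.data$subject_id, .data$posture) |>
    dplyr::left_join(
      idx |>
        dplyr::select("subject_id", "posture", "dcvo", "djvdi", "cfi",
                      "ccdi") |>
        dplyr::rename(DCVO = "dcvo", DJVDI = "djvdi", CFI = "cfi",
                      CCDI = "ccdi"),
      by = c("subject_id", "posture")) |>
    dplyr::left_join(agg, by = c("subject_id", "posture")) |>
    dplyr::left_join(persite, by = c("subject_id", "posture"))
}

#' Compare two cohorts quantity by quantity
#'
#' Builds every per-subject quantity (per-site flows, the aggregate
#' HBinF/CBF/CVO/HBoutF, and the four drainage indexes) in each cohort
#' and runs [mann_whitney_u()] per quantity and posture. Subjects
#' missing a quantity are excluded from that comparison (with `n_a`/
#' `n_b` reporting what remained). No multiplicity or demographic
#' adjustment is applied.
#'
#' @param hc,pt Cohort tables (reference and comparison group).
#' @param quantities Optional character vector restricting the
#'   comparisons (matched against the quantity column names).
#' @param method Passed to [mann_whitney_u()].
#' @return Tibble of comparison rows, one per quantity and posture.
#' @export
compare_cohorts <- function(hc, pt, quantities = NULL,
                            method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  qa <- subject_quantities(hc)
  qb <- subject_quantities(pt)
  common <- intersect(names(qa), names(qb))
  vars <- setdiff(common, c("subject_id", "posture"))
  if (!is.null(quantities)) vars <- intersect(vars, quantities)
  out <- list()
  for (p in intersect(unique(qa$posture), unique(qb$posture))) {
    a_p <- qa[qa$posture == p, ]
    b_p <- qb[qb$posture == p, ]
    for (v in vars) {
      a <- a_p[[v]][!is.na(a_p[[v]])]
      b <- b_p[[v]][!is.na(b_p[[v]])]
      if (length(a) == 0 || length(b) == 0) next
      res <- mann_whitney_u(a, b, quantity = v, method = method)
      res$posture <- p
      out[[length(out) + 1L]] <- res
    }
  }
  dplyr::bind_rows(out)
}

segment_order <- c("J3", "J2", "J1", "C45", "V2", "none")
side_order <- c("right", "left")

#' Render cohort summary and comparison reports
#'
#' Fixed-width text report in the printed-table layout (group, posture,
#' segments J3 to J1 then VV, right side before left) plus machine-
#' readable CSV of both tables.
#'
#' @param summaries Output of [summarize_cohort()].
#' @param comparisons Output of [compare_cohorts()] (optional).
#' @param dir Optional output directory for `summary.csv`,
#'   `comparisons.csv` and `report.txt`.
#' @return Character vector of report lines, invisibly when `dir` is
#'   given.
#' @export
render_tables <- function(summaries, comparisons = NULL, dir = NULL) {
  s <- summaries |>
    dplyr::arrange(factor(.data$group, levels = cvo_groups),
                   factor(.data$posture, levels = cvo_postures),
                   factor(.data$segment, levels = segment_order),
                   factor(.data$side, levels = side_order),
                   .data$vessel)
  lines <- c(
    sprintf("%-6s %-8s %-5s %-5s %-4s %3s %9s %9s %9s %9s %10s %10s",
            "group", "posture", "vess", "seg", "side", "n",
            "CSA.v", "CSA.sd", "TAV.v", "TAV.sd", "Q.v", "Q.sd"),
    sprintf("%-6s %-8s %-5s %-5s %-4s %3d %9.3f %9.3f %9.2f %9.2f %10.2f %10.2f",
            s$group, s$posture, s$vessel, s$segment, s$side, s$n,
            s$mean_csa, s$sd_csa, s$mean_tav, s$sd_tav, s$mean_q, s$sd_q))
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    lines <- c(lines, "",
      sprintf("%-16s %-8s %6s %10s %10s %7s %10s %5s",
              "quantity", "posture", "U", "mean.A", "mean.B", "p",
              "p.approx", "sig"),
      sprintf("%-16s %-8s %6.1f %10.2f %10.2f %7.4g %10.4g %5s",
              comparisons$quantity, comparisons$posture, comparisons$u,
              comparisons$mean_a, comparisons$mean_b,
              comparisons$p_value, comparisons$p_approx,
              ifelse(comparisons$significant, "*", "")))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(s, file.path(dir, "summary.csv"))
    if (!is.null(comparisons))
      readr::write_csv(comparisons, file.path(dir, "comparisons.csv"))
    writeLines(lines, file.path(dir, "report.txt"))
    return(invisible(lines))
  }
  lines
}
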